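# In-silico PCR: IUPAC-aware primer-site scanning and amplicon extraction.
#
# Matching semantics: a template base matches a pattern letter iff the
# template letter's expansion set is a subset of the pattern letter's
# (so a concrete base matches iff it belongs to the pattern expansion,
# and an ambiguous template base such as N counts as a mismatch unless
# fully contained).  A site additionally requires a mismatch-free 3'
# clamp, mirroring the polymerase's intolerance of 3'-terminal
# mismatches.

#' Count IUPAC-aware mismatches between a pattern and a template window
#'
#' @param pattern IUPAC DNA string.
#' @param window template DNA string of the same length (IUPAC letters
#'   allowed; ambiguous template letters match only if their expansion is
#'   a subset of the pattern letter's).
#' @return Integer mismatch count.
#' @examples
#' iupacMismatches("CAR", "CAG")  # 0
#' iupacMismatches("CAR", "CAT")  # 1
#' @export
iupacMismatches <- function(pattern, window) {
  p <- toupper(.chars(pattern)); w <- toupper(.chars(window))
  if (length(p) != length(w))
    stop("pattern and window lengths differ (", length(p), " vs ",
         length(w), ")")
  compat <- .compatMatrix()
  sum(!compat[cbind(p, w)])
}

# Scan one strand of a template (given as an uppercase character vector)
# for a pattern.  clampSide says which end of the *pattern as written*
# must be mismatch-free: "right" for a primer scanned in its own
# orientation, "left" when the pattern is the reverse complement of a
# primer (the primer's 3' end then maps to the pattern's first bases).
.scanPattern <- function(tmplChars, pattern, maxMismatch, clampLen,
                         clampSide = c("right", "left")) {
  clampSide <- match.arg(clampSide)
  p <- toupper(.chars(pattern))
  L <- length(p); n <- length(tmplChars)
  empty <- data.frame(start = integer(), end = integer(),
                      mismatches = integer())
  if (L > n) {
    warning("pattern longer than template (", L, " > ", n, ")")
    return(empty)
  }
  compat <- .compatMatrix()
  nWin <- n - L + 1L
  mm <- integer(nWin)
  clampBad <- integer(nWin)
  clampIdx <- if (clampLen <= 0L) integer() else if (clampSide == "right")
    (L - min(clampLen, L) + 1L):L else 1L:min(clampLen, L)
  for (i in seq_len(L)) {
    bad <- !compat[p[[i]], tmplChars[i:(nWin + i - 1L)]]
    mm <- mm + bad
    if (i %in% clampIdx) clampBad <- clampBad + bad
  }
  ok <- which(mm <= maxMismatch & clampBad == 0L)
  data.frame(start = ok, end = ok + L - 1L, mismatches = mm[ok])
}

#' Locate degenerate-primer annealing sites on a contig
#'
#' Scans both strands.  A window qualifies iff its total IUPAC-aware
#' mismatch count is at most `maxMismatch` *and* the `clampLen` positions
#' at the primer's 3' end are mismatch-free.  Coordinates are reported on
#' the forward strand, 1-based inclusive, with a `strand` column giving
#' the annealing strand.
#'
#' @param contig character string, [Biostrings::DNAString], or a named
#'   length-one [Biostrings::DNAStringSet].
#' @param primer a [DegeneratePrimer-class] or an IUPAC pattern string.
#' @param maxMismatch mismatch budget (default 2).
#' @param clampLen length of the mismatch-free 3' clamp (default 3).
#' @param id contig id for the report (taken from names when available).
#' @return `data.frame` with columns `contig_id`, `strand`, `start`,
#'   `end`, `mismatches`, ordered by `start`.
#' @export
findPrimerSites <- function(contig, primer, maxMismatch = 2L, clampLen = 3L,
                            id = NULL) {
  if (maxMismatch < 0L || clampLen < 0L)
    stop("maxMismatch and clampLen must be >= 0")
  s <- .contigString(contig)
  if (is.null(id)) id <- .contigId(contig)
  pat <- if (is(primer, "DegeneratePrimer")) primerPattern(primer) else primer
  ch <- .chars(s); n <- length(ch)
  plus <- .scanPattern(ch, pat, maxMismatch, clampLen, "right")
  minus <- .scanPattern(.chars(revComp(s)), pat, maxMismatch, clampLen,
                        "right")
  out <- rbind(
    if (nrow(plus)) data.frame(contig_id = id, strand = "+",
                               start = plus$start, end = plus$end,
                               mismatches = plus$mismatches),
    if (nrow(minus)) data.frame(contig_id = id, strand = "-",
                                start = n - minus$end + 1L,
                                end = n - minus$start + 1L,
                                mismatches = minus$mismatches))
  if (is.null(out))
    out <- data.frame(contig_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      mismatches = integer())
  out[order(out$start, out$strand), , drop = FALSE]
}

.contigString <- function(contig) {
  if (is(contig, "XStringSet")) {
    if (length(contig) != 1L)
      stop("expected a single contig; got ", length(contig))
    toupper(as.character(contig[[1L]]))
  } else toupper(as.character(contig))
}

.contigId <- function(contig) {
  if (is(contig, "XStringSet") && !is.null(names(contig))) names(contig)[[1L]]
  else "contig"
}

#' Extract amplicons delimited by a degenerate primer pair
#'
#' Every pairing of a forward-primer site with a downstream
#' opposite-strand reverse-primer site is reported (screening favours
#' sensitivity; no shortest-product rule), on both orientations of the
#' template.  The amplicon spans from the 5' end of the forward site to
#' the 5' end of the reverse site inclusive, so its sequence begins with
#' the forward-primer window and ends with the reverse complement of the
#' reverse-primer window.
#'
#' @param contigs a [Biostrings::DNAStringSet] (multi-contig), a single
#'   contig, or a path handled by [readFasta()] upstream.
#' @param fwd,rev forward and reverse [DegeneratePrimer-class] objects.
#' @param maxMismatch per-primer mismatch budget (default 2).
#' @param clampLen mismatch-free 3' clamp length (default 3).
#' @param minLen,maxLen product length window in bp (defaults 50 and
#'   2000).
#' @return `data.frame` with columns `contig_id`, `strand`, `start`,
#'   `end` (forward-strand 1-based inclusive), `length`,
#'   `fwd_mismatches`, `rev_mismatches`, `sequence` (the amplified
#'   strand, 5' to 3' from the forward primer).  Empty when there is no
#'   product.
#' @examples
#' pair <- swfPrimerPair()
#' # a contig with exact planted sites 219 bp apart would yield one row
#' @export
amplify <- function(contigs, fwd, rev, maxMismatch = 2L, clampLen = 3L,
                    minLen = 50L, maxLen = 2000L) {
  if (is(contigs, "XStringSet") && length(contigs) > 1L) {
    parts <- lapply(seq_along(contigs), function(i)
      amplify(contigs[i], fwd, rev, maxMismatch, clampLen, minLen, maxLen))
    return(do.call(rbind, parts))
  }
  s <- .contigString(contigs)
  id <- .contigId(contigs)
  fwdPat <- primerPattern(fwd)
  revSite <- revComp(primerPattern(rev))  # reverse primer's annealing site
  n <- nchar(s)

  ampOneStrand <- function(tmpl) {
    ch <- .chars(tmpl)
    f <- .scanPattern(ch, fwdPat, maxMismatch, clampLen, "right")
    r <- .scanPattern(ch, revSite, maxMismatch, clampLen, "left")
    out <- list()
    for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
      if (r$start[j] <= f$end[i]) next
      len <- r$end[j] - f$start[i] + 1L
      if (len < minLen || len > maxLen) next
      out[[length(out) + 1L]] <- data.frame(
        start = f$start[i], end = r$end[j], length = len,
        fwd_mismatches = f$mismatches[i], rev_mismatches = r$mismatches[j],
        sequence = substr(tmpl, f$start[i], r$end[j]),
        stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }

  plus <- ampOneStrand(s)
  minus <- ampOneStrand(revComp(s))
  rows <- list()
  if (!is.null(plus))
    rows[[1L]] <- cbind(data.frame(contig_id = id, strand = "+"), plus)
  if (!is.null(minus)) {
    minus2 <- minus
    minus2$start <- n - minus$end + 1L
    minus2$end <- n - minus$start + 1L
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(contig_id = id, strand = "-"), minus2)
  }
  if (!length(rows)) {
    return(data.frame(contig_id = character(), strand = character(),
                      start = integer(), end = integer(), length = integer(),
                      fwd_mismatches = integer(), rev_mismatches = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Write an amplicon report (TSV + FASTA)
#'
#' @param amplicons data.frame from [amplify()].
#' @param tsvPath,fastaPath output paths; either may be `NULL` to skip.
#' @param header optional character vector of `#`-prefixed comment lines
#'   prepended to the TSV.
#' @return Invisibly, the amplicon data.frame.
#' @export
writeAmplicons <- function(amplicons, tsvPath = NULL, fastaPath = NULL,
                           header = NULL) {
  if (!is.null(tsvPath)) {
    con <- file(tsvPath, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(header, con)
    cols <- setdiff(names(amplicons), "sequence")
    write.table(amplicons[, cols], con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(fastaPath)) {
    ids <- sprintf("%s_amplicon_%d_%d_%s", amplicons$contig_id,
                   amplicons$start, amplicons$end, amplicons$strand)
    writeFasta(setNames(amplicons$sequence, ids), fastaPath)
  }
  invisible(amplicons)
}
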