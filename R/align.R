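# Global pairwise protein alignment and percent identity, backing the
# identity-based screening of amplified acyltransferase fragments.
# The optimisation is delegated to Biostrings::pairwiseAlignment; identity
# bookkeeping (denominator convention) is handled here.

#' Optimal global alignment with percent identity
#'
#' Needleman-Wunsch global alignment under linear gap scoring
#' (defaults: match +1, mismatch 0, gap -1, i.e. identity-style scoring).
#' Percent identity uses, by default, the total number of alignment
#' columns (gaps included) as denominator - the stricter and more
#' reproducible convention; `denominator = "ungapped"` switches to the
#' BLAST-style count over columns where neither sequence is gapped.
#'
#' @param a,b protein sequences (character or [Biostrings::AAString]).
#' @param match,mismatch,gap scores (gap is the per-position linear gap
#'   score, negative).
#' @param denominator `"columns"` (default) or `"ungapped"`.
#' @return List with `a`, `b` (gapped aligned strings), `score`,
#'   `matches`, `columns`, `identity` (percent) and `denominator`.
#' @examples
#' globalAlign("ACDEFGHIK", "ACDEFGHIR")$identity  # 88.9
#' @export
globalAlign <- function(a, b, match = 1, mismatch = 0, gap = -1,
                        denominator = c("columns", "ungapped")) {
  denominator <- match.arg(denominator)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  if (gap >= 0) stop("gap score must be negative")
  lets <- unique(c(setdiff(.aaLetters(), "*"), "X", "*", "U", "B", "Z"))
  mat <- matrix(mismatch, length(lets), length(lets),
                dimnames = list(lets, lets))
  diag(mat) <- match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap,
    type = "global")
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  ca <- .chars(ga); cb <- .chars(gb)
  matches <- sum(ca == cb & ca != "-")
  columns <- length(ca)
  denom <- if (denominator == "columns") columns
           else sum(ca != "-" & cb != "-")
  list(a = ga, b = gb, score = Biostrings::score(aln), matches = matches,
       columns = columns, identity = 100 * matches / denom,
       denominator = denominator)
}

#' Pairwise percent-identity matrix
#'
#' Convenience wrapper around [globalAlign()] for screening reports
#' (e.g. amplified fragments against reference homologues).
#'
#' @param proteins [Biostrings::AAStringSet] or named character vector.
#' @param ... passed to [globalAlign()].
#' @return Symmetric numeric matrix of percent identities (100 on the
#'   diagonal).
#' @export
identityMatrix <- function(proteins, ...) {
  nms <- names(proteins)
  seqs <- as.character(proteins)
  if (is.null(names(seqs))) names(seqs) <- nms
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%02d", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- globalAlign(seqs[[i]], seqs[[j]], ...)$identity
  }
  m
}
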