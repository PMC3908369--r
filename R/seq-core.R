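# Sequence I/O, translation and the ORF coordinate arithmetic used in
# cluster annotation tables.  Sequences are held in Biostrings containers
# (DNAStringSet / AAStringSet); plain character input is accepted by the
# lower-level operations.

#' Read a FASTA file into a validated Biostrings set
#'
#' Wraps [Biostrings::readBStringSet()] with the checks a screening
#' pipeline needs up front: the file must be non-empty, record ids (first
#' whitespace-delimited token of each header) must be unique, and every
#' residue must belong to the declared alphabet.  Residues are uppercased
#' on read.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @param type `"DNA"` (IUPAC nucleotide codes allowed) or `"AA"`
#'   (20 amino acids plus `*` stop and `X` unknown).
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet],
#'   one element per record, input order preserved.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acgt"), tf)
#' readFasta(tf, "DNA")
#' @export
readFasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate record id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  allowed <- if (type == "DNA") .iupacLetters() else
    c(setdiff(.aaLetters(), "*"), "*", "X")
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) == 0L)
      stop("record '", ids[[i]], "' is empty")
    bad <- setdiff(unique(.chars(seqs[[i]])), allowed)
    if (length(bad)) {
      stop("record '", ids[[i]], "' (record ", i, ", near line ",
           .fastaRecordLine(path, ids[[i]]), ") contains illegal ",
           type, " character(s): ", paste(bad, collapse = ", "))
    }
  }
  if (type == "DNA") Biostrings::DNAStringSet(seqs)
  else Biostrings::AAStringSet(seqs)
}

# Line number of a record's header inside a FASTA file (for error reports).
.fastaRecordLine <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  hit <- grep(paste0("^>", id, "(\\s|$)"), lines)
  if (length(hit)) hit[[1]] else NA_integer_
}

#' Write sequences to FASTA
#'
#' @param x an XStringSet (or named character vector).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' IUPAC-aware reverse complement
#'
#' Complements every IUPAC nucleotide letter (R <-> Y, S <-> S, W <-> W,
#' K <-> M, B <-> V, D <-> H, N <-> N) and reverses the sequence.
#' An involution: `revComp(revComp(x))` equals `x`.
#'
#' @param x character string, [Biostrings::DNAString] or
#'   [Biostrings::DNAStringSet].
#' @return Same class as the input.
#' @examples
#' revComp("AAR")  # "YTT"
#' @export
revComp <- function(x) {
  if (is.character(x)) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  } else {
    Biostrings::reverseComplement(x)
  }
}

#' Translate one reading frame of a nucleotide sequence
#'
#' Standard genetic code (table 1).  Stops are rendered `*`; a trailing
#' partial codon is dropped; ambiguity codons are translated to the unique
#' amino acid when all expansions agree (e.g. `CAR` -> `Q`), else to `X`.
#'
#' @param seq character string or [Biostrings::DNAString].
#' @param frame reading frame, 1, 2 or 3.
#' @param strand `"+"` (translate as given) or `"-"` (translate the
#'   reverse complement; frames are counted on the reverse-complemented
#'   strand).
#' @return An [Biostrings::AAString].
#' @examples
#' translateFrame("ATGGCTTAA")          # MA*
#' translateFrame("CARCAY")             # QH
#' @export
translateFrame <- function(seq, frame = 1L, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (!frame %in% 1:3) stop("frame must be 1, 2 or 3 (got ", frame, ")")
  s <- if (is.character(seq)) Biostrings::DNAString(seq) else seq
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  if (length(s) < frame + 2L)
    stop("sequence too short for frame ", frame)
  s <- Biostrings::subseq(s, start = frame)
  usable <- 3L * (length(s) %/% 3L)
  s <- Biostrings::subseq(s, start = 1L, width = usable)
  Biostrings::translate(s, if.fuzzy.codon = "solve")
}

#' Amino-acid count of an ORF from its table-style coordinates
#'
#' Annotation tables give ORFs as 1-based inclusive nucleotide positions,
#' with `start > end` signalling the reverse strand, the span including
#' the stop codon, and the amino-acid count excluding it:
#' `aa = (|end - start| + 1) / 3 - 1`.
#'
#' @param start,end 1-based inclusive nucleotide positions (vectorised).
#' @return Integer vector of amino-acid counts.
#' @examples
#' orfAaLength(26422, 33471)  # 2349
#' orfAaLength(4873, 1796)    # 1025 (reverse strand)
#' @export
orfAaLength <- function(start, end) {
  span <- abs(end - start) + 1
  if (any(span %% 3 != 0))
    stop("ORF span not divisible by 3 for (start, end) = (",
         paste(start[span %% 3 != 0], end[span %% 3 != 0], sep = ", ",
               collapse = "), ("), ")")
  as.integer(span / 3 - 1)
}

#' Find complete open reading frames on both strands
#'
#' Reports every maximal start-codon-to-stop span (default start `ATG`)
#' on both strands with at least `minAa` encoded amino acids (stop codon
#' excluded).  Coordinates follow the annotation-table convention:
#' 1-based inclusive, stop codon included in the span, and
#' `start > end` on the reverse strand.
#'
#' @param seq character string or [Biostrings::DNAString].
#' @param minAa minimum amino-acid count (>= 1).
#' @param id contig id used in the report (default `"contig"`).
#' @param startCodons allowed start codons; `ATG` only by default, add
#'   `GTG`/`TTG` for bacterial-style alternative starts.
#' @return `data.frame` with columns `contig_id`, `start`, `end`,
#'   `strand`, `aa_length`, `protein`.
#' @export
findOrfs <- function(seq, minAa = 50L, id = "contig", startCodons = "ATG") {
  if (minAa < 1L) stop("minAa must be >= 1")
  s <- toupper(as.character(seq))
  n <- nchar(s)
  rows <- list()
  for (strand in c("+", "-")) {
    tmpl <- if (strand == "+") s else revComp(s)
    for (frame in 1:3) {
      nCodon <- (n - frame + 1L) %/% 3L
      if (nCodon < minAa + 1L) next
      starts <- frame + 3L * (seq_len(nCodon) - 1L)
      codons <- substring(tmpl, starts, starts + 2L)
      aa <- Biostrings::GENETIC_CODE[codons]
      aa[is.na(aa)] <- "X"  # ambiguity codons cannot start/stop an ORF here
      isStart <- codons %in% startCodons
      isStop <- aa == "*"
      segStart <- 1L
      for (stop_i in which(isStop)) {
        cand <- which(isStart[segStart:(stop_i - 1L)])
        if (stop_i > segStart && length(cand)) {
          m <- segStart + cand[[1L]] - 1L
          aaLen <- stop_i - m
          if (aaLen >= minAa) {
            ntStart <- frame + 3L * (m - 1L)
            ntEnd <- frame + 3L * stop_i - 1L
            if (strand == "-") {
              tmp <- ntStart
              ntStart <- n - tmp + 1L
              ntEnd <- n - ntEnd + 1L
            }
            rows[[length(rows) + 1L]] <- data.frame(
              contig_id = id, start = ntStart, end = ntEnd, strand = strand,
              aa_length = aaLen,
              protein = paste(aa[m:(stop_i - 1L)], collapse = ""),
              stringsAsFactors = FALSE)
          }
        }
        segStart <- stop_i + 1L
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      aa_length = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(pmin(out$start, out$end), out$strand), , drop = FALSE]
}

#' Write an ORF report as TSV
#'
#' Columns `contig_id`, `start`, `end`, `strand`, `aa_length` in the
#' table coordinate convention produced by [findOrfs()].
#'
#' @param orfs data.frame from [findOrfs()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeOrfReport <- function(orfs, path) {
  write.table(orfs[, c("contig_id", "start", "end", "strand", "aa_length")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
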