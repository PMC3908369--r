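# Degenerate primer design: reverse translation of conserved protein
# motifs into minimally degenerate IUPAC patterns.
#
# Case carries meaning in a motif: an uppercase residue contributes the
# minimal IUPAC pattern covering its standard codons (position-wise union
# of codon bases); a lowercase residue marks a low-confidence position and
# contributes fully degenerate NNN.

#' DegeneratePrimer class
#'
#' A degenerate oligonucleotide derived from a conserved protein motif.
#' The pattern is written 5' to 3'; a reverse-orientation primer is the
#' IUPAC-aware reverse complement of the motif's coding-strand pattern and
#' anneals to the coding strand.
#'
#' @slot name primer name.
#' @slot pattern IUPAC DNA pattern, 5' to 3'.
#' @slot sourceMotif protein motif the pattern was derived from
#'   (lowercase = fully degenerate position).
#' @slot orientation `"forward"` or `"reverse"`.
#' @slot degeneracy number of concrete DNA sequences the pattern covers
#'   (product of per-position IUPAC expansion counts).
#' @seealso [makePrimer()], [reverseTranslateMotif()]
#' @export
setClass("DegeneratePrimer",
  representation(name = "character", pattern = "character",
                 sourceMotif = "character", orientation = "character",
                 degeneracy = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@orientation %in% c("forward", "reverse"))
      msg <- c(msg, "orientation must be 'forward' or 'reverse'")
    if (nchar(object@pattern) != 3L * nchar(object@sourceMotif))
      msg <- c(msg, "pattern length must be 3 x motif length")
    if (!isTRUE(all.equal(object@degeneracy,
                          patternDegeneracy(object@pattern))))
      msg <- c(msg, "degeneracy does not match the pattern")
    if (length(msg)) msg else TRUE
  })

#' @describeIn DegeneratePrimer primer name.
#' @param object,x a `DegeneratePrimer`.
#' @export
setGeneric("primerName", function(x) standardGeneric("primerName"))
#' @export
setMethod("primerName", "DegeneratePrimer", function(x) x@name)

#' @describeIn DegeneratePrimer IUPAC pattern, 5' to 3'.
#' @export
setGeneric("primerPattern", function(x) standardGeneric("primerPattern"))
#' @export
setMethod("primerPattern", "DegeneratePrimer", function(x) x@pattern)

#' @describeIn DegeneratePrimer source protein motif.
#' @export
setGeneric("primerMotif", function(x) standardGeneric("primerMotif"))
#' @export
setMethod("primerMotif", "DegeneratePrimer", function(x) x@sourceMotif)

#' @describeIn DegeneratePrimer orientation.
#' @export
setGeneric("primerOrientation",
           function(x) standardGeneric("primerOrientation"))
#' @export
setMethod("primerOrientation", "DegeneratePrimer", function(x) x@orientation)

#' @describeIn DegeneratePrimer degeneracy (number of covered sequences).
#' @export
setGeneric("primerDegeneracy",
           function(x) standardGeneric("primerDegeneracy"))
#' @export
setMethod("primerDegeneracy", "DegeneratePrimer", function(x) x@degeneracy)

setMethod("show", "DegeneratePrimer", function(object) {
  cat("DegeneratePrimer ", object@name, " (", object@orientation, ")\n",
      "  motif:      ", object@sourceMotif, "\n",
      "  pattern:    5'-", object@pattern, "-3' (",
      nchar(object@pattern), " nt)\n",
      "  degeneracy: ", format(object@degeneracy, big.mark = ","), "\n",
      sep = "")
})

#' Reverse-translate a protein motif into a degenerate IUPAC pattern
#'
#' Each uppercase residue becomes the position-wise minimal IUPAC cover of
#' its standard codons (`Q` -> `CAR`, `W` -> `TGG`); each lowercase residue
#' is treated as fully variable and becomes `NNN`.  For residues whose
#' codon set is a Cartesian product over positions (all amino acids except
#' Ser, Leu and Arg) the pattern covers exactly the codon set; for
#' Ser/Leu/Arg the single-oligo union necessarily over-covers.
#'
#' @param motif protein motif string; case carries meaning.
#' @return IUPAC DNA string of length `3 * nchar(motif)`.
#' @examples
#' reverseTranslateMotif("QW")   # "CARTGG"
#' reverseTranslateMotif("s")    # "NNN"
#' @export
reverseTranslateMotif <- function(motif) {
  res <- .chars(motif)
  aaOk <- setdiff(.aaLetters(), "*")
  out <- vapply(res, function(r) {
    if (r %in% letters) return("NNN")
    if (!r %in% aaOk)
      stop("not an amino-acid letter: '", r, "' in motif ", motif)
    codons <- .codonsFor(r)
    paste(vapply(1:3, function(p) {
      .iupacFromBases(substring(codons, p, p))
    }, character(1)), collapse = "")
  }, character(1))
  paste(out, collapse = "")
}

#' Degeneracy of an IUPAC pattern
#'
#' Product over positions of the IUPAC expansion counts; invariant under
#' reverse complementation.
#'
#' @param pattern IUPAC DNA string.
#' @return Numeric scalar.
#' @examples
#' patternDegeneracy("CARTGG")  # 2
#' @export
patternDegeneracy <- function(pattern) {
  prod(.degeneracyPerLetter(.chars(pattern)))
}

#' Build a degenerate primer from a protein motif
#'
#' A forward primer is the reverse translation of the motif; a reverse
#' primer is its IUPAC-aware reverse complement (it anneals to the coding
#' strand).  Degeneracy is unchanged by reverse complementation.
#'
#' @param name primer name.
#' @param motif source protein motif (case carries meaning, see
#'   [reverseTranslateMotif()]).
#' @param orientation `"forward"` or `"reverse"`.
#' @return A [DegeneratePrimer-class] object.
#' @examples
#' makePrimer("SWF_ATF", "FSGQGTQW", "forward")
#' @export
makePrimer <- function(name, motif, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  pat <- reverseTranslateMotif(motif)
  if (orientation == "reverse") pat <- revComp(pat)
  new("DegeneratePrimer", name = name, pattern = pat, sourceMotif = motif,
      orientation = orientation, degeneracy = patternDegeneracy(pat))
}

#' Built-in primer pairs of the swf screening workflow
#'
#' `atPrimerPair()` returns the broad acyltransferase screening pair
#' AT1F/AT3R2, designed from the conserved regions `FPGQGsQW` (the
#' lowercase position is fully degenerate) and `QGEIAAA`.
#' `swfPrimerPair()` returns the swf-specific pair SWF_ATF/SWF_ATR,
#' designed from `FSGQGTQW` and the swf signature `QCALVEL`.
#'
#' @return A named list with elements `fwd` and `rev`.
#' @examples
#' swfPrimerPair()
#' @export
atPrimerPair <- function() {
  list(fwd = makePrimer("AT1F", "FPGQGsQW", "forward"),
       rev = makePrimer("AT3R2", "QGEIAAA", "reverse"))
}

#' @rdname atPrimerPair
#' @export
swfPrimerPair <- function() {
  list(fwd = makePrimer("SWF_ATF", "FSGQGTQW", "forward"),
       rev = makePrimer("SWF_ATR", "QCALVEL", "reverse"))
}

#' Read or write primer definitions as TSV
#'
#' Columns: `name`, `motif`, `orientation`, `pattern`, `degeneracy`.
#' On read, primers are rebuilt from name/motif/orientation and checked
#' against the stored pattern.
#'
#' @param primers list of [DegeneratePrimer-class] objects.
#' @param path file path.
#' @return `writePrimers` returns `path` invisibly; `readPrimers` a list
#'   of primers.
#' @export
writePrimers <- function(primers, path) {
  df <- do.call(rbind, lapply(primers, function(p) data.frame(
    name = primerName(p), motif = primerMotif(p),
    orientation = primerOrientation(p), pattern = primerPattern(p),
    degeneracy = primerDegeneracy(p), stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePrimers
#' @export
readPrimers <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    p <- makePrimer(df$name[i], df$motif[i], df$orientation[i])
    if (primerPattern(p) != df$pattern[i])
      stop("stored pattern for primer '", df$name[i],
           "' does not match its motif")
    p
  })
}
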