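# IUPAC nucleotide semantics shared by primer design and in-silico PCR.
# All lookups are built once from Biostrings::IUPAC_CODE_MAP at load time.

.pkgCache <- new.env(parent = emptyenv())

.iupacLetters <- function() names(Biostrings::IUPAC_CODE_MAP)

#' Bases covered by an IUPAC nucleotide letter
#'
#' @param letter single IUPAC letter (case-insensitive).
#' @return Character vector of concrete bases (subset of A, C, G, T).
#' @examples
#' iupacBases("R")  # A, G
#' @export
iupacBases <- function(letter) {
  letter <- toupper(letter)
  map <- Biostrings::IUPAC_CODE_MAP
  if (!letter %in% names(map))
    stop("not an IUPAC nucleotide letter: '", letter, "'")
  strsplit(map[[letter]], "")[[1]]
}

# Logical matrix compat[p, t]: TRUE when the expansion of template letter t
# is a subset of the expansion of pattern letter p.  A concrete template
# base therefore matches iff it belongs to the pattern letter's expansion;
# an ambiguous template letter matches only when fully contained.
.compatMatrix <- function() {
  if (!is.null(.pkgCache$compat)) return(.pkgCache$compat)
  lets <- .iupacLetters()
  sets <- lapply(lets, iupacBases)
  names(sets) <- lets
  m <- matrix(FALSE, length(lets), length(lets), dimnames = list(lets, lets))
  for (p in lets) for (t in lets)
    m[p, t] <- all(sets[[t]] %in% sets[[p]])
  .pkgCache$compat <- m
  m
}

# Inverse IUPAC map: sorted concatenation of bases -> ambiguity letter.
.iupacFromBases <- function(bases) {
  if (is.null(.pkgCache$inv)) {
    lets <- .iupacLetters()
    keys <- vapply(lets, function(l) paste(sort(iupacBases(l)), collapse = ""),
                   character(1))
    .pkgCache$inv <- setNames(lets, keys)
  }
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  out <- .pkgCache$inv[[key]]
  if (is.null(out)) stop("no IUPAC letter for base set: ", key)
  out
}

.degeneracyPerLetter <- function(letters) {
  vapply(toupper(letters), function(l) length(iupacBases(l)), numeric(1))
}

# Split a string into single characters.
.chars <- function(x) strsplit(as.character(x), "")[[1]]

# Standard genetic code, codon -> amino acid, from Biostrings.
.codonsFor <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == aa]
}

.aaLetters <- function() sort(unique(Biostrings::GENETIC_CODE))  # 20 aa + "*"
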