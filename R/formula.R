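# Chemical formulas as element-count maps, with the arithmetic used in
# proteoform analysis (adduct addition, apo/holo differences, disulfide
# dimers).

#' ChemicalFormula class
#'
#' An elemental composition: a named map element symbol -> non-negative
#' integer count.  Only elements present in the bundled isotope table
#' (see [isotopeTable()]) are accepted.
#'
#' @slot counts named integer vector of element counts.
#' @seealso [parseFormula()], [monoisotopicMass()], [formulaString()]
#' @export
setClass("ChemicalFormula",
  representation(counts = "integer"),
  validity = function(object) {
    msg <- character()
    cnt <- object@counts
    if (is.null(names(cnt)) || any(names(cnt) == ""))
      msg <- c(msg, "counts must be a named vector")
    bad <- setdiff(names(cnt), isotopeTable()$element)
    if (length(bad))
      msg <- c(msg, paste0("unknown element symbol(s): ",
                           paste(bad, collapse = ", ")))
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "ChemicalFormula", function(object) {
  cat("ChemicalFormula:", formulaString(object), "\n")
  cat("  monoisotopic mass:", format(monoisotopicMass(object), nsmall = 4),
      "amu\n")
})

#' Parse a Hill-style chemical formula string
#'
#' Accepts element symbols followed by optional counts (implicit count
#' 1), e.g. `"C449H704N134O140S3"` or `"H2O"`.  Serialization with
#' [formulaString()] round-trips.
#'
#' @param text formula string.
#' @return A [ChemicalFormula-class] object.
#' @examples
#' parseFormula("C460H724N136O146PS4")
#' @export
parseFormula <- function(text) {
  text <- gsub("\\s", "", as.character(text))
  if (!nchar(text)) stop("empty formula string")
  rx <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (paste(tokens, collapse = "") != text)
    stop("malformed formula: '", text, "'")
  el <- sub("[0-9]*$", "", tokens)
  nstr <- sub("^[A-Za-z]+", "", tokens)
  cnt <- as.integer(ifelse(nstr == "", "1", nstr))
  counts <- tapply(cnt, el, sum)
  counts <- setNames(as.integer(counts), names(counts))
  new("ChemicalFormula", counts = counts)
}

#' Serialize a formula in Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetically;
#' count 1 is implicit; zero-count elements are dropped.
#'
#' @param f a [ChemicalFormula-class].
#' @return Character scalar.
#' @export
formulaString <- function(f) {
  cnt <- f@counts[f@counts > 0]
  els <- names(cnt)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste(vapply(ord, function(e) {
    if (cnt[[e]] == 1L) e else paste0(e, cnt[[e]])
  }, character(1)), collapse = "")
}

#' Element counts of a formula
#'
#' @param f a [ChemicalFormula-class].
#' @return Named integer vector.
#' @export
formulaCounts <- function(f) f@counts

.alignCounts <- function(a, b) {
  els <- union(names(a@counts), names(b@counts))
  ca <- setNames(integer(length(els)), els); ca[names(a@counts)] <- a@counts
  cb <- setNames(integer(length(els)), els); cb[names(b@counts)] <- b@counts
  list(a = ca, b = cb)
}

#' Formula arithmetic
#'
#' Elementwise sum, difference and integer multiple.  Subtraction errors
#' when any count would become negative (e.g. apo minus holo).
#' The operators `+`, `-` and `*` are also available.
#'
#' @param a,b [ChemicalFormula-class] objects.
#' @param k non-negative integer multiplier.
#' @return A [ChemicalFormula-class].
#' @examples
#' holo <- parseFormula("C460H724N136O146PS4")
#' apo <- parseFormula("C449H704N134O140S3")
#' formulaString(formulaSubtract(holo, apo))  # "C11H20N2O6PS"
#' @export
formulaAdd <- function(a, b) {
  al <- .alignCounts(a, b)
  new("ChemicalFormula", counts = al$a + al$b)
}

#' @rdname formulaAdd
#' @export
formulaSubtract <- function(a, b) {
  al <- .alignCounts(a, b)
  d <- al$a - al$b
  if (any(d < 0))
    stop("negative count for element(s): ",
         paste(names(d)[d < 0], collapse = ", "))
  new("ChemicalFormula", counts = d)
}

#' @rdname formulaAdd
#' @export
formulaMultiply <- function(a, k) {
  k <- as.integer(k)
  if (k < 0) stop("multiplier must be non-negative")
  new("ChemicalFormula", counts = a@counts * k)
}

#' @export
setMethod("+", signature("ChemicalFormula", "ChemicalFormula"),
          function(e1, e2) formulaAdd(e1, e2))
#' @export
setMethod("-", signature("ChemicalFormula", "ChemicalFormula"),
          function(e1, e2) formulaSubtract(e1, e2))
#' @export
setMethod("*", signature("ChemicalFormula", "numeric"),
          function(e1, e2) formulaMultiply(e1, e2))

#' Phosphopantetheinylation adduct formulas
#'
#' Phosphopantetheinylation of an acyl carrier protein serine adds, in
#' the canonical even-electron description, phosphopantetheine
#' (dihydrogenophosphate form, 358) minus water: `C11H21N2O6PS`, nominal
#' mass 340.  The experimentally established shift, however, is 339,
#' corresponding to the odd-electron (radical) fragment `C11H20N2O6PS` -
#' consistent with the holo protein being observed as a disulfide-linked
#' species whose S-S bond cleaves homolytically in the ESI source.
#'
#' @param apo apo-protein [ChemicalFormula-class].
#' @param variant `"radical"` (adds `C11H20N2O6PS`, nominal 339; this
#'   reproduces the printed holo formula) or `"even_electron"` (adds
#'   `C11H21N2O6PS`, nominal 340).
#' @return The holo-form [ChemicalFormula-class].
#' @examples
#' apo <- parseFormula("C449H704N134O140S3")
#' formulaString(ppantAdduct(apo))  # "C460H724N136O146PS4"
#' @export
ppantAdduct <- function(apo, variant = c("radical", "even_electron")) {
  variant <- match.arg(variant)
  adduct <- parseFormula(
    if (variant == "radical") "C11H20N2O6PS" else "C11H21N2O6PS")
  formulaAdd(apo, adduct)
}

#' Disulfide dimer of a thiol-bearing proteoform
#'
#' Oxidative S-S coupling of two monomers: `2 x f - H2`.
#'
#' @param f monomer [ChemicalFormula-class] (needs at least 2 H).
#' @return Dimer [ChemicalFormula-class].
#' @export
disulfideDimer <- function(f) {
  if (is.na(f@counts["H"]) || f@counts[["H"]] < 2L)
    stop("monomer must contain at least 2 hydrogen atoms")
  formulaSubtract(formulaMultiply(f, 2L), parseFormula("H2"))
}
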