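# Isotope masses/abundances, monoisotopic masses, unit-mass-binned
# isotope patterns by per-element convolution, and charge-state m/z
# prediction for positive-mode ESI of proteins.

# CIAAW/NIST standard atomic masses and isotopic abundances, pinned so
# every report is reproducible and discrepancies with other calculators
# are attributable to the table, not the algorithm.
.ISOTOPE_TABLE_VERSION <- "CIAAW-2021/NIST"

.isotopeData <- function() {
  if (!is.null(.pkgCache$isotopes)) return(.pkgCache$isotopes)
  tab <- rbind(
    data.frame(element = "H", massNumber = c(1L, 2L),
               mass = c(1.00782503207, 2.01410177785),
               abundance = c(0.999885, 0.000115)),
    data.frame(element = "C", massNumber = c(12L, 13L),
               mass = c(12.0, 13.00335483507),
               abundance = c(0.9893, 0.0107)),
    data.frame(element = "N", massNumber = c(14L, 15L),
               mass = c(14.00307400443, 15.00010889888),
               abundance = c(0.99636, 0.00364)),
    data.frame(element = "O", massNumber = c(16L, 17L, 18L),
               mass = c(15.99491461957, 16.99913175650, 17.99915961286),
               abundance = c(0.99757, 0.00038, 0.00205)),
    data.frame(element = "P", massNumber = 31L,
               mass = 30.97376199842, abundance = 1.0),
    data.frame(element = "S", massNumber = c(32L, 33L, 34L, 36L),
               mass = c(31.9720711744, 32.9714589098, 33.967867004,
                        35.96708071),
               abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
  )
  .pkgCache$isotopes <- tab
  tab
}

#' Bundled isotope table
#'
#' Masses (amu) and natural abundances of the isotopes of C, H, N, O, P
#' and S, with the table version recorded in the `"version"` attribute
#' and echoed in every workflow report.
#'
#' @return `data.frame` with columns `element`, `massNumber`, `mass`,
#'   `abundance`.
#' @export
isotopeTable <- function() {
  tab <- .isotopeData()
  attr(tab, "version") <- .ISOTOPE_TABLE_VERSION
  tab
}

#' @rdname isotopeTable
#' @export
isotopeTableVersion <- function() .ISOTOPE_TABLE_VERSION

#' Proton mass used for charge-state arithmetic
#'
#' @return Proton mass in amu (positive-mode ESI charge carrier).
#' @export
protonMass <- function() 1.007276466

#' Monoisotopic mass of a formula
#'
#' Sum of element counts times lightest-isotope masses from the bundled
#' isotope table.  Additive over formula sums.
#'
#' @param f a [ChemicalFormula-class] or a formula string.
#' @return Mass in amu.
#' @examples
#' monoisotopicMass("H2O")  # 18.0106
#' @export
monoisotopicMass <- function(f) {
  f <- .asFormula(f)
  tab <- .isotopeData()
  lightest <- vapply(split(tab, tab$element),
                     function(d) d$mass[which.min(d$massNumber)], numeric(1))
  cnt <- f@counts
  sum(cnt * lightest[names(cnt)])
}

#' Nominal (integer) mass of a formula
#'
#' Sum of the lightest-isotope mass numbers; equals the monoisotopic
#' mass rounded to the nearest integer for the molecules handled here.
#'
#' @param f a [ChemicalFormula-class] or formula string.
#' @return Integer mass in amu.
#' @examples
#' nominalMass("C11H20N2O6PS")  # 339
#' @export
nominalMass <- function(f) {
  f <- .asFormula(f)
  tab <- .isotopeData()
  lightest <- vapply(split(tab, tab$element),
                     function(d) min(d$massNumber), integer(1))
  cnt <- f@counts
  as.integer(sum(cnt * lightest[names(cnt)]))
}

.asFormula <- function(f) {
  if (is(f, "ChemicalFormula")) f else parseFormula(f)
}

#' IsotopePattern class
#'
#' A unit-mass-binned isotope distribution: one peak per nucleon-count
#' bin at and above the monoisotopic peak, each with the
#' abundance-weighted mean mass of its isotopologues.  Abundances are
#' normalized to a maximum of 1; the un-normalized probability retained
#' after pruning is stored in `totalProb`.
#'
#' @slot mass numeric, strictly increasing neutral masses (amu).
#' @slot abundance numeric in (0, 1], max exactly 1.
#' @slot totalProb un-normalized retained probability (<= 1).
#' @slot formula Hill-order formula string.
#' @seealso [isotopePattern()], [peakMz()]
#' @export
setClass("IsotopePattern",
  representation(mass = "numeric", abundance = "numeric",
                 totalProb = "numeric", formula = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@mass) != length(object@abundance))
      msg <- c(msg, "mass and abundance lengths differ")
    if (is.unsorted(object@mass, strictly = TRUE))
      msg <- c(msg, "masses must be strictly increasing")
    if (length(object@abundance) &&
        (any(object@abundance <= 0) || max(object@abundance) != 1))
      msg <- c(msg, "abundances must be in (0, 1] with max 1")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "IsotopePattern", function(object) {
  cat("IsotopePattern of", object@formula, "-", length(object@mass),
      "unit-mass bins\n")
  top <- order(object@abundance, decreasing = TRUE)[
    seq_len(min(5L, length(object@mass)))]
  for (i in sort(top))
    cat(sprintf("  %12.4f  %.4f\n", object@mass[i], object@abundance[i]))
})

#' @describeIn IsotopePattern peak masses (amu).
#' @param x an `IsotopePattern`.
#' @export
patternMasses <- function(x) x@mass

#' @describeIn IsotopePattern normalized peak abundances.
#' @export
patternAbundances <- function(x) x@abundance

# Convolve two binned patterns.  Each pattern: list(bin = integer nucleon
# offsets, mass = absolute masses, ab = un-normalized probabilities).
.convolvePattern <- function(p1, p2, prune) {
  bins <- outer(p1$bin, p2$bin, `+`)
  ab <- outer(p1$ab, p2$ab)
  wmass <- outer(p1$mass, p2$mass, `+`) * ab
  abAgg <- tapply(as.vector(ab), as.vector(bins), sum)
  mAgg <- tapply(as.vector(wmass), as.vector(bins), sum) / abAgg
  keep <- abAgg >= prune
  list(bin = as.integer(names(abAgg))[keep],
       mass = as.numeric(mAgg[keep]), ab = as.numeric(abAgg[keep]))
}

.patternPower <- function(p, n, prune) {
  result <- NULL
  base <- p
  while (n > 0L) {
    if (n %% 2L == 1L) {
      result <- if (is.null(result)) base
                else .convolvePattern(result, base, prune)
    }
    n <- n %/% 2L
    if (n > 0L) base <- .convolvePattern(base, base, prune)
  }
  result
}

#' Unit-mass-binned isotope pattern of a formula
#'
#' Per-element isotope distributions are convolved (binary powering per
#' element, then across elements), aggregating isotopologues into
#' unit-mass (nucleon-count) bins; each bin's mass is the
#' abundance-weighted mean of its isotopologues.  Peaks below
#' `pruneThreshold` (un-normalized) are dropped after every convolution
#' step, so the retained total probability is >= 1 minus a small
#' multiple of the threshold.
#'
#' @param f a [ChemicalFormula-class] or formula string.
#' @param pruneThreshold per-step pruning threshold on un-normalized
#'   abundance (default `1e-10`; must be <= 1e-3).
#' @return An [IsotopePattern-class].
#' @examples
#' isotopePattern("C449H704N134O140S3")
#' @export
isotopePattern <- function(f, pruneThreshold = 1e-10) {
  if (pruneThreshold <= 0 || pruneThreshold > 1e-3)
    stop("pruneThreshold must be in (0, 1e-3]")
  f <- .asFormula(f)
  tab <- .isotopeData()
  cnt <- f@counts[f@counts > 0]
  if (!length(cnt))
    return(new("IsotopePattern", mass = 0, abundance = 1, totalProb = 1,
               formula = ""))
  total <- NULL
  for (el in names(cnt)) {
    d <- tab[tab$element == el, ]
    d <- d[order(d$massNumber), ]
    single <- list(bin = d$massNumber - d$massNumber[1L],
                   mass = d$mass, ab = d$abundance)
    elPattern <- .patternPower(single, cnt[[el]], pruneThreshold)
    total <- if (is.null(total)) elPattern
             else .convolvePattern(total, elPattern, pruneThreshold)
  }
  ord <- order(total$mass)
  new("IsotopePattern", mass = total$mass[ord],
      abundance = total$ab[ord] / max(total$ab),
      totalProb = sum(total$ab), formula = formulaString(f))
}

#' m/z of a designated isotopic peak at a given charge state
#'
#' Selects the monoisotopic or the most intense unit-mass bin of the
#' isotope pattern and converts to m/z with proton charge carriers:
#' `m/z = (peak mass + z * 1.007276) / z`.
#'
#' @param f a [ChemicalFormula-class], formula string, or an
#'   [IsotopePattern-class] already computed.
#' @param z positive charge state (>= 1).
#' @param which `"most_intense"` (default) or `"monoisotopic"`.
#' @param pruneThreshold passed to [isotopePattern()] when `f` is a
#'   formula.
#' @return `data.frame` with one row: `z`, `which`, `neutral_mass`,
#'   `mz`.
#' @examples
#' peakMz("C449H704N134O140S3", z = 6)$mz  # about 1720.197
#' @export
peakMz <- function(f, z, which = c("most_intense", "monoisotopic"),
                   pruneThreshold = 1e-10) {
  which <- match.arg(which)
  if (z < 1L) stop("charge z must be >= 1")
  pat <- if (is(f, "IsotopePattern")) f else isotopePattern(f, pruneThreshold)
  m <- if (which == "monoisotopic") pat@mass[1L]
       else pat@mass[which.max(pat@abundance)]
  data.frame(z = as.integer(z), which = which, neutral_mass = m,
             mz = (m + z * protonMass()) / z)
}

#' Signed mass error in parts per million
#'
#' `1e6 * (calculated - measured) / calculated`; the sign convention is
#' stated so reports are unambiguous (printed spectra usually report the
#' magnitude).
#'
#' @param measured,calculated m/z or mass values; `calculated` must be
#'   positive.
#' @return ppm error (vectorised).
#' @examples
#' ppmError(1720.1949, 1720.1972)  # about +1.3 ppm
#' @export
ppmError <- function(measured, calculated) {
  if (any(calculated <= 0)) stop("calculated value must be positive")
  1e6 * (calculated - measured) / calculated
}

#' Charge ladder of predicted peaks
#'
#' Monoisotopic and most-intense peak m/z for a range of charge states,
#' as used to read a multiply charged ESI spectrum of a protein.
#'
#' @param f a [ChemicalFormula-class] or formula string.
#' @param zRange integer vector of charge states (default `1:10`).
#' @param pruneThreshold passed to [isotopePattern()].
#' @return `data.frame` with columns `z`, `mz_monoisotopic`,
#'   `mz_most_intense`.
#' @export
chargeLadder <- function(f, zRange = 1:10, pruneThreshold = 1e-10) {
  pat <- isotopePattern(f, pruneThreshold)
  mono <- pat@mass[1L]
  most <- pat@mass[which.max(pat@abundance)]
  data.frame(z = as.integer(zRange),
             mz_monoisotopic = (mono + zRange * protonMass()) / zRange,
             mz_most_intense = (most + zRange * protonMass()) / zRange)
}

#' Match observed peaks to a predicted charge ladder
#'
#' For each observed m/z, finds the nearest predicted most-intense peak
#' across the charge ladder and reports the ppm error.
#'
#' @param peaks `data.frame` with columns `mz` (and optionally
#'   `intensity`), or a numeric vector of m/z values.
#' @param f a [ChemicalFormula-class] or formula string.
#' @param zRange charge states to consider.
#' @param pruneThreshold passed to [isotopePattern()].
#' @return `data.frame` with `mz_observed`, `z`, `mz_calculated`,
#'   `ppm_error`.
#' @export
matchPeaks <- function(peaks, f, zRange = 1:10, pruneThreshold = 1e-10) {
  if (is.numeric(peaks)) peaks <- data.frame(mz = peaks)
  ladder <- chargeLadder(f, zRange, pruneThreshold)
  rows <- lapply(peaks$mz, function(mz) {
    i <- which.min(abs(ladder$mz_most_intense - mz))
    data.frame(mz_observed = mz, z = ladder$z[i],
               mz_calculated = ladder$mz_most_intense[i],
               ppm_error = ppmError(mz, ladder$mz_most_intense[i]))
  })
  do.call(rbind, rows)
}
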