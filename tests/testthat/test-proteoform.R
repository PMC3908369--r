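apoF <- "C449H704N134O140S3"
holoF <- "C460H724N136O146PS4"

test_that("formula parsing is exact and round-trips", {
  f <- parseFormula(apoF)
  expect_equal(formulaCounts(f),
               c(C = 449L, H = 704L, N = 134L, O = 140L, S = 3L))
  expect_equal(formulaString(f), apoF)
  expect_equal(formulaCounts(parseFormula("H2O")), c(H = 2L, O = 1L))
  h <- parseFormula(holoF)   # implicit P count of 1
  expect_equal(formulaCounts(h)[["P"]], 1L)
  expect_equal(formulaString(h), holoF)
  expect_error(parseFormula("C2Qx3"), "unknown element")
  expect_error(parseFormula("2CO"), "malformed")
})

test_that("formula arithmetic supports the apo/holo difference", {
  apo <- parseFormula(apoF); holo <- parseFormula(holoF)
  expect_equal(formulaString(formulaSubtract(holo, apo)), "C11H20N2O6PS")
  expect_equal(formulaString(holo - apo), "C11H20N2O6PS")
  expect_equal(sum(formulaCounts(formulaSubtract(apo, apo))), 0L)
  expect_error(formulaSubtract(apo, holo), "negative")
  expect_equal(formulaString(apo + (holo - apo)), holoF)
})

test_that("monoisotopic masses match the published calculated values", {
  expect_equal(monoisotopicMass("H2O"), 18.0106, tolerance = 0.0005 / 18)
  expect_equal(monoisotopicMass(apoF), 10309.123, tolerance = 0.005 / 10309)
  expect_equal(monoisotopicMass(holoF), 10648.202, tolerance = 0.005 / 10648)
  # additivity over formula sums
  expect_equal(monoisotopicMass(parseFormula(apoF) + parseFormula("H2O")),
               monoisotopicMass(apoF) + monoisotopicMass("H2O"))
})

test_that("phosphopantetheinylation adducts reproduce the 339/340 dichotomy", {
  apo <- parseFormula(apoF)
  expect_equal(formulaString(ppantAdduct(apo, "radical")), holoF)
  expect_equal(nominalMass("C11H20N2O6PS"), 339L)
  expect_equal(nominalMass("C11H21N2O6PS"), 340L)
  dRad <- monoisotopicMass(ppantAdduct(apo, "radical")) - monoisotopicMass(apo)
  expect_true(dRad >= 339.073 && dRad <= 339.083)
  dEven <- monoisotopicMass(ppantAdduct(apo, "even_electron")) -
    monoisotopicMass(apo)
  hMass <- monoisotopicMass("H")
  expect_equal(dEven - dRad, hMass, tolerance = 1e-9)
})

test_that("isotope patterns are normalized, complete and convolutive", {
  pC <- isotopePattern("C")
  expect_equal(patternAbundances(pC)[2] / patternAbundances(pC)[1],
               0.0107 / 0.9893, tolerance = 1e-6)
  pW <- isotopePattern("H2O")
  expect_gt(patternAbundances(pW)[1] / sum(patternAbundances(pW)), 0.99)
  for (f in c("H2O", "C100H150N20O30S2", apoF)) {
    p <- isotopePattern(f)
    expect_equal(p@totalProb, 1, tolerance = 1e-6)
    expect_true(all(diff(patternMasses(p)) > 0))
    expect_equal(max(patternAbundances(p)), 1)
    expect_equal(patternMasses(p)[1], monoisotopicMass(f), tolerance = 1e-9)
  }
  # pattern of a formula sum equals the convolution of the two patterns
  f1 <- "C30H50N8O10"; f2 <- "C25H40N5O8S"
  p12 <- isotopePattern(parseFormula(f1) + parseFormula(f2))
  p1 <- isotopePattern(f1); p2 <- isotopePattern(f2)
  # compare the first few unit-mass bin probabilities
  raw1 <- patternAbundances(p1) / sum(patternAbundances(p1))
  raw2 <- patternAbundances(p2) / sum(patternAbundances(p2))
  raw12 <- patternAbundances(p12) / sum(patternAbundances(p12))
  for (k in 0:4) {
    convK <- sum(vapply(0:k, function(i) {
      a <- if (i + 1 <= length(raw1)) raw1[i + 1] else 0
      b <- if (k - i + 1 <= length(raw2)) raw2[k - i + 1] else 0
      a * b
    }, numeric(1)))
    expect_equal(raw12[k + 1], convK, tolerance = 1e-6)
  }
  expect_error(isotopePattern(apoF, pruneThreshold = 0.1), "pruneThreshold")
})

test_that("charge-state m/z of the most intense peaks match the spectra", {
  apo6 <- peakMz(apoF, 6)
  expect_equal(apo6$mz, 1720.197, tolerance = 0.002 / 1720)
  holo6 <- peakMz(holoF, 6)
  expect_equal(holo6$mz, 1776.710, tolerance = 0.002 / 1776)
  # monoisotopic peak at z=1 sits one proton above the neutral mass
  one <- peakMz(apoF, 1, "monoisotopic")
  expect_equal(one$mz - monoisotopicMass(apoF), protonMass(),
               tolerance = 1e-9)
  # the most intense bin of a ~10 kDa protein lies 5-7 bins above
  # the monoisotopic bin
  p <- isotopePattern(apoF)
  expect_true((which.max(patternAbundances(p)) - 1L) %in% 5:7)
})

test_that("ppm errors carry the stated sign convention", {
  expect_equal(ppmError(1720.1949, 1720.1972), 1.337, tolerance = 0.01)
  expect_equal(ppmError(1776.7079, 1776.7101), 1.238, tolerance = 0.01)
  expect_equal(ppmError(5, 5), 0)
  expect_lt(ppmError(1720.1990, 1720.1972), 0)
})

test_that("disulfide dimers lose H2 and avoid monomer peak coincidence", {
  holo <- parseFormula(holoF)
  dimer <- disulfideDimer(holo)
  expect_equal(formulaString(dimer), "C920H1446N272O292P2S8")
  expect_equal(monoisotopicMass(dimer),
               2 * monoisotopicMass(holo) - monoisotopicMass("H2"),
               tolerance = 1e-9)
  # odd-charged dimer peaks fall between monomer charge states
  dimerZ7 <- peakMz(dimer, 7)$mz
  monomer <- vapply(1:12, function(z) peakMz(holo, z)$mz, numeric(1))
  expect_gt(min(abs(monomer - dimerZ7)), 5)
  expect_error(disulfideDimer(parseFormula("CO2")), "hydrogen")
})
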