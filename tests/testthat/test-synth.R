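test_that("generated proteins carry their family's motif bundle", {
  p <- makeSwfProtein(plantSpec("swf"), seed = 1)
  expect_equal(substr(p$protein, 591, 597), "QCALVEL")
  expect_equal(substr(p$protein, 525, 532), "FSGQGTQW")
  expect_equal(substr(p$protein, 180, 184), "DPQIR")
  expect_equal(substr(p$protein, 1, 1), "M")
  expect_equal(nchar(p$protein), 650)

  d <- makeSwfProtein(plantSpec("cisAT_decoy"), seed = 1)
  expect_true(grepl("DPQQR", d$protein) && grepl("HGTGT", d$protein))
  expect_false(grepl("CALVE", d$protein))

  # determinism under the seed
  expect_identical(makeSwfProtein(plantSpec("swf"), seed = 9)$protein,
                   makeSwfProtein(plantSpec("swf"), seed = 9)$protein)

  # background is scrubbed: the only diagnostic hits are the planted ones
  for (s in 1:5) {
    prot <- makeSwfProtein(plantSpec("swf"), seed = s)$protein
    expect_equal(length(gregexpr("DPQ[QIV]R", prot)[[1]]), 1)
    expect_equal(length(gregexpr(".CALVE.", prot)[[1]]), 1)
    expect_equal(gregexpr("C...C..C", prot)[[1]][1], -1)
  }
})

test_that("plantSpec validates layouts", {
  expect_error(plantSpec("swf", length = 500), "exceed")
  expect_error(plantSpec("swf", strand = "x"), "strand")
  lay <- data.frame(motif = c("QCALVEL", "FSGQGTQW"), position = c(10, 12))
  expect_error(plantSpec("swf", layout = lay), "overlap")
})

test_that("contigs are deterministic and internally consistent with the manifest", {
  cm1 <- makeContig(list(plantSpec("swf")), seed = 33)
  cm2 <- makeContig(list(plantSpec("swf")), seed = 33)
  expect_identical(as.character(cm1$contig), as.character(cm2$contig))

  g <- cm1$manifest$genes[[1]]
  expect_equal(g$family, "swf")
  expect_lt(g$start, g$end)                       # forward strand
  expect_equal(orfAaLength(g$start, g$end), g$aa_length)
  # the planted gene is a real ORF of the contig
  orfs <- findOrfs(cm1$contig[[1]], minAa = 600)
  expect_true(any(orfs$start == g$start & orfs$end == g$end))

  # reverse-strand plant: table convention start > end, still amplifiable
  cmr <- makeContig(list(plantSpec("swf", strand = "-")), seed = 34)
  gr <- cmr$manifest$genes[[1]]
  expect_gt(gr$start, gr$end)
  pair <- swfPrimerPair()
  amp <- amplify(cmr$contig, pair$fwd, pair$rev)
  expect_equal(amp$length, gr$expected_amplicon_length)
  expect_equal(amp$strand, "-")
})

test_that("requested primer-site substitutions are realized exactly", {
  cm <- makeContig(list(plantSpec("swf", fwdMismatches = 2)), seed = 35)
  pair <- swfPrimerPair()
  s2 <- findPrimerSites(cm$contig, pair$fwd, maxMismatch = 2)
  expect_equal(nrow(s2), 1)
  expect_equal(s2$mismatches, 2)
  expect_equal(nrow(findPrimerSites(cm$contig, pair$fwd, maxMismatch = 1)), 0)
  # the reverse site is untouched
  expect_equal(findPrimerSites(cm$contig, pair$rev,
                               maxMismatch = 0)$mismatches, 0)
  # unrealizable request errors
  expect_error(makeContig(list(plantSpec("swf", fwdMismatches = 25)),
                          seed = 36), "cannot realize")
})

test_that("manifests serialize to JSON and back", {
  cm <- makeContig(list(plantSpec("cisAT_decoy")), seed = 37)
  tf <- tempfile(fileext = ".json")
  writeManifest(cm$manifest, tf)
  back <- readManifest(tf)
  expect_equal(back$contig_id, cm$manifest$contig_id)
  expect_equal(back$genes[[1]]$family, "cisAT_decoy")
  expect_equal(back$genes[[1]]$expected_amplicon_length,
               cm$manifest$genes[[1]]$expected_amplicon_length)
})

test_that("alignment simulation follows the uniform-exchange model", {
  # zero-length branches give identical sequences
  t0 <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  aln0 <- simulateAlignment(t0, 200, seed = 3)
  s <- as.character(aln0)
  expect_identical(s[["A"]], s[["B"]])
  expect_identical(s[["A"]], s[["C"]])

  # determinism
  tr <- syntheticPhylogeny()
  expect_identical(as.character(simulateAlignment(tr, 300, seed = 4)),
                   as.character(simulateAlignment(tr, 300, seed = 4)))

  # saturation: at very long path lengths p-distance approaches 19/20
  t2 <- ape::read.tree(text = "(X:25,Y:25);")
  a2 <- as.character(simulateAlignment(t2, 4000, seed = 5))
  pd <- mean(strsplit(a2[["X"]], "")[[1]] != strsplit(a2[["Y"]], "")[[1]])
  expect_equal(pd, 0.95, tolerance = 0.03)

  # expected divergence is increasing in path length
  t3 <- ape::read.tree(text = "((P:0.05,Q:0.05):0.5,R:0.55);")
  a3 <- as.character(simulateAlignment(t3, 4000, seed = 6))
  dPQ <- mean(strsplit(a3[["P"]], "")[[1]] != strsplit(a3[["Q"]], "")[[1]])
  dPR <- mean(strsplit(a3[["P"]], "")[[1]] != strsplit(a3[["R"]], "")[[1]])
  expect_lt(dPQ, dPR)
})
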