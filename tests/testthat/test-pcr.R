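test_that("IUPAC mismatch counting uses expansion-subset semantics", {
  expect_equal(iupacMismatches("CAR", "CAG"), 0)
  expect_equal(iupacMismatches("CAR", "CAT"), 1)
  expect_equal(iupacMismatches("NNN", "GTC"), 0)
  # ambiguous template base: mismatch unless a subset of the pattern letter
  expect_equal(iupacMismatches("N", "R"), 0)
  expect_equal(iupacMismatches("R", "N"), 1)
  expect_equal(iupacMismatches("D", "R"), 0)   # {A,G} within {A,G,T}
  expect_equal(iupacMismatches("R", "D"), 1)
  expect_error(iupacMismatches("CAR", "CA"), "length")
})

test_that("primer-site scanning respects mismatch budget and 3' clamp", {
  set.seed(51)
  fwd <- swfPrimerPair()$fwd
  site <- concretizePattern(primerPattern(fwd))
  contig <- paste0(randomDna(100), site, randomDna(100))

  hits <- findPrimerSites(contig, fwd, maxMismatch = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 101)
  expect_equal(hits$end, 124)
  expect_equal(hits$mismatches, 0)
  expect_equal(hits$strand, "+")

  # minus-strand annealing is reported in plus coordinates
  hitsRc <- findPrimerSites(revComp(contig), fwd, maxMismatch = 0)
  expect_equal(nrow(hitsRc), 1)
  expect_equal(hitsRc$strand, "-")
  expect_equal(hitsRc$start, nchar(contig) - 124 + 1)

  # two substitutions outside the clamp exceed a budget of 1
  site2 <- site
  substr(site2, 2, 2) <- setdiff(c("A","C","G","T"),
                                 iupacBases(substr(primerPattern(fwd),2,2)))[1]
  substr(site2, 5, 5) <- setdiff(c("A","C","G","T"),
                                 iupacBases(substr(primerPattern(fwd),5,5)))[1]
  contig2 <- paste0(randomDna(100), site2, randomDna(100))
  expect_equal(nrow(findPrimerSites(contig2, fwd, maxMismatch = 1)), 0)
  expect_equal(findPrimerSites(contig2, fwd, maxMismatch = 2)$mismatches, 2)

  # a 3'-terminal substitution disqualifies even within the budget
  site3 <- site
  substr(site3, 24, 24) <- "C"  # pattern ends ...TGG; C mismatches G
  contig3 <- paste0(randomDna(100), site3, randomDna(100))
  expect_equal(nrow(findPrimerSites(contig3, fwd, maxMismatch = 2,
                                    clampLen = 3)), 0)
  expect_equal(nrow(findPrimerSites(contig3, fwd, maxMismatch = 2,
                                    clampLen = 0)), 1)
})

test_that("amplify pairs forward sites with downstream reverse sites", {
  set.seed(61)
  pair <- swfPrimerPair()
  fwdSite <- concretizePattern(primerPattern(pair$fwd))       # 24 nt
  revSite <- concretizePattern(revComp(primerPattern(pair$rev)))  # 21 nt
  # forward site at 100; reverse-primer 5' end at position 389
  contig <- paste0(randomDna(99), fwdSite, randomDna(389 - 99 - 24 - 21),
                   revSite, randomDna(150))
  amp <- amplify(contig, pair$fwd, pair$rev)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$start, 100)
  expect_equal(amp$end, 389)
  expect_equal(amp$length, 290)
  expect_true(startsWith(amp$sequence, fwdSite))
  expect_true(endsWith(amp$sequence, revSite))

  # length filter
  expect_equal(nrow(amplify(contig, pair$fwd, pair$rev, minLen = 300)), 0)

  # results are invariant under reverse-complementing the contig
  ampRc <- amplify(revComp(contig), pair$fwd, pair$rev)
  expect_equal(nrow(ampRc), 1)
  expect_equal(ampRc$length, 290)
  expect_equal(ampRc$strand, "-")
  expect_equal(ampRc$sequence, amp$sequence)
  expect_equal(ampRc$start, nchar(contig) - amp$end + 1)
})

test_that("a planted swf gene with motifs 66 codons apart gives a 219 bp product", {
  cm <- makeContig(list(plantSpec("swf")), seed = 42)
  pair <- swfPrimerPair()
  amp <- amplify(cm$contig, pair$fwd, pair$rev)
  expect_equal(amp$length, 219)
  expect_equal(amp$length, cm$manifest$genes[[1]]$expected_amplicon_length)
  # translating in the frame anchored by the forward primer reproduces
  # the forward motif at the protein start
  prot <- as.character(translateFrame(amp$sequence, 1, "+"))
  expect_true(startsWith(prot, "FSGQGTQW"))
  expect_true(endsWith(prot, "QCALVEL"))
})

test_that("exact planted sites are recovered with perfect precision and recall", {
  mg <- makeMetagenome(nSwf = 3, nDecoy = 3, seed = 8)
  pairs <- list(swf = swfPrimerPair(), cisAT_decoy = atPrimerPair())
  for (cid in names(mg$manifest$contigs)) {
    man <- mg$manifest$contigs[[cid]]
    contig <- mg$contigs[cid]
    for (g in man$genes) {
      pair <- pairs[[g$family]]
      for (side in c("fwd", "rev")) {
        found <- findPrimerSites(contig, pair[[side]], maxMismatch = 0)
        truth <- g$sites[[side]]
        # recall: the planted site is found; precision: nothing else is
        expect_equal(nrow(found), 1, info = paste(cid, side))
        expect_equal(found$start, truth$start)
        expect_equal(found$end, truth$end)
        expect_equal(found$strand, truth$strand)
      }
      amp <- amplify(contig, pair$fwd, pair$rev, maxMismatch = 0)
      expect_equal(amp$length, g$expected_amplicon_length)
    }
  }
})
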