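test_that("readFasta normalizes case, preserves order and validates", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgt"), tf)
  x <- readFasta(tf, "DNA")
  expect_length(x, 1)
  expect_equal(as.character(x[[1]]), "ACGT")

  writeLines(c(">a desc", "ACGT", ">b", "GGTT", "AACC"), tf)
  x <- readFasta(tf, "DNA")
  expect_equal(names(x), c("a", "b"))
  expect_equal(as.character(x[[2]]), "GGTTAACC")

  writeLines(c(">a", "ACG9T"), tf)
  expect_error(readFasta(tf, "DNA"), "record 'a'")

  writeLines(c(">a", "ACGT", ">a", "TTTT"), tf)
  expect_error(readFasta(tf, "DNA"), "duplicate")
})

test_that("revComp follows the IUPAC complement table and is an involution", {
  expect_equal(revComp("GATC"), "GATC")
  expect_equal(revComp("AAR"), "YTT")
  expect_equal(revComp("BDHV"), "BDHV")
  set.seed(11)
  lets <- names(Biostrings::IUPAC_CODE_MAP)
  for (i in 1:25) {
    s <- paste(sample(lets, 40, replace = TRUE), collapse = "")
    expect_equal(revComp(revComp(s)), s)
  }
})

test_that("translation follows the standard code with ambiguity solving", {
  expect_equal(as.character(translateFrame("ATGGCTTAA")), "MA*")
  expect_equal(as.character(translateFrame("CAR")), "Q")
  expect_equal(as.character(translateFrame("CAY")), "H")
  expect_equal(as.character(translateFrame("RAY")), "X")
  # oracle: enumerate all expansions of random ambiguity codons
  set.seed(21)
  lets <- names(Biostrings::IUPAC_CODE_MAP)
  for (i in 1:40) {
    codon <- paste(sample(lets, 3, replace = TRUE), collapse = "")
    expect_equal(as.character(translateFrame(codon)),
                 translateCodonOracle(codon), info = codon)
  }
  # trailing partial codon dropped
  expect_equal(as.character(translateFrame("ATGGC")), "M")
  expect_error(translateFrame("ATGGCT", frame = 4), "frame")
})

test_that("reverse-strand translation equals forward translation of the revcomp", {
  set.seed(31)
  for (i in 1:10) {
    s <- randomDna(60 + i)
    for (f in 1:3)
      expect_equal(as.character(translateFrame(s, f, "-")),
                   as.character(translateFrame(revComp(s), f, "+")))
  }
})

test_that("ORF coordinate arithmetic matches the cluster annotation tables", {
  expect_identical(orfAaLength(26422, 33471), 2349L)
  expect_identical(orfAaLength(4873, 1796), 1025L)   # reverse strand
  expect_identical(orfAaLength(33468, 35987), 839L)
  expect_identical(orfAaLength(12302, 19387), 2361L)
  tab <- orfTableRows()
  expect_equal(orfAaLength(tab$start, tab$end), tab$aa)
  # same count regardless of strand encoding
  expect_identical(orfAaLength(1796, 4873), orfAaLength(4873, 1796))
  expect_error(orfAaLength(1, 5), "divisible")
})

test_that("findOrfs reports maximal ATG-to-stop spans on both strands", {
  set.seed(41)
  prot <- paste0("M", randomProtein(99))
  codons <- vapply(strsplit(prot, "")[[1]], function(r) {
    cs <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == r]
    cs[1]
  }, character(1))
  gene <- paste(c(codons, "TAA"), collapse = "")
  # all-C flanks carry no start or stop codons on either strand
  contig <- paste0(strrep("C", 90), gene, strrep("C", 90))
  orfs <- findOrfs(contig, minAa = 50, id = "c1")
  hit <- orfs[orfs$aa_length == 100, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 91)
  expect_equal(hit$end, 91 + 3 * 101 - 1)
  expect_equal(hit$strand, "+")
  expect_equal(hit$protein, prot)
  expect_identical(orfAaLength(hit$start, hit$end), 100L)

  # reverse-strand plant is reported with start > end
  contigRev <- paste0(strrep("C", 90), revComp(gene), strrep("C", 90))
  orfsRev <- findOrfs(contigRev, minAa = 50)
  hitRev <- orfsRev[orfsRev$aa_length == 100, ]
  expect_equal(nrow(hitRev), 1)
  expect_gt(hitRev$start, hitRev$end)
  expect_equal(hitRev$protein, prot)

  # no stop codon => no complete ORF
  expect_equal(nrow(findOrfs(strrep("A", 300), minAa = 10)), 0)
})
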