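test_that("p-distance uses pairwise deletion over gap-free columns", {
  aln <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKL", c = "ACDEFGHIRR")
  D <- pDistance(aln)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.2)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))

  # gap columns are excluded pairwise, not listwise
  aln2 <- c(a = "AAAAAAAAAA", b = "AAAA--AAAC", c = "CC--AAAAAA")
  D2 <- pDistance(aln2)
  expect_equal(D2["a", "b"], 1 / 8)   # 8 comparable columns, 1 differs
  expect_equal(D2["a", "c"], 2 / 8)
  expect_equal(D2["b", "c"], 3 / 6)   # only 6 columns shared

  expect_error(pDistance(c(a = "A-", b = "-A", c = "AA")), "comparable")
  expect_error(pDistance(c(a = "AA", b = "AAA", c = "AA")), "unequal")
})

test_that("three-taxon trees match the closed-form branch lengths", {
  D <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(D)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["a"]], (0.3 + 0.4 - 0.5) / 2, tolerance = 1e-12)
  expect_equal(len[["b"]], (0.3 + 0.5 - 0.4) / 2, tolerance = 1e-12)
  expect_equal(len[["c"]], (0.4 + 0.5 - 0.3) / 2, tolerance = 1e-12)
})

test_that("NJ recovers additive matrices exactly (path-length oracle)", {
  set.seed(111)
  for (n in c(4, 5, 6, 8)) {
    for (rep in 1:5) {
      t0 <- ape::rtree(n)
      D <- pathLengthMatrix(t0)
      t1 <- njTree(D)
      expect_equal(ape::dist.topo(ape::unroot(t0), t1), 0,
                   ignore_attr = TRUE)
      expect_equal(pathLengthMatrix(t1)[rownames(D), colnames(D)], D,
                   tolerance = 1e-8)
    }
  }
  # equidistant matrix: deterministic under the lexicographic tie rule
  De <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(De) <- 0
  expect_equal(ape::write.tree(njTree(De)), ape::write.tree(njTree(De)))
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("bootstrap support is seeded, bounded and saturates on strong signal", {
  # one clade differing from the rest at half the columns
  block <- function(ch, n) strrep(ch, n)
  aln <- c(a1 = paste0(block("A", 50), block("K", 50)),
           a2 = paste0(block("A", 50), block("K", 50)),
           b1 = paste0(block("A", 50), block("R", 50)),
           b2 = paste0(block("A", 50), block("R", 50)))
  tr <- bootstrapSupport(aln, nReplicates = 100, seed = 5)
  sup <- as.numeric(tr$node.label)
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  # the single non-trivial bipartition is present in every replicate
  expect_true(100 %in% sup[-1])

  tr2 <- bootstrapSupport(aln, nReplicates = 100, seed = 5)
  expect_equal(tr$node.label, tr2$node.label)
  tr3 <- bootstrapSupport(aln, nReplicates = 100, seed = 6)
  expect_equal(ape::write.tree(tr3), ape::write.tree(tr3))
})

test_that("outgroup rooting preserves leaf paths and isolates the outgroup", {
  set.seed(121)
  t0 <- ape::rtree(6)
  t0$tip.label <- c("FabB", paste0("ks", 1:5))
  rt <- rootWithOutgroup(t0, "FabB")
  expect_true(ape::is.rooted(rt))
  rootKids <- rt$edge[rt$edge[, 1] == length(rt$tip.label) + 1L, 2]
  expect_true(which(rt$tip.label == "FabB") %in% rootKids)
  D0 <- pathLengthMatrix(ape::unroot(t0))
  D1 <- pathLengthMatrix(rt)[rownames(D0), colnames(D0)]
  expect_equal(D1, D0, tolerance = 1e-10)
  # re-rooting elsewhere and back gives an isomorphic tree
  back <- rootWithOutgroup(rootWithOutgroup(rt, "ks3"), "FabB")
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(rt)), 0,
               ignore_attr = TRUE)
  expect_equal(pathLengthMatrix(back)[rownames(D0), colnames(D0)], D0,
               tolerance = 1e-10)
  expect_error(rootWithOutgroup(t0, "nope"), "not found")
})

test_that("condensation collapses exactly the edges below the cutoff", {
  txt <- "(((a:1,b:1)90:1,(c:1,d:1)30:1)50:1,(e:1,f:1)35:1,g:1);"
  tr <- ape::read.tree(text = txt)
  cond <- condenseTree(tr, 35)
  # the support-30 clade (c,d) dissolves; 35 and above are retained
  labs <- cond$node.label
  expect_false("30" %in% labs)
  expect_true(all(c("90", "50", "35") %in% labs))
  expect_equal(cond$Nnode, tr$Nnode - 1L)
  expect_setequal(cond$tip.label, tr$tip.label)
  # cutoff 0 leaves the tree unchanged
  same <- condenseTree(tr, 0)
  expect_equal(same$Nnode, tr$Nnode)
  expect_equal(ape::dist.topo(same, tr), 0, ignore_attr = TRUE)
})
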