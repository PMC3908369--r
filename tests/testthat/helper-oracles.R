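# Independent oracles and fixtures shared across the suite.

# --- alignment oracles -------------------------------------------------

# Literal enumeration of every global alignment (recursion over the three
# moves, no memoization).  Exponential; for tiny sequences only.
enumAlignScore <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb))
      best <- max(best, (if (ca[i] == cb[j]) match else mismatch) +
                    rec(i + 1, j + 1))
    if (i <= length(ca)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(cb)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Plain iterative Needleman-Wunsch score, written independently of the
# package's Biostrings-backed implementation.
dpAlignScore <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    S[i + 1, j + 1] <- max(
      S[i, j] + if (ca[i] == cb[j]) match else mismatch,
      S[i, j + 1] + gap,
      S[i + 1, j] + gap)
  }
  S[n + 1, m + 1]
}

randomProtein <- function(n) {
  paste(sample(setdiff(unique(Biostrings::GENETIC_CODE), "*"), n,
               replace = TRUE), collapse = "")
}

# --- IUPAC / codon oracles ---------------------------------------------

# All concrete DNA sequences covered by an IUPAC pattern (brute force).
expandIupacPattern <- function(pattern) {
  sets <- lapply(strsplit(pattern, "")[[1]], iupacBases)
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

# All codon concatenations encoding a protein motif (standard code).
codonConcatenations <- function(motif) {
  gc <- Biostrings::GENETIC_CODE
  out <- ""
  for (r in strsplit(motif, "")[[1]]) {
    codons <- names(gc)[gc == r]
    out <- as.vector(outer(out, codons, paste0))
  }
  out
}

# Translate a (possibly ambiguous) codon by enumerating its expansions.
translateCodonOracle <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aas <- unique(gc[expandIupacPattern(codon)])
  if (length(aas) == 1) aas else "X"
}

# Pick one concrete sequence from an IUPAC pattern (first base of each
# expansion set) - used to plant exact primer sites in fixtures.
concretizePattern <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]],
               function(l) iupacBases(l)[1], character(1)), collapse = "")
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- published ORF coordinate tables -----------------------------------

# Coordinate / aa-count rows of the two cluster annotation tables
# (pPS11G3 and pPSA11D7).  Two printed rows are internally inconsistent
# and kept separate: the pPS11G3 ORF1 row (515-1783 / 423: its span gives
# 422 under the convention satisfied by every other row) and the pPSA11D7
# ORF9 row (10469-10784 / 104: span not divisible by 3).
orfTableRows <- function() {
  data.frame(rbind(
    # pPS11G3
    c(4873, 1796, 1025), c(5016, 6143, 375), c(6241, 7743, 500),
    c(7792, 9927, 711), c(10017, 10904, 295), c(10922, 12394, 490),
    c(13621, 12410, 403), c(14889, 13618, 423), c(15102, 16220, 372),
    c(16245, 17453, 402), c(17453, 19066, 537), c(19063, 20667, 534),
    c(20708, 21874, 388), c(21969, 22625, 218), c(23738, 22662, 358),
    c(23842, 25515, 557), c(25597, 25944, 115), c(25987, 26265, 92),
    c(26422, 33471, 2349), c(33468, 35987, 839), c(36003, 37760, 585),
    # pPSA11D7
    c(1564, 488, 358), c(3534, 1570, 654), c(3985, 3695, 96),
    c(4123, 5823, 566), c(5926, 7167, 413), c(7161, 8072, 303),
    c(8069, 9061, 330), c(10431, 9385, 348), c(10837, 12291, 484),
    c(12302, 19387, 2361), c(19396, 21894, 832), c(22917, 21928, 329)
  )) |> setNames(c("start", "end", "aa"))
}

# --- tree oracle --------------------------------------------------------

# Leaf-to-leaf path-length matrix computed by explicit path summation
# over the edge list (independent of ape's cophenetic C code).
pathLengthMatrix <- function(tree) {
  nt <- length(tree$tip.label)
  nodes <- nt + tree$Nnode
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  D <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(nt)) {
    dist <- rep(NA_real_, nodes); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]; w <- adj[[v]][k, 2]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + w
          queue <- c(queue, u)
        }
      }
    }
    D[s, ] <- dist[seq_len(nt)]
  }
  D
}
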