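# Seeded synthetic data: proteins carrying configurable signature-motif
# bundles, contigs with primer sites realized at an exact mismatch count,
# ground-truth manifests verified on write, and alignments simulated down
# a known tree.  Everything a pipeline stage consumes can be generated
# here with a single top-level seed.

.AA20 <- function() setdiff(.aaLetters(), "*")

# Patterns that must not arise by chance outside their planted spans:
# the classification motifs (including the edge-relaxed swf signature)
# and the primer-design motifs.  The generator redraws background
# residues that create accidental hits, so the truth manifest is the
# only source of motif evidence.
.scrubPatterns <- function() {
  c("DPQ[QIV]R", "H[GA]TGT", "IAFH", "GHS.GE", ".CALVE.", "C...C..C",
    "FSGQGTQW", "FPGQG.QW", "QGEIAAA")
}

# Default motif layouts per family.  The swf bundle follows the domain
# anatomy of a mono-modular PKS/FAS: KS motifs inside the first ~420 aa
# (the KS domain), AT motifs after, with the swf signature QCALVEL at
# amino acids 591-597 and the forward primer motif FSGQGTQW 66 codons
# upstream of it.  The cis-AT decoy bundles the canonical motif variants
# inside the window spanned by the broad AT primer pair so that its
# translated amplicon carries them.
.familyLayout <- function(family) {
  switch(family,
    swf = data.frame(
      motif = c("DPQIR", "HATGT", "IAFH", "GHSSGE", "FSGQGTQW", "QCALVEL"),
      position = c(180L, 320L, 470L, 500L, 525L, 591L),
      stringsAsFactors = FALSE),
    cisAT_decoy = data.frame(
      motif = c("FPGQGSQW", "DPQQR", "HGTGT", "IAFH", "GHSAGE", "QGEIAAA"),
      position = c(100L, 120L, 140L, 155L, 170L, 190L),
      stringsAsFactors = FALSE),
    radicalSAM_decoy = data.frame(
      motif = "CLSACERC", position = 300L, stringsAsFactors = FALSE),
    stop("unknown family: '", family, "'"))
}

.familyPrimerPair <- function(family) {
  switch(family,
    swf = swfPrimerPair(),
    cisAT_decoy = atPrimerPair(),
    radicalSAM_decoy = NULL)
}

#' Specification of one planted gene
#'
#' @param family `"swf"`, `"cisAT_decoy"` or `"radicalSAM_decoy"`.
#' @param strand `"+"` or `"-"` strand of the contig.
#' @param fwdMismatches,revMismatches number of nucleotide substitutions
#'   to realize in the forward / reverse primer binding site (outside
#'   the 3' clamp, so a site with `k <= maxMismatch` substitutions stays
#'   detectable at the default clamp).
#' @param length protein length in amino acids (must accommodate the
#'   family's motif layout; default 650).
#' @param layout optional `data.frame(motif, position)` overriding the
#'   family default (positions are 1-based amino-acid starts and must
#'   not overlap).
#' @return A `plantSpec` list.
#' @export
plantSpec <- function(family = c("swf", "cisAT_decoy", "radicalSAM_decoy"),
                      strand = "+", fwdMismatches = 0L, revMismatches = 0L,
                      length = 650L, layout = NULL) {
  family <- match.arg(family)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (fwdMismatches < 0L || revMismatches < 0L)
    stop("mismatch counts must be >= 0")
  if (is.null(layout)) layout <- .familyLayout(family)
  layout <- layout[order(layout$position), , drop = FALSE]
  ends <- layout$position + nchar(layout$motif) - 1L
  if (any(ends > length))
    stop("motif positions exceed protein length ", length)
  if (nrow(layout) > 1L &&
      any(layout$position[-1L] <= ends[-nrow(layout)]))
    stop("motif positions overlap")
  list(family = family, strand = strand, fwdMismatches = fwdMismatches,
       revMismatches = revMismatches, length = length, layout = layout)
}

#' Generate a protein carrying a family's motif bundle
#'
#' Uniform random background residues (residue 1 fixed to M so the gene
#' is a well-formed ORF) with the family's motifs planted at their
#' layout positions.  Background stretches that would create an
#' accidental hit of any diagnostic or primer motif are redrawn, so the
#' planted spans are the only motif evidence in the sequence.
#'
#' @param spec a [plantSpec()].
#' @param seed optional RNG seed; omit when calling under an outer seed.
#' @return List with `protein` (character string) and `layout` (the
#'   planted `data.frame(motif, position)`).
#' @examples
#' p <- makeSwfProtein(plantSpec("swf"), seed = 1)
#' substr(p$protein, 591, 597)  # "QCALVEL"
#' @export
makeSwfProtein <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- .AA20()
  res <- sample(aa, spec$length, replace = TRUE)
  res[1L] <- "M"
  planted <- rep(FALSE, spec$length)
  for (i in seq_len(nrow(spec$layout))) {
    pos <- spec$layout$position[i]
    mot <- .chars(spec$layout$motif[i])
    idx <- pos:(pos + length(mot) - 1L)
    res[idx] <- mot
    planted[idx] <- TRUE
  }
  res <- .scrubAccidentalMotifs(res, planted)
  list(protein = paste(res, collapse = ""), layout = spec$layout)
}

.scrubAccidentalMotifs <- function(res, planted, maxIter = 100L) {
  aa <- .AA20()
  for (iter in seq_len(maxIter)) {
    s <- paste(res, collapse = "")
    dirty <- FALSE
    for (pat in .scrubPatterns()) {
      hits <- gregexpr(pat, s)[[1]]
      if (hits[1L] == -1L) next
      lens <- attr(hits, "match.length")
      for (h in seq_along(hits)) {
        span <- hits[h]:(hits[h] + lens[h] - 1L)
        if (all(planted[span])) next  # the planted motif itself
        redraw <- span[!planted[span]]
        res[redraw] <- sample(aa, length(redraw), replace = TRUE)
        dirty <- TRUE
      }
      if (dirty) break  # rescan from scratch after any redraw
    }
    if (!dirty) return(res)
  }
  stop("could not scrub accidental motif hits after ", maxIter,
       " iterations")
}

# Uniform synonymous back-translation of a protein (no stop codon).
.backTranslate <- function(protein) {
  vapply(.chars(protein), function(r) {
    codons <- .codonsFor(r)
    if (!length(codons)) stop("cannot back-translate residue '", r, "'")
    if (length(codons) == 1L) codons else sample(codons, 1L)
  }, character(1), USE.NAMES = FALSE)
}

# Introduce exactly k substitutions into a primer binding site (given as
# a character vector of site bases), relative to an IUPAC pattern.
# Positions inside the primer's 3' clamp are avoided so planted
# mismatched sites remain detectable; clampSide follows .scanPattern
# ("right" for a forward-primer site, "left" for the reverse-complement
# site of a reverse primer).
.applySiteMismatches <- function(siteBases, pattern, k, clampLen = 3L,
                                 clampSide = c("right", "left")) {
  clampSide <- match.arg(clampSide)
  if (k == 0L) return(siteBases)
  p <- .chars(pattern)
  L <- length(p)
  clampIdx <- if (clampSide == "right") (L - clampLen + 1L):L
              else 1L:clampLen
  eligible <- setdiff(which(.degeneracyPerLetter(p) < 4), clampIdx)
  if (length(eligible) < k)
    stop("cannot realize ", k, " substitutions: only ", length(eligible),
         " non-degenerate positions outside the clamp")
  for (pos in sample(eligible, k)) {
    outside <- setdiff(c("A", "C", "G", "T"), iupacBases(p[pos]))
    siteBases[pos] <- if (length(outside) == 1L) outside
                      else sample(outside, 1L)
  }
  siteBases
}

.randomFlank <- function(n, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

#' Assemble a synthetic contig with planted genes and a truth manifest
#'
#' Each plant's protein is generated ([makeSwfProtein()]),
#' back-translated with uniform synonymous codons, given an in-frame
#' TAA stop, and embedded on the requested strand between random
#' flanks.  Primer binding sites are realized with exactly the
#' requested substitution counts against the family's primer pair
#' (swf: SWF_ATF/SWF_ATR; cis-AT decoy: AT1F/AT3R2).  The manifest
#' records gene coordinates (1-based inclusive, `start > end` on the
#' reverse strand, stop codon included), primer-site coordinates and
#' mismatch counts, and the expected amplicon length; it is verified
#' against the emitted sequence by an independent re-scan before
#' return.
#'
#' @param plants list of [plantSpec()]s.
#' @param seed top-level RNG seed; all randomness flows from it.
#' @param id contig id.
#' @param flankLen length of the random flanks between/around genes.
#' @param gc GC content of the flanks.
#' @return List with `contig` (named length-one
#'   [Biostrings::DNAStringSet]) and `manifest` (see Details).
#' @export
makeContig <- function(plants, seed = 1L, id = "contig", flankLen = 300L,
                       gc = 0.5) {
  set.seed(seed)
  parts <- character()
  genes <- list()
  offset <- 0L
  addPart <- function(x) {
    parts[[length(parts) + 1L]] <<- x
    offset <<- offset + nchar(x)
  }
  addPart(.randomFlank(flankLen, gc))
  for (pl in plants) {
    prot <- makeSwfProtein(pl)
    codons <- .backTranslate(prot$protein)
    pair <- .familyPrimerPair(pl$family)
    sites <- NULL
    if (!is.null(pair)) {
      fmot <- primerMotif(pair$fwd); rmot <- primerMotif(pair$rev)
      fpos <- prot$layout$position[prot$layout$motif == toupper(fmot)]
      rpos <- prot$layout$position[prot$layout$motif == rmot]
      stopifnot(length(fpos) == 1L, length(rpos) == 1L)
      fIdx <- fpos:(fpos + nchar(fmot) - 1L)
      rIdx <- rpos:(rpos + nchar(rmot) - 1L)
      fBases <- .chars(paste(codons[fIdx], collapse = ""))
      rBases <- .chars(paste(codons[rIdx], collapse = ""))
      fBases <- .applySiteMismatches(fBases, primerPattern(pair$fwd),
                                     pl$fwdMismatches, clampSide = "right")
      rBases <- .applySiteMismatches(rBases, revComp(primerPattern(pair$rev)),
                                     pl$revMismatches, clampSide = "left")
      codons[fIdx] <- substring(paste(fBases, collapse = ""),
                                seq(1, by = 3, length.out = length(fIdx)),
                                seq(3, by = 3, length.out = length(fIdx)))
      codons[rIdx] <- substring(paste(rBases, collapse = ""),
                                seq(1, by = 3, length.out = length(rIdx)),
                                seq(3, by = 3, length.out = length(rIdx)))
      # coding-strand nt offsets of the two sites within the gene
      sites <- list(
        fwd = list(name = primerName(pair$fwd),
                   nt_start = 3L * (fpos - 1L) + 1L,
                   nt_end = 3L * (fpos - 1L) + 3L * nchar(fmot),
                   mismatches = pl$fwdMismatches),
        rev = list(name = primerName(pair$rev),
                   nt_start = 3L * (rpos - 1L) + 1L,
                   nt_end = 3L * (rpos - 1L) + 3L * nchar(rmot),
                   mismatches = pl$revMismatches))
    }
    geneDna <- paste(c(codons, "TAA"), collapse = "")
    geneLen <- nchar(geneDna)
    geneStart <- offset + 1L
    addPart(if (pl$strand == "+") geneDna else revComp(geneDna))
    geneEnd <- offset
    toPlus <- function(ntStart, ntEnd) {
      if (pl$strand == "+")
        c(geneStart + ntStart - 1L, geneStart + ntEnd - 1L)
      else
        c(geneEnd - ntEnd + 1L, geneEnd - ntStart + 1L)
    }
    geneRec <- list(
      family = pl$family, strand = pl$strand,
      start = if (pl$strand == "+") geneStart else geneEnd,
      end = if (pl$strand == "+") geneEnd else geneStart,
      aa_length = nchar(prot$protein),
      protein = prot$protein)
    if (!is.null(sites)) {
      fPlus <- toPlus(sites$fwd$nt_start, sites$fwd$nt_end)
      rPlus <- toPlus(sites$rev$nt_start, sites$rev$nt_end)
      geneRec$primer_pair <- paste(sites$fwd$name, sites$rev$name, sep = "/")
      geneRec$sites <- list(
        fwd = list(name = sites$fwd$name, start = fPlus[1L],
                   end = fPlus[2L], strand = pl$strand,
                   mismatches = sites$fwd$mismatches),
        rev = list(name = sites$rev$name, start = rPlus[1L],
                   end = rPlus[2L],
                   # the reverse primer anneals the strand opposite the gene
                   strand = if (pl$strand == "+") "-" else "+",
                   mismatches = sites$rev$mismatches))
      geneRec$expected_amplicon_length <-
        sites$rev$nt_end - sites$fwd$nt_start + 1L
    }
    genes[[length(genes) + 1L]] <- geneRec
    addPart(.randomFlank(flankLen, gc))
  }
  seqStr <- paste(parts, collapse = "")
  contig <- Biostrings::DNAStringSet(setNames(seqStr, id))
  manifest <- list(seed = seed, contig_id = id, length = nchar(seqStr),
                   genes = genes)
  .verifyManifest(contig, manifest)
  list(contig = contig, manifest = manifest)
}

# Independent re-scan of the emitted contig against its manifest; errors
# if any planted site is missing, has the wrong mismatch count, or the
# expected amplicon is not produced.
.verifyManifest <- function(contig, manifest) {
  pairs <- list(swf = swfPrimerPair(), cisAT_decoy = atPrimerPair())
  for (g in manifest$genes) {
    if (is.null(g$sites)) next
    pair <- pairs[[g$family]]
    for (side in c("fwd", "rev")) {
      site <- g$sites[[side]]
      primer <- pair[[side]]
      found <- findPrimerSites(contig, primer,
                               maxMismatch = max(2L, site$mismatches),
                               clampLen = 3L)
      hit <- found[found$start == site$start & found$end == site$end, ]
      if (nrow(hit) != 1L || hit$mismatches != site$mismatches)
        stop("manifest verification failed: ", side, " site of ",
             g$family, " gene at ", site$start, "-", site$end,
             " not recovered as planted")
    }
    if (g$sites$fwd$mismatches <= 2L && g$sites$rev$mismatches <= 2L) {
      amp <- amplify(contig, pair$fwd, pair$rev)
      if (!g$expected_amplicon_length %in% amp$length)
        stop("manifest verification failed: expected ",
             g$expected_amplicon_length, " bp amplicon not produced")
    }
  }
  invisible(TRUE)
}

#' Generate a multi-contig synthetic metagenome
#'
#' One planted gene per contig: `nSwf` swf genes followed by `nDecoy`
#' cis-AT decoys (strands alternating + / -), each with exact primer
#' sites by default.  The defaults mirror a twelve-sequence screening
#' round in which four amplicons derive from swf genes.
#'
#' @param nSwf,nDecoy number of swf / cis-AT decoy contigs.
#' @param seed top-level seed; per-contig seeds are derived from it.
#' @param ... passed to [plantSpec()] (e.g. mismatch counts).
#' @return List with `contigs` (a named [Biostrings::DNAStringSet]) and
#'   `manifest` (list with `seed` and per-contig manifests).
#' @export
makeMetagenome <- function(nSwf = 4L, nDecoy = 8L, seed = 1L, ...) {
  fams <- c(rep("swf", nSwf), rep("cisAT_decoy", nDecoy))
  ids <- c(sprintf("swf_contig_%02d", seq_len(nSwf)),
           sprintf("decoy_contig_%02d", seq_len(nDecoy)))
  strands <- rep(c("+", "-"), length.out = length(fams))
  contigs <- NULL
  manifests <- list()
  for (i in seq_along(fams)) {
    cm <- makeContig(list(plantSpec(fams[i], strand = strands[i], ...)),
                     seed = seed * 1000L + i, id = ids[i])
    contigs <- if (is.null(contigs)) cm$contig
               else c(contigs, cm$contig)
    manifests[[ids[i]]] <- cm$manifest
  }
  list(contigs = contigs, manifest = list(seed = seed, contigs = manifests))
}

#' Write / read a truth manifest as JSON
#'
#' @param manifest manifest list from [makeContig()] or
#'   [makeMetagenome()].
#' @param path file path.
#' @return `writeManifest` returns `path` invisibly; `readManifest` the
#'   manifest list.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' A small reference phylogeny for simulation experiments
#'
#' Six taxa in three cherries around a central node, with 0.08
#' substitutions/site internal edges and 0.15 pendant edges - enough
#' signal for distance methods to recover the topology from a long
#' alignment.
#'
#' @return An [ape::phylo] tree.
#' @export
syntheticPhylogeny <- function() {
  ape::read.tree(text = paste0(
    "((A:0.15,B:0.15):0.08,(C:0.15,D:0.15):0.08,(E:0.15,F:0.15):0.08);"))
}

#' Simulate a protein alignment down a tree
#'
#' Sites evolve independently under a uniform-exchange 20-state model:
#' along a branch of length t (expected substitutions per site), a site
#' is redrawn uniformly from the 20 amino acids with probability
#' `1 - exp(-20 t / 19)` (so the probability of observing a difference
#' is `(19/20) (1 - exp(-20 t / 19))`, saturating at 0.95).  Branch
#' lengths of zero therefore yield identical sequences.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param length number of sites (>= 1).
#' @param rate multiplier applied to all branch lengths.
#' @param seed optional RNG seed.
#' @return An [Biostrings::AAStringSet], one aligned row per tip.
#' @export
simulateAlignment <- function(tree, length, rate = 1, seed = NULL) {
  if (length < 1L) stop("length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  aa <- .AA20()
  nt <- length(tree$tip.label)
  tree2 <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  seqs <- vector("list", nt + tree2$Nnode)
  root <- nt + 1L
  seqs[[root]] <- sample(aa, length, replace = TRUE)
  for (e in seq_len(nrow(tree2$edge))) {
    parent <- tree2$edge[e, 1L]; child <- tree2$edge[e, 2L]
    t <- tree2$edge.length[e] * rate
    s <- seqs[[parent]]
    hit <- stats::runif(length) < 1 - exp(-20 * t / 19)
    if (any(hit)) s[hit] <- sample(aa, sum(hit), replace = TRUE)
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(nt), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  Biostrings::AAStringSet(setNames(out, tree2$tip.label))
}
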