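# Distance-based phylogeny: p-distances with pairwise deletion,
# neighbour-joining (ape), bootstrap bipartition support, outgroup
# rooting on the midpoint of the outgroup's pendant edge, and
# support-cutoff condensation of a tree into polytomies.

# Coerce an alignment (AAStringSet, named character vector of equal
# lengths, or character matrix) to a character matrix, rows = taxa.
.alnMatrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- toupper(aln)
  } else {
    nms <- names(aln)
    seqs <- toupper(as.character(aln))
    if (is.null(names(seqs))) names(seqs) <- nms
    w <- nchar(seqs)
    if (length(unique(w)) != 1L)
      stop("alignment rows have unequal lengths: ",
           paste(unique(w), collapse = ", "))
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("taxon%02d", seq_len(nrow(m)))
  m
}

#' Uncorrected p-distance matrix with pairwise deletion
#'
#' For each pair of aligned sequences, the proportion of differing sites
#' over the columns where neither sequence has a gap (`-`).  An optional
#' Poisson correction `-log(1 - p)` is available for multiple hits.
#'
#' @param aln alignment: [Biostrings::AAStringSet], named character
#'   vector of equal-length strings, or character matrix (rows = taxa).
#' @param correction `"none"` (default) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal and taxa labels
#'   as dimnames.
#' @export
pDistance <- function(aln, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  m <- .alnMatrix(aln)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 taxa (got ", n, ")")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  notGap <- m != "-"
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    comp <- notGap[i, ] & notGap[j, ]
    if (!any(comp))
      stop("no comparable (gap-free) columns between '", rownames(m)[i],
           "' and '", rownames(m)[j], "'")
    p <- mean(m[i, comp] != m[j, comp])
    if (correction == "poisson") {
      if (p >= 1) stop("Poisson correction undefined at p >= 1")
      p <- -log(1 - p)
    }
    D[i, j] <- D[j, i] <- p
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]).  Taxa are ordered
#' lexicographically before clustering so that ties in the rate-corrected
#' criterion are broken deterministically by label.  Negative branch
#' lengths are clamped to zero; the total clamped deficit is recorded in
#' the `"clamped"` attribute of the returned tree.
#'
#' @param D symmetric distance matrix with labelled rows/columns (or a
#'   `dist` object).
#' @return An unrooted [ape::phylo] tree.
#' @export
njTree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix is not symmetric")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  ord <- order(rownames(D))
  D <- D[ord, ord, drop = FALSE]
  tr <- ape::nj(D)
  neg <- tr$edge.length < 0
  attr(tr, "clamped") <- sum(-tr$edge.length[neg])
  tr$edge.length[neg] <- 0
  tr
}

#' Bootstrap bipartition support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement `nReplicates` times,
#' rebuilds the NJ tree per replicate, and attaches to each internal
#' node of the full-data tree the percentage of replicate trees
#' containing the same leaf bipartition (via [ape::boot.phylo()]).
#'
#' @param aln alignment accepted by [pDistance()]; must have at least
#'   2 columns.
#' @param nReplicates number of bootstrap replicates (>= 1).
#' @param seed RNG seed (recorded in the `"seed"` attribute).
#' @param correction distance correction, see [pDistance()].
#' @return The NJ tree with numeric `node.label` support values in
#'   \[0, 100\] (the root label is the trivial full-leaf-set partition).
#' @export
bootstrapSupport <- function(aln, nReplicates = 100L, seed = 1L,
                             correction = "none") {
  if (nReplicates < 1L) stop("nReplicates must be >= 1")
  m <- .alnMatrix(aln)
  if (ncol(m) < 2L) stop("alignment must have at least 2 columns")
  buildFun <- function(x) njTree(pDistance(x, correction = correction))
  tr <- buildFun(m)
  set.seed(seed)
  counts <- ape::boot.phylo(tr, m, buildFun, B = nReplicates, quiet = TRUE)
  tr$node.label <- 100 * counts / nReplicates
  attr(tr, "seed") <- seed
  attr(tr, "nReplicates") <- nReplicates
  tr
}

#' Root a tree on the midpoint of an outgroup's pendant edge
#'
#' The root is placed halfway along the pendant edge of the named
#' outgroup leaf, so the leaf set and all pairwise leaf-to-leaf path
#' lengths are preserved.
#'
#' @param tree an [ape::phylo] tree containing `outgroup` as a tip.
#' @param outgroup tip label to root on.
#' @return A rooted [ape::phylo] tree.
#' @export
rootWithOutgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup label not found in tree: '", outgroup, "'")
  tr <- ape::root(ape::unroot(tree), outgroup = outgroup,
                  resolve.root = TRUE, edgelabel = TRUE)
  rootNode <- length(tr$tip.label) + 1L
  kidEdges <- which(tr$edge[, 1] == rootNode)
  tipIdx <- which(tr$tip.label == outgroup)
  ogEdge <- kidEdges[tr$edge[kidEdges, 2] == tipIdx]
  otherEdge <- setdiff(kidEdges, ogEdge)
  if (length(ogEdge) == 1L && length(otherEdge) == 1L) {
    half <- tr$edge.length[ogEdge] / 2
    tr$edge.length[ogEdge] <- half
    tr$edge.length[otherEdge] <- tr$edge.length[otherEdge] + half
  }
  tr
}

#' Condense a tree by collapsing low-support edges into polytomies
#'
#' Every internal edge whose bipartition support is strictly below
#' `cutoff` is collapsed (its child's children are re-attached to its
#' parent); edges with support greater than or equal to the cutoff are
#' retained.  Branch lengths of retained edges are unchanged; the length
#' of a collapsed edge is discarded, as in a condensed topology display.
#'
#' @param tree an [ape::phylo] tree with numeric support values in
#'   `node.label` (as produced by [bootstrapSupport()]).
#' @param cutoff support cutoff in percent.
#' @return An [ape::phylo] tree, possibly multifurcating.
#' @export
condenseTree <- function(tree, cutoff) {
  if (is.null(tree$node.label))
    stop("tree has no support values (node.label is NULL)")
  nt <- length(tree$tip.label)
  support <- suppressWarnings(as.numeric(tree$node.label))
  rooted <- ape::is.rooted(tree)
  rootNode <- nt + 1L
  # serialize to newick, splicing out marked internal nodes
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  edgeLen <- tree$edge.length
  marked <- function(node) {
    if (node <= nt || node == rootNode) return(FALSE)
    s <- support[node - nt]
    !is.na(s) && s < cutoff
  }
  serParts <- function(node) {
    # returns character vector of newick fragments for node's children
    unlist(lapply(kids[[as.character(node)]], function(e) {
      child <- tree$edge[e, 2]
      if (child <= nt) {
        paste0(tree$tip.label[child], ":", format(edgeLen[e], digits = 12))
      } else if (marked(child)) {
        serParts(child)  # splice: drop the collapsed edge
      } else {
        lab <- tree$node.label[child - nt]
        paste0("(", paste(serParts(child), collapse = ","), ")",
               if (is.na(lab)) "" else lab, ":",
               format(edgeLen[e], digits = 12))
      }
    }))
  }
  rootLab <- tree$node.label[1L]
  txt <- paste0("(", paste(serParts(rootNode), collapse = ","), ")",
                if (is.na(rootLab)) "" else rootLab, ";")
  out <- ape::read.tree(text = txt)
  out
}

#' Serialize / read trees as Newick
#'
#' Thin wrappers over [ape::write.tree()] and [ape::read.tree()] so the
#' pipeline's tree I/O goes through one place (supports are written as
#' internal node labels).
#'
#' @param tree an [ape::phylo] tree.
#' @param path file path.
#' @return `writeNewick` returns `path` invisibly; `readNewick` a
#'   [ape::phylo] tree.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)
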