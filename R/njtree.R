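# Neighbour-joining tree construction, polytomy collapse, outgroup rooting
# and bootstrap supports. Trees are ape "phylo" objects throughout.

.check_tip_labels <- function(labs) {
  bad <- grepl("[(),:;\\s']", labs, perl = TRUE)
  if (any(bad))
    stop("specimen ids unusable as newick tip labels: ",
         paste(labs[bad], collapse = ", "))
}

#' Build a neighbour-joining tree
#'
#' Saitou--Nei agglomeration on a pairwise distance matrix, returning an
#' unrooted \code{phylo} with a basal trifurcation. The result is
#' deterministic: ties in the Q criterion are broken by the lowest (i, j)
#' index pair in the current matrix order, where freshly merged nodes are
#' appended after all existing ones. Negative branch lengths are clamped to
#' zero with the deficit moved to the sibling branch, so the pairwise sum is
#' preserved and downstream polytomy collapse behaves sensibly.
#'
#' @param dm a \code{\link{k2p_distmat}} or a plain symmetric matrix with
#'   dimnames. All entries among included taxa must be defined.
#' @return an unrooted \code{phylo} object.
#' @export
build_nj <- function(dm) {
  d <- if (inherits(dm, "k2p_distmat")) dm$d else as.matrix(dm)
  n <- nrow(d)
  if (n < 3L) stop("neighbour joining needs at least 3 taxa")
  labs <- rownames(d)
  if (is.null(labs)) stop("distance matrix needs taxon labels")
  .check_tip_labels(labs)
  if (anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop("undefined distance(s) among included taxa: ",
         paste(sprintf("%s-%s", labs[bad[, 1L]], labs[bad[, 2L]]),
               collapse = ", "))
  }
  node <- labs
  while (n > 3L) {
    rs <- rowSums(d)
    Q <- (n - 2) * d - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin & upper.tri(Q), arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    dnew <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    node <- c(node[keep], sprintf("(%s:%.12g,%s:%.12g)", node[i], li,
                                  node[j], lj))
    n <- n - 1L
  }
  lx <- max((d[1, 2] + d[1, 3] - d[2, 3]) / 2, 0)
  ly <- max((d[1, 2] + d[2, 3] - d[1, 3]) / 2, 0)
  lz <- max((d[1, 3] + d[2, 3] - d[1, 2]) / 2, 0)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 node[1L], lx, node[2L], ly, node[3L], lz)
  ape::read.tree(text = txt)
}

#' Collapse negligible internal branches into polytomies
#'
#' Contracts every internal branch of length at most \code{epsilon};
#' terminal (leaf) branches are never contracted. Idempotent. This realises
#' the polytomies that the node-level tree identification criterion (NJT_M)
#' reasons about.
#'
#' @param tree a \code{phylo}.
#' @param epsilon length threshold; branches \code{<= epsilon} collapse.
#'   Default \code{1e-9}, i.e. effectively zero-length branches only.
#' @return a \code{phylo}, possibly multifurcating.
#' @export
collapse_short_branches <- function(tree, epsilon = 1e-9) {
  stopifnot(inherits(tree, "phylo"))
  if (epsilon < 0) stop("epsilon must be >= 0")
  internal <- tree$edge[, 2L] > ape::Ntip(tree)
  tree$edge.length[internal & tree$edge.length <= epsilon] <- 0
  # di2multi collapses strictly-below-tol branches; edges to drop are now 0
  ape::di2multi(tree, tol = .Machine$double.xmin)
}

#' Root a tree on an outgroup leaf
#'
#' Places the root on the outgroup's pendant branch; ingroup topology and
#' all pairwise path lengths are unchanged. Idempotent.
#'
#' @param tree a \code{phylo}.
#' @param outgroup_id a leaf label.
#' @return a rooted \code{phylo}.
#' @export
root_with_outgroup <- function(tree, outgroup_id) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup_id %in% tree$tip.label)
    stop("unknown leaf '", outgroup_id, "'")
  if (ape::is.rooted(tree)) {
    # already rooted on this outgroup? then a re-root is a no-op
    root_node <- ape::Ntip(tree) + 1L
    kids <- tree$edge[tree$edge[, 1L] == root_node, 2L]
    tip <- which(tree$tip.label == outgroup_id)
    if (tip %in% kids) return(tree)
  }
  ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
}

#' Bootstrap supports for a neighbour-joining tree
#'
#' Felsenstein column resampling: each replicate resamples alignment columns
#' with replacement, recomputes the K2P matrix and the NJ tree, and the
#' support of an internal branch is the percentage of replicate trees
#' containing the same bipartition. Replicates whose resampled matrix has an
#' undefined distance are dropped (with a message). Reproducible given
#' \code{seed}.
#'
#' @param dataset a \code{barcode_dataset}.
#' @param n_replicates number of replicates (>= 1).
#' @param seed optional integer seed.
#' @param resample_indices optional list of integer vectors (one per
#'   replicate, each of length \code{alignment_length}) overriding the
#'   random column draws; used for reproducibility checks.
#' @return the NJ tree of the full dataset with \code{node.label} set to
#'   support percentages (NA where undefined, e.g. the basal trifurcation);
#'   attribute \code{n_replicates_used} records replicates kept.
#' @export
bootstrap_supports <- function(dataset, n_replicates = 1000, seed = NULL,
                               resample_indices = NULL) {
  stopifnot(inherits(dataset, "barcode_dataset"))
  m <- .seq_matrix(dataset)
  ref <- build_nj(k2p_distmat(.k2p_from_matrix(m)))
  L <- ncol(m)
  if (is.null(resample_indices)) {
    if (n_replicates < 1L) stop("n_replicates must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    resample_indices <- replicate(n_replicates,
                                  sample.int(L, L, replace = TRUE),
                                  simplify = FALSE)
  }
  trees <- list()
  dropped <- 0L
  for (idx in resample_indices) {
    db <- .k2p_from_matrix(m[, idx, drop = FALSE])
    if (anyNA(db[upper.tri(db)])) { dropped <- dropped + 1L; next }
    trees[[length(trees) + 1L]] <- build_nj(k2p_distmat(db))
  }
  if (dropped > 0L)
    message(dropped, " bootstrap replicate(s) dropped (undefined distances)")
  if (!length(trees)) stop("all bootstrap replicates were dropped")
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  ref$node.label <- 100 * counts / length(trees)
  attr(ref, "n_replicates_used") <- length(trees)
  ref
}
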