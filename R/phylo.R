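# Distance-tree construction: canonical neighbor-joining on p-distances,
# column-bootstrap supports, outgroup rooting.

#' Neighbor-joining tree
#'
#' Canonical neighbor-joining (Q-criterion agglomeration) implemented from
#' first principles: exact on additive distance matrices, deterministic
#' tie-breaking by the smallest index pair, negative estimated branch lengths
#' clamped to zero.
#'
#' @param d an `snp_dist` from [snp_distance()], a `dist`, or a symmetric
#'   numeric matrix with row/column names.
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "snp_dist")) {
    if (any(d$flagged))
      stop("distance matrix has undefined entries (no comparable sites); ",
           "cannot build a tree")
    m <- d$d
  } else if (inherits(d, "dist")) {
    m <- as.matrix(d)
  } else {
    m <- as.matrix(d)
  }
  n <- nrow(m)
  if (n < 3L) stop("neighbor joining needs at least 3 samples")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(n))
  if (any(is.na(m))) stop("distance matrix contains NA")
  labs <- rownames(m)
  # active subtrees as newick fragments
  nwk <- labs
  D <- m
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (nrow(D) > 3L) {
    r <- nrow(D)
    S <- rowSums(D)
    Q <- (r - 2) * D - outer(S, S, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    d_iu <- 0.5 * D[i, j] + (S[i] - S[j]) / (2 * (r - 2))
    d_ju <- D[i, j] - d_iu
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(d_iu), nwk[j], fmt(d_ju))
    d_new <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], d_new[keep]),
                c(d_new[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], "u")
    D <- D2
  }
  la <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  lb <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  lc <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    nwk[1L], fmt(la), nwk[2L], fmt(lb), nwk[3L], fmt(lc))
  ape::read.tree(text = newick)
}

# p-distance matrix straight from a call matrix (sites x samples);
# used by the bootstrap resampler.
pdist_from_calls <- function(m) {
  obs <- !is.na(m)
  comparable <- crossprod(obs)
  idm <- matrix(0, ncol(m), ncol(m))
  for (v in unique(m[obs])) {
    iv <- obs & (m == v)
    iv[is.na(iv)] <- FALSE
    idm <- idm + crossprod(iv)
  }
  if (any(comparable == 0))
    stop("sample pair with no comparable sites in bootstrap replicate")
  d <- 1 - idm / comparable
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

#' Neighbor-joining tree with column-bootstrap supports
#'
#' Builds the point-estimate NJ tree on p-distances from the genotype
#' matrix, then resamples site columns with replacement (same count)
#' `n_reps` times, rebuilds the NJ tree per replicate, and annotates each
#' internal bipartition of the point-estimate tree with the number of
#' replicates containing it (as integer node labels).
#'
#' @param x a [genotype_matrix] restricted to the samples and site set of
#'   interest.
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed integer seed; replicate `r` draws its columns from a stream
#'   derived deterministically from `(seed, r)`.
#' @param scope optional replicon scope; resampling happens within the
#'   scoped site set only.
#' @return an [ape::phylo] with `node.label` holding support counts out of
#'   `n_reps` (attribute `n_reps`).
#' @export
bootstrap_support <- function(x, n_reps = 100L, seed = 1L, scope = NULL) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  x <- scope_sites(x, scope)
  base <- nj_tree(snp_distance(x))
  m <- x$calls
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    cols <- sample.int(nrow(m), nrow(m), replace = TRUE)
    reps[[r]] <- nj_tree(pdist_from_calls(m[cols, , drop = FALSE]))
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  base$node.label <- as.character(counts)
  attr(base, "n_reps") <- as.integer(n_reps)
  base
}

#' Root a tree on the outgroup
#'
#' Reroots on the edge subtending the outgroup leaf; bipartitions are
#' unchanged.
#'
#' @param tree an [ape::phylo].
#' @param outgroup_id leaf label of the outgroup sample.
#' @return a rooted [ape::phylo].
#' @export
root_at_outgroup <- function(tree, outgroup_id) {
  if (!outgroup_id %in% tree$tip.label)
    stop("unknown leaf: ", outgroup_id)
  ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE,
            edgelabel = TRUE)
}

#' Test whether a set of leaves forms a clade in a rooted tree
#'
#' @param tree a rooted [ape::phylo].
#' @param tips character vector of leaf labels.
#' @return `TRUE` iff `tips` is exactly the leaf set of some node.
#' @export
is_clade <- function(tree, tips) {
  stopifnot(all(tips %in% tree$tip.label))
  tipn <- match(tips, tree$tip.label)
  if (length(tipn) == 1L) return(TRUE)
  mrca <- ape::getMRCA(tree, tipn)
  desc <- ape::extract.clade(tree, mrca)$tip.label
  setequal(desc, tips)
}
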