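# Haplotype group discovery: single-linkage clustering on SNP difference
# counts, consensus haplotypes, inter-haplotype divergence, subgroup
# detection and chloroplast/mitochondrion concordance.

#' Cluster focal samples into haplotype groups
#'
#' Single-linkage agglomeration on pairwise SNP difference counts
#' ([divergence_counts()]): two samples end up in the same haplotype iff they
#' are connected by a chain of pairs each differing at no more than
#' `linkage_threshold` sites. Single linkage is the natural choice for
#' clonally propagated maternal lineages, where most members of a haplotype
#' are exact copies and rare private mutations hang off the core at small
#' distances. Cluster labels (`H1`, `H2`, ...) are assigned deterministically
#' by decreasing size, ties broken by the lexicographically smallest member
#' ID, so the result is invariant to sample input order.
#'
#' @param x a [genotype_matrix] filtered to the analysis site set; only FOCAL
#'   samples are clustered.
#' @param linkage_threshold non-negative integer; maximum SNP difference
#'   joined by single linkage. The default 5 separates haplotypes >= 10 SNPs
#'   apart while absorbing one-off subgroup members.
#' @param scope optional replicon scope (see [scope_sites()]).
#' @return a `haplotype_partition`: list with `assignment` (data.frame
#'   `sample_id`, `haplotype`), `members` (list label -> sample IDs),
#'   `consensus` (integer matrix sites x labels, `NA` = missing/tie),
#'   `sites` (site table), `calls` (focal call matrix),
#'   `linkage_threshold`.
#' @export
cluster_haplotypes <- function(x, linkage_threshold = 5L, scope = NULL) {
  if (linkage_threshold < 0) stop("linkage_threshold must be >= 0")
  x <- scope_sites(x, scope)
  foc <- focal_samples(x)
  if (!length(foc)) stop("no FOCAL samples to cluster")
  xf <- x[, foc]
  sim <- pairwise_similarity(xf)
  div <- divergence_counts(sim)
  n <- length(foc)
  cl <- if (n == 1L) stats::setNames(1L, foc) else {
    hc <- stats::hclust(stats::as.dist(div), method = "single")
    stats::cutree(hc, h = linkage_threshold)
  }
  members <- split(foc, cl)
  ord <- order(-lengths(members),
               vapply(members, function(m) sort(m)[1L], character(1)))
  members <- members[ord]
  members <- lapply(members, sort)
  names(members) <- sprintf("H%d", seq_along(members))
  assignment <- data.frame(
    sample_id = unlist(members, use.names = FALSE),
    haplotype = rep(names(members), lengths(members)),
    stringsAsFactors = FALSE
  )
  assignment <- assignment[match(foc, assignment$sample_id), , drop = FALSE]
  rownames(assignment) <- NULL
  consensus <- vapply(members, function(m) {
    consensus_calls(xf$calls[, m, drop = FALSE])
  }, integer(nrow(xf$sites)))
  if (nrow(xf$sites) == 0L)
    consensus <- matrix(integer(0), 0L, length(members),
                        dimnames = list(NULL, names(members)))
  else rownames(consensus) <- rownames(xf$sites)
  structure(list(assignment = assignment,
                 members = members,
                 consensus = consensus,
                 sites = xf$sites,
                 calls = xf$calls,
                 linkage_threshold = as.integer(linkage_threshold)),
            class = "haplotype_partition")
}

# Majority non-missing state per site; ties and all-missing -> NA.
consensus_calls <- function(m) {
  apply(m, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    tab <- table(v)
    top <- tab[tab == max(tab)]
    if (length(top) > 1L) NA_integer_ else as.integer(names(top))
  })
}

#' @export
print.haplotype_partition <- function(x, ...) {
  cat(sprintf("haplotype_partition: %d samples, %d clusters (threshold %d)\n",
              nrow(x$assignment), length(x$members), x$linkage_threshold))
  print(stats::setNames(lengths(x$members), names(x$members)))
  invisible(x)
}

#' Consensus genotype of one haplotype
#'
#' Per site, the most frequent non-missing collapsed state among cluster
#' members; ties and all-missing sites are `NA`.
#'
#' @param partition a `haplotype_partition`.
#' @param label cluster label, e.g. `"H1"`.
#' @return named integer vector over the partition's site set.
#' @export
consensus_genotype <- function(partition, label) {
  if (!label %in% colnames(partition$consensus))
    stop("unknown haplotype label: ", label)
  partition$consensus[, label]
}

#' Pairwise divergence between haplotype consensus genotypes
#'
#' Counts differing sites between consensus vectors at sites where both are
#' non-missing.
#'
#' @param partition a `haplotype_partition`.
#' @param scope optional replicon scope applied to the partition's site set.
#' @return data.frame with `hap_a`, `hap_b`, `differences`, `compared`.
#' @export
haplotype_divergence <- function(partition, scope = NULL) {
  labs <- colnames(partition$consensus)
  if (length(labs) < 2L) stop("need at least 2 haplotype clusters")
  keep <- if (is.null(scope)) seq_len(nrow(partition$sites))
          else which(partition$sites$replicon %in% scope)
  cons <- partition$consensus[keep, , drop = FALSE]
  pairs <- utils::combn(labs, 2L)
  out <- data.frame(
    hap_a = pairs[1L, ], hap_b = pairs[2L, ],
    differences = NA_integer_, compared = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(ncol(pairs))) {
    a <- cons[, pairs[1L, k]]
    b <- cons[, pairs[2L, k]]
    both <- !is.na(a) & !is.na(b)
    out$compared[k] <- sum(both)
    out$differences[k] <- sum(a[both] != b[both])
  }
  out
}

#' Detect subgroup members at a fixed distance from their consensus
#'
#' Lists, within each haplotype, the samples whose call vector differs from
#' the cluster consensus at exactly `exact_diff` pairwise-complete sites,
#' together with the distinguishing site coordinates. Samples sharing the
#' same distinguishing-site signature form a candidate named subgroup (e.g.
#' a cultivar family one mutation off the main haplotype); samples with
#' unique signatures are isolated private-mutation carriers.
#'
#' @param partition a `haplotype_partition`.
#' @param exact_diff integer distance to report (default 1).
#' @return data.frame with `sample_id`, `haplotype`, `n_diff`, `diff_sites`
#'   (`;`-collapsed `replicon:pos` keys).
#' @export
detect_subgroups <- function(partition, exact_diff = 1L) {
  res <- list()
  for (lab in names(partition$members)) {
    cons <- partition$consensus[, lab]
    for (s in partition$members[[lab]]) {
      v <- partition$calls[, s]
      both <- !is.na(v) & !is.na(cons)
      dif <- both & v != cons
      if (sum(dif) == exact_diff) {
        res[[length(res) + 1L]] <- data.frame(
          sample_id = s, haplotype = lab, n_diff = as.integer(exact_diff),
          diff_sites = paste(rownames(partition$sites)[dif], collapse = ";"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(res))
    return(data.frame(sample_id = character(0), haplotype = character(0),
                      n_diff = integer(0), diff_sites = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Summarise subgroups by shared distinguishing-site signature
#'
#' @param subgroups output of [detect_subgroups()].
#' @return data.frame `haplotype`, `diff_sites`, `n_samples`, `sample_ids`,
#'   sorted by decreasing subgroup size.
#' @export
subgroup_signatures <- function(subgroups) {
  if (!nrow(subgroups))
    return(data.frame(haplotype = character(0), diff_sites = character(0),
                      n_samples = integer(0), sample_ids = character(0),
                      stringsAsFactors = FALSE))
  key <- paste(subgroups$haplotype, subgroups$diff_sites, sep = "\r")
  grp <- split(subgroups, key)
  out <- do.call(rbind, lapply(grp, function(g) data.frame(
    haplotype = g$haplotype[1L], diff_sites = g$diff_sites[1L],
    n_samples = nrow(g),
    sample_ids = paste(sort(g$sample_id), collapse = ";"),
    stringsAsFactors = FALSE
  )))
  out <- out[order(-out$n_samples, out$haplotype, out$diff_sites), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Number of pairs co-clustered under `fine` but split under `coarse`,
# plus each sample's involvement count. Labels: named character vectors.
refinement_violations <- function(fine, coarse) {
  ids <- names(fine)
  inv <- stats::setNames(numeric(length(ids)), ids)
  for (cl in unique(fine)) {
    m <- ids[fine == cl]
    sub <- coarse[m]
    tab <- table(sub)
    # member with coarse label c disagrees with |cluster| - tab[c] others
    inv[m] <- inv[m] + (length(m) - as.numeric(tab[sub]))
  }
  list(total = sum(inv) / 2, per_sample = inv)
}

#' Concordance of chloroplast and mitochondrial haplotype partitions
#'
#' Organellar genomes are co-transmitted maternally, so the two partitions
#' should never "mix": every haplotype of the finer partition should sit
#' inside a single haplotype of the coarser one (the chloroplast partition
#' can legitimately be coarser when two maternal lineages differ at a single
#' chloroplast site). The partitions are concordant iff one refines the
#' other. Discordant samples (e.g. a sample whose chloroplast matches one
#' lineage and mitochondrion another) are identified by greedily removing
#' the sample involved in the most refinement-violating pairs until none
#' remain.
#'
#' @param partition_cp,partition_mt `haplotype_partition`s over the same
#'   sample set.
#' @return list with `concordant` (logical), `direction` (which partition
#'   refines which), `discordant` (character vector of flagged samples),
#'   `n_violating_pairs`, and `table` (cp x mt label contingency).
#' @export
organelle_concordance <- function(partition_cp, partition_mt) {
  a <- stats::setNames(partition_cp$assignment$haplotype,
                       partition_cp$assignment$sample_id)
  b <- stats::setNames(partition_mt$assignment$haplotype,
                       partition_mt$assignment$sample_id)
  if (!setequal(names(a), names(b)))
    stop("partitions cover different sample sets")
  b <- b[names(a)]
  v_mt_in_cp <- refinement_violations(b, a) # mt refines cp?
  v_cp_in_mt <- refinement_violations(a, b) # cp refines mt?
  if (v_mt_in_cp$total <= v_cp_in_mt$total) {
    v <- v_mt_in_cp; direction <- "mt_refines_cp"; fine <- b; coarse <- a
  } else {
    v <- v_cp_in_mt; direction <- "cp_refines_mt"; fine <- a; coarse <- b
  }
  n0 <- v$total
  removed <- character(0)
  while (v$total > 0) {
    worst <- names(which.max(v$per_sample))
    worst <- sort(names(v$per_sample)[v$per_sample == v$per_sample[worst]])[1L]
    removed <- c(removed, worst)
    fine <- fine[names(fine) != worst]
    coarse <- coarse[names(coarse) != worst]
    v <- refinement_violations(fine, coarse)
  }
  list(concordant = n0 == 0,
       direction = direction,
       discordant = removed,
       n_violating_pairs = n0,
       table = table(cp = a, mt = b))
}
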