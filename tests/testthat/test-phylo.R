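# Path-sum distances of a tree with branch lengths: the additivity oracle.
tree_distances <- function(tr) {
  ape::cophenetic.phylo(tr)
}

test_that("NJ recovers additive trees exactly (topology and lengths)", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(4:8, 1L)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    D <- tree_distances(tr)
    est <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), est), 0,
                 ignore_attr = TRUE)
    expect_equal(tree_distances(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  for (seed in c(3, 7, 9)) {
    gm <- random_gm(seed + 500, n_sites = 60L, n_samp = 7L,
                    p_missing = 0.05, p_het = 0)
    d <- snp_distance(gm)
    mine <- nj_tree(d)
    ref <- ape::nj(stats::as.dist(d$d))
    expect_equal(ape::dist.topo(mine, ref), 0, ignore_attr = TRUE)
  }
})

test_that("three-taxon NJ is the closed-form star resolution", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  expect_identical(ape::Ntip(tr), 3L)
  len <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(len[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("negative branch-length estimates are clamped to zero", {
  # classic non-additive configuration producing a negative NJ estimate
  D <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4, 4)
  D[1, 2] <- D[2, 1] <- 7  # force the inner estimate negative
  dimnames(D) <- list(letters[1:4], letters[1:4])
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are seeded, bounded and saturate on a
           planted split", {
  fv <- matrix(0L, 2, 40)
  fv[2, 1:34] <- 1L
  cfg <- sim_config(seed = 2, founders = c("P", "Q"),
                    n_sites_cp = 0L, n_sites_mt = 40L,
                    divergence_cp = matrix(0L, 2, 2),
                    divergence_mt = hamming_matrix(fv),
                    samples_per_founder = c(4L, 4L),
                    subgroup = FALSE, congeners = FALSE,
                    representatives = FALSE, country_table = FALSE,
                    n_extra_cp = 0L, n_extra_mt = 0L,
                    n_numt_sites = 0L, n_indel_sites = 0L,
                    n_lowqual_sites = 0L,
                    within_group_mut = 0.3, max_mut_per_sample = 1L,
                    missing_rate = 0, outgroup_divergence = 0.5,
                    outgroup_missing_rate = 0)
  sim <- simulate_population(cfg)
  intra <- run_filter_pipeline(sim$matrix, mode = "INTRA_GROUP")$matrix
  foc <- intra[, focal_samples(intra)]
  tr <- bootstrap_support(foc, n_reps = 100L, seed = 5L)
  expect_true(all(as.integer(tr$node.label) >= 0))
  expect_true(all(as.integer(tr$node.label) <= 100))
  # support of the planted P|Q bipartition
  p_ids <- names(sim$truth$founder_of)[sim$truth$founder_of == "P"]
  q_ids <- names(sim$truth$founder_of)[sim$truth$founder_of == "Q"]
  rooted <- root_at_outgroup(tr, p_ids[1])
  mrca <- ape::getMRCA(rooted, match(q_ids, rooted$tip.label))
  expect_identical(rooted$node.label[mrca - ape::Ntip(rooted)], "100")
  # determinism and n_reps = 1 bounds
  tr2 <- bootstrap_support(foc, n_reps = 100L, seed = 5L)
  expect_identical(tr$node.label, tr2$node.label)
  tr1 <- bootstrap_support(foc, n_reps = 1L, seed = 5L)
  expect_true(all(as.integer(tr1$node.label) %in% 0:1))
  expect_error(bootstrap_support(foc, n_reps = 0L), "n_reps")
})

test_that("outgroup rooting preserves leaves and bipartitions", {
  gm <- random_gm(777, n_sites = 50L, n_samp = 6L, p_missing = 0)
  tr <- nj_tree(snp_distance(gm))
  rooted <- root_at_outgroup(tr, "S06")
  expect_setequal(rooted$tip.label, tr$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(rooted), tr), 0,
               ignore_attr = TRUE)
  again <- root_at_outgroup(rooted, "S06")
  expect_equal(ape::dist.topo(ape::unroot(again), ape::unroot(rooted)), 0,
               ignore_attr = TRUE)
  # the ingroup stays a clade under repeated rooting
  expect_true(is_clade(rooted, setdiff(rooted$tip.label, "S06")))
  expect_true(is_clade(again, setdiff(again$tip.label, "S06")))
  expect_error(root_at_outgroup(tr, "nope"), "unknown leaf")
})

test_that("rooted synthetic tree mirrors the planted lineage structure", {
  sim <- simulate_population(sim_config(seed = 12))
  intra <- run_filter_pipeline(sim$matrix, mode = "INTRA_GROUP")$matrix
  part <- cluster_haplotypes(intra, 5)
  taxa <- tree_taxa(part, intra)
  tr <- root_at_outgroup(nj_tree(snp_distance(intra[, taxa])), "BraheaSpp")
  # the NA1-like haplotype groups with the sylvestris-like congener
  expect_true(is_clade(tr, c("69-MDJL-US", "P24-SYL-US")))
  # the two close founders (AG1-like and its derived NA2-like) are sisters
  expect_true(is_clade(tr, c("43-KHLS-QA", "DegNoor")))
})
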