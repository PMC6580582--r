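test_that("single-linkage clusters match brute-force components", {
  for (seed in 1:12) {
    gm <- random_gm(seed + 100, n_sites = 20L, n_samp = 8L,
                    p_missing = 0.15, p_het = 0.05)
    h <- sample(0:6, 1L)
    part <- cluster_haplotypes(gm, linkage_threshold = h)
    div <- divergence_counts(pairwise_similarity(gm))
    want <- bf_components(div, h)
    got <- part$assignment$haplotype[
      match(gm$samples$sample_id, part$assignment$sample_id)]
    # same partition up to labels
    expect_identical(table(paste(want, got)) |> length(),
                     length(unique(want)))
    expect_identical(length(unique(got)), length(unique(want)))
  }
})

test_that("labels are deterministic and invariant to sample order", {
  sim <- simulate_population(small_sim_cfg(seed = 9))
  intra <- run_filter_pipeline(sim$matrix, mode = "INTRA_GROUP")$matrix
  p1 <- cluster_haplotypes(intra, 5)
  set.seed(1)
  perm <- sample(ncol(intra$calls))
  p2 <- cluster_haplotypes(intra[, perm], 5)
  expect_identical(p1$members, p2$members)
  expect_identical(names(p1$members), paste0("H", seq_along(p1$members)))
  # two identical samples always co-cluster at threshold 0
  twin_samples <- data.frame(sample_id = c("t1", "t2"), taxon = "FOCAL",
                             stringsAsFactors = FALSE)
  twin <- genotype_matrix(intra$sites, twin_samples,
                          intra$calls[, c(1, 1)])
  pt <- cluster_haplotypes(twin, 0)
  expect_identical(length(pt$members), 1L)
})

test_that("consensus is the per-site majority with ties as missing", {
  sites <- data.frame(replicon = "cp", pos = 1:3, ref = "A", alt = "G",
                      qual = 1000, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("a", "b", "c"), taxon = "FOCAL",
                        stringsAsFactors = FALSE)
  calls <- rbind(c(1L, 1L, 0L),   # majority 1
                 c(0L, 1L, NA),   # tie -> NA
                 c(NA, NA, NA))   # all missing -> NA
  gm <- genotype_matrix(sites, samples, calls)
  part <- cluster_haplotypes(gm, linkage_threshold = 20L)
  expect_identical(length(part$members), 1L)
  expect_identical(unname(consensus_genotype(part, "H1")),
                   c(1L, NA, NA))
  expect_error(consensus_genotype(part, "H9"), "unknown")
  # singleton cluster: consensus equals the sample
  p1 <- cluster_haplotypes(gm[, "a"], 0)
  expect_identical(unname(consensus_genotype(p1, "H1")),
                   unname(gm$calls[, "a"]))
})

test_that("haplotype divergence counts planted founder differences exactly", {
  cfg <- small_sim_cfg(seed = 5, within_group_mut = 0, missing_rate = 0)
  sim <- simulate_population(cfg)
  intra <- run_filter_pipeline(sim$matrix, mode = "INTRA_GROUP")$matrix
  part <- cluster_haplotypes(intra, 5)
  expect_identical(length(part$members), 4L)
  # map labels to founders through membership
  lab_of <- vapply(names(part$members), function(l)
    unique(sim$truth$founder_of[part$members[[l]]]), character(1))
  D <- cfg$divergence$chloroplast + cfg$divergence$mitochondrion
  divg <- haplotype_divergence(part)
  for (k in seq_len(nrow(divg))) {
    fa <- lab_of[[divg$hap_a[k]]]
    fb <- lab_of[[divg$hap_b[k]]]
    expect_identical(divg$differences[k], D[fa, fb])
  }
  # per-replicon scope restricts the comparison
  dcp <- haplotype_divergence(part, scope = "chloroplast")
  expect_true(all(dcp$compared <= sum(intra$sites$replicon == "chloroplast")))
  p1 <- cluster_haplotypes(intra[, part$members$H1], 5)
  expect_error(haplotype_divergence(p1), "at least 2")
})

test_that("subgroup detection finds planted one-off samples by signature", {
  sim <- simulate_population(small_sim_cfg(seed = 31))
  intra <- run_filter_pipeline(sim$matrix, mode = "INTRA_GROUP")$matrix
  part <- cluster_haplotypes(intra, 5)
  sg <- detect_subgroups(part, exact_diff = 1L)
  sig <- subgroup_signatures(sg)
  hit <- sig[sig$diff_sites == sim$truth$subgroup_site, , drop = FALSE]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$n_samples, 2L)
  expect_setequal(strsplit(hit$sample_ids, ";")[[1]],
                  sim$truth$oneoff_samples)
  # a cluster whose members all equal the consensus yields no rows
  clean <- simulate_population(small_sim_cfg(seed = 32,
                                             within_group_mut = 0,
                                             subgroup = FALSE,
                                             missing_rate = 0))
  ic <- run_filter_pipeline(clean$matrix, mode = "INTRA_GROUP")$matrix
  expect_identical(nrow(detect_subgroups(cluster_haplotypes(ic, 5), 1L)), 0L)
})

test_that("concordance accepts nested partitions and flags planted swaps", {
  sim <- simulate_population(small_sim_cfg(seed = 61))
  intra <- run_filter_pipeline(sim$matrix, mode = "INTRA_GROUP")$matrix
  pcp <- cluster_haplotypes(intra, 5, scope = "chloroplast")
  pmt <- cluster_haplotypes(intra, 5, scope = "mitochondrion")
  cc <- organelle_concordance(pcp, pmt)
  expect_true(cc$concordant)
  expect_identical(cc$discordant, character(0))
  # identical partitions are trivially concordant
  cc2 <- organelle_concordance(pmt, pmt)
  expect_true(cc2$concordant)

  swapped <- plant_discordant_sample(simulate_population(
    small_sim_cfg(seed = 61)), "F1-003", "F2")
  si <- run_filter_pipeline(swapped$matrix, mode = "INTRA_GROUP")$matrix
  cc3 <- organelle_concordance(
    cluster_haplotypes(si, 5, scope = "chloroplast"),
    cluster_haplotypes(si, 5, scope = "mitochondrion"))
  expect_false(cc3$concordant)
  expect_identical(cc3$discordant, "F1-003")

  bad <- cluster_haplotypes(intra[, focal_samples(intra)[1:5]], 5)
  expect_error(organelle_concordance(bad, pmt), "different sample sets")
})
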