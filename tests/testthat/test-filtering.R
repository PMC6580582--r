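# A hand-built matrix exercising every filter rule: 2 focal, 1 congener,
# 1 outgroup sample.
filter_fixture <- function() {
  sites <- data.frame(
    replicon = "cp",
    pos = 1:7,
    ref = c("A", "A", "AT", "A", "A", "A", "A"),
    alt = c("G", "G", "A", "G", "G", "G", "G"),
    qual = c(1000, 900, 1500, 900.01, 2000, 1800, 1600),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = c("f1", "f2", "c1", "o1"),
    taxon = c("FOCAL", "FOCAL", "CONGENER", "OUTGROUP"),
    stringsAsFactors = FALSE
  )
  # pos1: clean focal polymorphism; pos2: qual == 900 boundary;
  # pos3: indel; pos4: qual just above threshold, variant in outgroup only;
  # pos5: HET in both focal samples (artifact); pos6: HET in one focal +
  # congener/outgroup hets (kept); pos7: all-reference.
  calls <- rbind(
    c(0L, 1L, 0L, 0L),
    c(0L, 1L, 0L, 0L),
    c(0L, 1L, 0L, 0L),
    c(0L, 0L, 0L, 1L),
    c(GT_HET, GT_HET, 0L, 0L),
    c(GT_HET, 0L, GT_HET, GT_HET),
    c(0L, 0L, 0L, 0L)
  )
  genotype_matrix(sites, samples, calls)
}

test_that("each removal filter applies exactly its stated rule", {
  gm <- filter_fixture()
  cfg <- filter_config()

  expect_identical(rownames(filter_indels(gm)$sites),
                   setdiff(rownames(gm$sites), "cp:3"))
  expect_identical(filter_indels(filter_indels(gm)), filter_indels(gm))

  kept_q <- filter_quality(gm, cfg)
  expect_false("cp:2" %in% rownames(kept_q$sites))  # 900 is not > 900
  expect_true("cp:4" %in% rownames(kept_q$sites))   # 900.01 survives

  kept_h <- filter_multi_het(gm, cfg)
  expect_false("cp:5" %in% rownames(kept_h$sites))  # HET in 2 focal
  expect_true("cp:6" %in% rownames(kept_h$sites))   # 1 focal + non-focal hets
})

test_that("selection stages implement any-sample vs within-group rules", {
  gm <- filter_fixture()
  any_s <- select_any_sample_variants(gm)
  expect_false("cp:7" %in% rownames(any_s$sites))   # no alt anywhere
  expect_false("cp:5" %in% rownames(any_s$sites))   # HET is not alt evidence
  expect_true("cp:4" %in% rownames(any_s$sites))    # outgroup-only variant

  intra <- select_intra_group_variants(gm)
  expect_true("cp:1" %in% rownames(intra$sites))
  expect_false("cp:4" %in% rownames(intra$sites))   # not focal-polymorphic
  expect_false("cp:6" %in% rownames(intra$sites))   # HET-only variation

  # fixed difference vs reference: all focal alt, outgroup ref
  fx <- gm
  fx$calls["cp:7", ] <- c(1L, 1L, 1L, 0L)
  expect_false("cp:7" %in%
                 rownames(select_intra_group_variants(fx)$sites))
  expect_true("cp:7" %in%
                rownames(select_any_sample_variants(fx)$sites))
})

test_that("removal filters commute and the cascade report conserves counts", {
  gm <- filter_fixture()
  cfg <- filter_config()
  perm1 <- filter_multi_het(filter_quality(filter_indels(gm), cfg), cfg)
  perm2 <- filter_indels(filter_quality(filter_multi_het(gm, cfg), cfg))
  expect_identical(rownames(perm1$sites), rownames(perm2$sites))

  res <- run_filter_pipeline(gm, cfg, "ANY_SAMPLE")
  rep <- as.data.frame(res$report)
  expect_true(all(rep$sites_in - rep$sites_removed == rep$sites_out))
  expect_identical(rep$sites_in[-1], rep$sites_out[-nrow(rep)])
  expect_identical(rep$sites_removed, rowSums(
    rep[, grep("^removed_", names(rep)), drop = FALSE]) |> as.integer() |>
      unname() |> identity())

  empty <- gm[integer(0), ]
  res0 <- run_filter_pipeline(empty, cfg, "INTRA_GROUP")
  expect_identical(n_sites(res0$matrix), 0L)
  expect_true(all(as.data.frame(res0$report)$sites_removed == 0L))
})

test_that("within-group selection is a subset of any-sample selection", {
  for (seed in 1:20) {
    gm <- random_gm(seed, n_sites = 25L, n_samp = 6L)
    cfg <- filter_config(min_qual = 500)
    a <- run_filter_pipeline(gm, cfg, "ANY_SAMPLE")$matrix
    b <- run_filter_pipeline(gm, cfg, "INTRA_GROUP")$matrix
    expect_true(all(rownames(b$sites) %in% rownames(a$sites)))
  }
})

test_that("filters remove exactly the planted decoys on synthetic data", {
  sim <- simulate_population(small_sim_cfg(seed = 42))
  tc <- sim$truth$site_class
  res <- run_filter_pipeline(sim$matrix, mode = "ANY_SAMPLE")
  kept <- rownames(res$matrix$sites)
  expect_setequal(kept, c(tc$planted, tc$extra))
  rep <- as.data.frame(res$report)
  expect_identical(rep$sites_removed[rep$stage == "indels"],
                   length(tc$indel))
  expect_identical(rep$sites_removed[rep$stage == "quality"],
                   length(tc$lowqual))
  expect_identical(rep$sites_removed[rep$stage == "multi_het"],
                   length(tc$numt))

  intra <- run_filter_pipeline(sim$matrix, mode = "INTRA_GROUP")$matrix
  expect_setequal(rownames(intra$sites),
                  c(sim$truth$variable_sites, sim$truth$subgroup_site))
})

test_that("het threshold is configurable", {
  gm <- filter_fixture()
  lax <- filter_config(max_het_focal = 2L)
  expect_true("cp:5" %in% rownames(filter_multi_het(gm, lax)$sites))
  strict <- filter_config(max_het_focal = 0L)
  expect_false("cp:6" %in% rownames(filter_multi_het(gm, strict)$sites))
})
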