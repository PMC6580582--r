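# Shared fixtures, all built in code.

# Pairwise Hamming distances of binary founder vectors (rows).
hamming_matrix <- function(v) {
  K <- nrow(v)
  D <- matrix(0L, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    D[i, j] <- sum(v[i, ] != v[j, ])
  D
}

# Four founders built from explicit binary vectors, so the divergence
# matrices are Hamming-realizable by construction.
small_founder_vectors <- function() {
  # F1/F3 are a nested pair 2 apart on cp (like the AG1/NA2 chloroplast);
  # all other distances stay >= 8 so that <=1 private mutation per sample
  # can never chain distinct founders across the default threshold of 5.
  f_cp <- rbind(
    F1 = rep(0L, 16),
    F2 = as.integer(seq_len(16) %in% 1:10),
    F3 = as.integer(seq_len(16) %in% 11:12),
    F4 = as.integer(seq_len(16) %in% c(1:6, 13:16))
  )
  f_mt <- rbind(
    F1 = rep(0L, 22),
    F2 = as.integer(seq_len(22) %in% 1:10),
    F3 = as.integer(seq_len(22) %in% 11:18),
    F4 = as.integer(seq_len(22) %in% c(1:5, 19:22))
  )
  list(cp = f_cp, mt = f_mt)
}

# Scaled-down 4-founder configuration: 12+1 chloroplast and 20 mitochondrial
# within-group sites, a 2-sample subgroup, decoys, no congeners.
small_sim_cfg <- function(seed = 1L, ...) {
  fv <- small_founder_vectors()
  args <- list(
    seed = seed,
    founders = rownames(fv$cp),
    n_sites_cp = 17L, n_sites_mt = 22L,
    divergence_cp = hamming_matrix(fv$cp),
    divergence_mt = hamming_matrix(fv$mt),
    samples_per_founder = c(8L, 6L, 4L, 3L),
    subgroup = list(founder = "F2", n = 2L, replicon = "chloroplast",
                    pos = 5000L),
    congeners = FALSE, representatives = FALSE, country_table = FALSE,
    n_extra_cp = 4L, n_extra_mt = 8L,
    n_numt_sites = 4L, n_indel_sites = 3L, n_lowqual_sites = 3L,
    within_group_mut = 0.2, max_mut_per_sample = 1L,
    missing_rate = 0.01, outgroup_missing_rate = 0.05,
    congener_het_rate = 0
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# Random genotype matrix (FOCAL samples only) exercising multiallelic SNPs,
# indels, HET and missing calls: round-trip / property fodder.
random_gm <- function(seed, n_sites = 10L, n_samp = 5L,
                      p_missing = 0.1, p_het = 0.1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  repl <- sample(c("chloroplast", "mitochondrion"), n_sites, replace = TRUE)
  pos <- integer(n_sites)
  for (r in unique(repl))
    pos[repl == r] <- sample.int(10000L, sum(repl == r))
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(seq_len(n_sites), function(i) {
    n_alt <- sample(1:2, 1L)
    paste(sample(setdiff(bases, ref[i]), n_alt), collapse = ",")
  }, character(1))
  idx_indel <- sample.int(n_sites, max(0L, n_sites %/% 5L))
  alt[idx_indel] <- paste0(ref[idx_indel], "A")
  n_alt <- lengths(strsplit(alt, ","))
  calls <- matrix(NA_integer_, n_sites, n_samp)
  for (i in seq_len(n_sites)) {
    u <- runif(n_samp)
    calls[i, ] <- sample(0:n_alt[i], n_samp, replace = TRUE)
    calls[i, u < p_het] <- GT_HET
    calls[i, u > 1 - p_missing] <- NA_integer_
  }
  sites <- data.frame(replicon = repl, pos = pos, ref = ref, alt = alt,
                      qual = round(runif(n_sites, 0, 3000), 2),
                      stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("S%02d", seq_len(n_samp)),
                        taxon = "FOCAL", stringsAsFactors = FALSE)
  genotype_matrix(sites, samples, calls)
}

# Brute-force single linkage at threshold h: connected components of the
# graph with edges wherever divergence <= h.
bf_components <- function(div, h) {
  n <- nrow(div)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (div[i, j] <= h && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Map a partition's labels to the planted founder names via majority vote.
partition_vs_truth_ari <- function(partition, truth) {
  ids <- partition$assignment$sample_id
  mclust::adjustedRandIndex(partition$assignment$haplotype,
                            truth$founder_of[ids])
}
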