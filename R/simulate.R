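# Synthetic organellar population generator. Plants K founder haplotypes
# whose pairwise Hamming distances equal a configured matrix exactly (cut
# decomposition), clonally derived focal samples with rare private
# mutations, a one-off subgroup, congener and outgroup lineages, and decoy
# artifact records (multi-sample heterozygous NUMT mimics, indels,
# low-quality sites) so that every pipeline stage has exact ground truth.

#' Simulation configuration
#'
#' Defaults emulate a population survey of a clonally propagated crop over
#' two organellar replicons: 201 focal samples in four founder haplotypes
#' (90/76/18/17), founder divergences realized exactly per replicon
#' (37 chloroplast + 168 mitochondrial within-crop polymorphic sites,
#' including a 7-sample subgroup one SNP off the second-largest haplotype at
#' chloroplast position 38,168), four congener lineages (one close to the
#' NA1-like founder), a distant outgroup, extra sites variant only outside
#' the focal group (bringing the any-sample SNP total to 177 + 841), and
#' planted decoy records.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_sites_cp,n_sites_mt within-focal-group polymorphic site counts
#'   per replicon (defaults 37, 168).
#' @param founders founder (haplotype) names, largest group first.
#' @param divergence_cp,divergence_mt symmetric integer matrices of founder
#'   pairwise Hamming distances per replicon (defaults reproduce exemplar
#'   per-organelle difference counts whose sums give the combined
#'   96/158/10/146/156/96 pattern).
#' @param samples_per_founder focal samples per founder (defaults
#'   90, 76, 18, 17).
#' @param within_group_mut expected number of private mutations per focal
#'   sample (Poisson; placed on founder-variable sites only, so planted site
#'   counts are preserved). Default 0.2.
#' @param max_mut_per_sample hard cap on private mutations per sample
#'   (default `Inf`); clonally propagated material is expected to carry at
#'   most a few.
#' @param missing_rate per-call missingness probability for focal and
#'   congener samples (default 0.02).
#' @param n_numt_sites decoy sites heterozygous in >= 2 focal samples
#'   (default 20).
#' @param n_indel_sites,n_lowqual_sites decoy indel and low-quality records
#'   (defaults 10, 10).
#' @param n_extra_cp,n_extra_mt sites variant only in congener/outgroup
#'   samples (defaults 140, 673).
#' @param subgroup `NULL`, or list `founder`, `n`, `replicon`, `pos`: plants
#'   `n` samples of that founder carrying one shared extra SNP at the stated
#'   coordinate (default: 7 samples of the second founder at
#'   chloroplast:38168).
#' @param congeners data.frame `name`, `sample_id`, `nearest` (founder
#'   name), `div_cp`, `div_mt` (SNP flips from the nearest founder per
#'   replicon).
#' @param outgroup_id outgroup sample name.
#' @param outgroup_divergence probability that the outgroup carries the
#'   alternate allele at a planted site (default 0.5).
#' @param outgroup_missing_rate per-call missingness for the outgroup
#'   (default 0.15; distant mapping loses calls).
#' @param congener_het_rate probability of a spurious heterozygous call in a
#'   congener at a kept site (default 0.01).
#' @param clean_representatives if `TRUE` (default) the first sample of each
#'   founder (the named exemplar) receives no private mutations and no
#'   missing calls.
#' @param representatives data.frame `founder`, `sample_id`, `country` of
#'   founder exemplars.
#' @param country_table data.frame `country` plus one integer column per
#'   founder; column sums must equal `samples_per_founder`.
#' @param replicon_len named numeric vector of replicon lengths.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_sites_cp = 37L, n_sites_mt = 168L,
                       founders = c("AG1", "NA1", "NA2", "AG2"),
                       divergence_cp = NULL, divergence_mt = NULL,
                       samples_per_founder = c(90L, 76L, 18L, 17L),
                       within_group_mut = 0.2,
                       max_mut_per_sample = Inf,
                       missing_rate = 0.02,
                       n_numt_sites = 20L,
                       n_indel_sites = 10L,
                       n_lowqual_sites = 10L,
                       n_extra_cp = 140L, n_extra_mt = 673L,
                       subgroup = list(founder = "NA1", n = 7L,
                                       replicon = "chloroplast",
                                       pos = 38168L),
                       congeners = NULL,
                       outgroup_id = "BraheaSpp",
                       outgroup_divergence = 0.5,
                       outgroup_missing_rate = 0.15,
                       congener_het_rate = 0.01,
                       clean_representatives = TRUE,
                       representatives = NULL,
                       country_table = NULL,
                       replicon_len = c(chloroplast = 158462,
                                        mitochondrion = 715001)) {
  K <- length(founders)
  # FALSE disables a component that would otherwise get a 4-founder default
  if (isFALSE(subgroup)) subgroup <- NULL
  no_congeners <- isFALSE(congeners)
  if (no_congeners) congeners <- NULL
  no_reps <- isFALSE(representatives)
  if (no_reps) representatives <- NULL
  no_country <- isFALSE(country_table)
  if (no_country) country_table <- NULL
  dmat <- function(m, vals) {
    if (!is.null(m)) {
      m <- as.matrix(m); dimnames(m) <- list(founders, founders); return(m)
    }
    if (K != 4L)
      stop("default divergence matrices are defined for 4 founders; ",
           "supply divergence_cp/divergence_mt")
    out <- matrix(0L, 4L, 4L, dimnames = list(founders, founders))
    out[lower.tri(out)] <- vals
    out[upper.tri(out)] <- t(out)[upper.tri(out)]
    out
  }
  # lower.tri order for founders (AG1, NA1, NA2, AG2):
  # (NA1,AG1) (NA2,AG1) (AG2,AG1) (NA2,NA1) (AG2,NA1) (AG2,NA2)
  divergence_cp <- dmat(divergence_cp, c(33L, 1L, 11L, 32L, 28L, 10L))
  divergence_mt <- dmat(divergence_mt, c(125L, 9L, 85L, 124L, 118L, 86L))
  for (m in list(divergence_cp, divergence_mt)) {
    stopifnot(isSymmetric(unname(m)), all(diag(m) == 0), all(m >= 0))
  }
  if (is.null(congeners) && K == 4L && !no_congeners) {
    congeners <- data.frame(
      name = c("sylvestris", "theophrasti", "canariensis", "roebelenii"),
      sample_id = c("P24-SYL-US", "Q19-THE-US", "P6-CAN-US", "P3-ROE-US"),
      nearest = c("NA1", "AG1", "AG1", "AG1"),
      div_cp = c(12L, 13L, 12L, 13L),
      div_mt = c(39L, 74L, 77L, 74L),
      stringsAsFactors = FALSE
    )
  } else if (is.null(congeners)) {
    congeners <- data.frame(name = character(0), sample_id = character(0),
                            nearest = character(0), div_cp = integer(0),
                            div_mt = integer(0), stringsAsFactors = FALSE)
  }
  if (is.null(representatives) && K == 4L && !no_reps) {
    representatives <- data.frame(
      founder = c("AG1", "NA1", "NA2", "AG2"),
      sample_id = c("43-KHLS-QA", "69-MDJL-US", "DegNoor", "15-JBR-AE"),
      country = c("Qatar", "USA", "USA", "UAE"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(country_table) && K == 4L && !no_country) {
    country_table <- data.frame(
      country = c("Algeria", "Egypt", "Iran", "Iraq", "Jordan",
                  "Saudi Arabia", "Libya", "Morocco", "Oman", "Pakistan",
                  "Qatar", "Sudan", "Tunisia", "UAE", "USA"),
      AG1 = c(12L, 4L, 1L, 3L, 4L, 17L, 1L, 8L, 4L, 2L, 5L, 0L, 0L, 17L, 12L),
      NA1 = c(13L, 6L, 0L, 0L, 0L, 1L, 4L, 24L, 0L, 3L, 0L, 6L, 3L, 0L, 16L),
      NA2 = c(3L, 1L, 0L, 0L, 1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 2L, 0L, 10L),
      AG2 = c(0L, 0L, 3L, 0L, 0L, 3L, 0L, 0L, 3L, 0L, 2L, 0L, 0L, 4L, 2L),
      stringsAsFactors = FALSE
    )
  }
  samples_per_founder <- stats::setNames(as.integer(samples_per_founder),
                                         founders)
  if (!is.null(country_table)) {
    for (f in founders) {
      if (sum(country_table[[f]]) != samples_per_founder[[f]])
        stop("country_table column ", f, " sums to ",
             sum(country_table[[f]]), ", expected ",
             samples_per_founder[[f]])
    }
  }
  if (!is.null(subgroup)) {
    stopifnot(subgroup$founder %in% founders,
              subgroup$replicon %in% names(replicon_len),
              subgroup$n <= samples_per_founder[[subgroup$founder]])
  }
  structure(list(
    seed = as.integer(seed),
    founders = founders,
    n_sites = c(chloroplast = as.integer(n_sites_cp),
                mitochondrion = as.integer(n_sites_mt)),
    divergence = list(chloroplast = divergence_cp,
                      mitochondrion = divergence_mt),
    samples_per_founder = samples_per_founder,
    within_group_mut = within_group_mut,
    max_mut_per_sample = max_mut_per_sample,
    missing_rate = missing_rate,
    n_numt_sites = as.integer(n_numt_sites),
    n_indel_sites = as.integer(n_indel_sites),
    n_lowqual_sites = as.integer(n_lowqual_sites),
    n_extra = c(chloroplast = as.integer(n_extra_cp),
                mitochondrion = as.integer(n_extra_mt)),
    subgroup = subgroup,
    congeners = congeners,
    outgroup_id = outgroup_id,
    outgroup_divergence = outgroup_divergence,
    outgroup_missing_rate = outgroup_missing_rate,
    congener_het_rate = congener_het_rate,
    clean_representatives = isTRUE(clean_representatives),
    representatives = representatives,
    country_table = country_table,
    replicon_len = replicon_len
  ), class = "sim_config")
}

# ---------------------------------------------------------------------------
# Exact Hamming realization of a founder distance matrix as weighted binary
# splits (cut decomposition). Returns list(sizes, carriers) where carriers
# are founder-index sets carrying the alternate allele for each block of
# `sizes` identical sites. Founder 1 is kept reference-like where possible.

realize_hamming_blocks <- function(D, target = NULL) {
  D <- unname(as.matrix(D))
  K <- nrow(D)
  stopifnot(isSymmetric(D), all(diag(D) == 0), all(D >= 0),
            all(D == round(D)))
  build <- function(sizes, carriers) {
    keep <- sizes > 0
    list(sizes = as.integer(sizes[keep]), carriers = carriers[keep])
  }
  verify <- function(bl) {
    R <- matrix(0L, K, K)
    for (b in seq_along(bl$sizes)) {
      cs <- bl$carriers[[b]]
      sep <- outer(seq_len(K) %in% cs, seq_len(K) %in% cs, `!=`)
      R <- R + bl$sizes[b] * sep
    }
    all(R == D)
  }
  candidates <- list()
  if (K == 1L) {
    candidates <- list(build(integer(0), list()))
  } else if (K == 2L) {
    candidates <- list(build(D[1, 2], list(2L)))
  } else if (K == 3L) {
    x <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
           (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
           (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    if (any(x < 0) || any(x != round(x)))
      stop("divergence matrix violates triangle/parity constraints; ",
           "not realizable as Hamming distances")
    candidates <- list(build(x, list(1L, 2L, 3L)))
  } else if (K == 4L) {
    s1 <- D[1, 2] + D[3, 4]; s2 <- D[1, 3] + D[2, 4]; s3 <- D[1, 4] + D[2, 3]
    for (t in 0:max(D)) {
      y <- c(t, t - (s2 - s1) / 2, t - (s3 - s1) / 2)
      if (any(y != round(y)) || any(y < 0)) next
      pAB <- D[1, 2] - (y[2] + y[3])
      pAC <- D[1, 3] - (y[1] + y[3])
      pAD <- D[1, 4] - (y[1] + y[2])
      pBC <- D[2, 3] - (y[1] + y[2])
      xA <- (pAB + pAC - pBC) / 2
      x <- c(xA, pAB - xA, pAC - xA, pAD - xA)
      if (any(x != round(x)) || any(x < 0)) next
      bl <- build(c(x, y),
                  c(list(1L, 2L, 3L, 4L),
                    list(c(3L, 4L), c(2L, 4L), c(2L, 3L))))
      if (verify(bl)) candidates[[length(candidates) + 1L]] <- bl
    }
    if (!length(candidates))
      stop("4-founder divergence matrix is not realizable as Hamming ",
           "distances (parity or non-negativity violated)")
  } else {
    # K > 4: require a tree-additive matrix; allocate blocks on NJ edges.
    rownames(D) <- colnames(D) <- paste0("F", seq_len(K))
    tr <- nj_tree(D)
    co <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    if (max(abs(co - D)) > 1e-8)
      stop("divergence matrices for more than 4 founders must be ",
           "tree-additive")
    if (any(abs(tr$edge.length - round(tr$edge.length)) > 1e-8))
      stop("tree-additive divergence matrix has non-integer edge lengths")
    sizes <- integer(0); carriers <- list()
    for (e in seq_len(nrow(tr$edge))) {
      len <- as.integer(round(tr$edge.length[e]))
      if (len == 0L) next
      child <- tr$edge[e, 2L]
      tips <- if (child <= K) tr$tip.label[child] else
        ape::extract.clade(tr, child)$tip.label
      idx <- match(tips, rownames(D))
      if (1L %in% idx) idx <- setdiff(seq_len(K), idx)
      sizes <- c(sizes, len)
      carriers <- c(carriers, list(sort(idx)))
    }
    bl <- build(sizes, carriers)
    if (!verify(bl)) stop("internal error: tree allocation mismatch")
    candidates <- list(bl)
  }
  used <- vapply(candidates, function(b) sum(b$sizes), numeric(1))
  if (!is.null(target)) {
    ok <- used <= target
    if (!any(ok))
      stop("divergence matrix needs at least ", min(used),
           " sites; only ", target, " configured")
    pick <- which(ok)[which.max(used[ok])]
  } else {
    pick <- which.max(used)
  }
  candidates[[pick]]
}

#' Plant founder haplotypes with exact pairwise divergences
#'
#' Constructs, per replicon, binary founder haplotype vectors whose realized
#' pairwise Hamming differences equal the configured divergence matrix
#' exactly, by allocating blocks of identical sites to binary splits of the
#' founder set (closed-form cut decomposition for up to 4 founders;
#' NJ-edge allocation for larger, tree-additive matrices). Unfilled columns
#' up to the configured site count are monomorphic across founders; the
#' planted subgroup site occupies one such column.
#'
#' @param cfg a [sim_config()].
#' @return named list (per replicon) of lists with `F` (founders x sites 0/1
#'   matrix), `variable` (columns where founders differ) and `subgroup_col`
#'   (column index of the subgroup site or `NA`).
#' @export
plant_founders <- function(cfg) {
  K <- length(cfg$founders)
  out <- list()
  for (r in names(cfg$replicon_len)) {
    target <- cfg$n_sites[[r]]
    has_sub <- !is.null(cfg$subgroup) && cfg$subgroup$replicon == r
    bl <- realize_hamming_blocks(cfg$divergence[[r]],
                                 target = target - as.integer(has_sub))
    used <- sum(bl$sizes)
    F <- matrix(0L, K, target, dimnames = list(cfg$founders, NULL))
    col <- 0L
    for (b in seq_along(bl$sizes)) {
      F[bl$carriers[[b]], col + seq_len(bl$sizes[b])] <- 1L
      col <- col + bl$sizes[b]
    }
    sub_col <- NA_integer_
    if (has_sub) {
      if (used + 1L > target)
        stop("no free column for the subgroup site on ", r)
      sub_col <- used + 1L
    }
    out[[r]] <- list(F = F, variable = seq_len(used), subgroup_col = sub_col)
  }
  out
}

# ---------------------------------------------------------------------------

#' Simulate an organellar population with planted truth
#'
#' Generates the full genotype matrix (focal samples copied from their
#' founders plus Poisson private mutations and per-call missingness, a
#' one-off subgroup, congeners, outgroup, extra non-focal variant sites, and
#' decoy NUMT/indel/low-quality records) together with a truth object
#' recording everything planted. Deterministic given `cfg$seed`.
#'
#' Generator guarantees (required for exact truth at any seed): private
#' mutations land only on founder-variable sites; planted one-off samples
#' receive none; the subgroup site is never masked; a missingness mask that
#' would erase a site's last alternate-allele call, or a planted site's
#' focal polymorphism, is repaired.
#'
#' @param cfg a [sim_config()].
#' @return an `organelle_sim`: list with `matrix` (a [genotype_matrix]),
#'   `truth`, and `config`.
#' @export
simulate_population <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  K <- length(cfg$founders)
  planted <- plant_founders(cfg)
  reps <- names(cfg$replicon_len)

  # --- samples ----------------------------------------------------------
  founder_of <- rep(cfg$founders, cfg$samples_per_founder)
  focal_ids <- character(length(founder_of))
  country <- character(length(founder_of))
  k <- 0L
  for (f in cfg$founders) {
    nf <- cfg$samples_per_founder[[f]]
    ids <- sprintf("%s-%03d", f, seq_len(nf))
    ctry <- rep("synthetic", nf)
    if (!is.null(cfg$country_table)) {
      pool <- rep(cfg$country_table$country, cfg$country_table[[f]])
    } else pool <- ctry
    rep_row <- if (!is.null(cfg$representatives))
      which(cfg$representatives$founder == f) else integer(0)
    if (length(rep_row)) {
      ids[1L] <- cfg$representatives$sample_id[rep_row[1L]]
      rc <- cfg$representatives$country[rep_row[1L]]
      hit <- match(rc, pool)
      if (is.na(hit)) stop("representative country ", rc,
                           " not present in country_table for ", f)
      ctry[1L] <- rc
      ctry[-1L] <- pool[-hit]
    } else ctry <- pool
    focal_ids[k + seq_len(nf)] <- ids
    country[k + seq_len(nf)] <- ctry
    k <- k + nf
  }
  n_focal <- length(focal_ids)
  cong <- cfg$congeners
  all_ids <- c(focal_ids, cong$sample_id, cfg$outgroup_id)
  n_all <- length(all_ids)
  i_focal <- seq_len(n_focal)
  i_cong <- n_focal + seq_len(nrow(cong))
  i_out <- n_all
  rep_ids <- if (!is.null(cfg$representatives)) cfg$representatives$sample_id
             else character(0)

  # --- sites ------------------------------------------------------------
  n_planted <- vapply(planted, function(z) ncol(z$F), integer(1))
  prop <- if (sum(n_planted)) n_planted / sum(n_planted)
          else rep(1 / length(reps), length(reps))
  alloc <- function(n) {
    a <- floor(n * prop)
    r <- n - sum(a)
    if (r > 0) {
      o <- order(n * prop - a, decreasing = TRUE)
      a[o[seq_len(r)]] <- a[o[seq_len(r)]] + 1L
    }
    stats::setNames(as.integer(a), reps)
  }
  n_numt <- alloc(cfg$n_numt_sites)
  n_indel <- alloc(cfg$n_indel_sites)
  n_lowqual <- alloc(cfg$n_lowqual_sites)

  site_rows <- list()
  calls_rows <- list()
  truth_class <- list(planted = character(0), extra = character(0),
                      numt = character(0), indel = character(0),
                      lowqual = character(0))
  variable_keys <- character(0)
  founder_keys <- list()
  subgroup_key <- NA_character_
  bases <- c("A", "C", "G", "T")

  for (r in reps) {
    P <- n_planted[[r]]
    E <- cfg$n_extra[[r]]
    counts <- c(planted = P, extra = E, numt = n_numt[[r]],
                indel = n_indel[[r]], lowqual = n_lowqual[[r]])
    total_r <- sum(counts)
    if (total_r == 0L) next
    L <- cfg$replicon_len[[r]]
    has_sub <- !is.na(planted[[r]]$subgroup_col)
    if (has_sub) {
      pos <- sample((seq_len(L))[-cfg$subgroup$pos], total_r - 1L)
    } else {
      pos <- sample.int(L, total_r)
    }
    role <- rep(names(counts), counts)
    # positions in drawn (random) order; planted subgroup column pinned
    if (has_sub) {
      pos <- append(pos, cfg$subgroup$pos, after = planted[[r]]$subgroup_col - 1L)
    }
    ref <- sample(bases, total_r, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    # indel decoys: single-base insertion in ALT
    alt[role == "indel"] <- paste0(ref[role == "indel"],
                                   sample(bases, sum(role == "indel"),
                                          replace = TRUE))
    qual <- round(stats::runif(total_r, 900.01, 3000), 2)
    qual[role == "lowqual"] <- round(stats::runif(sum(role == "lowqual"),
                                                  0, 900), 2)
    key <- paste(r, pos, sep = ":")
    if (anyDuplicated(key)) stop("internal: duplicate synthetic positions")

    m <- matrix(0L, total_r, n_all)
    # planted founder sites
    if (P) {
      Fz <- planted[[r]]$F
      m[which(role == "planted"), i_focal] <-
        Fz[match(founder_of, cfg$founders), , drop = FALSE] |> t()
      # congeners: copy nearest founder, flip div_r founder-variable sites
      if (nrow(cong)) {
        div_col <- if (r == "chloroplast") "div_cp" else "div_mt"
        for (ci in seq_len(nrow(cong))) {
          v <- Fz[cong$nearest[ci], ]
          nf <- min(cong[[div_col]][ci], length(planted[[r]]$variable))
          flip <- sample(planted[[r]]$variable, nf)
          v[flip] <- 1L - v[flip]
          m[which(role == "planted"), i_cong[ci]] <- v
        }
      }
      m[which(role == "planted"), i_out] <-
        stats::rbinom(P, 1L, cfg$outgroup_divergence)
      variable_keys <- c(variable_keys, key[role == "planted"][planted[[r]]$variable])
      founder_keys[[r]] <- key[role == "planted"]
      if (has_sub) subgroup_key <- key[planted[[r]]$subgroup_col]
    }
    # extra sites: variant only outside the focal group
    if (E) {
      er <- which(role == "extra")
      if (nrow(cong))
        for (ci in seq_len(nrow(cong)))
          m[er, i_cong[ci]] <- stats::rbinom(E, 1L, 0.25)
      m[er, i_out] <- stats::rbinom(E, 1L, 0.8)
      none <- rowSums(m[er, c(i_cong, i_out), drop = FALSE]) == 0L
      m[er[none], i_out] <- 1L
    }
    # NUMT mimics: HET in >= 2 focal samples
    for (ri in which(role == "numt")) {
      sz <- sample(2:min(6L, n_focal), 1L)
      m[ri, sample(i_focal, sz)] <- GT_HET
    }
    # indel / low-quality decoys carry real focal variation so only their
    # own filter removes them
    for (ri in which(role %in% c("indel", "lowqual"))) {
      nsub <- sample(seq_len(K - 1L), 1L)
      fsub <- sample(cfg$founders, nsub)
      m[ri, i_focal[founder_of %in% fsub]] <- 1L
    }

    site_rows[[r]] <- data.frame(replicon = r, pos = pos, ref = ref,
                                 alt = alt, qual = qual,
                                 stringsAsFactors = FALSE)
    rownames(site_rows[[r]]) <- key
    calls_rows[[r]] <- m
    for (cl in names(counts))
      truth_class[[cl]] <- c(truth_class[[cl]], key[role == cl])
  }

  sites <- do.call(rbind, unname(site_rows))
  calls <- do.call(rbind, unname(calls_rows))
  rownames(sites) <- paste(sites$replicon, sites$pos, sep = ":")
  rownames(calls) <- rownames(sites)
  colnames(calls) <- all_ids

  # --- subgroup one-offs -------------------------------------------------
  oneoff_ids <- character(0)
  if (!is.na(subgroup_key)) {
    pool <- focal_ids[founder_of == cfg$subgroup$founder]
    pool <- setdiff(pool, rep_ids)
    oneoff_ids <- sort(sample(pool, cfg$subgroup$n))
    calls[subgroup_key, oneoff_ids] <- 1L
  }

  # --- private mutations -------------------------------------------------
  mut_log <- list()
  mut_eligible <- setdiff(focal_ids, c(oneoff_ids,
                                       if (cfg$clean_representatives) rep_ids))
  if (length(variable_keys) && cfg$within_group_mut > 0) {
    for (s in mut_eligible) {
      nm <- stats::rpois(1L, cfg$within_group_mut)
      nm <- min(nm, cfg$max_mut_per_sample, length(variable_keys))
      if (nm == 0L) next
      ks <- sample(variable_keys, nm)
      calls[ks, s] <- 1L - calls[ks, s]
      mut_log[[s]] <- ks
    }
  }

  # --- congener heterozygous calls --------------------------------------
  if (length(i_cong) && cfg$congener_het_rate > 0) {
    kept <- c(truth_class$planted, truth_class$extra)
    for (ci in i_cong) {
      zero <- kept[calls[kept, ci] == 0L]
      het <- zero[stats::runif(length(zero)) < cfg$congener_het_rate]
      calls[het, ci] <- GT_HET
    }
  }

  # --- missingness with truth-preserving repair --------------------------
  rate <- rep(cfg$missing_rate, n_all)
  rate[i_out] <- cfg$outgroup_missing_rate
  mask <- matrix(stats::runif(length(calls)), nrow(calls)) <
    matrix(rate, nrow(calls), n_all, byrow = TRUE)
  dimnames(mask) <- dimnames(calls)
  if (cfg$clean_representatives)
    mask[, colnames(calls) %in% rep_ids] <- FALSE
  if (!is.na(subgroup_key)) mask[subgroup_key, ] <- FALSE
  foc_cols <- i_focal
  for (ri in seq_len(nrow(calls))) {
    mrow <- mask[ri, ]
    if (!any(mrow)) next
    v <- calls[ri, ]
    # keep at least one visible alternate-allele call where one was planted
    alt_idx <- which(v >= 1L)
    if (length(alt_idx) && all(mrow[alt_idx]))
      mrow[alt_idx[1L]] <- FALSE
    # keep focal polymorphism visible at planted polymorphic sites
    if (rownames(calls)[ri] %in% variable_keys ||
        identical(rownames(calls)[ri], subgroup_key)) {
      f1 <- foc_cols[v[foc_cols] >= 1L]
      f0 <- foc_cols[v[foc_cols] == 0L]
      if (length(f1) && all(mrow[f1])) mrow[f1[1L]] <- FALSE
      if (length(f0) && all(mrow[f0])) mrow[f0[1L]] <- FALSE
    }
    mask[ri, ] <- mrow
  }
  calls[mask] <- NA_integer_

  # --- assemble ----------------------------------------------------------
  metadata <- data.frame(
    sample_id = all_ids,
    taxon = c(rep("FOCAL", n_focal), rep("CONGENER", nrow(cong)), "OUTGROUP"),
    country = c(country, rep("", nrow(cong)), ""),
    cultivar = c(ifelse(focal_ids %in% rep_ids, focal_ids,
                        paste0("cv-", focal_ids)),
                 cong$name, "outgroup"),
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(sites, metadata, calls,
                        replicon_len = cfg$replicon_len)
  truth <- list(
    founder_of = stats::setNames(founder_of, focal_ids),
    founder_calls = lapply(reps, function(r) {
      F <- planted[[r]]$F
      colnames(F) <- founder_keys[[r]]
      F
    }) |> stats::setNames(reps),
    site_class = truth_class,
    variable_sites = variable_keys,
    subgroup_site = subgroup_key,
    oneoff_samples = oneoff_ids,
    private_mutations = mut_log,
    representatives = rep_ids,
    congeners = cong,
    outgroup_id = cfg$outgroup_id
  )
  structure(list(matrix = gm, truth = truth, config = cfg),
            class = "organelle_sim")
}

#' @export
print.organelle_sim <- function(x, ...) {
  cat("organelle_sim (seed ", x$config$seed, ")\n", sep = "")
  print(x$matrix)
  invisible(x)
}

#' Plant a discordant sample (organelle swap)
#'
#' Replaces one focal sample's planted chloroplast genotypes with those of a
#' different founder, emulating a (never actually observed) mixed maternal
#' transmission; used to verify that concordance checking flags exactly the
#' manipulated sample.
#'
#' @param sim an `organelle_sim`.
#' @param sample_id focal sample to modify.
#' @param to_founder founder name whose chloroplast haplotype the sample
#'   receives.
#' @param replicon replicon to swap (default `"chloroplast"`).
#' @return the modified `organelle_sim` (truth gains `discordant_sample`).
#' @export
plant_discordant_sample <- function(sim, sample_id, to_founder,
                                    replicon = "chloroplast") {
  stopifnot(inherits(sim, "organelle_sim"),
            sample_id %in% names(sim$truth$founder_of),
            to_founder %in% rownames(sim$truth$founder_calls[[replicon]]))
  F <- sim$truth$founder_calls[[replicon]]
  sim$matrix$calls[colnames(F), sample_id] <- F[to_founder, ]
  if (!is.na(sim$truth$subgroup_site) &&
      sim$truth$subgroup_site %in% colnames(F))
    sim$matrix$calls[sim$truth$subgroup_site, sample_id] <- 0L
  sim$truth$discordant_sample <- sample_id
  sim
}

#' Write a simulated dataset to files
#'
#' Emits `genotypes.vcf`, `metadata.tsv` and `truth.json` into `dir`.
#'
#' @param sim an `organelle_sim`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
simulate_to_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "genotypes.vcf")
  meta <- file.path(dir, "metadata.tsv")
  truth <- file.path(dir, "truth.json")
  write_vcf(sim$matrix, vcf)
  write_sample_metadata(sim$matrix$samples, meta)
  tr <- sim$truth
  tr$founder_calls <- lapply(tr$founder_calls, function(F)
    apply(F, 1L, paste, collapse = ""))
  jsonlite::write_json(tr, truth, auto_unbox = TRUE, null = "null")
  invisible(c(vcf = vcf, metadata = meta, truth = truth))
}
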