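# End-to-end orchestration: read -> filter -> similarity -> haplotypes ->
# subgroups -> concordance -> divergence -> trees -> origin report, with a
# reproducible run manifest.

#' Choose tree taxa: one representative per haplotype plus all non-focal
#' samples
#'
#' The representative of a haplotype is the member closest to the cluster
#' consensus (ties broken lexicographically).
#'
#' @param partition a `haplotype_partition`.
#' @param x the [genotype_matrix] the partition was computed from (supplies
#'   congener/outgroup samples).
#' @return character vector of sample IDs.
#' @export
tree_taxa <- function(partition, x) {
  reps <- vapply(names(partition$members), function(lab) {
    cons <- partition$consensus[, lab]
    m <- partition$members[[lab]]
    dd <- vapply(m, function(s) {
      v <- partition$calls[, s]
      both <- !is.na(v) & !is.na(cons)
      sum(v[both] != cons[both])
    }, numeric(1))
    sort(m[dd == min(dd)])[1L]
  }, character(1))
  c(unname(reps), x$samples$sample_id[x$samples$taxon != "FOCAL"])
}

#' Run the whole analysis pipeline
#'
#' Executes: VCF ingest, the two filter cascades (any-sample and
#' intra-group), per-replicon and combined similarity matrices, haplotype
#' clustering (combined intra-group sites and per-replicon), subgroup
#' detection, organelle concordance, inter-haplotype divergence,
#' bootstrapped NJ trees per replicon on representative taxa, and the
#' country-by-haplotype report. All outputs are written to `out_dir` and
#' listed, with checksums, in `manifest.json`.
#'
#' @param vcf path to the multi-sample VCF, or a [genotype_matrix].
#' @param metadata sample metadata data.frame or TSV path (ignored when
#'   `vcf` is already a genotype matrix).
#' @param out_dir output directory.
#' @param cfg a [filter_config()].
#' @param linkage_threshold single-linkage threshold for
#'   [cluster_haplotypes()].
#' @param tree_reps,tree_seed bootstrap replicates and seed for
#'   [bootstrap_support()].
#' @param outgroup_id outgroup sample for rooting; defaults to the single
#'   OUTGROUP-taxon sample when present.
#' @return the manifest list, invisibly.
#' @export
run_all <- function(vcf, metadata = NULL, out_dir,
                    cfg = filter_config(),
                    linkage_threshold = 5L,
                    tree_reps = 100L, tree_seed = 1L,
                    outgroup_id = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- if (inherits(vcf, "genotype_matrix")) vcf else read_vcf(vcf, metadata)
  replicons <- sort(unique(gm$sites$replicon))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  any_res <- stage("filter_any_sample",
                   run_filter_pipeline(gm, cfg, "ANY_SAMPLE"))
  intra_res <- stage("filter_intra_group",
                     run_filter_pipeline(gm, cfg, "INTRA_GROUP"))
  files <- c(
    filter_report_any = file.path(out_dir, "filter_report_any_sample.tsv"),
    filter_report_intra = file.path(out_dir, "filter_report_intra_group.tsv")
  )
  write_filter_report(any_res$report, files[["filter_report_any"]])
  write_filter_report(intra_res$report, files[["filter_report_intra"]])

  intra <- intra_res$matrix
  reps_intra <- intersect(replicons, unique(intra$sites$replicon))
  sims <- list(combined = pairwise_similarity(intra))
  for (r in reps_intra) sims[[r]] <- pairwise_similarity(intra, scope = r)
  for (nm in names(sims)) {
    f <- file.path(out_dir, sprintf("similarity_%s.tsv", nm))
    files[[paste0("similarity_", nm)]] <- f
    write_similarity(sims[[nm]], f)
  }

  part <- stage("clustering",
                cluster_haplotypes(intra, linkage_threshold))
  files[["partition"]] <- file.path(out_dir, "haplotype_partition.tsv")
  utils::write.table(part$assignment, files[["partition"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  sub <- detect_subgroups(part, exact_diff = 1L)
  files[["subgroups"]] <- file.path(out_dir, "subgroups.tsv")
  utils::write.table(subgroup_signatures(sub), files[["subgroups"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)

  parts_rep <- lapply(reps_intra, function(r)
    stage(paste0("clustering_", r),
          cluster_haplotypes(intra, linkage_threshold, scope = r)))
  names(parts_rep) <- reps_intra
  conc <- if (length(reps_intra) == 2L)
    stage("concordance",
          organelle_concordance(parts_rep[[1L]], parts_rep[[2L]]))
  else NULL
  if (!is.null(conc)) {
    files[["concordance"]] <- file.path(out_dir, "concordance.json")
    jsonlite::write_json(
      list(concordant = conc$concordant, direction = conc$direction,
           discordant = conc$discordant,
           n_violating_pairs = conc$n_violating_pairs),
      files[["concordance"]], auto_unbox = TRUE)
  }

  divg <- stage("divergence", haplotype_divergence(part))
  files[["divergence"]] <- file.path(out_dir, "haplotype_divergence.tsv")
  utils::write.table(divg, files[["divergence"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  taxa <- tree_taxa(part, intra)
  if (is.null(outgroup_id)) {
    og <- gm$samples$sample_id[gm$samples$taxon == "OUTGROUP"]
    outgroup_id <- if (length(og) == 1L) og else NULL
  }
  trees <- list()
  for (r in reps_intra) {
    tr <- stage(paste0("tree_", r),
                bootstrap_support(intra[, taxa], n_reps = tree_reps,
                                  seed = tree_seed, scope = r))
    if (!is.null(outgroup_id) && outgroup_id %in% tr$tip.label)
      tr <- root_at_outgroup(tr, outgroup_id)
    f <- file.path(out_dir, sprintf("tree_%s.nwk", r))
    files[[paste0("tree_", r)]] <- f
    write_newick(tr, f)
    trees[[r]] <- tr
  }

  tab <- stage("report", contingency(part, gm$samples))
  files[["contingency"]] <- file.path(out_dir, "contingency.tsv")
  utils::write.table(tab, files[["contingency"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files[["haplotype_counts"]] <- file.path(out_dir, "haplotype_counts.tsv")
  hc <- haplotype_counts(part)
  utils::write.table(data.frame(haplotype = names(hc),
                                count = as.integer(hc)),
                     files[["haplotype_counts"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    parameters = list(min_qual = cfg$min_qual,
                      max_het_focal = cfg$max_het_focal,
                      drop_indels = cfg$drop_indels,
                      linkage_threshold = as.integer(linkage_threshold),
                      tree_reps = as.integer(tree_reps),
                      tree_seed = as.integer(tree_seed),
                      outgroup = outgroup_id),
    counts = list(
      samples = nrow(gm$samples),
      focal_samples = sum(gm$samples$taxon == "FOCAL"),
      sites_input = nrow(gm$sites),
      any_sample_sites = nrow(any_res$matrix$sites),
      intra_group_sites = nrow(intra$sites),
      per_replicon = lapply(stats::setNames(replicons, replicons),
        function(r) list(
          any_sample = sum(any_res$matrix$sites$replicon == r),
          intra_group = sum(intra$sites$replicon == r))),
      n_haplotypes = length(part$members),
      haplotype_sizes = as.list(haplotype_counts(part)),
      concordant = if (!is.null(conc)) conc$concordant else NA
    ),
    outputs = as.list(stats::setNames(basename(unlist(files)),
                                      names(files)))
  )
  files[["manifest"]] <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  md5 <- tools::md5sum(unlist(files))
  manifest$checksums <- as.list(stats::setNames(unname(md5),
                                                basename(names(md5))))
  invisible(manifest)
}
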