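# SNP filter cascade: indel removal, population call-quality threshold,
# multi-sample heterozygosity (NUMT-signature) filter, then selection of the
# population-wide or within-crop polymorphic site set.

#' Filter configuration
#'
#' @param min_qual sites are kept only if `qual > min_qual` (strict). The
#'   default, 900, matches a stringent population call-quality threshold for
#'   deeply sequenced organelles.
#' @param max_het_focal maximum number of FOCAL samples allowed to carry a
#'   heterozygous call at a kept site. Sites heterozygous in more focal
#'   samples than this are removed as likely duplicated/repetitive regions or
#'   nuclear-transferred organellar (NUMT) segments. Default 1, i.e.
#'   "heterozygous in multiple samples" triggers removal.
#' @param drop_indels drop non-SNP records (default `TRUE`).
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_qual = 900, max_het_focal = 1L,
                          drop_indels = TRUE) {
  stopifnot(min_qual >= 0, max_het_focal >= 0)
  structure(list(min_qual = min_qual,
                 max_het_focal = as.integer(max_het_focal),
                 drop_indels = isTRUE(drop_indels)),
            class = "filter_config")
}

#' Remove insertion/deletion records
#'
#' Retains only sites of class SNP; the sample set is unchanged.
#'
#' @param x a [genotype_matrix].
#' @return filtered [genotype_matrix].
#' @export
filter_indels <- function(x) {
  x[x$sites$vclass == "SNP", ]
}

#' Remove low-quality sites
#'
#' Retains sites whose population call quality is strictly greater than
#' `cfg$min_qual`; a site with `qual` exactly at the threshold is removed.
#'
#' @param x a [genotype_matrix].
#' @param cfg a [filter_config()].
#' @return filtered [genotype_matrix].
#' @export
filter_quality <- function(x, cfg = filter_config()) {
  keep <- !is.na(x$sites$qual) & x$sites$qual > cfg$min_qual
  x[keep, ]
}

#' Remove sites heterozygous in multiple focal samples
#'
#' Organelles are effectively haploid, so a site at which several focal
#' samples are called heterozygous is most plausibly a duplicated or
#' nuclear-transferred region rather than real variation. Heterozygous calls
#' in congener or outgroup samples do not trigger removal.
#'
#' @param x a [genotype_matrix].
#' @param cfg a [filter_config()]; sites with more than `max_het_focal` focal
#'   HET calls are removed.
#' @return filtered [genotype_matrix].
#' @export
filter_multi_het <- function(x, cfg = filter_config()) {
  foc <- x$samples$taxon == "FOCAL"
  if (!any(foc) || nrow(x$sites) == 0L) return(x)
  n_het <- rowSums(x$calls[, foc, drop = FALSE] == GT_HET, na.rm = TRUE)
  x[n_het <= cfg$max_het_focal, ]
}

#' Select sites variant in any sample
#'
#' Retains sites where at least one sample of any taxon carries a called
#' alternate allele (`ALLELE(k)`, k >= 1). Heterozygous and missing calls do
#' not count as alternate-allele evidence.
#'
#' @param x a [genotype_matrix].
#' @return filtered [genotype_matrix].
#' @export
select_any_sample_variants <- function(x) {
  if (nrow(x$sites) == 0L) return(x)
  any_alt <- rowSums(x$calls >= 1L, na.rm = TRUE) > 0L
  x[any_alt, ]
}

#' Select sites polymorphic within the focal group
#'
#' Retains sites at which at least two distinct called allele states occur
#' among FOCAL samples. Heterozygous and missing calls are excluded from the
#' distinct-state count, so a site that is monomorphic-nonreference in the
#' focal group (a fixed difference against the reference cultivar) or
#' variant only in congeners/outgroup is dropped.
#'
#' @param x a [genotype_matrix].
#' @return filtered [genotype_matrix].
#' @export
select_intra_group_variants <- function(x) {
  foc <- x$samples$taxon == "FOCAL"
  if (nrow(x$sites) == 0L) return(x)
  m <- x$calls[, foc, drop = FALSE]
  m[m == GT_HET] <- NA_integer_
  n_states <- apply(m, 1L, function(v) length(unique(v[!is.na(v)])))
  x[n_states >= 2L, ]
}

#' Run the full filter cascade
#'
#' Applies, in order: indel removal, quality threshold, multi-focal-het
#' (NUMT) removal, then the selection stage given by `mode`. The three
#' removal filters commute; the selection stage must run last.
#'
#' @param x a [genotype_matrix].
#' @param cfg a [filter_config()].
#' @param mode `"ANY_SAMPLE"` (variant in any sample, any taxon) or
#'   `"INTRA_GROUP"` (polymorphic within the focal group).
#' @return list with `matrix` (the filtered [genotype_matrix]) and `report`
#'   (a `filter_report` data.frame of per-stage and per-replicon counts).
#' @export
run_filter_pipeline <- function(x, cfg = filter_config(),
                                mode = c("ANY_SAMPLE", "INTRA_GROUP")) {
  mode <- match.arg(mode)
  stages <- list(
    indels = if (cfg$drop_indels) filter_indels else identity,
    quality = function(g) filter_quality(g, cfg),
    multi_het = function(g) filter_multi_het(g, cfg),
    selection = if (mode == "ANY_SAMPLE") select_any_sample_variants
                else select_intra_group_variants
  )
  replicons <- sort(unique(x$sites$replicon))
  rows <- list()
  cur <- x
  for (nm in names(stages)) {
    nxt <- stages[[nm]](cur)
    removed_keys <- setdiff(rownames(cur$sites), rownames(nxt$sites))
    by_rep <- table(factor(cur$sites[removed_keys, "replicon"],
                           levels = replicons))
    rows[[nm]] <- data.frame(
      stage = nm,
      sites_in = nrow(cur$sites),
      sites_removed = length(removed_keys),
      sites_out = nrow(nxt$sites),
      stringsAsFactors = FALSE
    )
    for (r in replicons) rows[[nm]][[paste0("removed_", r)]] <- as.integer(by_rep[[r]])
    cur <- nxt
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "mode") <- mode
  class(report) <- c("filter_report", class(report))
  list(matrix = cur, report = report)
}

#' Write a filter report as TSV
#' @param report a `filter_report` from [run_filter_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
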