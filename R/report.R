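# Reporting layer: haplotype-by-origin contingency tables and haplotype
# count summaries.

#' Country-by-haplotype contingency table
#'
#' Counts FOCAL samples per (country, haplotype) cell. Rows are countries in
#' alphabetical order (empty country becomes `"unknown"`); columns are
#' haplotype labels in cluster-label order; a `total` column holds row sums
#' computed from the cells.
#'
#' @param partition a `haplotype_partition`.
#' @param metadata sample metadata data.frame (`sample_id`, `country`, ...).
#' @return data.frame with `country`, one column per haplotype, and `total`.
#' @export
contingency <- function(partition, metadata) {
  asg <- partition$assignment
  miss <- setdiff(asg$sample_id, metadata$sample_id)
  if (length(miss))
    stop("assigned sample(s) absent from metadata: ",
         paste(miss, collapse = ", "))
  country <- metadata$country[match(asg$sample_id, metadata$sample_id)]
  country[is.na(country) | country == ""] <- "unknown"
  labs <- names(partition$members)
  if (!nrow(asg)) {
    out <- data.frame(country = character(0), stringsAsFactors = FALSE)
    for (h in labs) out[[h]] <- integer(0)
    out$total <- integer(0)
    return(out)
  }
  tab <- table(country = country, haplotype = factor(asg$haplotype, labs))
  out <- data.frame(country = sort(rownames(tab)), stringsAsFactors = FALSE)
  for (h in labs) out[[h]] <- as.integer(tab[out$country, h])
  out$total <- as.integer(rowSums(tab[out$country, , drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Haplotype group sizes
#'
#' @param partition a `haplotype_partition`.
#' @return named integer vector of cluster sizes; the sum equals the number
#'   of assigned focal samples.
#' @export
haplotype_counts <- function(partition) {
  lengths(partition$members)
}

#' Flag rows whose declared totals disagree with cell sums
#'
#' Published tables occasionally carry row totals that do not equal the sum
#' of their cells. This helper compares a computed contingency table against
#' externally declared row totals and flags mismatches instead of
#' reproducing them.
#'
#' @param tab contingency data.frame from [contingency()].
#' @param declared named integer vector of declared row totals
#'   (names = countries).
#' @return data.frame `country`, `cell_sum`, `declared`, `mismatch`.
#' @export
verify_row_totals <- function(tab, declared) {
  cell_sum <- tab$total
  names(cell_sum) <- tab$country
  common <- intersect(names(declared), names(cell_sum))
  data.frame(
    country = common,
    cell_sum = as.integer(cell_sum[common]),
    declared = as.integer(declared[common]),
    mismatch = as.integer(cell_sum[common]) != as.integer(declared[common]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
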