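# Pairwise identity with pairwise-complete denominators, and the derived
# p-distance matrix.

#' Pairwise similarity with pairwise-complete denominators
#'
#' For every ordered sample pair, `comparable` counts the sites at which both
#' samples have a non-missing call, and `identical` counts the subset of
#' those at which the two (collapsed) states are equal. States are compared
#' symbolically: HET equals HET; otherwise allele indices must match. This is
#' the "identical/comparable" cell convention of organellar similarity
#' tables, where missing data makes the denominator vary per pair.
#'
#' @param x a [genotype_matrix], typically already filtered to an analysis
#'   site set.
#' @param scope `NULL` for all replicons, or replicon name(s) (see
#'   [scope_sites()]).
#' @param samples optional character vector restricting the comparison to a
#'   sample subset.
#' @return an `snp_similarity` object: list with `samples`, integer matrices
#'   `identical` and `comparable`, and `n_sites`.
#' @export
pairwise_similarity <- function(x, scope = NULL, samples = NULL) {
  x <- scope_sites(x, scope)
  if (!is.null(samples)) x <- x[, samples]
  m <- x$calls
  obs <- !is.na(m)
  comparable <- crossprod(obs)
  identical_m <- matrix(0L, ncol(m), ncol(m))
  for (v in unique(m[obs])) {
    iv <- obs & (m == v)
    iv[is.na(iv)] <- FALSE
    identical_m <- identical_m + crossprod(iv)
  }
  storage.mode(comparable) <- "integer"
  storage.mode(identical_m) <- "integer"
  dimnames(comparable) <- dimnames(identical_m) <-
    list(x$samples$sample_id, x$samples$sample_id)
  structure(list(samples = x$samples$sample_id,
                 identical = identical_m,
                 comparable = comparable,
                 n_sites = nrow(x$sites)),
            class = "snp_similarity")
}

#' @export
print.snp_similarity <- function(x, ...) {
  cat(sprintf("snp_similarity: %d samples over %d sites\n",
              length(x$samples), x$n_sites))
  invisible(x)
}

#' Format a similarity matrix as "identical/comparable" cells
#'
#' @param sim an `snp_similarity`.
#' @return character matrix with cells like `"159/168"`.
#' @export
format_similarity <- function(sim) {
  out <- matrix(sprintf("%d/%d", sim$identical, sim$comparable),
                nrow = nrow(sim$identical),
                dimnames = dimnames(sim$identical))
  out
}

#' Write a similarity matrix as TSV
#' @param sim an `snp_similarity`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  fm <- format_similarity(sim)
  df <- data.frame(sample = rownames(fm), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise SNP difference counts
#'
#' `comparable - identical` per pair: the absolute number of differing calls
#' among pairwise-complete sites. This is the divergence scale on which
#' haplotype clustering operates.
#'
#' @param sim an `snp_similarity`.
#' @return integer matrix of difference counts.
#' @export
divergence_counts <- function(sim) {
  sim$comparable - sim$identical
}

#' p-distance matrix from similarity counts
#'
#' `d = 1 - identical/comparable`. Pairs with no comparable sites are
#' undefined: their entries are flagged and set to `NA`; tree construction
#' refuses flagged matrices.
#'
#' @param x a [genotype_matrix] or an `snp_similarity`.
#' @param scope,samples passed to [pairwise_similarity()] when `x` is a
#'   genotype matrix.
#' @return an `snp_dist` object: list with `samples`, numeric matrix `d`,
#'   and logical matrix `flagged`.
#' @export
snp_distance <- function(x, scope = NULL, samples = NULL) {
  sim <- if (inherits(x, "snp_similarity")) x
         else pairwise_similarity(x, scope = scope, samples = samples)
  flagged <- sim$comparable == 0L
  d <- 1 - sim$identical / sim$comparable
  d[flagged] <- NA_real_
  diag(d) <- 0
  diag(flagged) <- FALSE
  structure(list(samples = sim$samples, d = d, flagged = flagged),
            class = "snp_dist")
}

#' @export
print.snp_dist <- function(x, ...) {
  cat(sprintf("snp_dist: %d samples%s\n", length(x$samples),
              if (any(x$flagged)) sprintf(" (%d undefined pairs)",
                                          sum(x$flagged) %/% 2L) else ""))
  invisible(x)
}
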