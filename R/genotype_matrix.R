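# Central genotype container: sites x samples matrix of collapsed organellar
# calls. Organelles are effectively haploid, so diploid-style GTs from the
# caller are collapsed to a haploid-with-HET model:
#   integer k >= 0  -> ALLELE(k), k-th allele (0 = reference)
#   GT_HET (-1L)    -> mixed call (0/1 etc.); retained as an artifact signal
#   NA              -> missing call (./.)

#' Heterozygous-call code
#'
#' Integer code used in the calls matrix of a [genotype_matrix] for a mixed
#' (diploid-style heterozygous) call. Homozygous/haploid calls use the allele
#' index (`0` = reference); missing calls are `NA`.
#' @export
GT_HET <- -1L

TAXA <- c("FOCAL", "CONGENER", "OUTGROUP")

#' Construct a genotype matrix
#'
#' Bundles a site table, a sample metadata table and an integer call matrix
#' into the central container used by the whole pipeline. Sites are sorted by
#' `(replicon, pos)`; row names of `calls` become `"replicon:pos"` keys and
#' column names the sample IDs.
#'
#' @param sites data.frame with columns `replicon` (character), `pos`
#'   (1-based integer), `ref` (allele string), `alt` (comma-separated
#'   alternate allele strings), `qual` (non-negative population call quality).
#'   A `vclass` column (`"SNP"`, `"INDEL"`, `"OTHER"`) is computed from the
#'   alleles when absent.
#' @param samples data.frame with columns `sample_id`, `taxon` (one of
#'   `"FOCAL"`, `"CONGENER"`, `"OUTGROUP"`), and optionally `country` and
#'   `cultivar` (defaulted to `""`).
#' @param calls integer matrix, `nrow(sites)` x `nrow(samples)`; allele index
#'   codes with [GT_HET] for mixed calls and `NA` for missing.
#' @param replicon_len optional named numeric vector of replicon lengths
#'   (written as `##contig` headers).
#' @return An object of class `genotype_matrix` with elements `sites`,
#'   `samples`, `calls`, `replicon_len`.
#' @export
genotype_matrix <- function(sites, samples, calls, replicon_len = NULL) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(
    all(c("replicon", "pos", "ref", "alt", "qual") %in% names(sites)),
    all(c("sample_id", "taxon") %in% names(samples))
  )
  if (is.null(samples$country)) samples$country <- ""
  if (is.null(samples$cultivar)) samples$cultivar <- ""
  samples$country[is.na(samples$country)] <- ""
  samples$cultivar[is.na(samples$cultivar)] <- ""
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample metadata")
  bad_tax <- setdiff(unique(samples$taxon), TAXA)
  if (length(bad_tax))
    stop("unknown taxon value(s): ", paste(bad_tax, collapse = ", "))

  sites$pos <- as.integer(sites$pos)
  sites$qual <- as.numeric(sites$qual)
  if (nrow(sites) && any(sites$pos < 1L)) stop("site pos must be >= 1")
  if (nrow(sites) && any(!is.na(sites$qual) & sites$qual < 0))
    stop("site qual must be non-negative")
  if (is.null(sites$vclass)) {
    sites$vclass <- classify_variant(sites$ref, sites$alt)
  }

  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(sites) || ncol(calls) != nrow(samples))
    stop("calls must be nrow(sites) x nrow(samples)")

  ord <- order(sites$replicon, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  key <- paste(sites$replicon, sites$pos, sep = ":")
  if (anyDuplicated(key))
    stop("duplicated (replicon, pos): ", key[duplicated(key)][1L])
  rownames(sites) <- key
  rownames(calls) <- key
  colnames(calls) <- samples$sample_id
  rownames(samples) <- samples$sample_id

  n_alt <- if (nrow(sites)) lengths(strsplit(sites$alt, ",", fixed = TRUE)) else integer(0)
  if (nrow(sites)) {
    mx <- suppressWarnings(apply(calls, 1L, max, na.rm = TRUE))
    mx[!is.finite(mx)] <- 0L
    if (any(mx > n_alt))
      stop("allele index exceeds number of ALT alleles at ",
           key[which(mx > n_alt)[1L]])
    if (any(calls < GT_HET, na.rm = TRUE)) stop("invalid call code < -1")
  }

  structure(
    list(sites = sites, samples = samples, calls = calls,
         replicon_len = replicon_len),
    class = "genotype_matrix"
  )
}

#' Classify variants as SNP, INDEL or OTHER
#'
#' A site is a SNP iff the reference and every alternate allele are single
#' bases; length mismatches are INDELs; anything else (symbolic alleles) is
#' OTHER.
#'
#' @param ref character vector of reference alleles.
#' @param alt character vector of comma-separated alternate alleles.
#' @return character vector of `"SNP"`, `"INDEL"`, `"OTHER"`.
#' @export
classify_variant <- function(ref, alt) {
  if (!length(ref)) return(character(0))
  alts <- strsplit(alt, ",", fixed = TRUE)
  vapply(seq_along(ref), function(i) {
    a <- alts[[i]]
    if (!length(a)) return("OTHER")
    if (any(grepl("[^ACGTNacgtn]", c(ref[i], a)))) return("OTHER")
    if (nchar(ref[i]) == 1L && all(nchar(a) == 1L)) "SNP"
    else "INDEL"
  }, character(1))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples\n",
              nrow(x$sites), nrow(x$samples)))
  if (nrow(x$sites)) {
    tab <- table(x$sites$replicon)
    cat("  sites per replicon: ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n",
        sep = "")
    cat("  classes: ",
        paste(sprintf("%s=%d", names(table(x$sites$vclass)),
                      table(x$sites$vclass)), collapse = ", "), "\n",
        sep = "")
  }
  cat("  taxa: ",
      paste(sprintf("%s=%d", names(table(x$samples$taxon)),
                    table(x$samples$taxon)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' `i` indexes sites, `j` samples (logical, integer, or names / sample IDs).
#' Both site and sample subsets return a valid `genotype_matrix`.
#'
#' @param x a [genotype_matrix].
#' @param i,j site and sample indices.
#' @param ... ignored.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_len(nrow(x$samples))
  if (is.character(i)) i <- match(i, rownames(x$sites))
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  genotype_matrix(x$sites[i, , drop = FALSE],
                  x$samples[j, , drop = FALSE],
                  x$calls[i, j, drop = FALSE],
                  replicon_len = x$replicon_len)
}

#' Number of sites / samples
#' @param x a [genotype_matrix].
#' @return integer count.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_samples <- function(x) nrow(x$samples)

#' Sample IDs of the focal taxon
#' @param x a [genotype_matrix].
#' @return character vector of FOCAL sample IDs.
#' @export
focal_samples <- function(x) x$samples$sample_id[x$samples$taxon == "FOCAL"]

#' Restrict a genotype matrix to one or more replicons
#'
#' @param x a [genotype_matrix].
#' @param scope `NULL` (all replicons) or a character vector of replicon
#'   names present in the site table.
#' @return a [genotype_matrix] with only the scoped sites.
#' @export
scope_sites <- function(x, scope = NULL) {
  if (is.null(scope)) return(x)
  missing_rep <- setdiff(scope, unique(x$sites$replicon))
  if (length(missing_rep))
    stop("unknown replicon(s): ", paste(missing_rep, collapse = ", "))
  x[x$sites$replicon %in% scope, ]
}
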