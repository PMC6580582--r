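# VCF / PHYLIP / Newick / TSV input-output.

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.x (via \pkg{vcfR}) and collapses diploid-style genotypes
#' to the haploid-with-HET model: `0/0 -> 0`, `j/j -> j`, `j/k` with
#' `j != k` -> [GT_HET], `./.` -> `NA`. Haploid GTs map directly. Phased
#' separators (`|`) are treated like `/`. Sites are sorted by
#' `(replicon, pos)`.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param metadata sample metadata: a data.frame as in [genotype_matrix()]
#'   (or a path to a TSV readable by [read_sample_metadata()]). Every sample
#'   named in the VCF must be present.
#' @return a [genotype_matrix].
#' @export
read_vcf <- function(path, metadata) {
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- read_sample_metadata(metadata)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(colnames(vcf@gt)) || colnames(vcf@gt)[1L] != "FORMAT")
    stop("VCF has no FORMAT/genotype columns: ", path)
  vcf_samples <- colnames(vcf@gt)[-1L]
  absent <- setdiff(vcf_samples, metadata$sample_id)
  if (length(absent))
    stop("VCF sample(s) absent from metadata: ",
         paste(absent, collapse = ", "))
  meta <- metadata[match(vcf_samples, metadata$sample_id), , drop = FALSE]

  replicon_len <- NULL
  contig <- grep("^##contig=", vcf@meta, value = TRUE)
  if (length(contig)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", contig)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", contig)))
    if (!all(is.na(lens))) replicon_len <- stats::setNames(lens, ids)
  }

  if (nrow(vcf@fix) == 0L) {
    return(genotype_matrix(
      sites = data.frame(replicon = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         qual = numeric(0), stringsAsFactors = FALSE),
      samples = meta,
      calls = matrix(integer(0), 0L, nrow(meta)),
      replicon_len = replicon_len
    ))
  }

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!all(grepl("GT", vcf@gt[, "FORMAT"])))
    stop("VCF record without GT in FORMAT field")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  calls <- collapse_gt(gt, path)

  sites <- data.frame(
    replicon = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    stringsAsFactors = FALSE
  )
  genotype_matrix(sites, meta, calls, replicon_len = replicon_len)
}

# GT string matrix -> integer call matrix (vectorised over unique tokens).
collapse_gt <- function(gt, path = "<vcf>") {
  toks <- unique(as.character(gt))
  toks <- toks[!is.na(toks)]
  code <- vapply(toks, function(tk) {
    parts <- strsplit(gsub("|", "/", tk, fixed = TRUE), "/", fixed = TRUE)[[1L]]
    if (!length(parts) || any(!grepl("^([0-9]+|\\.)$", parts)))
      stop("malformed GT token '", tk, "' in ", path)
    if (any(parts == ".")) return(NA_integer_)
    a <- as.integer(parts)
    if (length(unique(a)) == 1L) a[1L] else GT_HET
  }, integer(1))
  out <- matrix(code[match(as.character(gt), toks)],
                nrow = nrow(gt), dimnames = dimnames(gt))
  storage.mode(out) <- "integer"
  out
}

#' Write a genotype matrix as VCF v4.2
#'
#' Inverse of [read_vcf()]: `ALLELE(k) -> k/k`, HET `-> 0/1`,
#' missing `-> ./.`. QUAL and alleles round-trip exactly.
#'
#' @param x a [genotype_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=orghap",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(x$replicon_len)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(x$replicon_len),
                          as.integer(x$replicon_len)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT",
                        x$samples$sample_id), collapse = "\t"))
  body <- character(0)
  if (nrow(x$sites)) {
    gt_chr <- matrix("./.", nrow(x$calls), ncol(x$calls))
    idx <- which(!is.na(x$calls))
    v <- x$calls[idx]
    gt_chr[idx] <- ifelse(v == GT_HET, "0/1", sprintf("%d/%d", v, v))
    qual <- ifelse(is.na(x$sites$qual), ".",
                   format(x$sites$qual, trim = TRUE, scientific = FALSE,
                          drop0trailing = TRUE))
    left <- paste(x$sites$replicon, x$sites$pos, ".", x$sites$ref,
                  x$sites$alt, qual, ".", ".", "GT", sep = "\t")
    body <- paste(left, apply(gt_chr, 1L, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write the sample metadata TSV
#'
#' Tab-separated with header `sample_id`, `taxon`, `country`, `cultivar`;
#' `taxon` is one of FOCAL, CONGENER, OUTGROUP (case-insensitive on read).
#'
#' @param path file path.
#' @return data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "taxon")
  if (!all(need %in% names(md)))
    stop("metadata must have columns sample_id, taxon: ", path)
  md$taxon <- toupper(md$taxon)
  if (is.null(md$country)) md$country <- ""
  if (is.null(md$cultivar)) md$cultivar <- ""
  md
}

#' @rdname read_sample_metadata
#' @param metadata data.frame of sample metadata.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

IUPAC2 <- c(AA = "A", CC = "C", GG = "G", TT = "T",
            AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

iupac_pair <- function(a, b) {
  key <- paste0(pmin(toupper(a), toupper(b)), pmax(toupper(a), toupper(b)))
  out <- unname(IUPAC2[key])
  out[is.na(out)] <- "N"
  out
}

#' Convert an all-SNP genotype matrix to aligned sequences
#'
#' One sequence per sample, one column per SNP site. Allele index `k` maps to
#' the k-th allele base (0 = REF); HET calls map to the IUPAC ambiguity code
#' of the REF and first ALT base; missing calls to `N`.
#'
#' @param x a [genotype_matrix] whose sites are all SNPs.
#' @return named character vector of sequences (names = sample IDs).
#' @export
to_phylip <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (any(x$sites$vclass != "SNP"))
    stop("to_phylip requires all sites to be SNPs; found ",
         sum(x$sites$vclass != "SNP"), " non-SNP site(s)")
  n <- nrow(x$sites)
  if (n == 0L)
    return(stats::setNames(rep("", nrow(x$samples)), x$samples$sample_id))
  alleles <- strsplit(paste(x$sites$ref, x$sites$alt, sep = ","), ",",
                      fixed = TRUE)
  het_code <- iupac_pair(x$sites$ref,
                         vapply(alleles, `[`, character(1), 2L))
  chr <- matrix("N", n, ncol(x$calls))
  for (i in seq_len(n)) {
    v <- x$calls[i, ]
    ok <- !is.na(v) & v >= 0L
    chr[i, ok] <- toupper(alleles[[i]][v[ok] + 1L])
    chr[i, !is.na(v) & v == GT_HET] <- het_code[i]
  }
  stats::setNames(apply(chr, 2L, paste, collapse = ""),
                  x$samples$sample_id)
}

#' Write sequences in relaxed PHYLIP format
#'
#' Relaxed dialect: full sample names (up to 250 characters) separated from
#' the sequence by whitespace, sequential layout.
#'
#' @param seqs named character vector as returned by [to_phylip()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nchar(names(seqs)) <= 250L))
  len <- unique(nchar(seqs))
  stopifnot(length(len) <= 1L)
  if (!length(len)) len <- 0L
  writeLines(c(sprintf("%d %d", length(seqs), len),
               sprintf("%s  %s", names(seqs), unname(seqs))), path)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()]. Integer
#' bootstrap supports travel as internal node labels.
#'
#' @param tree an [ape::phylo] tree.
#' @param path file path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed Newick in ", path)
  tr
}
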