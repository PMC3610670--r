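#' Construct a phased haplotype panel
#'
#' A haplotype panel holds a fully phased, fully observed allele matrix over
#' `H` chromosome copies (rows) and `S` biallelic SNPs (columns), together
#' with the per-SNP map. Phasing and imputation are upstream of this package:
#' panels with missing entries are rejected rather than imputed, because a
#' silently imputed allele would corrupt downstream haplotype homozygosity.
#'
#' @param alleles integer (or coercible) matrix of 0/1 alleles, one row per
#'   chromosome copy, one column per SNP. No missing values allowed.
#' @param snps data frame with columns `id`, `chrom`, `pos_bp` (0-based
#'   physical position) and optionally `pos_cm` (genetic position,
#'   centimorgan), `ref`, `alt`. Must be sorted by (`chrom`, `pos_bp`) with no
#'   duplicated positions within a chromosome.
#' @param sample_ids optional character vector of length `H/2`; defaults to
#'   `"sample1"`, ... Chromosome copies `2i-1` and `2i` belong to sample `i`.
#'
#' @return An object of class `haplotype_panel`: a list with elements
#'   `alleles`, `snps`, `sample_ids`.
#' @export
haplotype_panel <- function(alleles, snps, sample_ids = NULL) {
  alleles <- as.matrix(alleles)
  if (anyNA(alleles)) {
    stop("panel contains missing alleles; phase/impute upstream before entry")
  }
  storage.mode(alleles) <- "integer"
  if (!all(alleles == 0L | alleles == 1L)) {
    stop("alleles must be coded 0/1 (biallelic)")
  }
  H <- nrow(alleles)
  if (H %% 2L != 0L) stop("number of chromosome copies must be even")
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos_bp")
  if (!all(req %in% names(snps))) {
    stop("snps must have columns id, chrom, pos_bp")
  }
  if (nrow(snps) != ncol(alleles)) {
    stop("snps rows (", nrow(snps), ") != allele columns (", ncol(alleles), ")")
  }
  if (is.null(snps$pos_cm)) snps$pos_cm <- NA_real_
  if (is.null(snps$ref)) snps$ref <- "A"
  if (is.null(snps$alt)) snps$alt <- "B"
  snps$chrom <- as.character(snps$chrom)
  snps$pos_bp <- as.numeric(snps$pos_bp)
  if (any(snps$pos_bp < 0)) stop("pos_bp must be >= 0")
  .check_snp_order(snps)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(H %/% 2L))
  if (length(sample_ids) != H %/% 2L) {
    stop("sample_ids must have length H/2")
  }
  rownames(snps) <- NULL
  structure(
    list(alleles = alleles, snps = snps, sample_ids = as.character(sample_ids)),
    class = "haplotype_panel"
  )
}

.check_snp_order <- function(snps) {
  for (ch in unique(snps$chrom)) {
    p <- snps$pos_bp[snps$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("SNPs on chromosome ", ch,
           " are not strictly sorted by position (or duplicated)")
    }
    cm <- snps$pos_cm[snps$chrom == ch]
    if (!all(is.na(cm))) {
      if (anyNA(cm)) stop("pos_cm partially set on chromosome ", ch)
      if (is.unsorted(cm)) stop("pos_cm decreasing on chromosome ", ch)
    }
  }
  invisible(TRUE)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$alleles), "chromosome copies (",
      length(x$sample_ids), "samples ) x", ncol(x$alleles), "SNPs\n")
  cat("chromosomes:", paste(unique(x$snps$chrom), collapse = ", "), "\n")
  cat("genetic map:", if (all(is.na(x$snps$pos_cm))) "absent" else "attached",
      "\n")
  invisible(x)
}

#' @export
summary.haplotype_panel <- function(object, ...) {
  sp <- split(object$snps, factor(object$snps$chrom,
                                  levels = unique(object$snps$chrom)))
  rows <- lapply(sp, function(s) {
    n <- nrow(s)
    span <- diff(range(s$pos_bp))
    data.frame(
      chrom = s$chrom[1], n_snps = n,
      span_mb = span / 1e6,
      mean_spacing_kb = if (n > 1) span / (n - 1) / 1000 else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Number of chromosome copies / SNPs in a panel
#' @param panel a [haplotype_panel()]
#' @return integer count.
#' @export
n_copies <- function(panel) nrow(panel$alleles)

#' @rdname n_copies
#' @export
n_snps <- function(panel) ncol(panel$alleles)

# SNP (column) indices of one chromosome, in map order
.chrom_idx <- function(panel, chrom) which(panel$snps$chrom == chrom)

#' Subset a panel to a set of SNP columns (internal order preserved)
#' @noRd
.subset_snps <- function(panel, keep) {
  haplotype_panel(panel$alleles[, keep, drop = FALSE],
                  panel$snps[keep, , drop = FALSE],
                  panel$sample_ids)
}

#' Drop chromosomes from a panel
#'
#' Used to realize exclusion policies such as dropping the X chromosome
#' before a scan.
#'
#' @param panel a [haplotype_panel()]
#' @param chroms character vector of chromosome labels to drop.
#' @return filtered panel (possibly with zero SNPs).
#' @export
exclude_chromosomes <- function(panel, chroms) {
  if (length(chroms) == 0) return(panel)
  keep <- !(panel$snps$chrom %in% chroms)
  if (!any(keep)) warning("all SNPs excluded")
  .subset_snps(panel, which(keep))
}
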