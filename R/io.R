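#' Read a phased VCF into a haplotype panel
#'
#' Reads a VCF of phased biallelic SNP genotypes. Every GT field must be
#' phased (`|` separator) and complete; the panel refuses missing data.
#' Positions are 1-based in the VCF and stored 0-based internally.
#'
#' @param path path to a VCF (plain or gzipped).
#' @param mode `"strict"` errors on any multiallelic or unphased record;
#'   `"skip"` drops such records and reports the skip count.
#' @return a [haplotype_panel()] with `H = 2 x` samples rows.
#' @export
read_phased_vcf <- function(path, mode = c("strict", "skip")) {
  mode <- match.arg(mode)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  bial <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "ALT"]) > 0 &
    !is.na(fix[, "ALT"])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || nrow(gt) == 0) stop("VCF has no GT field")
  if (anyNA(gt) || any(gt == ".")) {
    bad <- which(is.na(gt) | gt == ".", arr.ind = TRUE)[1, ]
    stop("missing GT at record ", fix[bad[1], "ID"],
         " (", fix[bad[1], "CHROM"], ":", fix[bad[1], "POS"], ")")
  }
  unphased <- apply(gt, 1, function(g) any(grepl("/", g, fixed = TRUE)))
  keep <- bial & !unphased
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    if (mode == "strict") {
      i <- which(!keep)[1]
      what <- if (!bial[i]) "multiallelic" else "unphased GT"
      stop(what, " at record ", fix[i, "ID"],
           " (", fix[i, "CHROM"], ":", fix[i, "POS"], ")")
    }
    message("read_phased_vcf: skipped ", n_skip,
            " multiallelic/unphased record(s)")
  }
  if (!any(keep)) stop("no usable phased biallelic records in ", path)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  pos <- suppressWarnings(as.numeric(fix[, "POS"]))
  if (anyNA(pos) || any(!is.finite(pos))) {
    stop("non-finite POS at record ", fix[which(!is.finite(pos))[1], "ID"])
  }
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  if (any(a1 %in% c(".", "")) || any(a2 %in% c(".", ""))) {
    stop("missing allele in GT field")
  }
  S <- nrow(gt); nsamp <- ncol(gt)
  alleles <- matrix(0L, nrow = 2L * nsamp, ncol = S)
  alleles[seq(1L, 2L * nsamp, by = 2L), ] <- t(matrix(as.integer(a1), S, nsamp))
  alleles[seq(2L, 2L * nsamp, by = 2L), ] <- t(matrix(as.integer(a2), S, nsamp))
  snps <- data.frame(
    id = ifelse(fix[, "ID"] == "." | is.na(fix[, "ID"]),
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    chrom = fix[, "CHROM"],
    pos_bp = pos - 1,          # 0-based internally
    pos_cm = NA_real_,
    ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  haplotype_panel(alleles, snps, sample_ids = colnames(gt))
}

#' Read a plain haplotype table plus SNP map
#'
#' The haplotype table holds one row per chromosome copy as a string of 0/1
#' characters (no separators); the map is a TSV with header columns
#' `id`, `chrom`, `pos_bp` and optionally `pos_cm`.
#'
#' @param geno_path path to the 0/1 haplotype table.
#' @param map_path path to the SNP map TSV.
#' @return a [haplotype_panel()].
#' @export
read_haplotype_table <- function(geno_path, map_path) {
  lines <- readLines(geno_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty haplotype table ", geno_path)
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  S <- nrow(map)
  wid <- unique(nchar(lines))
  if (length(wid) != 1L || wid != S) {
    stop("haplotype row length (", paste(wid, collapse = ","),
         ") does not match map rows (", S, ")")
  }
  if (length(lines) %% 2L != 0L) {
    stop("odd number of chromosome copies (", length(lines), ")")
  }
  chars <- matrix(unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(lines), byrow = TRUE)
  if (!all(chars %in% c("0", "1"))) stop("haplotype table must be 0/1 only")
  alleles <- matrix(as.integer(chars), nrow = length(lines))
  haplotype_panel(alleles, map)
}

#' Write a panel as haplotype table + SNP map
#'
#' Inverse of [read_haplotype_table()]; the round trip is bit-exact on the
#' allele matrix.
#'
#' @param panel a [haplotype_panel()]
#' @param geno_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_haplotype_table <- function(panel, geno_path, map_path) {
  rows <- apply(panel$alleles, 1, paste, collapse = "")
  writeLines(rows, geno_path)
  utils::write.table(panel$snps[, c("id", "chrom", "pos_bp", "pos_cm")],
                     map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(geno_path, map_path))
}

#' Remove SNPs below a minor-allele-frequency floor
#'
#' Removes every SNP whose minor allele frequency is strictly below
#' `min_maf` (the QC rule is a strict "less than": a SNP at exactly the
#' floor is retained). Idempotent; order preserving.
#'
#' @param panel a [haplotype_panel()]
#' @param min_maf MAF floor, default 0.03.
#' @return filtered panel; the number of removed SNPs is reported via
#'   `message()` and stored in attribute `n_removed`.
#' @export
apply_maf_filter <- function(panel, min_maf = 0.03) {
  cnt <- colSums(panel$alleles)
  H <- nrow(panel$alleles)
  maf <- pmin(cnt, H - cnt) / H      # integer counts avoid 1-f rounding
  keep <- maf >= min_maf
  n_rm <- sum(!keep)
  if (n_rm > 0) message("apply_maf_filter: removed ", n_rm, " SNP(s) with MAF < ",
                        min_maf)
  if (!any(keep)) warning("MAF filter removed every SNP")
  out <- .subset_snps(panel, which(keep))
  attr(out, "n_removed") <- n_rm
  out
}

#' Attach genetic-map positions to a panel
#'
#' Sets `pos_cm` for all SNPs either from a constant recombination rate in
#' cM/Mb or from an explicit map table (`chrom`, `pos_bp`, `pos_cm`). The
#' default rate of 1 cM/Mb is the cattle-literature convention. An explicit
#' table overrides the rate.
#'
#' @param panel a [haplotype_panel()]
#' @param map either a single numeric rate (cM/Mb) or a data frame / TSV path
#'   with columns `chrom`, `pos_bp`, `pos_cm`.
#' @param strict if `TRUE` (default) every panel SNP must be present in an
#'   explicit map; if `FALSE` missing SNPs are linearly interpolated between
#'   map points (endpoints extended flat).
#' @return the panel with `pos_cm` set (non-decreasing per chromosome).
#' @export
attach_genetic_map <- function(panel, map = 1.0, strict = TRUE) {
  snps <- panel$snps
  if (is.numeric(map) && length(map) == 1L) {
    if (!is.finite(map) || map <= 0) stop("rate must be a positive cM/Mb value")
    snps$pos_cm <- snps$pos_bp * map / 1e6
  } else {
    if (is.character(map)) map <- utils::read.delim(map, stringsAsFactors = FALSE)
    map <- as.data.frame(map)
    if (!all(c("chrom", "pos_bp", "pos_cm") %in% names(map))) {
      stop("map table needs columns chrom, pos_bp, pos_cm")
    }
    map$chrom <- as.character(map$chrom)
    cm <- rep(NA_real_, nrow(snps))
    for (ch in unique(snps$chrom)) {
      i <- which(snps$chrom == ch)
      m <- map[map$chrom == ch, , drop = FALSE]
      if (nrow(m) == 0) {
        if (strict) stop("genetic map has no entries for chromosome ", ch)
        next
      }
      m <- m[order(m$pos_bp), , drop = FALSE]
      if (is.unsorted(m$pos_cm)) stop("decreasing cM values on chromosome ", ch)
      hit <- match(snps$pos_bp[i], m$pos_bp)
      if (strict && anyNA(hit)) {
        miss <- snps$id[i][which(is.na(hit))[1]]
        stop("genetic map gap at SNP ", miss, " (strict mode)")
      }
      cm[i] <- if (anyNA(hit)) {
        stats::approx(m$pos_bp, m$pos_cm, xout = snps$pos_bp[i], rule = 2,
                      ties = "ordered")$y
      } else m$pos_cm[hit]
    }
    if (anyNA(cm)) stop("genetic map does not cover all panel SNPs")
    snps$pos_cm <- cm
  }
  haplotype_panel(panel$alleles, snps, panel$sample_ids)
}

#' Read gene intervals from BED or GFF3
#'
#' BED input is 0-based half-open (kept as-is internally); GFF3 is 1-based
#' closed and converted. Gene identifiers come from the BED `name` column or
#' from the GFF3 `Name`/`ID`/`gene_id` attribute.
#'
#' @param path path to a BED or GFF3 file.
#' @param feature for GFF3, the feature type to keep (default `"gene"`).
#' @return data frame with columns `gene_id`, `chrom`, `start_bp`, `end_bp`
#'   (0-based half-open).
#' @export
read_genes <- function(path, feature = "gene") {
  fmt <- tolower(tools::file_ext(path))
  if (fmt %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "GFF3")
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      gr <- gr[as.character(gr$type) == feature]
    }
    md <- S4Vectors::mcols(gr)
    id <- if (!is.null(md$Name)) as.character(md$Name)
          else if (!is.null(md$ID)) as.character(md$ID)
          else if (!is.null(md$gene_id)) as.character(md$gene_id)
          else paste0("gene", seq_along(gr))
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    id <- if (!is.null(gr$name)) as.character(gr$name)
          else paste0("gene", seq_along(gr))
  }
  out <- data.frame(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr) - 1,   # back to 0-based half-open
    end_bp = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (any(out$start_bp >= out$end_bp)) stop("gene with start >= end in ", path)
  out[order(out$chrom, out$start_bp), , drop = FALSE]
}

#' Read a gene-to-term association table
#'
#' Two-column TSV (`gene_id`, `term_id`), the GeneMerge association format,
#' plus an optional term-description TSV (`term_id`, `description`).
#'
#' @param assoc_path path to the two-column gene/term TSV (header optional:
#'   a first line whose second field looks like a header is skipped).
#' @param desc_path optional term-description TSV path.
#' @return a `term_map`: list with `terms` (named list term_id -> character
#'   vector of gene ids) and `descriptions` (named character vector).
#' @export
read_term_map <- function(assoc_path, desc_path = NULL) {
  a <- utils::read.delim(assoc_path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("gene_id", "term_id"))
  if (nrow(a) > 0 && tolower(a$gene_id[1]) %in% c("gene", "gene_id")) {
    a <- a[-1, , drop = FALSE]
  }
  terms <- lapply(split(a$gene_id, a$term_id), unique)
  desc <- character(0)
  if (!is.null(desc_path)) {
    d <- utils::read.delim(desc_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("term_id", "description"))
    desc <- stats::setNames(d$description, d$term_id)
  }
  structure(list(terms = terms, descriptions = desc), class = "term_map")
}

#' @export
print.term_map <- function(x, ...) {
  cat("term_map:", length(x$terms), "terms over",
      length(unique(unlist(x$terms, use.names = FALSE))), "genes\n")
  invisible(x)
}
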