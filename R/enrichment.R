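#' Extend regions symmetrically and clamp to chromosome bounds
#'
#' Each region is padded by `pad_bp` on both sides (default 1 Mb), clamped
#' to `[0, chromosome length]`. Overlapping extended regions are merged by
#' default so downstream gene counting counts each gene once.
#'
#' @param regions data frame with `region_id`, `chrom`, `start_bp`,
#'   `end_bp` (0-based half-open).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp);
#'   every region chromosome must be present.
#' @param pad_bp symmetric extension in bp (default 1e6).
#' @param merge merge overlapping extended regions (default `TRUE`).
#' @return data frame with `region_id` (comma-joined when merged), `chrom`,
#'   `start_bp`, `end_bp`.
#' @export
extend_regions <- function(regions, chrom_lengths, pad_bp = 1e6,
                           merge = TRUE) {
  missing_ch <- setdiff(unique(regions$chrom), names(chrom_lengths))
  if (length(missing_ch)) {
    stop("unknown chromosome(s): ", paste(missing_ch, collapse = ", "))
  }
  if (nrow(regions) == 0) {
    return(data.frame(region_id = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0)))
  }
  start <- pmax(0, regions$start_bp - pad_bp)
  end <- pmin(unname(chrom_lengths[regions$chrom]), regions$end_bp + pad_bp)
  out <- data.frame(region_id = regions$region_id, chrom = regions$chrom,
                    start_bp = start, end_bp = end, stringsAsFactors = FALSE)
  if (!merge) return(out)
  gr <- GenomicRanges::GRanges(out$chrom,
                               IRanges::IRanges(out$start_bp + 1, out$end_bp))
  red <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(gr, red)
  ids <- vapply(split(out$region_id[S4Vectors::queryHits(ov)],
                      S4Vectors::subjectHits(ov)),
                paste, "", collapse = ",")
  data.frame(region_id = unname(ids[as.character(seq_along(red))]),
             chrom = as.character(GenomicRanges::seqnames(red)),
             start_bp = GenomicRanges::start(red) - 1,
             end_bp = GenomicRanges::end(red),
             stringsAsFactors = FALSE)
}

#' Map genes into extended regions
#'
#' A gene is included when its interval overlaps any region by at least one
#' base pair (half-open coordinates, so a gene abutting a region end is
#' excluded). Each gene is counted once regardless of how many regions it
#' touches; the result is invariant to region order.
#'
#' @param extended data frame of regions (`chrom`, `start_bp`, `end_bp`,
#'   0-based half-open).
#' @param genes data frame of gene intervals as from [read_genes()].
#' @return sorted character vector of unique gene ids.
#' @export
map_genes <- function(extended, genes) {
  if (nrow(extended) == 0 || nrow(genes) == 0) return(character(0))
  gr_r <- GenomicRanges::GRanges(extended$chrom,
                                 IRanges::IRanges(extended$start_bp + 1,
                                                  extended$end_bp))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start_bp + 1,
                                                  genes$end_bp))
  hit <- GenomicRanges::countOverlaps(gr_g, gr_r) > 0
  sort(unique(genes$gene_id[hit]))
}

#' Ratio of study fraction to background fraction
#'
#' The enrichment ratio reported alongside each term:
#' `(study_count/study_total) / (pop_count/pop_total)`.
#'
#' @param pop_count,pop_total background (genome-wide) term count and
#'   universe size.
#' @param study_count,study_total study-set term count and study-set size.
#' @return numeric ratio (vectorized).
#' @export
enrichment_ratio <- function(pop_count, pop_total, study_count, study_total) {
  (study_count / study_total) / (pop_count / pop_total)
}

#' Hypergeometric gene-set enrichment with Bonferroni correction
#'
#' For each term, tests whether the study gene set contains more of the
#' term's genes than expected when drawing `|study|` genes without
#' replacement from the background universe: the raw p-value is the
#' hypergeometric upper tail `P(X >= study_count)`. The Bonferroni
#' multiplier is the number of terms actually tested (those with at least
#' `min_study_hits` study genes), or all terms in the map when
#' `bonferroni_all = TRUE`.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `background`).
#' @param background character vector: the gene universe.
#' @param term_map a `term_map` from [read_term_map()], or a named list of
#'   term -> gene-id vectors.
#' @param min_study_hits minimum study genes in a term for it to be tested.
#' @param bonferroni_all use all terms as the multiplier.
#' @return data frame sorted by raw p: `term_id`, `description`,
#'   `pop_count`, `pop_total`, `study_count`, `study_total`, `ratio`,
#'   `p_raw`, `p_bonferroni`.
#' @export
hypergeometric_enrichment <- function(study, background, term_map,
                                      min_study_hits = 1,
                                      bonferroni_all = FALSE) {
  terms <- if (inherits(term_map, "term_map")) term_map$terms else term_map
  desc <- if (inherits(term_map, "term_map")) term_map$descriptions
          else character(0)
  study <- unique(study); background <- unique(background)
  if (!all(study %in% background)) {
    stop("study set contains genes outside the background universe")
  }
  N <- length(background); n <- length(study)
  if (n == 0) {
    return(data.frame(term_id = character(0), description = character(0),
                      pop_count = integer(0), pop_total = integer(0),
                      study_count = integer(0), study_total = integer(0),
                      ratio = numeric(0), p_raw = numeric(0),
                      p_bonferroni = numeric(0)))
  }
  K <- vapply(terms, function(g) sum(unique(g) %in% background), 0L)
  k <- vapply(terms, function(g) sum(unique(g) %in% study), 0L)
  keep <- k >= min_study_hits & K >= 1L
  tested <- names(terms)[keep]
  m <- if (bonferroni_all) length(terms) else length(tested)
  p <- stats::phyper(k[keep] - 1, K[keep], N - K[keep], n,
                     lower.tail = FALSE)
  out <- data.frame(
    term_id = tested,
    description = ifelse(tested %in% names(desc), desc[tested], ""),
    pop_count = K[keep], pop_total = N,
    study_count = k[keep], study_total = n,
    ratio = enrichment_ratio(K[keep], N, k[keep], n),
    p_raw = p,
    p_bonferroni = pmin(1, p * m),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect a study gene set with a reference gene list
#'
#' Case-normalized exact symbol intersection, reported as counts and
#' percentages of either side. Used for comparisons against external
#' association-study hits or candidate-gene databases.
#'
#' @param study,reference character vectors of gene symbols.
#' @param normalize case-fold and trim whitespace before matching.
#' @return list of class `gene_overlap`: `n_study`, `n_reference`,
#'   `n_overlap`, `pct_of_reference`, `pct_of_study`, `members`.
#' @export
intersect_gene_lists <- function(study, reference, normalize = TRUE) {
  norm <- function(x) if (normalize) toupper(trimws(x)) else x
  s <- unique(norm(study)); r <- unique(norm(reference))
  ov <- intersect(s, r)
  structure(list(
    n_study = length(s), n_reference = length(r), n_overlap = length(ov),
    pct_of_reference = if (length(r)) 100 * length(ov) / length(r) else NA_real_,
    pct_of_study = if (length(s)) 100 * length(ov) / length(s) else NA_real_,
    members = sort(ov)
  ), class = "gene_overlap")
}

#' @export
print.gene_overlap <- function(x, ...) {
  cat(sprintf(
    "gene overlap: %d of %d reference genes in study set (%.2f%%; %.2f%% of study)\n",
    x$n_overlap, x$n_reference, x$pct_of_reference, x$pct_of_study))
  invisible(x)
}
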