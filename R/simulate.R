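#' Simulation configuration for synthetic haplotype panels
#'
#' Defaults emulate a medium-density livestock SNP-chip panel: 2000 markers
#' at a mean spacing of 50 kb (a 100 Mb chromosome), 400 chromosome copies,
#' block-structured LD from a small founder pool, and a genetic map at
#' 1 cM/Mb. LD arises from two layers: founder haplotypes are built from
#' ancestral blocks (mean extent `block_mean_kb`) each carrying only a few
#' distinct block haplotypes, and each chromosome copy is a mosaic of
#' founders with switch points at `switch_rate_per_bp` (mean identical
#' tract 1 Mb), so LD decays with distance.
#'
#' @param n_copies even number of chromosome copies (default 400).
#' @param n_snps number of SNP markers (default 2000).
#' @param spacing_kb mean marker spacing; chromosome length is
#'   `n_snps * spacing_kb` kb.
#' @param n_founders founder haplotype pool size.
#' @param block_mean_kb mean ancestral LD-block extent.
#' @param block_hap_range range of distinct haplotypes per ancestral block.
#' @param switch_rate_per_bp founder-mosaic switch rate per bp.
#' @param map_rate_cm_per_mb constant genetic-map rate.
#' @param chrom chromosome label.
#' @param seed integer seed; all generator randomness flows from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_copies = 400, n_snps = 2000, spacing_kb = 50,
                       n_founders = 60, block_mean_kb = 250,
                       block_hap_range = c(3, 6),
                       switch_rate_per_bp = 2e-6,
                       map_rate_cm_per_mb = 1.0, chrom = "1", seed = 1) {
  stopifnot(n_copies %% 2 == 0, n_copies >= 4, n_snps >= 1)
  structure(list(n_copies = n_copies, n_snps = n_snps,
                 spacing_kb = spacing_kb, n_founders = n_founders,
                 block_mean_kb = block_mean_kb,
                 block_hap_range = block_hap_range,
                 switch_rate_per_bp = switch_rate_per_bp,
                 map_rate_cm_per_mb = map_rate_cm_per_mb,
                 chrom = chrom, seed = seed,
                 chrom_length_bp = n_snps * spacing_kb * 1000),
            class = "sim_config")
}

#' Simulate a neutral phased haplotype panel
#'
#' Marker positions are drawn uniformly and sorted. Founder haplotypes are
#' concatenations of ancestral blocks, each block offering a small pool of
#' distinct haplotypes with Dirichlet-weighted usage, which produces
#' strong within-block LD. Each chromosome copy is then a Poisson-switch
#' mosaic of the founders, which makes LD decay with distance. Output is
#' deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return a [haplotype_panel()] with the genetic map attached.
#' @export
simulate_neutral_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- config$n_snps; H <- config$n_copies; K <- config$n_founders
  len <- config$chrom_length_bp
  if (S < 1 || H < 4) stop("infeasible config: need n_snps >= 1, n_copies >= 4")
  pos <- sort(sample.int(len - 1L, S))
  # ancestral block boundaries (bp), mean extent block_mean_kb
  n_blocks <- max(1L, stats::rpois(1, len / (config$block_mean_kb * 1000)))
  bounds <- sort(stats::runif(n_blocks - 1, 0, len))
  block_of <- findInterval(pos, bounds) + 1L
  founders <- matrix(0L, nrow = K, ncol = S)
  for (b in unique(block_of)) {
    cols <- which(block_of == b)
    nh <- sample(seq(config$block_hap_range[1], config$block_hap_range[2]), 1)
    haps <- matrix(stats::rbinom(nh * length(cols), 1L, 0.5),
                   nrow = nh)
    w <- stats::rgamma(nh, 2); w <- w / sum(w)   # balanced block-haplotype usage
    pick <- sample.int(nh, K, replace = TRUE, prob = w)
    founders[, cols] <- haps[pick, , drop = FALSE]
  }
  alleles <- matrix(0L, nrow = H, ncol = S)
  for (h in seq_len(H)) {
    n_sw <- stats::rpois(1, len * config$switch_rate_per_bp)
    sw <- sort(stats::runif(n_sw, 0, len))
    seg <- findInterval(pos, sw) + 1L
    fid <- sample.int(K, n_sw + 1L, replace = TRUE)
    alleles[h, ] <- founders[cbind(fid[seg], seq_len(S))]
  }
  snps <- data.frame(
    id = sprintf("snp%05d", seq_len(S)), chrom = config$chrom,
    pos_bp = pos, pos_cm = pos * config$map_rate_cm_per_mb / 1e6,
    ref = "A", alt = "B", stringsAsFactors = FALSE
  )
  haplotype_panel(alleles, snps)
}

#' Plant a selective-sweep haplotype into a panel
#'
#' Replaces the alleles of a random carrier set with one template haplotype
#' over a tract of `+/- tract_half_length_cm` around `position_bp`, creating
#' the exact statistical signature an EHH scan targets: a long, perfectly
#' homozygous haplotype at controlled population frequency. Copies outside
#' the carrier set, and all SNPs outside the tract, are untouched.
#'
#' @param panel a [haplotype_panel()] with a genetic map.
#' @param position_bp sweep center (physical position).
#' @param carrier_fraction fraction of copies carrying the sweep, in (0,1);
#'   `floor(carrier_fraction * H)` must be at least 2.
#' @param tract_half_length_cm identical-tract half length in cM.
#' @param seed optional seed for carrier sampling (defaults to leaving the
#'   RNG state untouched).
#' @return list with elements `panel` (modified) and `truth` (list:
#'   `chrom`, `position_bp`, `start_bp`, `end_bp` of the tract, `snp_cols`,
#'   `carriers`, `carrier_fraction`).
#' @export
plant_sweep <- function(panel, position_bp, carrier_fraction = 0.4,
                        tract_half_length_cm = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (carrier_fraction <= 0 || carrier_fraction >= 1) {
    stop("carrier_fraction must be in (0, 1)")
  }
  H <- n_copies(panel)
  n_car <- floor(carrier_fraction * H)
  if (n_car < 2) stop("carrier set must have at least 2 copies")
  snps <- panel$snps
  if (anyNA(snps$pos_cm)) stop("genetic map not attached")
  ic <- which.min(abs(snps$pos_bp - position_bp))
  chrom <- snps$chrom[ic]
  on_chrom <- snps$chrom == chrom
  center_cm <- snps$pos_cm[ic]
  lo <- center_cm - tract_half_length_cm
  hi <- center_cm + tract_half_length_cm
  rng <- range(snps$pos_cm[on_chrom])
  if (lo < rng[1] || hi > rng[2]) {
    warning("sweep tract clamped to chromosome bounds")
    lo <- max(lo, rng[1]); hi <- min(hi, rng[2])
  }
  cols <- which(on_chrom & snps$pos_cm >= lo & snps$pos_cm <= hi)
  carriers <- sample.int(H, n_car)
  template <- panel$alleles[carriers[1], cols]
  panel$alleles[carriers, cols] <- matrix(template, nrow = n_car,
                                          ncol = length(cols), byrow = TRUE)
  truth <- list(chrom = chrom, position_bp = position_bp,
                start_bp = snps$pos_bp[cols[1]],
                end_bp = snps$pos_bp[cols[length(cols)]] + 1,
                snp_cols = cols, carriers = sort(carriers),
                carrier_fraction = carrier_fraction)
  list(panel = panel, truth = truth)
}

#' Simulate a gene annotation with an optional planted enriched term
#'
#' Places non-overlapping gene intervals uniformly along the chromosome
#' (one per equal-width slot) and assigns genes to terms at random, except
#' for one designated term whose genes are drawn with odds multiplied by
#' `multiplier` inside the given target intervals. With `multiplier = 1`
#' the planted term behaves like any other (null case).
#'
#' @param chrom_length_bp chromosome length.
#' @param n_genes number of genes (default 500).
#' @param n_terms number of terms (default 50).
#' @param genes_per_term mean genes per term (Poisson, min 1).
#' @param gene_length_bp gene interval length.
#' @param enriched list with `intervals` (data frame `start_bp`/`end_bp`)
#'   and `multiplier`, or `NULL` for a fully null annotation.
#' @param chrom chromosome label.
#' @param seed integer seed.
#' @return list with `genes` (gene-interval data frame), `term_map`
#'   (a `term_map`), and `truth` (planted term id and its genes, or `NULL`).
#' @export
simulate_annotation <- function(chrom_length_bp, n_genes = 500, n_terms = 50,
                                genes_per_term = 25, gene_length_bp = 20000,
                                enriched = NULL, chrom = "1", seed = 1) {
  set.seed(seed)
  if (n_genes < 1) stop("n_genes must be >= 1")
  slot <- chrom_length_bp / n_genes
  if (slot <= gene_length_bp) {
    stop("infeasible packing: slots narrower than gene length")
  }
  start <- (seq_len(n_genes) - 1) * slot +
    stats::runif(n_genes, 0, slot - gene_length_bp)
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)), chrom = chrom,
    start_bp = floor(start), end_bp = floor(start) + gene_length_bp,
    stringsAsFactors = FALSE
  )
  inside <- rep(FALSE, n_genes)
  if (!is.null(enriched)) {
    for (r in seq_len(nrow(enriched$intervals))) {
      inside <- inside |
        (genes$start_bp < enriched$intervals$end_bp[r] &
         genes$end_bp > enriched$intervals$start_bp[r])
    }
  }
  term_ids <- sprintf("T%03d", seq_len(n_terms))
  terms <- vector("list", n_terms)
  names(terms) <- term_ids
  for (t in seq_len(n_terms)) {
    m <- max(1L, stats::rpois(1, genes_per_term))
    m <- min(m, n_genes)
    w <- rep(1, n_genes)
    if (t == 1L && !is.null(enriched)) w[inside] <- enriched$multiplier
    terms[[t]] <- sort(sample(genes$gene_id, m, prob = w / sum(w)))
  }
  truth <- if (!is.null(enriched)) {
    list(term_id = term_ids[1], genes = terms[[1]],
         intervals = enriched$intervals, multiplier = enriched$multiplier)
  } else NULL
  tm <- structure(list(
    terms = terms,
    descriptions = stats::setNames(paste("synthetic term", term_ids), term_ids)
  ), class = "term_map")
  list(genes = genes, term_map = tm, truth = truth)
}

#' Write synthetic truth as JSON
#'
#' @param truth a truth list from [plant_sweep()] or [simulate_annotation()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' One replicate of the planted-sweep recovery benchmark
#'
#' Runs the full pipeline on one synthetic panel under the default study
#' conditions (H = 400 copies, 2000 SNPs at 50 kb, one sweep at carrier
#' fraction 0.4 with a +/- 1 cM identical tract at mid-chromosome) and asks
#' whether the top-REHH significant region overlaps the planted tract. With
#' `sweep = FALSE` the panel is neutral and the question becomes whether the
#' genome-wide top-REHH region overlaps a fixed mid-chromosome 2 Mb window
#' (a null false-hit probe).
#'
#' @param seed integer seed for this replicate.
#' @param sweep plant the sweep (`TRUE`) or run the neutral null (`FALSE`).
#' @param alpha significance level restricting the candidate tests when a
#'   sweep is planted.
#' @param config optional [sim_config()] overriding the default conditions
#'   (its seed is replaced by `seed`).
#' @return `TRUE`/`FALSE` for tract overlap of the top region; `NA` when no
#'   candidate test exists.
#' @export
sweep_benchmark <- function(seed, sweep = TRUE, alpha = 0.05, config = NULL) {
  cfg <- if (is.null(config)) sim_config(seed = seed) else {
    config$seed <- seed; config
  }
  panel <- simulate_neutral_panel(cfg)
  if (sweep) {
    sw <- plant_sweep(panel, position_bp = cfg$chrom_length_bp / 2,
                      carrier_fraction = 0.4, tract_half_length_cm = 1)
    panel <- sw$panel
    window <- c(sw$truth$start_bp, sw$truth$end_bp)
  } else {
    mid <- cfg$chrom_length_bp / 2
    window <- c(mid - 1e6, mid + 1e6)
  }
  panel <- suppressMessages(apply_maf_filter(panel))
  scan <- suppressMessages(ehh_scan(panel))
  tests <- scan$tests
  if (sweep) tests <- tests[tests$p_value < alpha, , drop = FALSE]
  if (nrow(tests) == 0) return(NA)
  top <- tests[which.max(tests$rehh), ]
  top$start_bp < window[2] && top$end_bp > window[1]
}
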