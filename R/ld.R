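#' Pairwise |D'| with a profile-likelihood confidence interval
#'
#' Phase is known, so the two-locus haplotype counts are observed directly
#' (no EM step). |D'| is the normalized LD coefficient |D|/Dmax. The
#' confidence interval comes from the profile likelihood of |D'| with the
#' allele frequencies held at their MLEs: the multinomial likelihood is
#' evaluated on a fine |D'| grid (in the direction of the observed sign of
#' D), normalized, and the central interval at the stated confidence is
#' read off the cumulative curve. Pairs are then classified by the
#' haplotype-block rule on the CI bounds: "strong LD" when the lower bound
#' clears `strong_low` and the upper bound clears `strong_high`; "strong
#' evidence of recombination" when the upper bound falls below
#' `recomb_high`; otherwise uninformative.
#'
#' @param panel a [haplotype_panel()] (no genetic map needed).
#' @param i,j SNP column indices, `i < j`, both polymorphic.
#' @param confidence CI mass, default 0.90 (central interval, i.e. the 5th
#'   and 95th percentiles of the normalized profile likelihood).
#' @param strong_low,strong_high,recomb_high classification bounds on the CI.
#' @param grid_step |D'| grid resolution.
#' @return list of class `pair_ld`: `dprime`, `ci_low`, `ci_high`,
#'   `classification` (one of `"strong_ld"`, `"recombination"`,
#'   `"uninformative"`).
#' @export
estimate_dprime_ci <- function(panel, i, j, confidence = 0.90,
                               strong_low = 0.70, strong_high = 0.98,
                               recomb_high = 0.90, grid_step = 0.005) {
  if (i >= j) stop("need i < j")
  H <- n_copies(panel)
  if (H < 4) stop("need at least 4 chromosome copies")
  x <- panel$alleles[, i]
  y <- panel$alleles[, j]
  if (length(unique(x)) < 2L) stop("SNP ", i, " is monomorphic")
  if (length(unique(y)) < 2L) stop("SNP ", j, " is monomorphic")
  res <- .dprime_ci_batch(
    n11 = sum(x == 1L & y == 1L), n10 = sum(x == 1L & y == 0L),
    n01 = sum(x == 0L & y == 1L), n00 = sum(x == 0L & y == 0L),
    confidence = confidence, grid_step = grid_step
  )
  cls <- .classify_ld(res$ci_low, res$ci_high, strong_low, strong_high,
                      recomb_high)
  structure(list(dprime = res$dprime[1], ci_low = res$ci_low[1],
                 ci_high = res$ci_high[1],
                 classification = c("uninformative", "strong_ld",
                                    "recombination")[cls + 1L][1]),
            class = "pair_ld")
}

#' @export
print.pair_ld <- function(x, ...) {
  cat(sprintf("|D'| = %.3f, CI [%.3f, %.3f] -> %s\n",
              x$dprime, x$ci_low, x$ci_high, x$classification))
  invisible(x)
}

# codes: 1 strong_ld, 2 recombination, 0 uninformative
.classify_ld <- function(ci_low, ci_high, strong_low, strong_high,
                         recomb_high) {
  out <- integer(length(ci_low))
  out[ci_low >= strong_low & ci_high >= strong_high] <- 1L
  out[ci_high < recomb_high] <- 2L
  out
}

# Vectorized |D'| point estimate + profile-likelihood CI for many pairs.
# Inputs are parallel vectors of phased two-locus haplotype counts.
.dprime_ci_batch <- function(n11, n10, n01, n00, confidence = 0.90,
                             grid_step = 0.005) {
  H <- n11 + n10 + n01 + n00
  pA <- (n11 + n10) / H
  pB <- (n11 + n01) / H
  D <- n11 / H - pA * pB
  s <- ifelse(D >= 0, 1, -1)
  dmax <- ifelse(D >= 0,
                 pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  dmax <- pmax(dmax, .Machine$double.eps)
  dprime <- pmin(abs(D) / dmax, 1)

  grid <- seq(0, 1, by = grid_step)
  G <- length(grid)
  n <- length(n11)
  # p11 over the grid, direction fixed at the observed sign of D
  base <- matrix(pA * pB, G, n, byrow = TRUE)
  step <- matrix(s * dmax, G, n, byrow = TRUE) * grid
  p11 <- base + step
  mA <- matrix(pA, G, n, byrow = TRUE)
  mB <- matrix(pB, G, n, byrow = TRUE)
  p10 <- mA - p11
  p01 <- mB - p11
  p00 <- 1 - mA - mB + p11
  eps <- 1e-12
  ll <- matrix(n11, G, n, byrow = TRUE) * log(pmax(p11, eps)) +
        matrix(n10, G, n, byrow = TRUE) * log(pmax(p10, eps)) +
        matrix(n01, G, n, byrow = TRUE) * log(pmax(p01, eps)) +
        matrix(n00, G, n, byrow = TRUE) * log(pmax(p00, eps))
  # invalid cells (negative probabilities beyond Dmax) get -Inf weight
  ll[p11 < -1e-9 | p10 < -1e-9 | p01 < -1e-9 | p00 < -1e-9] <- -Inf
  mx <- apply(ll, 2, max)
  w <- exp(sweep(ll, 2, mx))
  cw <- apply(w, 2, cumsum)
  tot <- cw[G, ]
  lo_q <- (1 - confidence) / 2
  hi_q <- 1 - lo_q
  ci_low <- grid[max.col(t(cw >= rep(lo_q * tot, each = G)), "first")]
  ci_high <- grid[max.col(t(cw >= rep(hi_q * tot, each = G)), "first")]
  list(dprime = dprime, ci_low = ci_low, ci_high = ci_high)
}

# Classify all SNP pairs on one chromosome with lag <= max_lag.
# Returns an integer matrix [max_lag x n]: entry [lag, j] is the class code
# of pair (j - lag, j); NA where out of range.
.classify_pairs_lag <- function(alleles, max_lag, confidence, strong_low,
                                strong_high, recomb_high,
                                grid_step = 0.005) {
  n <- ncol(alleles)
  out <- matrix(NA_integer_, nrow = max_lag, ncol = n)
  for (lag in seq_len(min(max_lag, n - 1L))) {
    a <- alleles[, seq_len(n - lag), drop = FALSE]
    b <- alleles[, seq.int(lag + 1L, n), drop = FALSE]
    n11 <- colSums(a * b)
    n10 <- colSums(a) - n11
    n01 <- colSums(b) - n11
    n00 <- nrow(alleles) - n11 - n10 - n01
    ci <- .dprime_ci_batch(n11, n10, n01, n00, confidence = confidence,
                           grid_step = grid_step)
    out[lag, seq.int(lag + 1L, n)] <-
      .classify_ld(ci$ci_low, ci$ci_high, strong_low, strong_high, recomb_high)
  }
  out
}

#' Detect core regions (strong-LD haplotype blocks)
#'
#' A core region is a maximal contiguous run of SNPs in which, among the
#' informative SNP pairs (those classified strong-LD or recombination), the
#' fraction classified strong-LD is at least `min_strong_fraction`.
#' Uninformative pairs are excluded from the denominator. Candidate runs are
#' assembled greedily, longest first (ties to the leftmost start), into a
#' non-overlapping sorted set per chromosome. Detection is fully
#' deterministic.
#'
#' @param panel a MAF-filtered [haplotype_panel()].
#' @param confidence CI mass for the pairwise |D'| intervals.
#' @param strong_low,strong_high,recomb_high pair classification bounds
#'   (see [estimate_dprime_ci()]).
#' @param min_strong_fraction minimum fraction of informative pairs in a run
#'   that must be strong-LD (default 0.95).
#' @param min_core_snps minimum SNPs per region (default 3).
#' @param max_core_snps optional cap on region size (default unlimited).
#' @return data frame of class `core_regions` with columns `region_id`,
#'   `chrom`, `snp_start`, `snp_end` (inclusive panel column indices),
#'   `start_bp`, `end_bp` (0-based half-open over the outermost SNPs),
#'   `n_snps`.
#' @export
detect_core_regions <- function(panel, confidence = 0.90, strong_low = 0.70,
                                strong_high = 0.98, recomb_high = 0.90,
                                min_strong_fraction = 0.95,
                                min_core_snps = 3, max_core_snps = Inf) {
  stopifnot(min_core_snps >= 2)
  chroms <- unique(panel$snps$chrom)
  all_regions <- list()
  for (ch in chroms) {
    idx <- .chrom_idx(panel, ch)
    n <- length(idx)
    if (n < min_core_snps) next
    A <- panel$alleles[, idx, drop = FALSE]
    cap_limit <- min(n, if (is.finite(max_core_snps)) max_core_snps else n)
    Lcap <- min(32L, cap_limit)
    repeat {
      cls <- .classify_pairs_lag(A, max_lag = Lcap - 1L,
                                 confidence = confidence,
                                 strong_low = strong_low,
                                 strong_high = strong_high,
                                 recomb_high = recomb_high)
      wins <- .qualifying_windows(cls, n, Lcap, min_core_snps,
                                  min_strong_fraction)
      hit_cap <- nrow(wins) > 0 && any(wins$len == Lcap)
      if (!hit_cap || Lcap >= cap_limit) break
      Lcap <- min(2L * Lcap, cap_limit)   # rerun with a wider search window
    }
    if (nrow(wins) == 0) next
    picked <- .greedy_pick(wins, n)
    if (nrow(picked) == 0) next
    picked <- picked[order(picked$i), , drop = FALSE]
    all_regions[[ch]] <- data.frame(
      chrom = ch,
      snp_start = idx[picked$i],
      snp_end = idx[picked$j],
      start_bp = panel$snps$pos_bp[idx[picked$i]],
      end_bp = panel$snps$pos_bp[idx[picked$j]] + 1,
      n_snps = picked$j - picked$i + 1L,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(all_regions)) do.call(rbind, all_regions) else
    data.frame(chrom = character(0), snp_start = integer(0),
               snp_end = integer(0), start_bp = numeric(0),
               end_bp = numeric(0), n_snps = integer(0))
  rownames(out) <- NULL
  out <- cbind(region_id = if (nrow(out)) paste0("CR", seq_len(nrow(out)))
               else character(0), out, stringsAsFactors = FALSE)
  class(out) <- c("core_regions", "data.frame")
  attr(out, "params") <- list(confidence = confidence, strong_low = strong_low,
                              strong_high = strong_high,
                              recomb_high = recomb_high,
                              min_strong_fraction = min_strong_fraction,
                              min_core_snps = min_core_snps,
                              max_core_snps = max_core_snps)
  out
}

# Enumerate all windows [i, j] (local chromosome indices) of length in
# [min_core_snps, Lcap] whose informative pairs are >= min_strong_fraction
# strong. cls is the [lag x n] class-code matrix.
.qualifying_windows <- function(cls, n, Lcap, min_core_snps,
                                min_strong_fraction) {
  max_lag <- nrow(cls)
  strong <- cls == 1L
  inform <- cls == 1L | cls == 2L
  strong[is.na(strong)] <- FALSE
  inform[is.na(inform)] <- FALSE
  # column-cumulative over lag: CS[lag, j] = # strong pairs (j-l, j), l <= lag
  CS <- apply(strong, 2, cumsum)
  CI <- apply(inform, 2, cumsum)
  if (is.null(dim(CS))) { CS <- matrix(CS, nrow = 1); CI <- matrix(CI, nrow = 1) }
  res_i <- integer(0); res_j <- integer(0)
  for (i in seq_len(n - min_core_snps + 1L)) {
    jmax <- min(n, i + Lcap - 1L)
    if (jmax <= i) next
    jj <- seq.int(i + 1L, jmax)
    lag <- pmin(jj - i, max_lag)
    s_add <- CS[cbind(lag, jj)]
    i_add <- CI[cbind(lag, jj)]
    cs <- cumsum(s_add)
    ci <- cumsum(i_add)
    len <- jj - i + 1L
    ok <- len >= min_core_snps & ci > 0 &
      cs >= min_strong_fraction * ci - 1e-9
    if (any(ok)) {
      res_i <- c(res_i, rep.int(i, sum(ok)))
      res_j <- c(res_j, jj[ok])
    }
  }
  data.frame(i = res_i, j = res_j, len = res_j - res_i + 1L)
}

# Greedy longest-first, ties to leftmost start; windows must not overlap.
.greedy_pick <- function(wins, n) {
  ord <- order(-wins$len, wins$i)
  covered <- logical(n)
  keep <- logical(nrow(wins))
  for (k in ord) {
    i <- wins$i[k]; j <- wins$j[k]
    if (!any(covered[i:j])) {
      covered[i:j] <- TRUE
      keep[k] <- TRUE
    }
  }
  wins[keep, , drop = FALSE]
}

#' @export
print.core_regions <- function(x, ...) {
  cat("core_regions:", nrow(x), "regions")
  if (nrow(x)) {
    cat("; SNPs/region", min(x$n_snps), "-", max(x$n_snps),
        "; total length", round(sum(x$end_bp - x$start_bp) / 1000, 1), "kb")
  }
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Enumerate core haplotypes of a region
#'
#' Tallies the distinct allele strings carried by the panel's chromosome
#' copies over the region's SNPs. The carrier lists partition all `H` copies
#' and the frequencies sum to 1.
#'
#' @param panel a [haplotype_panel()]
#' @param region one row of a `core_regions` data frame (or any list with
#'   `snp_start`, `snp_end`).
#' @return data frame sorted by decreasing frequency (ties broken by allele
#'   string) with columns `haplotype`, `count`, `frequency` and a list
#'   column `carriers` of chromosome-copy indices.
#' @export
enumerate_core_haplotypes <- function(panel, region) {
  i <- region$snp_start; j <- region$snp_end
  if (is.null(i) || is.null(j) || i < 1 || j > n_snps(panel) || i > j) {
    stop("invalid region indices")
  }
  cols <- lapply(seq.int(i, j), function(k) panel$alleles[, k])
  strings <- do.call(paste0, cols)
  carriers <- split(seq_len(n_copies(panel)), strings)
  counts <- lengths(carriers)
  ord <- order(-counts, names(carriers))
  carriers <- carriers[ord]
  counts <- counts[ord]
  out <- data.frame(haplotype = names(carriers), count = as.integer(counts),
                    frequency = as.numeric(counts) / n_copies(panel),
                    stringsAsFactors = FALSE)
  out$carriers <- I(unname(carriers))
  rownames(out) <- NULL
  out
}

#' Export core regions as BED plus a core-haplotype table
#'
#' @param panel a [haplotype_panel()]
#' @param regions a `core_regions` data frame.
#' @param bed_path,hap_path output paths (either may be `NULL` to skip).
#' @return invisibly, the written paths.
#' @export
write_core_regions <- function(panel, regions, bed_path = NULL,
                               hap_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(regions$chrom, format(regions$start_bp, scientific = FALSE,
                                            trim = TRUE),
                      format(regions$end_bp, scientific = FALSE, trim = TRUE),
                      regions$region_id, regions$n_snps)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(hap_path)) {
    rows <- lapply(seq_len(nrow(regions)), function(r) {
      h <- enumerate_core_haplotypes(panel, regions[r, ])
      data.frame(region_id = regions$region_id[r], haplotype = h$haplotype,
                 count = h$count, frequency = h$frequency,
                 stringsAsFactors = FALSE)
    })
    utils::write.table(do.call(rbind, rows), hap_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(bed_path, hap_path))
}
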