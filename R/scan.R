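#' Genome-wide EHH/REHH selection scan
#'
#' The central fitting function: detects core regions (unless supplied),
#' evaluates every (core haplotype x direction) REHH test at the matched
#' genetic distance, discards low-frequency core haplotypes, and assigns
#' frequency-binned significance. High REHH at high core-haplotype
#' frequency is the signature of recent positive selection.
#'
#' @param panel a MAF-filtered [haplotype_panel()] with a genetic map
#'   attached (see [apply_maf_filter()], [attach_genetic_map()]).
#' @param target_cm matched genetic distance in cM at which EHH values are
#'   compared across core haplotypes (default 0.5, suited to the long-range
#'   LD of livestock populations).
#' @param min_freq core-haplotype frequency floor; haplotypes with
#'   frequency strictly below it are discarded before significance
#'   (default 0.20, boundary inclusive).
#' @param bin_width width of the frequency bins within which ln(REHH) is
#'   standardized (default 0.05).
#' @param p_method `"gaussian_log"` fits a normal to ln(REHH) per bin and
#'   takes the upper tail; `"empirical_rank"` uses the within-bin rank.
#' @param min_bin_n bins with fewer tests are merged with the nearest bin.
#' @param alphas significance levels reported by [summary.ehh_scan()].
#' @param regions optional precomputed `core_regions`; when `NULL` they are
#'   detected with [detect_core_regions()] using the `...` parameters.
#' @param ... passed to [detect_core_regions()].
#' @return an object of class `ehh_scan`: list with `regions`, `tests_all`
#'   (every evaluated test incl. dropped ones with their flags), `tests`
#'   (frequency-filtered tests with `log_rehh` and `p_value`), `dropped`
#'   (named drop counts), `params`, `panel_info`, `call`.
#' @seealso [summary.ehh_scan()], [significant_regions()], [plot.ehh_scan()]
#' @export
ehh_scan <- function(panel, target_cm = 0.5, min_freq = 0.20,
                     bin_width = 0.05,
                     p_method = c("gaussian_log", "empirical_rank"),
                     min_bin_n = 10, alphas = c(0.05, 0.01),
                     regions = NULL, ...) {
  p_method <- match.arg(p_method)
  if (anyNA(panel$snps$pos_cm)) {
    stop("genetic map not attached; see attach_genetic_map()")
  }
  if (is.null(regions)) regions <- detect_core_regions(panel, ...)
  tests_all <- if (nrow(regions)) {
    do.call(rbind, lapply(seq_len(nrow(regions)), function(r) {
      .region_rehh_tests(panel, regions[r, ], target_cm = target_cm)
    }))
  } else .empty_tests()
  rownames(tests_all) <- NULL
  dropped <- c(
    edge = sum(tests_all$flag == "edge"),
    zero_others = sum(tests_all$flag == "zero_others"),
    low_frequency = 0L
  )
  valid <- tests_all[tests_all$flag == "ok", , drop = FALSE]
  tests <- filter_by_frequency(valid, min_freq = min_freq)
  dropped["low_frequency"] <- nrow(valid) - nrow(tests)
  tests <- assign_p_values(tests, bin_width = bin_width, method = p_method,
                           min_bin_n = min_bin_n, min_freq = min_freq)
  structure(list(
    regions = regions,
    tests_all = tests_all,
    tests = tests,
    dropped = dropped,
    params = list(target_cm = target_cm, min_freq = min_freq,
                  bin_width = bin_width, p_method = p_method,
                  min_bin_n = min_bin_n, alphas = alphas),
    panel_info = summary(panel),
    call = match.call()
  ), class = "ehh_scan")
}

#' Discard low-frequency core-haplotype tests
#'
#' Retains tests whose core-haplotype frequency is at least `min_freq`. The
#' boundary is inclusive: the discard rule is a strict "frequency below the
#' floor", so a haplotype at exactly the floor is kept.
#'
#' @param tests data frame of REHH tests with a `frequency` column.
#' @param min_freq frequency floor (default 0.20).
#' @return the retained rows.
#' @export
filter_by_frequency <- function(tests, min_freq = 0.20) {
  tests[tests$frequency >= min_freq, , drop = FALSE]
}

#' Assign frequency-binned p-values to REHH tests
#'
#' Tests are partitioned into core-haplotype frequency bins of width
#' `bin_width` spanning `[min_freq, 1]`; bins with fewer than `min_bin_n`
#' tests are merged with the nearest bin (by bin-center distance, ties to
#' the lower bin). Within each bin, `"gaussian_log"` fits mean and sd to
#' ln(REHH) and takes the upper-tail normal probability; a bin with zero
#' variance falls back to `"empirical_rank"` (p = fraction of bin values at
#' least as large). P-values are invariant to the order of the input rows.
#'
#' @param tests data frame with `rehh` (> 0) and `frequency` columns.
#' @param bin_width frequency bin width (default 0.05).
#' @param method `"gaussian_log"` or `"empirical_rank"`.
#' @param min_bin_n minimum bin occupancy before merging (default 10).
#' @param min_freq lower edge of the binned frequency range.
#' @return `tests` with columns `log_rehh`, `freq_bin`, `p_value` added.
#' @export
assign_p_values <- function(tests, bin_width = 0.05,
                            method = c("gaussian_log", "empirical_rank"),
                            min_bin_n = 10, min_freq = 0.20) {
  method <- match.arg(method)
  tests <- as.data.frame(tests)
  if (nrow(tests) == 0) {
    tests$log_rehh <- numeric(0); tests$freq_bin <- integer(0)
    tests$p_value <- numeric(0)
    return(tests)
  }
  if (any(!is.finite(tests$rehh)) || any(tests$rehh <= 0)) {
    stop("assign_p_values needs defined REHH > 0 for every test")
  }
  tests$log_rehh <- log(tests$rehh)
  breaks <- seq(min_freq, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  bin <- findInterval(tests$frequency, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  bin <- .merge_small_bins(bin, breaks, min_bin_n)
  p <- numeric(nrow(tests))
  for (b in unique(bin)) {
    sel <- bin == b
    x <- tests$log_rehh[sel]
    use_rank <- method == "empirical_rank"
    if (!use_rank) {
      mu <- mean(x); sdev <- stats::sd(x)
      if (length(x) < 2 || !is.finite(sdev) || sdev == 0) {
        message("assign_p_values: zero-variance bin, empirical-rank fallback")
        use_rank <- TRUE
      } else {
        p[sel] <- stats::pnorm(x, mean = mu, sd = sdev, lower.tail = FALSE)
      }
    }
    if (use_rank) {
      p[sel] <- vapply(x, function(v) sum(x >= v), 0) / length(x)
    }
  }
  tests$freq_bin <- bin
  tests$p_value <- p
  tests
}

# Merge bins with < min_bin_n members into their nearest occupied neighbour
# (bin-center distance; ties to the lower bin). Deterministic.
.merge_small_bins <- function(bin, breaks, min_bin_n) {
  centers <- (breaks[-length(breaks)] + breaks[-1]) / 2
  repeat {
    tab <- table(bin)
    ids <- as.integer(names(tab))
    if (length(ids) <= 1) break
    small <- ids[tab < min_bin_n]
    if (length(small) == 0) break
    b <- small[1]
    others <- setdiff(ids, b)
    d <- abs(centers[others] - centers[b])
    tgt <- others[order(d, others)][1]
    bin[bin == b] <- tgt
    # the merged bin's effective center: keep the target's center
  }
  bin
}

#' Call significant tests and regions
#'
#' A test is significant when `p < alpha` strictly; a region is significant
#' when any of its tests is.
#'
#' @param tests data frame with `p_value` and `region_id`.
#' @param alphas significance levels (default 0.05 and 0.01).
#' @return list with `tests` (named list per alpha of significant rows) and
#'   `regions` (data frame of per-region logical flags per alpha).
#' @export
call_significant <- function(tests, alphas = c(0.05, 0.01)) {
  if (is.null(tests$p_value)) stop("p-values not assigned")
  by_alpha <- lapply(alphas, function(a) {
    tests[tests$p_value < a, , drop = FALSE]
  })
  names(by_alpha) <- paste0("alpha_", alphas)
  ids <- unique(tests$region_id)
  flags <- data.frame(region_id = ids, stringsAsFactors = FALSE)
  for (k in seq_along(alphas)) {
    flags[[paste0("sig_", alphas[k])]] <-
      ids %in% by_alpha[[k]]$region_id
  }
  list(tests = by_alpha, regions = flags)
}

#' Significant regions of a scan
#'
#' @param scan an `ehh_scan` object.
#' @param alpha significance level (strict `p < alpha`).
#' @return the rows of `scan$regions` with at least one significant test.
#' @export
significant_regions <- function(scan, alpha = 0.05) {
  sig <- call_significant(scan$tests, alphas = alpha)
  ids <- sig$regions$region_id[sig$regions[[2]]]
  scan$regions[scan$regions$region_id %in% ids, , drop = FALSE]
}

#' Per-chromosome scan summary table
#'
#' One row per chromosome plus a totals row: SNP count, mean marker spacing,
#' core-region count and lengths, SNPs inside regions, frequency-filtered
#' test count, and significant-test counts at each level. Count columns in
#' the totals row are column sums; mean/sd columns are recomputed over all
#' regions.
#'
#' @param panel the scanned [haplotype_panel()].
#' @param regions `core_regions` data frame.
#' @param tests frequency-filtered tests with `p_value`.
#' @param alphas significance levels.
#' @return data frame of class `scan_summary`.
#' @export
summarize_scan <- function(panel, regions, tests, alphas = c(0.05, 0.01)) {
  chroms <- unique(panel$snps$chrom)
  rows <- lapply(chroms, function(ch) {
    i <- .chrom_idx(panel, ch)
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    tst <- tests[tests$chrom == ch, , drop = FALSE]
    len_kb <- (reg$end_bp - reg$start_bp) / 1000
    span <- diff(range(panel$snps$pos_bp[i]))
    out <- data.frame(
      chrom = ch, n_snps = length(i),
      mean_spacing_kb = if (length(i) > 1) span / (length(i) - 1) / 1000
                        else NA_real_,
      n_regions = nrow(reg),
      total_cr_kb = sum(len_kb), max_cr_kb = if (nrow(reg)) max(len_kb) else 0,
      mean_cr_kb = if (nrow(reg)) mean(len_kb) else NA_real_,
      sd_cr_kb = if (nrow(reg) > 1) stats::sd(len_kb) else NA_real_,
      cr_snps = sum(reg$n_snps), n_tests = nrow(tst),
      stringsAsFactors = FALSE
    )
    for (a in alphas) out[[paste0("sig_", a)]] <- sum(tst$p_value < a)
    out
  })
  out <- do.call(rbind, rows)
  len_all <- (regions$end_bp - regions$start_bp) / 1000
  tot <- data.frame(
    chrom = "Total", n_snps = sum(out$n_snps),
    mean_spacing_kb = mean(out$mean_spacing_kb, na.rm = TRUE),
    n_regions = sum(out$n_regions), total_cr_kb = sum(out$total_cr_kb),
    max_cr_kb = if (nrow(regions)) max(len_all) else 0,
    mean_cr_kb = if (nrow(regions)) mean(len_all) else NA_real_,
    sd_cr_kb = if (nrow(regions) > 1) stats::sd(len_all) else NA_real_,
    cr_snps = sum(out$cr_snps), n_tests = sum(out$n_tests),
    stringsAsFactors = FALSE
  )
  for (a in alphas) tot[[paste0("sig_", a)]] <- sum(out[[paste0("sig_", a)]])
  out <- rbind(out, tot)
  rownames(out) <- NULL
  class(out) <- c("scan_summary", "data.frame")
  out
}

#' @export
print.ehh_scan <- function(x, ...) {
  cat("EHH/REHH selection scan\n")
  cat("  core regions:  ", nrow(x$regions), "\n")
  cat("  tests evaluated:", nrow(x$tests_all),
      sprintf(" (dropped: %d edge, %d undefined, %d low-frequency)\n",
              x$dropped["edge"], x$dropped["zero_others"],
              x$dropped["low_frequency"]))
  cat("  tests retained: ", nrow(x$tests),
      " (frequency >=", x$params$min_freq, ")\n")
  for (a in x$params$alphas) {
    cat(sprintf("  significant at %.2f: %d tests in %d regions\n", a,
                sum(x$tests$p_value < a),
                length(unique(x$tests$region_id[x$tests$p_value < a]))))
  }
  invisible(x)
}

#' Summary method for an EHH scan
#'
#' @param object an `ehh_scan`.
#' @param panel the panel the scan was fitted to (the scan object keeps only
#'   per-chromosome metadata, so the panel must be passed back in for the
#'   spacing columns; omit to summarize from stored metadata).
#' @param ... unused.
#' @return a `scan_summary` data frame (see [summarize_scan()]).
#' @export
summary.ehh_scan <- function(object, panel = NULL, ...) {
  if (!is.null(panel)) {
    return(summarize_scan(panel, object$regions, object$tests,
                          object$params$alphas))
  }
  info <- object$panel_info
  rows <- lapply(seq_len(nrow(info)), function(k) {
    ch <- info$chrom[k]
    reg <- object$regions[object$regions$chrom == ch, , drop = FALSE]
    tst <- object$tests[object$tests$chrom == ch, , drop = FALSE]
    len_kb <- (reg$end_bp - reg$start_bp) / 1000
    out <- data.frame(chrom = ch, n_snps = info$n_snps[k],
                      mean_spacing_kb = info$mean_spacing_kb[k],
                      n_regions = nrow(reg), total_cr_kb = sum(len_kb),
                      max_cr_kb = if (nrow(reg)) max(len_kb) else 0,
                      mean_cr_kb = if (nrow(reg)) mean(len_kb) else NA_real_,
                      sd_cr_kb = if (nrow(reg) > 1) stats::sd(len_kb)
                                 else NA_real_,
                      cr_snps = sum(reg$n_snps), n_tests = nrow(tst),
                      stringsAsFactors = FALSE)
    for (a in object$params$alphas) {
      out[[paste0("sig_", a)]] <- sum(tst$p_value < a)
    }
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scan_summary", "data.frame")
  out
}

#' Plot REHH against core-haplotype frequency
#'
#' The classic scan diagnostic: each frequency-filtered test is one point,
#' colored by its p-value band. Sweeps appear as high-REHH outliers at high
#' frequency.
#'
#' @param x an `ehh_scan`.
#' @param p_bands p-value band edges for coloring.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.ehh_scan <- function(x, p_bands = c(0.01, 0.05), ...) {
  t <- x$tests
  if (nrow(t) == 0) {
    warning("no tests to plot")
    return(invisible(x))
  }
  band <- findInterval(t$p_value, sort(p_bands))
  cols <- c("red", "orange", "grey40")[band + 1L]
  graphics::plot(t$frequency, t$rehh, col = cols, pch = 16,
                 xlab = "core haplotype frequency", ylab = "REHH", ...)
  graphics::legend("topright", pch = 16, col = c("red", "orange", "grey40"),
                   legend = c(paste("p <", sort(p_bands)[1]),
                              paste("p <", sort(p_bands)[2]),
                              "n.s."), bty = "n")
  invisible(x)
}

#' Write scan test results as TSV
#'
#' @param scan an `ehh_scan`.
#' @param path output TSV path.
#' @param header optional character vector of `#`-prefixed header lines.
#' @return invisibly, the path.
#' @export
write_scan_tests <- function(scan, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(scan$tests, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
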