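#' EHH decay profile of one core haplotype
#'
#' Extended haplotype homozygosity at a marker is the probability that two
#' randomly chosen carriers of the core haplotype are identical over the
#' entire interval from the core edge to that marker. With `c` carriers
#' split into identity groups of sizes `e_i` at a given extent, EHH equals
#' `sum(choose(e_i, 2)) / choose(c, 2)`. The profile starts at 1 at the core
#' edge and is non-increasing, because identity groups can only split as the
#' interval grows. Genetic distance is measured from the outermost core SNP
#' in the tested direction.
#'
#' @param panel a [haplotype_panel()] with a genetic map attached.
#' @param region one row of a `core_regions` data frame.
#' @param haplotype a core haplotype allele string (as produced by
#'   [enumerate_core_haplotypes()]).
#' @param direction `"downstream"` (increasing position) or `"upstream"`.
#' @param max_distance_cm stop once the profile passes this distance
#'   (default: run to the chromosome end or EHH = 0). The first marker
#'   beyond the cap is included so the cap distance can be interpolated.
#' @return an object of class `ehh_profile` (list with `region_id`,
#'   `haplotype`, `direction`, `n_carriers`, and `points`, a data frame of
#'   `distance_cm`/`ehh`), or `NULL` with a message when the haplotype has
#'   fewer than 2 carriers (EHH undefined for singletons).
#' @export
ehh_profile <- function(panel, region, haplotype,
                        direction = c("downstream", "upstream"),
                        max_distance_cm = Inf) {
  direction <- match.arg(direction)
  haps <- enumerate_core_haplotypes(panel, region)
  k <- match(haplotype, haps$haplotype)
  if (is.na(k)) stop("haplotype ", haplotype, " not found in region")
  carriers <- haps$carriers[[k]]
  if (length(carriers) < 2L) {
    message("ehh_profile: singleton core haplotype, EHH undefined; skipped")
    return(NULL)
  }
  walk <- .ehh_walk(panel, region, direction, max_distance_cm,
                    subset = carriers, init_groups = rep(1L, length(carriers)))
  structure(list(region_id = region$region_id, haplotype = haplotype,
                 direction = direction, n_carriers = length(carriers),
                 points = walk),
            class = "ehh_profile")
}

#' @export
print.ehh_profile <- function(x, ...) {
  cat("ehh_profile:", x$haplotype, x$direction, "(", x$n_carriers,
      "carriers,", nrow(x$points), "points )\n")
  print(utils::head(x$points, 8))
  invisible(x)
}

# Walk markers outward from the core edge for a subset of copies, refining
# identity groups; returns data.frame(distance_cm, ehh) including the
# distance-0 point. Homozygosity of the initial grouping defines the value
# at distance 0 (1 when all start in one group).
.ehh_walk <- function(panel, region, direction, max_distance_cm, subset,
                      init_groups) {
  cm <- panel$snps$pos_cm
  if (anyNA(cm[region$snp_start:region$snp_end])) {
    stop("genetic map not attached; see attach_genetic_map()")
  }
  chrom_cols <- .chrom_idx(panel, panel$snps$chrom[region$snp_start])
  if (direction == "downstream") {
    edge <- region$snp_end
    path <- chrom_cols[chrom_cols > edge]
  } else {
    edge <- region$snp_start
    path <- rev(chrom_cols[chrom_cols < edge])
  }
  cc <- length(subset)
  tot_pairs <- cc * (cc - 1) / 2
  g <- match(init_groups, unique(init_groups))
  sz <- tabulate(g)
  ehh0 <- sum(sz * (sz - 1) / 2) / tot_pairs
  dist <- 0
  ehh <- ehh0
  for (m in path) {
    a <- panel$alleles[subset, m]
    g <- g * 2L + a
    g <- match(g, unique(g))
    sz <- tabulate(g)
    d <- abs(cm[m] - cm[edge])
    e <- sum(sz * (sz - 1) / 2) / tot_pairs
    dist <- c(dist, d)
    ehh <- c(ehh, e)
    if (e == 0 || d >= max_distance_cm) break
  }
  data.frame(distance_cm = dist, ehh = ehh)
}

#' EHH at a matched genetic distance
#'
#' Linearly interpolates an EHH profile between the two markers bracketing
#' the target distance. If the profile ends before the target because the
#' chromosome ran out while EHH was still positive, the value is undefined
#' and `NA` is returned with attribute `reason = "edge"` (such tests are
#' dropped). A profile that has already decayed to 0 stays at 0 beyond its
#' last marker.
#'
#' @param profile an `ehh_profile`, or any data frame with `distance_cm`
#'   and `ehh` columns.
#' @param target_cm matched genetic distance in cM (default 0.5).
#' @return EHH value in \[0, 1\], or flagged `NA`.
#' @export
ehh_at_distance <- function(profile, target_cm = 0.5) {
  if (target_cm < 0) stop("target_cm must be non-negative")
  pts <- if (inherits(profile, "ehh_profile")) profile$points else profile
  if (is.null(pts) || nrow(pts) == 0) stop("empty profile")
  .ehh_interp(pts$distance_cm, pts$ehh, target_cm)
}

.ehh_interp <- function(dist, ehh, target_cm) {
  # keep the last (smallest-EHH) point at any duplicated distance
  keep <- !duplicated(dist, fromLast = TRUE)
  dist <- dist[keep]; ehh <- ehh[keep]
  last <- length(dist)
  if (target_cm > dist[last]) {
    if (ehh[last] == 0) return(0)
    out <- NA_real_
    attr(out, "reason") <- "edge"
    return(out)
  }
  stats::approx(dist, ehh, xout = target_cm, ties = "ordered")$y
}

#' Relative EHH (REHH) of a core haplotype
#'
#' Compares the EHH of the tested core haplotype with the pooled EHH of all
#' other core haplotypes of the same region at the same matched genetic
#' distance, which corrects for local variation in recombination rate. The
#' pooled "others" homozygosity is computed over all non-tested copies with
#' identity groups seeded by their own core haplotype (groups never merge
#' across distinct core haplotypes).
#'
#' @inheritParams ehh_profile
#' @param target_cm matched genetic distance in cM (default 0.5).
#' @return list of class `rehh_value`: `ehh_tested`, `ehh_others`, `rehh`,
#'   `flag` (`"ok"`, `"singleton"`, `"no_others"`, `"edge"`, or
#'   `"zero_others"`; `rehh` is `NA` unless the flag is `"ok"`).
#' @export
rehh <- function(panel, region, haplotype,
                 direction = c("downstream", "upstream"), target_cm = 0.5) {
  direction <- match.arg(direction)
  haps <- enumerate_core_haplotypes(panel, region)
  k <- match(haplotype, haps$haplotype)
  if (is.na(k)) stop("haplotype ", haplotype, " not found in region")
  carriers <- haps$carriers[[k]]
  H <- n_copies(panel)
  others <- setdiff(seq_len(H), carriers)
  flag <- "ok"
  if (length(carriers) < 2L) flag <- "singleton"
  if (length(others) < 2L) flag <- "no_others"   # frequency-1 core haplotype
  if (flag != "ok") {
    return(structure(list(ehh_tested = NA_real_, ehh_others = NA_real_,
                          rehh = NA_real_, flag = flag),
                     class = "rehh_value"))
  }
  tw <- .ehh_walk(panel, region, direction, target_cm,
                  subset = carriers, init_groups = rep(1L, length(carriers)))
  hap_of <- rep(seq_len(nrow(haps)), lengths(haps$carriers))[
    order(unlist(haps$carriers, use.names = FALSE))]
  ow <- .ehh_walk(panel, region, direction, target_cm,
                  subset = others, init_groups = hap_of[others])
  et <- .ehh_interp(tw$distance_cm, tw$ehh, target_cm)
  eo <- .ehh_interp(ow$distance_cm, ow$ehh, target_cm)
  if (is.na(et) || is.na(eo)) {
    flag <- "edge"
    r <- NA_real_
  } else if (eo == 0) {
    flag <- "zero_others"
    r <- NA_real_
  } else {
    r <- et / eo
  }
  structure(list(ehh_tested = if (is.na(et)) NA_real_ else et,
                 ehh_others = if (is.na(eo)) NA_real_ else eo,
                 rehh = r, flag = flag),
            class = "rehh_value")
}

#' @export
print.rehh_value <- function(x, ...) {
  cat(sprintf("REHH = %s (EHH tested %.4f / others %.4f) [%s]\n",
              if (is.na(x$rehh)) "NA" else sprintf("%.3f", x$rehh),
              x$ehh_tested, x$ehh_others, x$flag))
  invisible(x)
}

# Joint REHH evaluation for every core haplotype of a region in one pass per
# direction. All H copies are refined together, seeded by core haplotype, so
# identity groups never cross core haplotypes; per-haplotype tested EHH and
# pooled-others EHH both fall out of the same group-size bookkeeping.
# Returns one row per (haplotype with >= min_carriers carriers) x direction.
.region_rehh_tests <- function(panel, region, target_cm = 0.5,
                               min_carriers = 2L) {
  haps <- enumerate_core_haplotypes(panel, region)
  H <- n_copies(panel)
  nh <- nrow(haps)
  hap_of <- rep(seq_len(nh), lengths(haps$carriers))[
    order(unlist(haps$carriers, use.names = FALSE))]
  cnt <- haps$count
  pairs_h <- cnt * (cnt - 1) / 2
  pairs_o <- (H - cnt) * (H - cnt - 1) / 2
  cm <- panel$snps$pos_cm
  chrom <- panel$snps$chrom[region$snp_start]
  chrom_cols <- .chrom_idx(panel, chrom)
  out <- vector("list", 2L)
  for (dir_i in 1:2) {
    direction <- c("downstream", "upstream")[dir_i]
    if (direction == "downstream") {
      edge <- region$snp_end
      path <- chrom_cols[chrom_cols > edge]
    } else {
      edge <- region$snp_start
      path <- rev(chrom_cols[chrom_cols < edge])
    }
    g <- hap_of
    sz <- tabulate(g)
    grp_hap <- seq_len(nh)
    pair_by_hap <- as.vector(rowsum(sz * (sz - 1) / 2, grp_hap))
    dist <- 0
    P <- matrix(pair_by_hap, nrow = 1)   # per-step pair sums by haplotype
    for (m in path) {
      a <- panel$alleles[, m]
      g <- g * 2L + a
      u <- !duplicated(g)
      grp_hap <- hap_of[u]               # first member's core haplotype
      g <- match(g, g[u])
      sz <- tabulate(g)
      # rowsum drops absent haplotype levels; rebuild a full-length vector
      full <- numeric(nh)
      full[sort(unique(grp_hap))] <- as.vector(
        rowsum(sz * (sz - 1) / 2, grp_hap, reorder = TRUE))
      d <- abs(cm[m] - cm[edge])
      dist <- c(dist, d)
      P <- rbind(P, full)
      if (sum(full) == 0 || d >= target_cm) break
    }
    total <- rowSums(P)
    rows <- lapply(which(cnt >= min_carriers & (H - cnt) >= 2L), function(h) {
      et <- .ehh_interp(dist, P[, h] / pairs_h[h], target_cm)
      eo <- .ehh_interp(dist, (total - P[, h]) / pairs_o[h], target_cm)
      flag <- "ok"; r <- NA_real_
      if (is.na(et) || is.na(eo)) flag <- "edge"
      else if (eo == 0) flag <- "zero_others"
      else r <- et / eo
      data.frame(region_id = region$region_id, chrom = chrom,
                 start_bp = region$start_bp, end_bp = region$end_bp,
                 haplotype = haps$haplotype[h], frequency = haps$frequency[h],
                 direction = direction,
                 ehh_tested = if (is.na(et)) NA_real_ else et,
                 ehh_others = if (is.na(eo)) NA_real_ else eo,
                 rehh = r, flag = flag, stringsAsFactors = FALSE)
    })
    out[[dir_i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) res <- .empty_tests()
  rownames(res) <- NULL
  res
}

.empty_tests <- function() {
  data.frame(region_id = character(0), chrom = character(0),
             start_bp = numeric(0), end_bp = numeric(0),
             haplotype = character(0), frequency = numeric(0),
             direction = character(0), ehh_tested = numeric(0),
             ehh_others = numeric(0), rehh = numeric(0),
             flag = character(0), stringsAsFactors = FALSE)
}
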