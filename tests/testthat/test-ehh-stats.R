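# EHH profiles, interpolation at the matched distance, and REHH.

test_that("EHH is 1 at the core edge and for identical carriers", {
  haps <- rbind(c(1L, 1L, 1L, 1L, 1L), c(0L, 0L, 0L, 0L, 1L))
  p <- block_panel(haps, c(6, 4))
  reg <- list(region_id = "r1", snp_start = 1, snp_end = 2)
  pr <- ehh_profile(p, reg, "11", direction = "downstream")
  expect_equal(pr$points$ehh[1], 1)                  # distance 0
  expect_true(all(pr$points$ehh == 1))               # identical carriers
})

test_that("carrier split 2/1/1 at the first flanking SNP gives EHH 1/6", {
  # 4 carriers of core "1"; extensions split 2/1/1 -> 1 identical pair of 6
  alleles <- rbind(
    c(1L, 0L, 0L), c(1L, 0L, 0L),      # group of 2
    c(1L, 1L, 0L),                     # singleton
    c(1L, 0L, 1L),                     # singleton
    c(0L, 0L, 0L), c(0L, 1L, 1L))
  p <- haplotype_panel(alleles, data.frame(id = paste0("s", 1:3), chrom = "1",
                                           pos_bp = (0:2) * 50000,
                                           pos_cm = (0:2) * 0.05))
  pr <- ehh_profile(p, list(region_id = "r", snp_start = 1, snp_end = 1),
                    "1", direction = "downstream")
  expect_equal(pr$points$ehh, c(1, 1 / 2, 1 / 6))    # C(2,2)/C(4,2) = 1/6
})

test_that("singleton core haplotypes are skipped with a message, not an error", {
  alleles <- rbind(c(1L, 0L), c(0L, 0L), c(0L, 1L), c(0L, 1L))
  p <- haplotype_panel(alleles, data.frame(id = c("a", "b"), chrom = "1",
                                           pos_bp = c(0, 50000),
                                           pos_cm = c(0, 0.05)))
  expect_message(
    pr <- ehh_profile(p, list(region_id = "r", snp_start = 1, snp_end = 1),
                      "1", "downstream"),
    "singleton")
  expect_null(pr)
})

test_that("group-count EHH equals pairwise-identity enumeration", {
  set.seed(31)
  for (rep in 1:40) {
    H <- 2 * sample(3:15, 1); S <- sample(6:20, 1)
    p <- random_panel(H = H, S = S)
    i <- sample(seq_len(S - 3), 1)
    reg <- list(region_id = "r", snp_start = i, snp_end = i + 1)
    h <- enumerate_core_haplotypes(p, reg)
    h <- h[h$count >= 2, , drop = FALSE]
    if (nrow(h) == 0) next
    hap <- h$haplotype[sample(nrow(h), 1)]
    carriers <- h$carriers[[match(hap, h$haplotype)]]
    for (dir in c("downstream", "upstream")) {
      pr <- ehh_profile(p, reg, hap, dir)
      path <- ext_cols(p, reg, dir, nrow(pr$points) - 1)
      for (k in seq_len(nrow(pr$points))) {
        cols <- if (k == 1) integer(0) else path[seq_len(k - 1)]
        expect_equal(pr$points$ehh[k],
                     oracle_ehh_pairwise(p$alleles, carriers, cols),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("profiles are monotone non-increasing and within [0,1]", {
  set.seed(77)
  for (rep in 1:30) {
    p <- random_panel(H = 20, S = 15)
    reg <- list(region_id = "r", snp_start = 7, snp_end = 8)
    h <- enumerate_core_haplotypes(p, reg)
    for (r in which(h$count >= 2)) {
      for (dir in c("downstream", "upstream")) {
        pr <- ehh_profile(p, reg, h$haplotype[r], dir)
        e <- pr$points$ehh
        expect_equal(e[1], 1)
        expect_true(all(diff(e) <= 1e-12))
        expect_true(all(e >= 0 & e <= 1))
      }
    }
  }
})

test_that("reversing SNP order swaps upstream and downstream profiles", {
  set.seed(12)
  p <- random_panel(H = 16, S = 11)
  reg <- list(region_id = "r", snp_start = 5, snp_end = 7)
  h <- enumerate_core_haplotypes(p, reg)
  hap <- h$haplotype[which(h$count >= 2)[1]]
  down <- ehh_profile(p, reg, hap, "downstream")
  # reverse the panel
  S <- n_snps(p)
  rev_alleles <- p$alleles[, S:1]
  pos <- p$snps$pos_bp
  rp <- haplotype_panel(rev_alleles, data.frame(
    id = paste0("r", 1:S), chrom = "1", pos_bp = max(pos) - rev(pos),
    pos_cm = (max(pos) - rev(pos)) / 1e6))
  rreg <- list(region_id = "r", snp_start = S - 7 + 1, snp_end = S - 5 + 1)
  rhap <- paste(rev(strsplit(hap, "")[[1]]), collapse = "")
  up <- ehh_profile(rp, rreg, rhap, "upstream")
  expect_equal(up$points$ehh, down$points$ehh)
  expect_equal(up$points$distance_cm, down$points$distance_cm)
})

test_that("EHH at a distance interpolates linearly and flags the edge", {
  pr <- data.frame(distance_cm = c(0, 0.4, 0.6), ehh = c(1, 0.8, 0.4))
  expect_equal(ehh_at_distance(pr, 0.5), 0.6)      # midpoint interpolation
  expect_equal(ehh_at_distance(pr, 0.4), 0.8)      # exactly at a marker
  short <- data.frame(distance_cm = c(0, 0.3), ehh = c(1, 0.5))
  v <- ehh_at_distance(short, 0.5)
  expect_true(is.na(v))
  expect_identical(attr(v, "reason"), "edge")      # chromosome ran out
  decayed <- data.frame(distance_cm = c(0, 0.3), ehh = c(1, 0))
  expect_equal(ehh_at_distance(decayed, 0.5), 0)   # 0 persists past the end
  expect_error(ehh_at_distance(pr, -0.1), "non-negative")
})

test_that("REHH is the ratio of tested to pooled-others EHH", {
  set.seed(99)
  for (rep in 1:15) {
    p <- random_panel(H = 24, S = 16)
    reg <- list(region_id = "r", snp_start = 8, snp_end = 9)
    h <- enumerate_core_haplotypes(p, reg)
    ok <- which(h$count >= 2 & (24 - h$count) >= 2)
    if (length(ok) == 0) next
    hap <- h$haplotype[ok[1]]
    r <- rehh(p, reg, hap, "downstream", target_cm = 0.1)
    if (r$flag != "ok") next
    carriers <- h$carriers[[match(hap, h$haplotype)]]
    others <- setdiff(1:24, carriers)
    # oracle at the exact marker 0.1 cM away (2 markers at 0.05 cM spacing)
    cols <- ext_cols(p, reg, "downstream", 2)
    et <- oracle_ehh_pairwise(p$alleles, carriers, cols)
    eo <- oracle_ehh_others(p$alleles, others, 8:9, cols)
    if (eo == 0) {
      expect_identical(r$flag, "zero_others")
    } else {
      expect_equal(r$ehh_tested, et, tolerance = 1e-12)
      expect_equal(r$ehh_others, eo, tolerance = 1e-12)
      expect_equal(r$rehh, et / eo, tolerance = 1e-12)
    }
  }
})

test_that("REHH of a frequency-1 haplotype is flagged, never infinite", {
  p <- block_panel(matrix(1L, 1, 6), 10)
  reg <- list(region_id = "r", snp_start = 3, snp_end = 4)
  r <- rehh(p, reg, "11", "downstream")
  expect_identical(r$flag, "no_others")
  expect_true(is.na(r$rehh))
})

test_that("joint region evaluation agrees with per-haplotype rehh()", {
  set.seed(41)
  for (rep in 1:10) {
    p <- random_panel(H = 30, S = 18)
    reg <- list(region_id = "r", chrom = "1", snp_start = 9, snp_end = 10,
                start_bp = p$snps$pos_bp[9], end_bp = p$snps$pos_bp[10] + 1)
    tests <- haploscan:::.region_rehh_tests(p, reg, target_cm = 0.2)
    for (r in seq_len(nrow(tests))) {
      single <- rehh(p, reg, tests$haplotype[r], tests$direction[r],
                     target_cm = 0.2)
      expect_identical(single$flag, tests$flag[r])
      if (single$flag == "ok") {
        expect_equal(single$rehh, tests$rehh[r], tolerance = 1e-12)
      }
    }
  }
})

test_that("a planted non-recombined sweep attains the region's top REHH", {
  set.seed(123)
  cfg <- sim_config(n_copies = 200, n_snps = 400, seed = 17)
  pan <- simulate_neutral_panel(cfg)
  sw <- plant_sweep(pan, position_bp = cfg$chrom_length_bp / 2,
                    carrier_fraction = 0.4, tract_half_length_cm = 1)
  pan <- sw$panel
  reg <- detect_core_regions(pan)
  inside <- reg[reg$start_bp >= sw$truth$start_bp + 5e5 &
                reg$end_bp <= sw$truth$end_bp - 5e5, , drop = FALSE]
  expect_gt(nrow(inside), 0)   # the fixed seed yields an interior region
  region <- inside[1, ]
  h <- enumerate_core_haplotypes(pan, region)
  swept <- vapply(h$carriers, function(cr) {
    mean(cr %in% sw$truth$carriers) > 0.5
  }, TRUE)
  tests <- haploscan:::.region_rehh_tests(pan, region)
  tests <- tests[tests$flag == "ok", ]
  swept_hap <- h$haplotype[which(swept)[1]]
  best_swept <- max(tests$rehh[tests$haplotype == swept_hap])
  expect_gte(best_swept, max(tests$rehh))
})
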