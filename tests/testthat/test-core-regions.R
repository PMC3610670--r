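# Pairwise D' classification and core-region detection.

test_that("perfect LD pair gives D' = 1 and strong-LD classification", {
  p <- block_panel(rbind(c(1L, 1L), c(0L, 0L)), c(50, 50))
  r <- estimate_dprime_ci(p, 1, 2)
  expect_equal(r$dprime, 1)
  expect_identical(r$classification, "strong_ld")
})

test_that("D' point estimate matches direct two-locus algebra", {
  # counts AB=40, Ab=10, aB=10, ab=40 -> D = 0.15, Dmax = 0.25, D' = 0.6
  x <- rep(c(1L, 1L, 0L, 0L), c(40, 10, 10, 40))
  y <- rep(c(1L, 0L, 1L, 0L), c(40, 10, 10, 40))
  p <- haplotype_panel(cbind(x, y), data.frame(id = c("a", "b"), chrom = "1",
                                               pos_bp = c(0, 1000)))
  expect_equal(estimate_dprime_ci(p, 1, 2)$dprime, 0.6)
  # random panels vs oracle
  set.seed(7)
  for (rep in 1:20) {
    q <- random_panel(H = 40, S = 2)
    expect_equal(estimate_dprime_ci(q, 1, 2)$dprime,
                 oracle_dprime(q$alleles[, 1], q$alleles[, 2]),
                 tolerance = 1e-12)
  }
})

test_that("independent loci at large H are classified recombination", {
  set.seed(91)
  hits <- 0L
  n_rep <- 200
  for (rep in seq_len(n_rep)) {
    x <- rbinom(2000, 1L, 0.5); y <- rbinom(2000, 1L, 0.5)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    p <- haplotype_panel(cbind(x, y), data.frame(id = c("a", "b"),
                                                 chrom = "1",
                                                 pos_bp = c(0, 1000)))
    if (estimate_dprime_ci(p, 1, 2)$classification == "recombination") {
      hits <- hits + 1L
    }
  }
  expect_gt(hits / n_rep, 0.9)   # large majority of independent pairs
})

test_that("monomorphic columns are refused", {
  a <- cbind(rep(0L, 10), rbinom(10, 1, 0.5))
  a[1, 2] <- 1L; a[2, 2] <- 0L
  p <- haplotype_panel(a, data.frame(id = c("a", "b"), chrom = "1",
                                     pos_bp = c(0, 1000)))
  expect_error(estimate_dprime_ci(p, 1, 2), "monomorphic")
})

test_that("a run of SNPs in perfect pairwise LD becomes one region", {
  haps <- rbind(rep(1L, 5), rep(0L, 5))
  p <- block_panel(haps, c(60, 40))
  reg <- detect_core_regions(p)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$n_snps, 5)
  expect_equal(reg$snp_start, 1)
  expect_equal(reg$snp_end, 5)
  expect_equal(reg$end_bp - reg$start_bp, 4 * 50000 + 1)
})

test_that("two perfect-LD triplets split by recombination give two regions", {
  set.seed(21)
  # block A: columns 1-3 perfectly correlated; block B: columns 4-6;
  # assignment of A-haplotype to B-haplotype is independent -> the cross
  # pairs show recombination at H = 400
  H <- 400
  a_hap <- rbinom(H, 1, 0.5)
  b_hap <- rbinom(H, 1, 0.5)
  alleles <- cbind(a_hap, a_hap, a_hap, b_hap, b_hap, b_hap)
  p <- haplotype_panel(alleles, data.frame(
    id = paste0("s", 1:6), chrom = "1", pos_bp = (0:5) * 50000,
    pos_cm = (0:5) * 0.05))
  reg <- detect_core_regions(p)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$n_snps, c(3, 3))
  expect_equal(reg$snp_start, c(1, 4))
})

test_that("mutually independent SNPs yield no regions at large H", {
  set.seed(33)
  p <- random_panel(H = 2000, S = 10)
  reg <- detect_core_regions(p)
  expect_equal(nrow(reg), 0)
})

test_that("detection agrees with exhaustive window evaluation on small panels", {
  set.seed(57)
  for (rep in 1:6) {
    # mix of correlated pairs and noise so that some windows qualify
    H <- 60
    base <- rbinom(H, 1, 0.5)
    S <- 8
    alleles <- sapply(seq_len(S), function(j) {
      if (j <= 4) {
        v <- base
        flip <- runif(H) < 0.02
        v[flip] <- 1L - v[flip]
        v
      } else rbinom(H, 1L, 0.5)
    })
    for (j in seq_len(S)) {
      if (length(unique(alleles[, j])) == 1L) {
        alleles[sample(H, 1), j] <- 1L - alleles[1, j]
      }
    }
    p <- haplotype_panel(alleles, data.frame(
      id = paste0("s", seq_len(S)), chrom = "1", pos_bp = (seq_len(S) - 1) * 5e4))
    reg <- detect_core_regions(p)
    orc <- oracle_regions(p)
    expect_equal(nrow(reg), nrow(orc))
    if (nrow(reg) > 0) {
      expect_equal(reg$snp_start, orc$i)
      expect_equal(reg$snp_end, orc$j)
    }
  }
})

test_that("detection is deterministic", {
  set.seed(5)
  p <- random_panel(H = 100, S = 20)
  r1 <- detect_core_regions(p)
  r2 <- detect_core_regions(p)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("core haplotypes tally, sort and partition correctly", {
  # H = 6 copies over a 2-SNP core: {00,00,00,01,01,11}
  alleles <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 0L),
                   c(0L, 1L), c(0L, 1L), c(1L, 1L))
  p <- haplotype_panel(alleles, data.frame(id = c("a", "b"), chrom = "1",
                                           pos_bp = c(0, 1000)))
  h <- enumerate_core_haplotypes(p, list(snp_start = 1, snp_end = 2))
  expect_equal(h$haplotype, c("00", "01", "11"))
  expect_equal(h$frequency, c(1 / 2, 1 / 3, 1 / 6))
  expect_equal(sum(h$frequency), 1)
  expect_setequal(unlist(h$carriers), 1:6)          # partition of all copies

  # all copies identical -> single haplotype at frequency 1
  p1 <- block_panel(matrix(1L, 1, 3), 8)
  h1 <- enumerate_core_haplotypes(p1, list(snp_start = 1, snp_end = 3))
  expect_equal(nrow(h1), 1)
  expect_equal(h1$frequency, 1)
})

test_that("core haplotype frequencies match a brute-force string tally", {
  set.seed(13)
  for (rep in 1:8) {
    p <- random_panel(H = 24, S = 6)
    h <- enumerate_core_haplotypes(p, list(snp_start = 2, snp_end = 5))
    brute <- table(apply(p$alleles[, 2:5], 1, paste, collapse = ""))
    expect_equal(sum(h$count), 24)
    for (r in seq_len(nrow(h))) {
      expect_equal(h$count[r], unname(brute[h$haplotype[r]]))
    }
    # carriers are disjoint and complete
    carr <- unlist(h$carriers)
    expect_equal(sort(carr), 1:24)
  }
})

test_that("region exports are written as BED and haplotype TSV", {
  haps <- rbind(rep(1L, 4), rep(0L, 4))
  p <- block_panel(haps, c(30, 10))
  reg <- detect_core_regions(p)
  bed <- tempfile(fileext = ".bed"); hap <- tempfile(fileext = ".tsv")
  write_core_regions(p, reg, bed, hap)
  b <- read.delim(bed, header = FALSE)
  expect_equal(nrow(b), 1)
  expect_equal(b$V2, 0)
  h <- read.delim(hap)
  expect_equal(sort(h$frequency), c(0.25, 0.75))
})
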