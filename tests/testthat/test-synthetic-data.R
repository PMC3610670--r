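# The mosaic haplotype generator, sweep planting, and synthetic annotation.

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_copies = 40, n_snps = 120, seed = 5)
  p1 <- simulate_neutral_panel(cfg)
  p2 <- simulate_neutral_panel(cfg)
  expect_identical(p1$alleles, p2$alleles)
  expect_identical(p1$snps, p2$snps)
})

test_that("infeasible configs are refused", {
  expect_error(sim_config(n_copies = 3), "n_copies")
  expect_error(sim_config(n_copies = 5), "n_copies")
})

test_that("zero switch rate makes every copy a founder (D' = 1 genome-wide)", {
  cfg <- sim_config(n_copies = 60, n_snps = 40, n_founders = 4,
                    block_hap_range = c(2, 2), switch_rate_per_bp = 0,
                    seed = 9)
  p <- simulate_neutral_panel(cfg)
  p <- suppressMessages(apply_maf_filter(p, 0.05))
  set.seed(1)
  for (rep in 1:15) {
    ij <- sort(sample(n_snps(p), 2))
    r <- estimate_dprime_ci(p, ij[1], ij[2])
    expect_equal(r$dprime, 1, tolerance = 1e-9)
  }
})

test_that("a very high switch rate destroys adjacent-SNP LD", {
  cfg <- sim_config(n_copies = 2000, n_snps = 60, n_founders = 40,
                    switch_rate_per_bp = 1e-3, seed = 10)
  p <- simulate_neutral_panel(cfg)
  p <- suppressMessages(apply_maf_filter(p, 0.05))
  cls <- vapply(seq_len(n_snps(p) - 1), function(i) {
    estimate_dprime_ci(p, i, i + 1)$classification
  }, "")
  # with ~50 expected switches between adjacent markers the copies draw
  # founders independently; founder-pool LD is what remains, so the
  # recombination class dominates
  expect_gt(mean(cls == "recombination"), 0.5)
  expect_lt(mean(cls == "strong_ld"), 0.1)
})

test_that("planted sweep makes exactly floor(f*H) copies identical on tract", {
  cfg <- sim_config(n_copies = 200, n_snps = 500, seed = 3)
  p <- simulate_neutral_panel(cfg)
  sw <- plant_sweep(p, position_bp = cfg$chrom_length_bp / 2,
                    carrier_fraction = 0.4, tract_half_length_cm = 1,
                    seed = 31)
  expect_equal(length(sw$truth$carriers), 80)
  tract <- sw$panel$alleles[sw$truth$carriers, sw$truth$snp_cols]
  expect_true(all(apply(tract, 2, function(col) length(unique(col)) == 1)))
  # untouched outside the carrier set
  non <- setdiff(seq_len(200), sw$truth$carriers)
  expect_identical(sw$panel$alleles[non, ], p$alleles[non, ])
  # EHH of the planted haplotype is 1 throughout the tract
  i <- sw$truth$snp_cols[which.min(abs(sw$panel$snps$pos_bp[sw$truth$snp_cols] -
                                         cfg$chrom_length_bp / 2))]
  reg <- list(region_id = "r", snp_start = i, snp_end = i)
  h <- enumerate_core_haplotypes(sw$panel, reg)
  swept <- which(vapply(h$carriers,
                        function(cr) all(sw$truth$carriers %in% cr), TRUE))
  pr <- ehh_profile(sw$panel, reg, h$haplotype[swept], "downstream",
                    max_distance_cm = 0.9)
  expect_true(all(pr$points$ehh >=
                    (80 * 79 / 2) / (h$count[swept] * (h$count[swept] - 1) / 2) - 1e-12))
})

test_that("sweep tract beyond the chromosome is clamped with a warning", {
  cfg <- sim_config(n_copies = 40, n_snps = 100, seed = 6)
  p <- simulate_neutral_panel(cfg)
  expect_warning(plant_sweep(p, position_bp = 1e5, carrier_fraction = 0.5,
                             tract_half_length_cm = 1), "clamped")
})

test_that("synthetic annotation is deterministic, non-overlapping, packed", {
  a1 <- simulate_annotation(1e8, n_genes = 200, n_terms = 20, seed = 7)
  a2 <- simulate_annotation(1e8, n_genes = 200, n_terms = 20, seed = 7)
  expect_identical(a1$genes, a2$genes)
  expect_identical(a1$term_map$terms, a2$term_map$terms)
  g <- a1$genes
  expect_true(all(g$start_bp[-1] >= g$end_bp[-nrow(g)]))   # non-overlapping
  expect_error(simulate_annotation(1e6, n_genes = 200, gene_length_bp = 2e4),
               "packing")
})

test_that("a strongly multiplied planted term tops the enrichment ranking", {
  target <- data.frame(start_bp = 4e7, end_bp = 6e7)
  ann <- simulate_annotation(1e8, n_genes = 600, n_terms = 30,
                             enriched = list(intervals = target,
                                             multiplier = 20), seed = 15)
  study <- map_genes(data.frame(region_id = "r", chrom = "1",
                                start_bp = 4e7, end_bp = 6e7), ann$genes)
  res <- hypergeometric_enrichment(study, ann$genes$gene_id, ann$term_map)
  expect_identical(res$term_id[1], ann$truth$term_id)
})

test_that("a unit multiplier behaves like the null (ratio near 1)", {
  target <- data.frame(start_bp = 2e7, end_bp = 8e7)
  set.seed(1)
  ratios <- vapply(1:10, function(s) {
    ann <- simulate_annotation(1e8, n_genes = 500, n_terms = 5,
                               enriched = list(intervals = target,
                                               multiplier = 1), seed = s)
    study <- map_genes(data.frame(region_id = "r", chrom = "1",
                                  start_bp = 2e7, end_bp = 8e7), ann$genes)
    res <- hypergeometric_enrichment(study, ann$genes$gene_id, ann$term_map,
                                     min_study_hits = 0)
    res$ratio[res$term_id == ann$truth$term_id]
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("truth JSON round-trips through jsonlite", {
  cfg <- sim_config(n_copies = 40, n_snps = 100, seed = 2)
  p <- simulate_neutral_panel(cfg)
  sw <- plant_sweep(p, 2.5e6, 0.5, 0.5, seed = 4)
  f <- tempfile(fileext = ".json")
  write_truth_json(sw$truth, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$carriers, sw$truth$carriers)
  expect_equal(back$start_bp, sw$truth$start_bp)
})

test_that("default conditions reproduce chip-scale structure after QC", {
  cfg <- sim_config(seed = 1)
  pan <- suppressMessages(apply_maf_filter(simulate_neutral_panel(cfg)))
  spacing_kb <- diff(range(pan$snps$pos_bp)) / (n_snps(pan) - 1) / 1000
  expect_gt(spacing_kb, 45)            # medium-density chip spacing band
  expect_lt(spacing_kb, 70)
  reg <- detect_core_regions(pan)
  expect_gt(nrow(reg), 50)
  expect_equal(min(reg$n_snps), 3)
  expect_lte(max(reg$n_snps), 12)      # core sizes at the reported scale
  f <- unlist(lapply(seq_len(nrow(reg)), function(r) {
    enumerate_core_haplotypes(pan, reg[r, ])$frequency
  }))
  f <- f[f >= 0.2]
  expect_gt(median(f), 0.25)           # filtered frequencies sit in 0.2-0.7
  expect_lt(median(f), 0.7)
})
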