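#' Default pipeline configuration
#'
#' Assembles the full parameter set of the scan-and-annotate pipeline with
#' the standard defaults: MAF floor 0.03, matched distance 0.5 cM,
#' core-haplotype frequency floor 0.20, significance at 0.05/0.01, and a
#' 1 Mb extension pad for annotation. Values supplied in `...` override the
#' defaults; a YAML file path may be given instead.
#'
#' @param ... named overrides of the defaults listed below.
#' @param yaml optional path to a YAML config whose entries override the
#'   defaults (entries in `...` win over the file).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., yaml = NULL) {
  cfg <- list(
    geno_path = NULL, map_path = NULL, vcf_path = NULL,
    genetic_map = 1.0,                 # cM/Mb rate or map file path
    exclude_chroms = c("X"),
    min_maf = 0.03,
    confidence = 0.90, strong_low = 0.70, strong_high = 0.98,
    recomb_high = 0.90, min_strong_fraction = 0.95, min_core_snps = 3,
    target_cm = 0.5, min_freq = 0.20, bin_width = 0.05,
    p_method = "gaussian_log", min_bin_n = 10, alphas = c(0.05, 0.01),
    pad_bp = 1e6,
    genes_path = NULL, assoc_path = NULL, desc_path = NULL,
    reference_lists = list(),
    simulate = NULL,                   # a sim_config() to generate input
    sweep = NULL,                      # list(position_bp, carrier_fraction,
                                       #      tract_half_length_cm)
    seed = 1
  )
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    cfg[names(y)] <- y
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

# short stable hash of the config for output-file provenance headers
.config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (chunk in split(v, ceiling(seq_along(v) / 1024))) {
    h <- (h * 33 + sum(chunk * seq_along(chunk))) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.provenance <- function(cfg, counts) {
  c(paste0("haploscan ", as.character(utils::packageVersion("haploscan")),
           "; config_hash=", .config_hash(cfg)),
    paste(names(counts), counts, sep = "=", collapse = "; "))
}

#' Run the scan stage of the pipeline
#'
#' Reads (or simulates) the panel, applies QC, detects core regions, runs
#' the EHH/REHH scan, and writes the region BED, per-test TSV and summary
#' TSV to `out_dir`. Every output carries a provenance header (package
#' version, config hash, stage counts); repeated runs with the same config
#' produce identical files. Any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the `ehh_scan` object, the QC'd panel,
#'   and the written paths.
#' @export
run_scan <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  set.seed(config$seed)
  panel <- stage("input", {
    if (!is.null(config$simulate)) {
      p <- simulate_neutral_panel(config$simulate)
      if (!is.null(config$sweep)) {
        sw <- config$sweep
        p <- plant_sweep(p, sw$position_bp, sw$carrier_fraction,
                         sw$tract_half_length_cm)$panel
      }
      p
    } else if (!is.null(config$vcf_path)) {
      read_phased_vcf(config$vcf_path)
    } else if (!is.null(config$geno_path)) {
      read_haplotype_table(config$geno_path, config$map_path)
    } else stop("no input configured (simulate, vcf_path or geno_path)")
  })
  panel <- stage("qc", {
    p <- exclude_chromosomes(panel, config$exclude_chroms)
    p <- apply_maf_filter(p, min_maf = config$min_maf)
    if (n_snps(p) == 0) stop("QC removed every SNP")
    p
  })
  panel <- stage("genetic_map", {
    if (all(is.na(panel$snps$pos_cm))) {
      attach_genetic_map(panel, config$genetic_map)
    } else panel
  })
  scan <- stage("scan", {
    ehh_scan(panel, target_cm = config$target_cm,
             min_freq = config$min_freq, bin_width = config$bin_width,
             p_method = config$p_method, min_bin_n = config$min_bin_n,
             alphas = config$alphas, confidence = config$confidence,
             strong_low = config$strong_low,
             strong_high = config$strong_high,
             recomb_high = config$recomb_high,
             min_strong_fraction = config$min_strong_fraction,
             min_core_snps = config$min_core_snps)
  })
  counts <- c(n_snps = n_snps(panel), n_regions = nrow(scan$regions),
              n_tests = nrow(scan$tests_all),
              n_tests_filtered = nrow(scan$tests),
              dropped_edge = unname(scan$dropped["edge"]),
              dropped_undefined = unname(scan$dropped["zero_others"]),
              dropped_low_freq = unname(scan$dropped["low_frequency"]))
  hdr <- .provenance(config, counts)
  paths <- list(
    regions_bed = file.path(out_dir, "regions.bed"),
    tests_tsv = file.path(out_dir, "tests.tsv"),
    summary_tsv = file.path(out_dir, "summary.tsv"),
    config_yaml = file.path(out_dir, "config.yaml")
  )
  write_core_regions(panel, scan$regions, bed_path = paths$regions_bed)
  write_scan_tests(scan, paths$tests_tsv, header = hdr)
  sm <- summarize_scan(panel, scan$regions, scan$tests, config$alphas)
  con <- file(paths$summary_tsv, "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(as.data.frame(sm), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)],
                   paths$config_yaml)
  invisible(list(scan = scan, panel = panel, paths = paths, counts = counts))
}

#' Run the annotation/enrichment stage of the pipeline
#'
#' Extends significant regions, maps genes into them, performs the
#' hypergeometric term enrichment against the full annotation as the
#' background universe, and (when reference gene lists are configured)
#' writes gene-list overlap reports.
#'
#' @param config a [pipeline_config()].
#' @param scan_result the list returned by [run_scan()].
#' @param out_dir output directory.
#' @param genes,term_map optional in-memory annotation objects overriding
#'   the config paths (useful with [simulate_annotation()]).
#' @param alpha significance level selecting the regions to annotate.
#' @return invisibly, a list with the enrichment table, the study gene set
#'   and the written paths.
#' @export
run_enrichment <- function(config, scan_result, out_dir, genes = NULL,
                           term_map = NULL, alpha = 0.05) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(genes)) {
    if (is.null(config$genes_path)) stop("no gene annotation configured")
    genes <- read_genes(config$genes_path)
  }
  if (is.null(term_map)) {
    if (is.null(config$assoc_path)) stop("no term associations configured")
    term_map <- read_term_map(config$assoc_path, config$desc_path)
  }
  panel <- scan_result$panel
  sig <- significant_regions(scan_result$scan, alpha = alpha)
  chrom_lengths <- tapply(panel$snps$pos_bp, panel$snps$chrom, max) + 1
  enr_path <- file.path(out_dir, "enrichment.tsv")
  if (nrow(sig) == 0) {
    writeLines(c("# no significant regions at this level",
                 paste("term_id", "description", "pop_frec", "cr_frec",
                       "ratio", "p_bonferroni", sep = "\t")), enr_path)
    return(invisible(list(enrichment = NULL, study = character(0),
                          paths = list(enrichment_tsv = enr_path))))
  }
  ext <- extend_regions(sig, chrom_lengths, pad_bp = config$pad_bp)
  study <- map_genes(ext, genes)
  enr <- hypergeometric_enrichment(study, genes$gene_id, term_map)
  out <- data.frame(
    term_id = enr$term_id, description = enr$description,
    pop_frec = paste0(enr$pop_count, "/", enr$pop_total),
    cr_frec = paste0(enr$study_count, "/", enr$study_total),
    ratio = round(enr$ratio, 2),
    p_bonferroni = signif(enr$p_bonferroni, 3),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, enr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- list(enrichment_tsv = enr_path)
  for (nm in names(config$reference_lists)) {
    ref <- config$reference_lists[[nm]]
    if (is.character(ref) && length(ref) == 1 && file.exists(ref)) {
      ref <- readLines(ref)
    }
    ov <- intersect_gene_lists(study, ref)
    if (ov$n_overlap == 0 && ov$n_reference > 0) {
      warning("no identifier overlap with reference list '", nm,
              "' (namespace mismatch?)")
    }
    p <- file.path(out_dir, paste0("overlap_", nm, ".tsv"))
    utils::write.table(
      data.frame(n_study = ov$n_study, n_reference = ov$n_reference,
                 n_overlap = ov$n_overlap,
                 pct_of_reference = round(ov$pct_of_reference, 2),
                 pct_of_study = round(ov$pct_of_study, 2)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("overlap_", nm)]] <- p
  }
  invisible(list(enrichment = enr, study = study, extended = ext,
                 paths = paths))
}
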