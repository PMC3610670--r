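# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (pair-by-pair enumeration, direct algebra)
# and never share code with the implementation paths they check.

# random small phased panel with a genetic map at 1 cM/Mb
random_panel <- function(H = 20, S = 12, spacing_bp = 50000, maf = NULL) {
  p <- if (is.null(maf)) runif(S, 0.1, 0.9) else rep(maf, S)
  alleles <- matrix(rbinom(H * S, 1L, rep(p, each = H)), nrow = H)
  # guard against monomorphic columns
  for (j in seq_len(S)) {
    if (length(unique(alleles[, j])) == 1L) {
      alleles[sample(H, 1), j] <- 1L - alleles[1, j]
    }
  }
  pos <- cumsum(rep(spacing_bp, S)) - spacing_bp
  haplotype_panel(alleles, data.frame(
    id = paste0("s", seq_len(S)), chrom = "1", pos_bp = pos,
    pos_cm = pos / 1e6, stringsAsFactors = FALSE
  ))
}

# panel in which every copy is one of `k` fixed haplotypes -> perfect LD runs
block_panel <- function(haps, counts) {
  alleles <- haps[rep(seq_along(counts), counts), , drop = FALSE]
  S <- ncol(haps)
  pos <- (seq_len(S) - 1) * 50000
  haplotype_panel(alleles, data.frame(
    id = paste0("s", seq_len(S)), chrom = "1", pos_bp = pos,
    pos_cm = pos / 1e6, stringsAsFactors = FALSE
  ))
}

# ---- oracles ----

# two-locus |D'| by direct algebra on phased counts
oracle_dprime <- function(x, y) {
  pA <- mean(x); pB <- mean(y)
  D <- mean(x == 1 & y == 1) - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  abs(D) / dmax
}

# EHH by pair-by-pair identity enumeration over an interval of columns
oracle_ehh_pairwise <- function(alleles, carriers, cols) {
  c <- length(carriers)
  if (c < 2) return(NA_real_)
  ident <- 0L
  for (a in seq_len(c - 1)) {
    for (b in seq.int(a + 1, c)) {
      if (length(cols) == 0 ||
          all(alleles[carriers[a], cols] == alleles[carriers[b], cols])) {
        ident <- ident + 1L
      }
    }
  }
  ident / (c * (c - 1) / 2)
}

# pooled-others EHH oracle: pairs must share the core haplotype AND the
# extension; enumerated pair by pair over core + extension columns
oracle_ehh_others <- function(alleles, others, core_cols, ext_cols) {
  oracle_ehh_pairwise(alleles, others, c(core_cols, ext_cols))
}

# hypergeometric upper tail by explicit combinatorial summation
oracle_hyper_tail <- function(N, K, n, k) {
  kk <- k:min(n, K)
  kk <- kk[kk >= max(0, n - (N - K))]
  if (length(kk) == 0) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# exhaustive core-region finder on tiny panels: evaluates every contiguous
# window under the same pair-classification rule, then the same greedy pick
oracle_regions <- function(panel, min_core_snps = 3, min_strong_fraction = 0.95) {
  S <- n_snps(panel)
  cls <- matrix(NA_character_, S, S)
  for (i in seq_len(S - 1)) {
    for (j in seq.int(i + 1, S)) {
      cls[i, j] <- estimate_dprime_ci(panel, i, j)$classification
    }
  }
  wins <- list()
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (j - i + 1 < min_core_snps) next
      sub <- cls[i:j, i:j]
      v <- sub[upper.tri(sub)]
      ninf <- sum(v %in% c("strong_ld", "recombination"))
      if (ninf == 0) next
      if (sum(v == "strong_ld") >= min_strong_fraction * ninf - 1e-9) {
        wins[[length(wins) + 1]] <- c(i = i, j = j)
      }
    }
  }
  if (length(wins) == 0) return(data.frame(i = integer(0), j = integer(0)))
  w <- as.data.frame(do.call(rbind, wins))
  w$len <- w$j - w$i + 1
  w <- w[order(-w$len, w$i), ]
  covered <- logical(S); keep <- logical(nrow(w))
  for (r in seq_len(nrow(w))) {
    if (!any(covered[w$i[r]:w$j[r]])) {
      covered[w$i[r]:w$j[r]] <- TRUE
      keep[r] <- TRUE
    }
  }
  out <- w[keep, c("i", "j")]
  out[order(out$i), , drop = FALSE]
}

# path of extension columns used by a profile, matching the distance origin
# (outermost core SNP in the tested direction)
ext_cols <- function(panel, region, direction, upto) {
  if (direction == "downstream") {
    cols <- seq_len(n_snps(panel))
    cols <- cols[cols > region$snp_end]
  } else {
    cols <- rev(seq_len(n_snps(panel))[seq_len(n_snps(panel)) < region$snp_start])
  }
  head(cols, upto)
}
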