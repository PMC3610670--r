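---
title: "Detecting selective sweeps with EHH and REHH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps with EHH and REHH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploscan)
```

## The model

Recent positive selection drives a beneficial allele — and the haplotype it
sits on — to high frequency faster than recombination can break that
haplotype apart. The resulting footprint is a haplotype that is both
*common* and *unusually long-range homozygous*. `haploscan` detects this
footprint in phased biallelic SNP panels in four stages.

**Core regions.** A core region is a contiguous run of SNPs in strong
mutual linkage disequilibrium, within which historical recombination has
been rare. We classify each SNP pair by the confidence interval of its
|D′|: with phased data the two-locus haplotype counts are observed, so the
profile likelihood of |D′| (allele frequencies held at their MLEs) is
evaluated on a grid, normalized, and the central interval at 90% confidence
read off. A pair is *strong LD* when the lower bound reaches 0.70 and the
upper bound 0.98; it shows *strong evidence of recombination* when the
upper bound is below 0.90; otherwise it is uninformative. A run of SNPs
qualifies as a core region when at least 95% of its informative pairs are
strong-LD (uninformative pairs are excluded from the denominator — the
choice had to be made and exclusion is documented here and in the
configuration help). Candidate runs are assembled greedily, longest first,
ties to the leftmost start, into a non-overlapping set. All five thresholds
are exposed as arguments; the defaults are the published block-partition
convention, and observed cores of 3–12 SNPs provide a sanity envelope.

**EHH.** For a core haplotype carried by $c$ chromosome copies, the
extended haplotype homozygosity at a marker is the probability that two
randomly chosen carriers are identical over the whole interval from the
core edge to that marker:

$$\mathrm{EHH} = \frac{\sum_i \binom{e_i}{2}}{\binom{c}{2}},$$

where the $e_i$ are the sizes of the identity groups among the carriers at
that extent. The profile starts at 1 at the core edge and can only
decrease, because groups only split as the interval grows. Genetic distance
is measured from the outermost core SNP in the tested direction, and each
core haplotype is tested in both directions independently.

**REHH.** Raw EHH confounds selection with locally low recombination. The
relative EHH divides the tested haplotype's EHH by the pooled EHH of all
*other* core haplotypes of the same region at the same matched genetic
distance (default 0.5 cM — appropriate for the long-range LD of livestock;
human-scale panels would use a shorter distance). The pooled statistic is
the homozygosity over all non-tested copies with identity groups seeded by
their own core haplotype, so groups never merge across core haplotypes.
EHH between bracketing markers is linearly interpolated (a step-function
alternative would systematically favor the marker before the target; linear
is the minimal assumption). Three degenerate cases are flagged and dropped
rather than coerced to numbers: singleton haplotypes (EHH undefined),
frequency-1 haplotypes (no "others"; REHH must never be reported as
infinite), and profiles that hit the chromosome end while still positive
(the matched distance cannot be evaluated). Drop counts are kept in the
scan object so the test bookkeeping is auditable.

**Significance.** REHH grows with haplotype frequency, so tests are only
comparable within frequency strata. After discarding core haplotypes with
frequency strictly below 0.20 (the boundary is kept — the discard rule is a
strict "below"), tests are binned by frequency in bins of width 0.05 over
[0.20, 1]; bins with fewer than 10 tests merge with the nearest bin by
center distance, ties to the lower bin. Within each bin the default method
fits a normal distribution to ln(REHH) and takes the upper tail; a
zero-variance bin falls back to the assumption-free empirical rank, as can
the whole scan (`p_method = "empirical_rank"`). Significance calls use
strict inequalities (`p < alpha`), and a region is significant when any of
its tests is. No multiple-testing correction is applied across the scan by
default, matching the conventional reporting of raw significant-test counts
at 0.05 and 0.01 in this literature.

The distributional step deserves honesty: published scans of this design
name the software used but not how p-values were derived from REHH. The
frequency-binned Gaussian fit to ln(REHH) is the convention of the EHH
literature and reproduces the familiar frequency-stratified scatter; the
empirical-rank alternative makes no distributional assumption at all. On
simulated neutral panels with log-normal REHH the Gaussian method is
calibrated to the nominal level within Monte-Carlo error (this is asserted
by a test at 3000 tests).

## Annotation and enrichment

Each significant core region is extended by 1 Mb on both sides (clamped to
the chromosome), overlapping extended regions are merged so genes are
counted once, and a gene is mapped into the region set when its interval
overlaps by at least one base pair — the most permissive rule consistent
with counting genes "involved in" regions; coordinates are 0-based
half-open throughout, so an abutting gene does not count. Term enrichment
is the hypergeometric upper tail $P(X \ge k)$ for $k$ study genes of a term
with $K$ background genes, drawn $n$ from a universe of $N$; the reported
ratio is $(k/n)/(K/N)$ and the Bonferroni multiplier is the number of terms
actually tested (those with at least one study gene), configurable to all
terms. The background universe is always an explicit input — the full gene
list of the supplied annotation — never a baked-in constant. The package
does not embed the GO hierarchy: second-level-term analyses are realized by
supplying the term subset of interest, and ontology-graph traversal is out
of scope.

## The synthetic study conditions

No genotypes ship with the package; every pipeline stage is exercised
against a generator whose defaults emulate a medium-density livestock
panel: 400 chromosome copies, 2000 markers at a mean spacing of 50 kb (one
100 Mb chromosome), a constant genetic map of 1 cM/Mb (the cattle
convention), and a MAF floor of 0.03 applied after simulation. LD has two
layers. Founder haplotypes are concatenations of ancestral blocks (mean
extent 250 kb) that each carry only 3–6 distinct block haplotypes with
balanced (Dirichlet shape 2) usage among 60 founders — within-block
diversity of a handful of haplotypes is what medium-density panels show in
commercial dairy populations, whose effective population size is of order
100. Each chromosome copy is then a Poisson mosaic of founders with a
switch rate of 2e-6 per bp (mean identity-by-descent tract 500 kb), which
makes LD decay with distance. Under these defaults the post-filter marker
spacing is ~57 kb, detected cores span 3–12 SNPs, and filtered
core-haplotype frequencies concentrate in 0.2–0.7 — the structure reported
by chip-based cattle scans.

A sweep is planted as a hard identical tract: a random carrier set
(fraction 0.4 by default) has its alleles replaced by one template
haplotype over ±1 cM around the sweep position. This creates exactly the
statistical signature the scan targets with controllable truth, at the cost
of realism in what it does *not* model: no demography, no mutation, no
soft sweeps, no ascertainment bias, and the tract boundary is sharp rather
than recombination-eroded. Passing the recovery study therefore shows the
pipeline finds the idealized footprint reliably; it does not certify power
on real data, where signals are weaker and confounded.

Two study-condition properties are asserted by the validation suite, each
over 20 fixed-seed replicates: the top-REHH significant region overlaps
the planted tract in at least 18 replicates, and with no sweep planted the
genome-wide top-REHH region overlaps a fixed mid-chromosome 2 Mb window in
at most 2. The same study is recomputed by `scripts/acceptance.R`.

The annotation generator places non-overlapping genes one per equal-width
slot and assigns terms at random, except one designated term whose genes
are drawn with multiplied odds inside target intervals; at multiplier 1 it
is exactly null, and at multiplier ≥ 5 the planted term should top the
enrichment ranking.

## Numerical and design choices

- **Coordinates** are 0-based half-open internally; VCF positions (1-based)
  and BED intervals are converted at the boundary.
- **Missing data are refused**, not imputed: phasing/imputation is upstream
  of this package, and silently imputed alleles would corrupt EHH.
- **The |D′| CI grid** has step 0.005; the CI bounds are therefore
  quantized at that resolution, which is an order of magnitude finer than
  the classification thresholds they are compared against.
- **Monomorphic sites** are an error in pair classification (they should
  have been removed by the MAF filter, whose removal rule is a strict
  "below the floor", so a SNP at exactly 0.03 is retained). MAF is computed
  from integer allele counts to avoid floating-point boundary artifacts.
- **Interpolation at the matched distance** keeps, at duplicated map
  positions, the last (smallest-EHH) point, making the profile a function
  of distance before interpolating.
- **Determinism**: core-region detection and the scan contain no
  randomness; the simulators draw everything from a single configured seed;
  reruns of the pipeline produce byte-identical outputs.
- **Problem sizes** used by the validation suite — 200 oracle panels,
  10,000 profile checks, exhaustive hypergeometric enumeration to universe
  25, and 20+20 recovery replicates at the default 400 × 2000 conditions —
  were chosen to exercise every code path at desk scale.

## Known limitations

- The scan statistic is REHH only; integrated-EHH statistics (iHS),
  cross-population comparisons (XP-EHH, F~ST~) and composite-likelihood
  combinations are out of scope.
- The generator's hard-tract sweep is an idealization (see above).
- Region detection assembles blocks greedily; a dynamic-programming
  partition could differ on ties, though the exhaustive-window oracle test
  shows agreement on small panels.
- With very small "others" pools (core haplotypes near frequency 1), REHH
  is numerically unstable; such tests are legitimate per the definition but
  their heavy tail is the main source of neutral false positives.
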