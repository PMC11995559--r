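---
title: "Methods: ac4C epitranscriptome analysis with acripseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ac4C epitranscriptome analysis with acripseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acripseq)
```

## The measurement problem

acRIP-seq profiles N4-acetylcytidine (ac4C) on mRNA by immunoprecipitating
fragmented RNA with an anti-ac4C antibody and sequencing the pulled-down
fragments alongside two controls: the *input* (fragmented RNA before
pulldown, measuring abundance) and an *IgG* pulldown (measuring
non-specific antibody/bead binding). A region is evidence of acetylation
only if its acRIP coverage exceeds what abundance predicts **and** the
excess is not explained by non-specific binding. `acripseq` operationalises
this for two-group, replicated designs and reconciles the resulting
per-mRNA acetylation estimates with matched proteomics and RNA-seq.

## Peak detection: a window-Poisson scan

Coverage is represented as counts in fixed-width windows (default 50 bp)
rather than reads. For each window of each sample the IP count is tested
against the null mean

$$\lambda = \max\!\big(\text{input} \times N_{IP}/N_{input},\;
\lambda_{floor}\big),$$

with the upper-tail Poisson probability $P(X \ge \text{ip})$, followed by
Benjamini–Hochberg adjustment across all windows of that sample.
Significant windows ($q < q_{max}$) merge into peaks when separated by at
most `merge_gap` non-significant windows; peaks spanning fewer than
`min_windows` windows are dropped; the summit is the window of minimal
p-value (leftmost on ties). A chromosome blacklist (default `chrM`) is
applied before testing, mirroring the usual exclusion of mitochondrial
alignments.

This scan is a deliberately simple, fully specified stand-in for read-level
peak callers: no read-shift model and no local-lambda background exist in
window space. Its known limitation is anti-conservatism when window counts
are strongly overdispersed relative to Poisson — the plug-in $\lambda$
ignores input sampling noise, so with variance far above the mean the
false-window rate exceeds the nominal FDR. The synthetic generator
therefore simulates mildly overdispersed counts (see below), the regime the
scan models; real data with strong biological overdispersion would need
larger `min_windows`/`q_max` margins, which is exactly what the downstream
FE, IgG and replicate-consensus filters provide.

## The reliability filter chain

Retained acRIP peaks must, in this order (the filters are pure predicates,
so the final set is order-independent; the test suite asserts this by
permutation):

1. **Significance and enrichment:** peak $q < 0.05$ and fold enrichment
   $FE = (\text{acRIP} - \text{IgG})/\text{Input} > 1$, computed on
   depth-normalised (counts-per-million) mean coverage over the peak, with
   the input floored at `input_floor` (default 0.5 CPM) so a zero-input
   window cannot divide by zero.
2. **Protein-coding exons:** at least 50 % of the peak's length overlaps
   the exons of a protein-coding transcript (`exon_overlap_frac`; the
   fraction is a package choice — interval overlap is the natural
   symmetric, testable operationalisation). The host transcript is the one
   with maximal exonic overlap, ties broken to the lexicographically
   smallest id; the region class (5'UTR/CDS/3'UTR) comes from the summit
   window's position within the host's segments, falling back to
   whole-peak overlap if the summit touches no segment.
3. **IgG calibration:** any coordinate overlap (≥ 1 bp, half-open
   intervals, strand ignored) with a same-sample IgG peak removes the
   acRIP peak.
4. **Replicate consensus:** per group, per-sample peaks are clustered by
   single-linkage coordinate overlap; clusters supported by fewer than
   `consensus_min = 2` distinct replicates are dropped. The consensus
   interval is the union; the group FE is the **arithmetic mean** of the
   contributing sample FEs. Averaging (rather than pooling reads or
   summing) keeps the group FE invariant to the number of contributing
   replicates — a genuinely open design point, flagged here because a
   pooled recomputation would differ.
5. **RNA-seq validation:** the host gene must be detected by RNA-seq in
   that group (raw count > 1 in ≥ 2 replicates).

## Per-mRNA statistics

Multiple peaks can sit on one mRNA, so the mRNA-level fold enrichment is
the sum over its consensus peaks, $FE_{mRNA} = \sum_i FE_{peak_i}$ (a
single peak contributes its FE directly), and the acetylation fold change
uses a pseudocount to survive group-exclusive detection:

$$FC = \frac{FE_{case} + 1}{FE_{ref} + 1},$$

with $FE = 0$ for an undetected group. A case-exclusive mRNA therefore has
$FC = FE_{case} + 1$; since every retained peak has $FE > 1$, exclusives
always clear the $FC \ge 2$ gate, which is what makes the composition
arithmetic of the exclusive classes exact.

## Differential calling

* **Overlay features** (quantified in both groups) are tested with an
  empirical-Bayes moderated t. Per-feature pooled variances $s^2$ on
  $df = n_1 + n_2 - 2$ degrees of freedom are shrunk toward a prior
  estimated by moment matching on the log scale: with
  $e_i = \log s_i^2 - \psi(df/2) + \log(df/2)$, the prior df solves
  $\psi'(d_0/2) = \mathrm{var}(e) - \psi'(df/2)$ (Newton inversion of the
  trigamma function, relative tolerance $10^{-12}$) and
  $s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. When the observed
  log-variances are no more dispersed than sampling noise the prior df is
  infinite and all posterior variances equal $s_0^2$. The moderated t uses
  $d_0 + df$ degrees of freedom and BH adjustment. This is authored in the
  package; the test suite checks it against an independent transcription
  of the closed forms (bisection instead of Newton) to $10^{-10}$ and
  against limma as an external cross-check.
* **Decision rules per layer:** proteins and ac4C mRNAs are `up` when
  adj. p < 0.05 and $FC \ge 2$, `down` when adj. p < 0.05 and
  $FC \le 0.5$ (the symmetric mirror of the 2-fold gate). Group-exclusive
  proteins are differential by assumption (direction from which group
  detects them); group-exclusive ac4C mRNAs additionally need the FC gate.
  Features with any missing value are routed off the overlay test onto the
  exclusive path — missingness means "not detected", never zero.
* **RNA-seq** uses an exact conditional test: given the two groups' summed
  counts $c_1 + c_2 = n$ and library sizes $N_1, N_2$, $c_1$ is binomial
  with $\pi_0 = N_1/(N_1+N_2)$ under the null; the two-sided p sums all
  outcome probabilities no larger than the observed one. This is a
  Poisson-conditional simplification of dispersion-aware count tests,
  chosen because the RNA layer's role here is detection/validation and a
  near-null differential screen; normalisation is total-count scaling, not
  TMM. The exact construction guarantees size ≤ nominal for every total
  (asserted exhaustively for totals ≤ 30). Whether the RNA gate uses
  adjusted or raw p is configurable (`rna_use_adjusted`, default `TRUE`).
* The ac4C overlay test runs on $\log_2(FE + 1)$ of **per-replicate** gene
  FEs (the sum of that replicate's calibrated peak FEs, 0 when the
  replicate has none). This is the vignette's most interpretive decision:
  group-level FEs alone admit no within-group variance estimate, so the
  replicate-level sums are the only quantities a moderated test can use.

## Integration layer

Detection Venn classes per layer ("AD absent" = reference-only, "Overlay",
"AD unique" = case-only) partition the detection union. The protein × ac4C
cross-classification indexes the nine verdict pairs with an explicit
lookup fixing group 1 = up/up and group 7 = down/down (the two named
classes); "differential at both levels" counts pairs with both verdicts
non-`ns`. Distribution comparisons use the two-sample Kolmogorov–Smirnov
test (asymptotic p); 2×2 association uses the Yates-corrected χ² (cells
with $|O - E| < 0.5$ contribute zero) and the φ coefficient, with
$|\varphi| < 0.3$ annotated "low relevance". PCA first drops features with
variance ≤ 1 (a proteomics-scale floor; disable with 0), keeps the top
half by median absolute deviation (ties at the cutoff kept), centres, and
decomposes by SVD. The log₁₀ FE histogram (bin width 0.1) is fitted with
$a\,e^{-(x-\mu)^2/2\sigma^2}$ by Levenberg–Marquardt least squares; the
area $a\sigma\sqrt{2\pi}$ summarises total peak mass, and a constant input
(undefined σ) is an error rather than a silent degenerate fit. Stage
specificity across two timepoints is the fraction of timepoint-1 calls not
reproduced (same direction) at timepoint 2.

## The synthetic generator

`sim_config()` fixes the study conditions: two groups × three biological
replicates; one toy chromosome of non-overlapping gene models
(5'UTR/CDS/3'UTR in exonic space, alternating strands, all coordinates
window-aligned so region classification is unambiguous); negative-binomial
background coverage (mean 20 reads/window, dispersion 0.01 — variance/mean
≈ 1.2, i.e. the mild overdispersion regime the Poisson scan models);
planted enrichment peaks (8× by default) inside CDS-interior exons, a
configurable fraction group-exclusive; "sticky" windows enriched in *both*
the IgG and acRIP assays (rate 2 %), so IgG calibration has real work to
do — these are placed far enough from planted peaks that gap-bridging
cannot merge the two, keeping truth labels unambiguous; RNA counts around
log-normal gene means with an almost-null group effect (0.5 % of genes);
and log-normal protein intensities (replicate SD 0.3 on the log₂ scale)
with planted ±2 log₂-fold changes on 10 % of overlay proteins and
group-exclusive missingness on 20 %. A single seeded stream with a
documented draw order (annotation → peak placement → sticky placement →
counts by assay/group/replicate) makes a fixed configuration byte-identical
across runs; intensities are rounded to 6 decimals for stable output.

What the generator does **not** emulate: read-level artefacts (alignment,
duplicates, fragment-length effects), batch effects, expression-dependent
coverage of the input, isoform complexity, and strong biological
overdispersion. Passing recovery tests therefore demonstrate the
correctness and power of the statistical chain under its own model, not
performance on real libraries.

## Numerical choices and degenerate inputs

* `lambda_floor = 0.5` prevents zero-mean Poisson nulls; `input_floor =
  0.5` CPM prevents division by zero in FE.
* Ties: summit → leftmost window; host transcript → smallest id; region
  class → 5'UTR < CDS < 3'UTR order; MAD cutoff → ties kept.
* All internal coordinates are 0-based half-open; only GTF I/O converts
  (losslessly). Overlap anywhere means ≥ 1 bp.
* Degenerate inputs error loudly with the offending field or sample named:
  zero-total TPM samples, all-missing FOT samples, p-values outside
  (0, 1], zero-margin 2×2 tables, constant FE vectors, annotations whose
  CDS escapes its exons.
* Exactly-constant features in the moderated test get their variance
  floored at $10^{-12}$ rather than producing NaN statistics.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
desk scale, the package's chosen validation sizes: 40–120 genes
(~1,000–2,200 windows) for pipeline runs, 2,000 features for null
calibration of the moderated t, exhaustive enumeration for the exact count
test (totals ≤ 30), 100 shuffles for the window-scan false-call bound, and
five seeds × 80 genes for parameter recovery. The composition checks of
the classification layer are exact arithmetic on planted detection
patterns and run in milliseconds at their real sizes (thousands of
features).

## Known limitations

The window scan inherits plug-in-λ anti-conservatism under strong
overdispersion; the exact RNA test ignores biological dispersion (it is a
validation screen here, not the package's contribution); the consensus
group FE averages rather than pools; single-nucleotide resolution of
acetylation sites, motif analysis, isoform-level quantification and
enrichment against external pathway databases are out of scope.
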