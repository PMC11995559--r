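# acripseq

Multi-omics analysis of N4-acetylcytidine (ac4C) mRNA modification from
acRIP-seq, with matched label-free proteomics and RNA-seq layers.

ac4C is the only known acetylation mark on eukaryotic RNA; it stabilises
mRNAs and promotes their translation, so shifts in ac4C can change protein
output without any change in mRNA abundance. Detecting such shifts requires
comparing immunoprecipitated (acRIP) coverage against both an input control
and a non-specific IgG control, and then reconciling the resulting per-mRNA
acetylation estimates with protein and transcript abundance. `acripseq`
implements that whole chain for two-group designs (e.g. a disease model
versus wild-type littermates, three biological replicates each), plus a
seeded synthetic-data generator with planted ground truth so every stage can
be validated end to end without any external data.

## The statistics at the core

* **Window enrichment scan.** Coverage is represented as fixed-width window
  counts. For each window, the IP count is tested against
  λ = max(input × N<sub>IP</sub>/N<sub>input</sub>, λ<sub>floor</sub>) with an
  upper-tail Poisson probability, BH-adjusted per sample; adjacent
  significant windows merge into per-sample peaks.
* **Per-peak fold enrichment.** FE = (acRIP − IgG) / Input, on
  depth-normalised coverage over the peak. Peaks are kept when
  adj. p < 0.05 and FE > 1, lie on protein-coding exons (≥ 50 % of their
  length), do not overlap any same-sample IgG peak, recur in ≥ 2 of 3
  replicates, and sit on an mRNA detected by RNA-seq.
* **Per-mRNA FE and FC.** FE(mRNA) = Σ FE(peak<sub>i</sub>) over the mRNA's
  consensus peaks, and the pseudocounted fold change
  FC = (FE<sub>case</sub> + 1) / (FE<sub>ref</sub> + 1), so mRNAs acetylated
  in only one group still get a finite FC.
* **Moderated differential testing.** An empirical-Bayes moderated t
  (Smyth-style variance shrinkage: prior (d₀, s₀²) by moment matching on
  log s², posterior variance (d₀s₀² + df·s²)/(d₀ + df)) for features
  quantified in both groups; exclusive-detection rules for the rest
  (group-exclusive proteins are differential by assumption; group-exclusive
  ac4C mRNAs when FC ≥ 2 or ≤ 0.5). RNA-seq uses an exact conditional
  binomial count test. FOT (fraction-of-total × 10⁶) and TPM
  normalisations feed the protein and RNA layers.
* **Integration.** Detection Venn classes ("AD absent" / "Overlay" /
  "AD unique"), a 3×3 protein × ac4C cross-classification (group 1 =
  up/up, group 7 = down/down), Kolmogorov–Smirnov comparison of FE
  distributions, Yates-corrected χ² and the φ coefficient, MAD-filtered
  PCA, Spearman sample correlation, a Gaussian fit to the log₁₀ FE
  histogram, and stage specificity across timepoints.

## Worked example

```r
library(acripseq)
cfg <- pipeline_config(simulate = sim_config(n_genes = 120, seed = 42))
res <- run_ac4c_pipeline(cfg)
```

```
[simulate] 120 genes, 2162 windows, 36 true peaks
[callpeaks] 323 acRIP peaks, 137 IgG peaks across samples
[filter] 196 peaks pass q < 0.05 and FE > 1
[filter] 196 peaks on protein-coding exons
[filter] 195 peaks after IgG calibration
[consensus] 65 consensus peaks (WT: 34, FAD: 31)
[diffexp] ac4c: 2 up, 5 down of 36 modified mRNAs
[diffexp] protein: 16 up, 18 down of 120 detected
[diffexp] rna: 1 up, 0 down of 120 genes
```

The per-stage counts trace the filter chain: 323 raw per-sample acRIP peaks
reduce to 196 after the significance/FE thresholds, 195 after IgG
calibration, and 65 replicate-consensus peaks on RNA-validated mRNAs (34 in
WT, 31 in the case group). The fitted objects are broom-friendly:

```r
print(res)
#> ac4C multi-omics pipeline result
#>   consensus peaks: 65 | ac4C mRNAs: 36 | proteins: 120 | genes: 120
#>   both-level differential genes: 3

head(tidy(res$fits$protein)[c("feature", "log2fc", "t_mod", "adj_p")], 4)
#>   feature  log2fc  t_mod    adj_p
#> 1 g0001    0.0542  0.215 9.80e- 1
#> 2 g0003   -0.207  -0.822 8.77e- 1
#> 3 g0004   -1.76   -6.99  2.67e-11   # a planted 4-fold decrease, recovered
#> 4 g0005   -0.199  -0.794 8.92e- 1
```

`evaluate_recovery(res)` scores the run against the generator's planted
truth; on this seed every planted peak survives the filter chain
(`peak_sensitivity = 1`) with no false consensus peaks and no false protein
calls. `autoplot()` methods give volcano, FE-histogram and PCA views;
`write_result_bundle()` (or the `outdir` argument) writes a deterministic
TSV/BED/JSON bundle.

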