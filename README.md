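# peakmotifs

Downstream analysis of multi-factor ChIP-seq peak sets for transcriptional
co-activators (YAP/TAZ) that reach DNA only through sequence-specific
partner factors (TEAD, AP-1, STAT3). Starting from called peaks, signal
tracks, genomic sequence, a DHS atlas and an expression/survival cohort,
the package answers, in order:

1. **Where do the factors sit?** Signal smoothing (10 bp Gaussian), summit
   calling, fixed summit ±150 bp windows, TSS-proximity annotation, and
   pairwise summit-distance statistics between factors.
2. **Which motif recruits the co-activator at each site?** PWM scanning
   with *exact* match-p-value score thresholds (dynamic programming over
   discretized scores, p = 1e-4 per window; a peak has a TEAD motif if the
   monomer **or** dimer PWM matches), per-peak best scores, and a class
   label per peak: `AP1_only`, `TEAD_only`, `STAT3_only`, composites, or
   `none`.
3. **Is each motif enriched?** Control DHSs sampled to match the bound
   sites' accessibility Z-score distribution bin-for-bin (iteratively
   replacing any control that touches a target peak), then chi-square
   enrichment and pairwise motif co-occurrence versus those controls.
4. **Which sites prefer one paralog?** A negative-binomial Wald test on
   YAP vs TAZ replicate counts (median-of-ratios normalization,
   method-of-moments dispersion, BH adjustment; specific = |log2FC| > 0 and
   padj < 0.05), confirmed by requiring signal loss only in the matching
   knockout line.
5. **One complex or several?** Correlation of the per-peak
   `log2(JUNB/TEAD)` crosslinking ratio with AP-1 and TEAD motif scores.
6. **Does it matter for patients?** Motif-class gene signatures (genes with
   a qualifying peak within 2 kb of a TSS), a per-patient gene signature
   score `GSS_j = Σ_i (x_ij − μ_i)/σ_i` after a 5%–85% CV filter,
   stratification at GSS ≥ 0, and Kaplan–Meier / log-rank comparison.

A seeded synthetic-data generator (`generate_dataset()`) produces a
complete dataset with recorded ground truth — planted motif classes,
paralog-specific sites, a planted crosslink correlation, and a planted
hazard ratio on the high-GSS group — so the whole workflow is testable end
to end. `run_pipeline()` orchestrates every stage and writes a manifest
with MD5 checksums; runs are byte-identical given the same configuration.

## Worked example

```r
library(peakmotifs)

res <- run_pipeline(pipeline_config(seed = 1), outdir = "pipeline_out")
res$summary$class_recovery
#> [1] 0.9834
res$summary$crosslink_r
#>         AP1        TEAD
#>  0.48816629 -0.04605478
subset(res$summary$enrichment, motif %in% c("TEAD", "NFKB"))
#>   motif frac_target frac_control       fold     chisq        pvalue
#> 2  TEAD      0.3354  0.011106541 30.1984222 973.37868 1.098649e-213
#> 5  NFKB      0.0062  0.006581654  0.9420125   0.03791  8.456244e-01
```

Reading: 98.3% of peaks recover their planted motif class at the 1e-4
scanning threshold; the JUNB:TEAD crosslinking ratio correlates with the
AP-1 motif score at the planted strength (0.5) and not with the TEAD
score, the pattern expected when AP-1 recruits the co-activator
independently of TEAD; the planted TEAD motif is ~30-fold enriched over
accessibility-matched controls while the never-planted NF-κB motif sits at
fold ≈ 1 (negative control). The knockout step confirms 125 YAP-specific
and 443 TAZ-specific sites of the 125 + 450 planted, and only the gene
signature carrying the planted hazard effect separates survival
(`res$summary$survival`): log-rank p = 0.0083 for the AP-1 signature with
the high-GSS group faring worse, p ≈ 0.96 and 0.32 for the TEAD and
composite signatures.

The numbered scripts under `analysis/` walk the same stages one at a time
(simulate → summits → motif classes → matched controls/enrichment →
specific sites and ratios → signatures/survival), each printing what it
found and writing its tables under `results/`.

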