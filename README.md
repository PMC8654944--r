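# sng4kit

Downstream analysis of single-nuclei G-quadruplex (G4) CUT&Tag data in R.

G4s are four-stranded DNA secondary structures formed by guanine-rich
sequence. Antibody-directed tagmentation (BG4 CUT&Tag) maps them
genome-wide, and with droplet barcoding each deduplicated fragment carries
a cell barcode, so G4 landscapes can be resolved per nucleus. `sng4kit` is
for analysts working with the resulting *fragment files*
(`chrom  start  end  barcode  read_support`, 0-based half-open): it answers
whether cell identity can be recovered from single-cell G4 profiles alone,
which G4 loci are common to two cell types versus type-specific, how many
cells support each locus, and which promoter G4 peaks are differentially
enriched between two clusters and sit on amplified genes.

## What it computes

* **Signal matrices** — cells x regions fragment or Tn5 cut-site counts, and
  regions x libraries RPM (`count * 1e6 / library_total`); FRiP; cluster
  pseudobulks; bedGraph coverage tracks.
* **Cell clustering** — latent semantic indexing (binarize, TF-IDF, L2,
  truncated SVD, depth component dropped) followed by k-medoids.
  PAM and its subsampling extension CLARA are implemented in the package
  (multi-start BUILD + best-improvement SWAP, deterministic given a seed).
* **Identity imputation** — pseudobulk cluster profiles are correlated
  (Spearman r_s) with bulk reference libraries over a merged G4 reference
  set; each cluster takes the best-correlating label with the margin to the
  runner-up reported. The joint matrix is also z-scored per region row,
  capped at its global 75th percentile, rescaled to [0, 1], and its region
  rows clustered by CLARA (K = 4 signal archetypes) for concordance.
* **Supporting cells** — for each peak and cluster, the number of distinct
  barcodes with >= 1 overlapping fragment; peaks partitioned into
  common/cluster-specific; top 25% supported loci; Mann–Whitney
  common-vs-specific comparison.
* **Differential promoters** — promoter windows (1,000 bp upstream to
  100 bp downstream of the TSS, strand-aware); per promoter peak
  `log2FC = log2(((a+1)/A) / ((b+1)/B))` with a two-sided Fisher's exact
  test on `[a, A−a; b, B−b]`, filtered at |log2FC| > 0.6 and p < 0.05,
  top 50 by p; gene copy-number annotation
  (log2(relative to ploidy + 1) > 1.5 flagged high).
* **Peak calling** — a calibrated Poisson sliding-window stand-in
  (window 147 bp; null rate `sum(window + frag_len − 1)/genome`;
  Benjamini–Hochberg over windows).
* **Simulator** — barcoded fragments for a two-type mixed population with
  full ground truth (cell labels, peak classes, differential promoters,
  copy-number table), so the entire pipeline is testable offline.

## Worked example

```r
library(sng4kit)

cfg  <- sim_config(seed = 7)              # 300 + 300 cells, median 800 frags/cell
data <- simulate_dataset(cfg, seed = 7)   # fragments + bulk + truth
report <- run_mixed_population_workflow(
  run_config(sim = cfg, seed = 7, outdir = "g4run"), data = data)

report$ari_vs_truth
#> [1] 1
report$identity_calls
#>     cluster  label       r_s    margin low_confidence
#> 1: cluster1      A 0.9808891 0.7705747          FALSE
#> 2: cluster2      B 0.9839328 0.7800597          FALSE
report$support_comparison
#>     cluster median_common median_specific         direction       U   p_value
#> 1: cluster1         159.0             145 common > specific 21861.0 0.0134935
#> 2: cluster2         169.5             150 common > specific 21265.5 0.2424656
report$differential$n_significant
#> [1] 29
```

Reading the output: the two k-medoids clusters match the simulated cell
types exactly (adjusted Rand index 1). Each cluster's pseudobulk correlates
with the correct bulk reference at r_s ≈ 0.98, with a ~0.77 margin over the
wrong label — identity imputation is unambiguous. Common peaks are
supported by more cells than cluster-specific peaks in both clusters
(median 159 vs 145 and 169.5 vs 150), and 29 promoter peaks pass the
differential filter, which includes all 20 simulated truth promoters.
`g4run/` holds every artifact (cluster assignments, per-cluster peak and
support BEDs, the differential table, `report.json`, `log.txt`), all
re-readable with the package's own readers and byte-identical on rerun with
the same seed.

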