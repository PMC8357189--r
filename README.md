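# slamwave

Analysis toolkit for **rapid transcription-factor induction time courses
read out by metabolic RNA labeling** (SLAM-seq with an inducible TF).
After TF activation, cells receive a short 4-thiouridine pulse at each
time point; alkylation makes s⁴U read as C instead of T, so reads from
transcripts synthesized during the pulse carry T>C conversions (~2–3% per
T position) over a much lower background (< 0.15%). Counting reads with
≥ 2 conversions per 3'-anchored window measures **transcription rate**
per gene per time point. Integrated with genome-wide TF occupancy, this
separates target genes into temporal **waves**:

| wave | occupancy | first significant change |
|---|---|---|
| immediate-early direct (transient / sustained) | bound | 0.5 or 1 h |
| delayed direct | bound | ≥ 2 h |
| secondary | unbound | ≥ 2 h |
| immediate-early unbound (flagged) | unbound | 0.5 or 1 h |
| unresponsive | — | never |

The package provides, as tested R functions:

* **`sim_config()` / `build_reference()` / `simulate_timecourse()` /
  `simulate_reads()` / `simulate_occupancy()`** — a synthetic-study
  generator (reference FASTA, window/gene BED, aligned reads as SAM and a
  TSV dialect, occupancy peaks, ground truth) with planted gene classes,
  T>C chemistry, background errors and homozygous-like variants;
* **`detect_variants()` / `count_conversions()` / `classify_reads()` /
  `utr_conversion_rate()` / `build_count_matrix()`** — conversion-aware
  quantification: pooled variant masking (mismatch fraction ≥ 0.2),
  strand-aware conversion counting, labeled-read calling (≥ 2 T>C),
  per-UTR conversion rates normalized to T content and coverage;
* **`run_contrasts()`** (with `normalize_counts()`, `fit_models()`,
  `ebayes()`) — moderated linear-model testing across the time course:
  log2-CPM, per-gene OLS over arm × time groups, empirical-Bayes variance
  shrinkage with moment-estimated prior df
  (s̃²_g = (d₀s₀² + d_g s_g²)/(d₀+d_g), moderated t on d₀+d_g df),
  consecutive and vs-0h contrast families, BH FDR;
* **`assign_peaks()` / `feature_distribution()`** — nearest-TSS peak
  annotation with strand-aware promoter windows (−2000/+500 bp default)
  and deterministic tie-breaking;
* **`classify_waves()` / `bound_fraction_by_first_time()` /
  `overlap_stats()` / `run_pipeline()`** — wave classification with a
  control-arm veto, bound-fraction summaries, exact hypergeometric
  set-overlap tests, and end-to-end orchestration scored against the
  planted truth.

The repository is organized as an analysis workflow: numbered drivers
under `analysis/` run the five stages over the package and write tables
under `results/`.

## Worked example

Run the workflow from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_quantify.R
Rscript analysis/03_timecourse_testing.R
Rscript analysis/04_occupancy_annotation.R
Rscript analysis/05_wave_classification.R
```

Step 2 prints, for the default 200-gene study (24 samples, depth 150):

```
Variant mask: 20 positions (planted 20; recovered 20, spurious 0)
Count matrix: 200 genes x 24 samples; labeled fraction 0.37
Mean per-UTR conversion rate: 2.03% (range 1.98-2.06%)
```

— every planted variant was masked with no false calls, and the
incorporation rate sits in the expected ~2% regime (0.8 labeled fraction
× 2.5% conversion probability). Step 5 ends with:

```
Exact class recovery among responsive genes: 98.0%
```

after printing the full confusion matrix of planted versus recovered wave
classes (the residual errors are secondary genes picked up slightly early
or late, never confused with direct targets), the bound fraction per
first-significant time point, and an exact hypergeometric test of the
regulated/bound gene-set overlap.

Programmatic equivalent:

```r
library(slamwave)
cfg <- sim_config(n_genes = 200, mean_depth = 150, seed = 1)
run <- run_pipeline(cfg)          # simulate -> quantify -> test -> classify
run$report$class_recovery
table(run$waves$class)
```

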