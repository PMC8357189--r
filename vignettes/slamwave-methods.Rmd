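---
title: "Models and methods behind slamwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slamwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slamwave)
```

# The experiment this package models

slamwave analyzes rapid transcription-factor (TF) induction time courses
read out by metabolic RNA labeling. In the assay being modeled, a TF fused
to an ERT2 domain is activated by 4-hydroxytamoxifen; at each of several
time points after activation (0, 0.5, 1, 2, 4 and 8 h by default, two
replicates, with a matched control arm carrying an empty construct) the
cells receive a short 4-thiouridine (s⁴U) pulse. After alkylation, s⁴U
reads out as a T>C mismatch during reverse transcription, so reads derived
from transcripts made *during the pulse* carry T>C conversions at ~2-3% of
their T positions while pre-existing transcripts show only background
substitution noise (< 0.15%). Counting reads with two or more conversions
per 3'-anchored counting window therefore measures transcription rate per
gene per time point, largely independent of pre-existing mRNA pools.

Integrating these transcription-rate time courses with genome-wide TF
occupancy (e.g. from CUT&Tag peak calls) separates TF targets into waves:

* **immediate-early direct** — occupied by the TF and significantly changed
  already at 0.5 and/or 1 h; *transient* if the change has reverted at all
  later time points, *sustained* otherwise;
* **delayed direct** — occupied, but first changed at ≥ 2 h;
* **secondary** — not occupied, first changed at ≥ 2 h (presumed to act
  through an intermediary regulator);
* **immediate-early unbound** — changed at 0.5/1 h without detected
  occupancy. These are kept as their own flagged class rather than folded
  into "secondary": a fast response without an occupancy call is more
  plausibly a missed peak than a two-step cascade, and folding them away
  would hide that ambiguity;
* **unresponsive** — no significant change anywhere.

Every stage of that reasoning is implemented here against synthetic data
whose ground truth is known, so each analytical claim can be scored.

# The synthetic-data generator

`sim_config()` + `build_reference()` + `simulate_timecourse()` +
`simulate_reads()` + `simulate_occupancy()` produce a full study: a
reference genome, 3'-anchored counting windows, aligned labeled reads for
every sample, occupancy peaks, and the planted truth.

**Geometry.** Genes are laid out on chromosome-like contigs with 12 kb
spacing and a 2 kb span, the counting window being the 3'-most 250 bases
(the 3'-UTR-anchored quantification unit). The wide spacing makes every
peak unambiguously nearest its own gene's TSS, so occupancy assignment is
noise-free by construction — classification errors can then be attributed
to the expression side. Bases are drawn uniformly, giving ~25% convertible
T content per window (strand-aware: reference A counts for minus-strand
genes).

**Kinetics.** Kinetic profiles are step functions on the sampled grid, not
continuous decay curves: only per-time-point labeled counts are observable,
so a smoother parameterization would add parameters without adding
testable structure. With effect size $e$ (log2, default 1.0):
immediate-early transient genes deviate by $e$ at 0.5 and 1 h and return to
baseline from 2 h; immediate-early sustained genes hold $e$ from 0.5 h on;
delayed and secondary genes switch on at an onset drawn from {2, 4, 8} h
(weights 0.5/0.3/0.2 — the class definition constrains only onset ≥ 2 h,
and spreading onsets populates the per-time bound-fraction summary);
the control arm is flat. The magnitude of transcriptional responses is not
something the assay pins down; $e$ is a free simulator parameter.

**Read model.** Each read spans its full window (read length = window
length), which removes alignment ambiguity — alignment itself is out of
scope. Per gene and sample, labeled reads are Poisson with mean
$\mu \cdot \ell_0 \cdot 2^{\Delta(t)}$ and unlabeled reads Poisson with
mean $\mu (1-\ell_0)$, where $\mu$ is `mean_depth` times a per-gene
lognormal expression multiplier (log2 SD 0.5) and $\ell_0$ is the baseline
labeled fraction. Induction therefore *adds* labeled read mass rather than
re-partitioning a fixed total — new transcription makes new RNA.
Degradation during the 15-minute pulse is ignored (pulse ≪ typical mRNA
half-life), so the labeled fraction is proportional to the transcription
rate.

The default $\ell_0 = 0.8$ is a phenomenological choice, not a mechanistic
estimate of the nascent fraction: it is set so that the aggregate per-UTR
conversion rate of a mixed sample ($\ell_0 \times 2.5\% = 2\%$) falls
inside the empirically observed 1.5–3.5% incorporation window while an
unlabeled control stays below 0.15%. Real 3'-end libraries reach such
incorporation via capture chemistry that this generator does not model
base-by-base.

**Chemistry.** Labeled reads convert each convertible T with probability
`p_conv` = 0.025; every read picks up background substitutions at `p_err` =
0.001 per position (uniform over the three alternative bases). A fraction
of windows (10%) carries a planted homozygous-like variant — always T>C at
a convertible position, i.e. exactly the failure mode that would inflate
conversion counts if unmasked — present in every covering read.
The degenerate `p_conv = p_err = 0` configuration is allowed as a
no-chemistry control; otherwise `p_err < p_conv` is enforced.

**Occupancy.** Every bound gene (IE and delayed classes) gets one 200 bp
peak; with probability 0.612 its midpoint falls in the promoter window
(−2000/+500 bp of the TSS, strand-aware), otherwise in the gene body (70%
of the remainder) or the 3' flank (30%). The 0.612 default is the promoter
fraction reported for the occupancy data this design emulates, used here
as a *planted parameter the annotator must recover*, not as a reproduction
claim. Secondary and unresponsive genes get no peak; optional decoys land
in gene-free contig tails beyond any assignment distance.

**Reproducibility.** One master seed; each sample, and each generator
stage, derives a child RNG stream by a stable string hash of its name, so
any subset of samples can be regenerated identically and generation order
never matters. Identical (config, seed) gives byte-identical FASTA, BED,
SAM and TSV outputs.

**What the generator does not emulate.** Sequencing quality scores,
indels, multi-mapping, partial window overlap, 3'-bias within the window,
pulse-length kinetics, mRNA degradation, transcriptional bursting, and
peak-calling noise (occupancy is noise-free). Passing recovery tests
therefore demonstrates the *analysis logic* is correct under the assay's
idealized statistical structure; it does not certify performance on real
libraries, where mapping artifacts and overdispersion add error modes the
simulation deliberately excludes.

# Conversion-aware quantification

`detect_variants()` masks positions whose pooled mismatch fraction is at
least 0.2 (inclusive — a fraction of exactly 0.20 masks; the boundary is
stated so it is testable) at pooled coverage ≥ 10. Variants are genotype
properties, so calling is pooled across all samples of an experiment and
the mask is shared by every downstream contrast.

`count_conversions()` counts, per read, strand-aware T>C conversions
(reference A read as G for minus-strand genes) at unmasked convertible
positions; `classify_reads()` calls a read labeled iff it has ≥ 2
conversions. `utr_conversion_rate()` computes per-position rates
(conversions / coverage over unmasked T positions with coverage ≥ 1) and
averages them *unweighted* across positions — each position gets one vote
after coverage normalization, the literal reading of per-position
normalization averaged per UTR. Windows with no qualifying position report
`NA`, never 0. Background conversions are reported diagnostically (control
arm rates) but not subtracted from labeled counts: at `p_err` = 0.001 the
chance a purely background read reaches two T>C substitutions is ~ $(L
p_{err}/3)^2 \approx 10^{-3}$ per read relative to Poisson noise, so the
≥ 2-conversion rule itself is the background filter.

`build_count_matrix()` tallies labeled and total reads per gene and
sample. Reads partially overlapping a window cannot occur in simulated
data; SAM input from other sources is expected pre-trimmed to windows.

# Moderated time-course testing

`normalize_counts()` computes
$\log_2\!\big((\text{labeled}+0.5)/(\text{lib}+1)\times 10^6\big)$ with the
library size taken from **total** counts, so a genuine gain of labeled mass
is not normalized away by its own effect on the labeled column sum.

`fit_models()` fits per-gene OLS under a group-means design (arm × time
point, 12 cells, 2 replicates each, residual df 12). `ebayes()` shrinks
gene-wise variances through the standard hierarchical model in which
sample variances are scaled-F distributed around a prior variance $s_0^2$
with prior df $d_0$; the posterior variance is
$\tilde s^2_g = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and the moderated $t$
uses $d_0 + d_g$ df. Hyperparameters come from the method of moments on
$\log s_g^2$ (mean and variance matched to the log-F distribution, with a
Newton inversion of the trigamma function) rather than maximum likelihood:
closed-form, deterministic, and adequate at these ensemble sizes. When the
observed log-variance dispersion does not exceed chi-squared sampling
noise the moment equation has no finite root; $d_0$ is then infinite and
all genes share the pooled variance $\overline{s^2}$. Genes with zero
sample variance are excluded from hyperparameter estimation but still
receive a posterior variance. The implementation is cross-checked in the
test suite against an independent reference implementation of the same
moderated-t machinery on random data.

`run_contrasts()` emits both contrast families per arm — consecutive
(0.5 vs 0, 1 vs 0.5, …) and each time vs 0 h — with BH correction within
each contrast. Significance requires q < 0.05 **and** |log2FC| > 0.5; the
parent RNA-seq analysis style prints q < 0.01 for steady-state comparisons,
but the labeling assay's thresholds are not printed anywhere, so the
defaults here are declared choices (both configurable). No precision
weights are used: simulated depths are homoscedastic enough that the
mean–variance trend is flat, and modeling it would add a component the
design does not test.

The control arm is used as a veto, not as an interaction term: a gene
significant in any matching control-arm vs-0h contrast is set to
unresponsive before classification. A filter is transparent, testable, and
does not require asserting a model for control-arm drift.

# Occupancy annotation

`assign_peaks()` anchors each peak at its midpoint and assigns it to the
gene with the nearest TSS (within 10 kb; farther peaks stay unassigned).
Equidistant TSSs resolve by lexicographic gene id so results are invariant
to input order. Features: promoter if the midpoint is within −2000/+500 bp
of the TSS in the gene's reading direction, else gene body inside the
span, else intergenic. The promoter window spans common conventions and is
exposed as an argument — there is no single field-wide definition. The
midpoint (not a caller-specific summit) anchors distance because peak
summits are a peak-caller detail this package does not consume. A gene is
"bound" given ≥ 1 assigned peak of any feature class: the classification
criterion is binary occupancy, not promoter-restricted occupancy.

# Wave classification and integration

`classify_genes()` applies first-significant-time precedence on the vs-0h
family: the first time point at which a gene is significant fixes its wave
(0.5/1 h → immediate-early; ≥ 2 h → delayed/secondary), and occupancy
picks the branch. "Transient" is operationalized as significant at 0.5
and/or 1 h with *every* vs-0h call at ≥ 2 h non-significant; "sustained"
as ≥ 2 significant time points including one ≥ 2 h. These verbal patterns
come from the schematic class descriptions; the exact cutoffs are this
package's formalization. The consecutive-contrast family is emitted for
shut-off inspection but precedence always rests with the vs-0h family —
the two families are used together in the source analyses without a stated
precedence, so one had to be fixed. Direction is the fold-change sign at
the first significant time; later sign flips set a warning flag rather
than a class, since a class per sign pattern would fragment the taxonomy.

`bound_fraction_by_first_time()` reports, per first-significant time, the
fraction of regulated genes with occupancy — the "how direct is each wave"
summary. `overlap_stats()` computes the exact upper-tail hypergeometric
probability of a gene-set overlap (via the cumulative hypergeometric
distribution, exact for any universe used here), with BH across pairs in
`pairwise_overlaps()`. The overlap universe defaults to expressed genes
(nonzero total count): unexpressed genes can never be called regulated, so
including them would inflate every enrichment.

# Numerical and degenerate-input choices

* Variant threshold inclusive at 0.2; minimum coverage 10 for a variant
  call (both configurable — the upstream tooling's exact boundary behavior
  and coverage floor are undocumented).
* Zero-coverage or fully masked windows report `NA` conversion rates.
* `trigamma_inverse()` uses Newton iteration with the standard asymptotic
  guards (`1/y` for small y, `1/sqrt(y)` for large).
* Zero residual standard errors give t = 0, p = 1 (never NaN).
* BH is applied within contrast; q-values are monotone in p by
  construction of the step-up procedure.
* Ties in nearest-TSS distance and in peak ordering resolve
  lexicographically; permuting input order never changes output.
* All internal coordinates are 1-based closed; BED and truth files are
  0-based half-open; SAM is 1-based.

# Problem sizes

The shipped analyses and tests run at desk scale, chosen so the full suite
exercises every code path on one CPU in minutes: the workflow scripts use
200 genes × 24 samples at depth 150 (~0.8 M reads); recovery tests use 200
genes at depth 200 with 40 genes per class; calibration uses 2 000 genes ×
10 replicate simulations at the count level (the count-level sampler draws
from the identical generative model, skipping per-base read synthesis);
oracle-equivalence tests run exact brute-force comparisons on 1 000 reads,
100 peaks, and universes of 12 genes.

# Known limitations

* The generator's idealizations listed above; in particular counts are
  Poisson, not overdispersed, so the moderated test's calibration here is
  a best case.
* The labeled fraction is a free parameter tied to observed incorporation,
  not derived from pulse kinetics.
* The control-arm veto discards genes with control-arm artifacts instead
  of modeling them.
* Direction changes within a significant time course are flagged, not
  classified.
* Occupancy is consumed as binary; peak strength and multiplicity play no
  role beyond the bound flag.
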