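---
title: "Spike-in calibrated absolute quantification: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in calibrated absolute quantification: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikequant)
```

## The calibration model

A sequencing run draws a roughly fixed number of reads per sample, so a
feature's read count is informative only relative to the other features in
its sample. Spike-in calibration restores the absolute scale: synthetic
standards of known copy number are added to the extracted DNA, co-amplified
and co-sequenced, and each sample's mapping from reads to copies is
estimated from the standards themselves.

The model behind the curve is that within one sample every template is
captured with a common per-sample efficiency, so expected reads are
proportional to input copies: $E[r_i] \propto c_i$. On log–log axes this is
a line of slope 1, and we fit the slightly more general

$$\log_{10}(\text{copies}) = a\,\log_{10}(\text{reads}) + b$$

by unweighted ordinary least squares over the usable ladder points. Fitting
the slope rather than pinning it at 1 lets the curve absorb mild, monotone
saturation effects (e.g. PCR plateau compressing the high rungs); a fitted
slope far from 1 is itself a useful diagnostic. The regression is oriented
with copies as the response so that converting a read count is a direct
evaluation of the fitted line — no inversion, and prediction error is
minimized in the quantity we report.

Assumptions worth stating explicitly:

* **Shared efficiency.** Spike-ins and biological templates are assumed to
  amplify with the same per-sample efficiency. Sequence-specific bias
  (primer mismatches, extreme GC, length differences) shifts individual
  features off the curve and is not corrected.
* **Post-extraction addition.** Standards are added after DNA extraction,
  so extraction efficiency differences between samples are *not* captured;
  absolute values are copies of extractable template, not cells.
* **Independent calibration per sample.** Curves are fit per sample, never
  pooled: spike-in capture varies sample to sample (inhibitors, loading),
  and per-sample fitting is what makes the totals comparable across
  samples. A pooled per-run option was considered and rejected because it
  silently transfers one sample's bias onto all others.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| assignment `threshold` | 0.97 | identity fraction | conventional OTU radius; spike-ins are designed to sit far (~0.5 identity) from biological sequences, so the partition is insensitive near this value |
| `min_reads` per calibration point | 1 | reads | a rung must be observed to be a point; zero-read rungs are excluded, never imputed — pseudocounts would bend the low end of the ladder |
| minimum points per curve | 3 | points | fewer cannot support a slope plus goodness-of-fit; such samples fail QC and are emitted as missing values |
| QC `r2_warn` / `r2_fail` | 0.95 / 0.80 | R² | strict-but-passable on simulated data at depth 10⁵; both exposed via `qc_thresholds()` |
| spike-in read fraction window | 0.005–0.30 | fraction | below: too few spike reads to calibrate reliably; above: the ladder is eating sequencing depth the community needed |
| concordance `flat_band` | 0.25 | log₂ fold change | changes smaller than ~19% in group means are not called a direction |
| concordance `min_support` | 20 | mean reads/sample | see the power argument below |
| ladder | 10³…10⁸, 10-fold | copies/dose | six rungs spanning five orders, mirroring a serial-dilution standard mixture |

The bundled spike-in FASTA (`inst/extdata/spikein_refs_synthetic.fasta`) is
six synthetic sequences of 312–446 bases, GC 45–55%, generated once with a
fixed seed; it is a *synthetic stand-in* with the right structure (multiple
distinct references, ladder of known copies), not a published standard set.

## Read assignment

Features are matched to spike-ins by normalized Levenshtein identity,
$1 - d(a,b)/\max(|a|,|b|)$, computed by full dynamic programming
(`utils::adist`). A feature joins the spike-in of maximal identity when
that identity reaches the threshold; exact ties go to the
lexicographically smallest spike-in id so results are order-independent. A
k-mer (k = 8) prefilter skips an alignment only when the q-gram bound —
one edit changes at most $2k$ k-mer occurrences, so
$d \ge \lVert P_a - P_b\rVert_1 / 2k$ — proves the pair cannot reach the
threshold; the filter is correctness-preserving by construction and the
test suite asserts filtered and unfiltered runs are identical. Matching
happens at the representative-sequence (feature) level, not the raw-read
level: the pipeline sits downstream of denoising, and per-read matching
would re-litigate what the denoiser already decided. Host removal is
represented as an explicit feature-exclusion list; excluded reads stay in
the accounting as their own partition.

## The three outputs and concordance

`absolute_table()` converts every biological count through its sample's
curve (0 reads ↦ 0 copies; predictions outside the curve's calibrated read
range are flagged as extrapolations), `relative_table()` renormalizes
counts per sample, and `aggregate_rank()` sums either table over the full
lineage prefix at each of the seven ranks — prefix keys keep two genera
with the same name in different families apart, and features missing from
the taxonomy are carried as Unassigned rather than dropped, so per-sample
sums are conserved at every rank.

`concordance()` compares directions of change (up / down / flat by log₂
fold change of arithmetic group means) between relative and absolute
space. The statuses are deliberately asymmetric:

* `discordant` — relative data call a direction the absolute data
  contradict. This is the compositional false positive the method exists
  to catch, and the only flagged status.
* `absolute_only` — relative data are flat while absolute data moved. Not
  an error: it is the extra information absolute quantification provides
  (when a whole community grows, every relative fraction is pinned while
  every absolute abundance rises).
* `concordant` — directions agree (the report also keeps a plain
  `concordant` boolean, which is exactly "directions equal").

A direction call needs adequate counts. The sampling standard error of a
log₂ fold change of group mean counts is approximately
$2.04/\sqrt{n\lambda}$ for $n$ samples per group at mean count $\lambda$;
requiring mean support of 20 reads per sample keeps the flat band
(0.25) at ≳2.5 standard errors for $n = 20$, so noise alone rarely crosses
it. Taxa below the support floor are reported `low_support` and never
flagged. No significance testing is attached: the report is descriptive,
and effect-size testing belongs to dedicated differential-abundance tools.

## The simulator

`simulate_dataset()` generates what the pipeline consumes: a log-normal
community (default 200 taxa, median 10⁴ template copies, σ = 1.5 on the
log scale), two groups of six samples, the 6-rung ladder added to every
sample, optional per-sequence capture efficiencies (log-normal, σ_eff; 0
means unbiased), and per-sample reads drawn *multinomially* at fixed depth
(default 10⁵) with probabilities ∝ copies × efficiency. Multinomial
sampling matches the fixed-depth character of a sequencing run and keeps
the moments tractable for oracle tests; PCR-cycle branching noise, chimera
formation, sequencing error and length-dependent ITS effects are
deliberately not modeled — passing tests demonstrate the *mathematical*
contracts of calibration, not robustness to those artifacts. The
`"expected"` mode returns the exact expected counts `depth × p`
(real-valued, not rounded): it is the diagnostic regime in which recovery
must be exact to float precision, and the integer-count invariant applies
to sampled data and to files on disk, where counts are rounded.

`inject_discordance()` builds a ground-truth compositional artifact by
scaling every taxon of one group *except* a focal taxon (by default the
most abundant one — dominant taxa are where closed-sum distortion is
strongest and where a fixed taxon remains detectable against the flat
band). With factor 0.5 the focal taxon is analytically relative-up /
absolute-flat.

With the default community and ladder the spike-ins take a large share of
reads, so simulator-based QC reports a spike-fraction warning; this is the
correct diagnostic for a ladder dosed high relative to community biomass,
and it illustrates why matching the dose to expected biomass matters in
practice.

## Numerical choices and degenerate inputs

* R² is $1 - SS_{res}/SS_{tot}$; if all used rungs share one copy value
  ($SS_{tot} = 0$) the fit is declared perfect only when residuals vanish.
  All spike-ins at identical read counts cannot support a slope and raise
  a calibration error.
* Calibration failures are classed conditions
  (`calibration_error`/`calibration_failure` records); failed samples are
  quantified as missing values, never zeros, and fail QC.
* Serial dilutions store the stock formulation plus a cumulative dilution
  factor; step-to-step equality holds exactly for decimal factors and to
  one part in 10¹⁴ otherwise (float associativity of $x/f^k$ versus
  repeated division).
* Output numbers are written with a fixed 12-significant-digit format so
  identical runs are byte-identical; no timestamps are embedded.
* CE peak areas are treated as directly molar (no length normalization) by
  default, honoring the capillary-electrophoresis principle that peak area
  tracks molarity; `per_base = TRUE` divides areas by fragment size for
  instruments whose signal tracks mass.

## Problem sizes used in the checks

The test-suite and acceptance-script simulations use the generator
defaults (200 taxa × 12 samples at depth 10⁵; 20 replicate seeds for the
stochastic checks; 20 samples per group for artifact detection), with
smaller 30–50-taxon instances for unit-level properties. These sizes were
chosen as the smallest at which the stochastic contracts are comfortably
identifiable.

## Known limitations

* Extraction efficiency and copy-number variation of the marker gene are
  outside the model: results are marker-gene copies, not cell counts.
* Low-biomass samples push the spike fraction high and leave few reads for
  the community; QC warns but cannot create information that is not there.
* The concordance report compares mean trends only; it is a
  cross-validation screen, not a differential-abundance test.
* A pooled (per-run) calibration option and third-generation/UMI-aware
  extensions are out of scope.
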