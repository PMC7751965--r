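---
title: "Promoter-window regression of TSS activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-window regression of TSS activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promreg)
```

## The problem and the model

ChIP-seq catalogues tell us *where* transcription factors (TFs) bind; CAGE
atlases tell us *how active* each transcription start site (TSS) is, per
cell line. `promreg` connects the two with a deliberately simple, fully
interpretable model: linear regression of log-transformed TSS activity on
the presence of TF binding in fixed promoter windows.

**Windows.** Eight closed offset intervals tile −5000..+1000 bp around each
TSS: `[-5000,-1001]`, `[-1000,-501]`, `[-500,-201]`, `[-200,-101]`,
`[-100,0]`, `[1,100]`, `[101,500]`, `[501,1000]`. Offset 0 is the TSS base
itself and belongs to `[-100,0]` — with closed bounds this is the only
assignment that tiles the range without gap or double-counting. Windows are
strand-aware: negative offsets are upstream on either strand.

**Features.** For m TFs the design has 8·(m+1) columns. Per window,
`Abundance = m0/m` is the fraction of TFs with at least one binding region
(TFBR) overlapping the window — a proxy for cis-regulatory-module presence;
per (TF, window), a binary presence indicator. Overlap always means at
least one shared bp; touching half-open intervals do not overlap. The
identity `Abundance = (sum of binaries)/m` holds exactly by construction
and is asserted matrix-wide in the tests.

**Response.** Raw expression EL is transformed to
`LTE = 0 if EL < 2, else log10(EL)`. The cutoff at 2 maps technical
noise-level tags to exactly zero; an important side effect is that a TSS
with no binding anywhere predicts at the model intercept, so falsely called
TSSs (which have empty promoters) are automatically predicted near zero.

**Fitting.** Greedy forward selection: at each step, the candidate whose
inclusion in the OLS model maximizes R_o-p (Pearson correlation between
fitted and observed response) is added; 20 steps by default, after which
increments become negligible; the reported coefficients and two-sided
t-test p-values come from a final refit on the selected set. Internally the
search runs on a Gram–Schmidt orthogonalized design — adding the candidate
with the largest squared partial correlation with the current residual is
algebraically the same selection — which makes each step O(n·p) instead of
p full regressions. The equivalence is not assumed: the test suite compares
the selected sequence step by step against an exhaustive `lm()`-based
oracle.

## Classification of TFs

Two separate schemes, never merged:

1. **Model-sign scheme.** Within a fitted selection model, a binary feature
   with a positive coefficient marks the TF as activator/coactivator in
   that window, negative as repressor/corepressor. No extra p filter: every
   selected feature is already highly significant.
2. **Per-TF eight-window scheme.** For one TF, a standalone OLS on its
   eight window columns; a window is a significant activator (repressor)
   if its coefficient is positive (negative) with p < 1e-5, otherwise
   insignificant. These single-TF models have modest R_o-p, which is
   reported with each call so the reader can weigh them.

The co-binding ratio P(both)/[P(a)·P(b)] quantifies avoidance (< 1) or
co-occurrence (> 1) of two features under an independence null — the only
estimator consistent with that interpretation.

## Meta-processing of peak sets

Per experiment, the outputs of several peak callers are pooled and the
connected components of the interval-overlap graph become consensus
clusters (support = number of distinct callers). If the experiment's FPCM
quality metric exceeds 3.0, single-caller clusters ("orphans") are dropped.
The FPCM formula itself is external to this package: the value is injected
per experiment (argument, config table, or user callable) rather than
guessed. Per TF, refined experiment sets are unioned into maximal
non-overlapping intervals. The emitted region per cluster is the union span
of its members, which preserves all evidence and matches common
meta-cluster practice; intersection would discard caller-specific flanks.

## Profile-level analyses

- **Mean profile**: per-TSS mean of LTE activities across cell lines. The
  averaging is done on the LTE scale (a config choice documented here;
  activities are used on that scale everywhere else in the pipeline).
- **Predicted mean profile**: forward selection is run per cell line, the
  fitted profiles are averaged. This captures cross-line commonality while
  remaining computable for novel TSSs; appended as a candidate column it
  typically wins step 1 of the "advanced" models.
- **Sum-transformation**: TSSs on the same chromosome closer than 100 bp
  are grouped by single linkage (the only clustering consistent with the
  symmetric pairwise criterion "has a neighbor < 100 bp"); each member gets
  the LTE of the group's summed EL. Distance is the absolute difference of
  the single-bp TSS anchors, strand-agnostic. Raw EL is conserved within
  groups by construction.

## The synthetic world

The generator states one fixed world; its defaults are not tuned to tests:

- **TSS landscape**: 5000 TSSs by default, 55.6% of them with a neighbor
  < 100 bp (clusters of 2–3 with uniform 1–99 bp gaps), the rest isolated.
  Units are spaced 11–13 kb apart so that the ±5 kb windows of distinct
  units can never overlap — binding propensities are then realized exactly
  in the features of isolated TSSs, which is what makes binomial checks on
  the generator sharp. Close pairs do share window territory; the resulting
  feature bleed is intended realism.
- **Binding**: per (TF, window, TSS) Bernoulli indicators with propensity
  0.2 by default (a typical promoter-occupancy rate that keeps binary
  features informative but sparse); each hit is realized as a random
  sub-interval strictly inside the window, at least 20 bp wide.
- **Activities**: `LTE* = 1.0 + Σ β·feature + N(0, 0.3)`, floored at 0;
  the ten default effects have |β| in [0.1, 0.5] with mixed signs. EL is
  the back-transform `10^LTE*` (or a uniform draw in [0, 2) when LTE* = 0),
  so refitting on LTE is correctly specified and parameter recovery is a
  valid acceptance surface. The intercept of 1.0 keeps the fraction of
  TSSs pushed below the floor small (a few percent); rows with
  0 < LTE* < log10(2) ≈ 0.301 are still floored to zero on recovery, a
  deliberate, documented imperfection of the EL representation. Tests that
  require exact noiseless identifiability therefore use intercept 1.5,
  which keeps every LTE* above the cutoff.
- **Caller replicates**: four callers reproduce each true peak with 5%
  dropout and Gaussian boundary jitter (sd 10 bp, clamped to preserve
  overlap with the truth), plus per-caller false peaks at 20% of the true
  count, placed to overlap nothing — these become exactly the support-1
  orphans the FPCM gate should remove.
- **Multiple cell lines** share the true coefficients and most binding:
  each non-base line redraws an indicator with probability 0.2. This
  yields cross-line activity correlations around 0.7–0.9, comparable to
  what is observed between real cell lines, and is what makes the
  predicted mean profile dominate advanced selection.

What a green test establishes: the pipeline's algebra and algorithms are
correct on data satisfying the model's own assumptions. What it does not:
anything about real chromatin — the generator has no sequence content, no
read-level noise, no peak-width biology, and its linear LTE model is the
assumption, not a finding.

## Numerical choices and edge cases

- Tie-breaking in selection: candidates within 1e-12 of the best gain tie;
  the lowest column index wins (determinism; the data give no reason to
  prefer otherwise).
- Constant candidate columns are skipped with one warning; candidates that
  become numerically collinear with the selected set (residual norm below
  1e-10 of their original) are silently retired.
- p-values below 1e-300 are floored and flagged; reports render them as
  `<1.0e-300`.
- Cross-validation splits TSS *rows* (not feature columns) 50/50 — the only
  reading under which train/test prediction is defined — and re-runs
  selection on the training half rather than freezing the full-data
  feature set.
- TSSs near a chromosome edge get clamped (possibly empty) windows rather
  than being dropped.
- TF column order is lexicographic (radix sort, locale-independent).
- Config files are JSON; seeds propagate from one base seed to
  per-stage streams so reruns are byte-identical.
- The attendant stop rule examines the least significant coefficient of
  the whole refitted model after each inclusion and rejects the feature
  that pushed it past 1e-20.

## Known limitations

Features are presence/absence only (no peak scores, summits or motif
information); regularized alternatives to greedy OLS are out of scope; the
per-TF eight-window classifier inherits all caveats of small
single-factor models; and the package deliberately does not download or
bundle any external atlas — real-data analyses start from the user's own
BED and activity tables.
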