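---
title: "Iterative interactome refinement with AFM interface scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative interactome refinement with AFM interface scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lisnet)
```

## Overview

`lisnet` turns an immunoprecipitation–mass-spectrometry (IP-MS) candidate
list into a grouped protein–protein interaction network by scoring
AlphaFold-Multimer (AFM) predicted aligned error (PAE) maps, and
quantifies position-effect-variegation (PEV) eye pigmentation from RGB
images. This vignette explains the model behind each stage, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design choices made where the method's published
description leaves the details open.

## Enrichment: from spectral counts to candidates

A prey becomes a candidate when its bait-versus-control fold change is
strictly greater than 2. The published rule states only the ">2-fold"
threshold, so two details are package choices, both exposed as arguments:

* **Replicate summary.** Each arm is summarised by the arithmetic mean of
  its replicate spectral counts. Summing is equivalent at equal replicate
  numbers; per-replicate ratios would conflate noise with enrichment.
* **Pseudocount.** `fold_change()` computes
  `(mean(bait) + c) / (mean(control) + c)` with `c = 1` by default, which
  keeps preys absent from controls (a common and biologically interesting
  case) finite instead of infinite. With `c = 0` the ratio is undefined at
  zero control mean and the function says so explicitly.

Candidates are ordered by descending fold change with lexicographic
tie-breaks, so every downstream manifest is reproducible. The filter is
deliberately not a statistical enrichment model: probabilistic scoring of
AP-MS data is the territory of dedicated published tools, and this
package only reproduces the simple fold rule actually used to seed the
structure-prediction screen.

## Interface scoring: LIS and LIA

For one AFM model of a two-chain complex, the PAE matrix `P` (side
`len_a + len_b`, entries in Ångström, not necessarily symmetric) is
reduced over its two off-diagonal blocks — the cells that relate a
residue of one chain to a residue of the other:

* `S = { (i, j) spanning the chain boundary : P[i, j] < C }` with PAE
  cutoff `C = 12` Å (strict inequality);
* `LIA = |S|` — a count of confident inter-chain residue pairs, an
  interface-size proxy;
* `LIS = mean over S of (C - P[i, j]) / C`, in `[0, 1]`, and 0 when `S`
  is empty (so `LIA = 0` forces `LIS = 0`).

A pair is a positive PPI when `LIS >= 0.203` **and** `LIA >= 3432`, both
inclusive — the printed decision boundary. The boundary semantics are
pinned by unit tests: the PAE cutoff is exclusive (a cell at exactly 12 Å
does not count), the retention thresholds are inclusive (a pair at
exactly (0.203, 3432) passes).

Three choices are configurable because the published account fixes only
the thresholds:

* **The formula and cutoff** follow the AFM-LIS method as summarised
  above; `pae_cutoff`, `tau_lis` and `tau_lia` are all `score_config()`
  fields, so other calibrations drop in without code changes.
* **Block handling.** PAE is asymmetric, and `LIA` counts cells in *both*
  off-diagonal blocks by default (uses all information; the mirrored
  default patch of the simulator gives `2 * 60 * 60 = 7200`).
  `lia_blocks = "max"` scores the stronger block alone instead.
* **Model aggregation.** AFM emits several models per pair but one
  LIS/LIA pair is reported per interaction; whether the printed
  thresholds apply per model or to an aggregate is not stated. The
  default aggregates by the arithmetic mean across models and applies the
  thresholds to the aggregate; `"max"` and `"best_model"` (both fields
  from the highest-LIS model, ties to the lowest model id) are
  alternatives.

AlphaFold PAE dumps come in two JSON dialects — the full square matrix,
and the legacy paired `residue1`/`residue2`/`distance` arrays — and both
are auto-detected by `read_pae_prediction()`. Chain lengths are not part
of either dialect; they travel embedded (files written by
`write_pae_prediction()`), in a `.chains.json` sidecar, or as arguments.
ipTM is read and reported but never thresholded.

## The three-round screen

`run_screen()` composes three rounds over a *prediction provider*, an
abstraction of the precomputed AFM output (a directory of per-pair files
via `dir_provider()`, or any function returning predictions for an
unordered pair):

1. **Round 1** scores the bait against every candidate. Passers become
   Group 1 (direct interactors); the rest form the failed set.
2. **Round 2** scores every Group 1 × failed pair — a failure passing
   against at least one Group 1 member is rescued into Group 2, with an
   edge to *every* passing Group 1 partner — plus every unordered
   intra-Group-1 pair, which can add edges but never nodes.
3. **Round 3** scores the remaining candidates against the consolidated
   core. The core is read literally as bait + Group 1 + Group 2
   (`include_bait_in_core = FALSE` excludes the bait). Passers become
   Group 3 with edges to all passing core partners.

Decisions a fixed-point reading might have made differently, and why this
implementation does not iterate:

* **Single pass per round.** A Group 2 rescue is not re-used as a
  screening partner within Round 2; "three rounds" is read as a bounded
  procedure, not iteration to convergence.
* **Same thresholds everywhere.** Intra-Group-1 scoring uses the same
  `score_config()` as candidate retention (configurable by passing a
  different config).
* **Missing predictions** count as non-passing with a logged warning, and
  the skipped pairs are listed in the run manifest; `strict = TRUE` turns
  them into errors. A screen must never silently drop a scored pair.
* **Determinism.** Candidates are processed in lexicographic order,
  unordered pairs are cached so no pair is ever scored twice, and edges
  are stored with lexicographically ordered endpoints. Identical inputs
  give byte-identical manifests and exports.

The structural invariants — exactly one bait, disjoint groups, every edge
above threshold, every node connected to the bait through passing edges —
are enforced by `validate_ppi_network()` on every constructed network,
and the staged algorithm is tested for exact agreement with an exhaustive
oracle that scores all pairs first and applies the round semantics
breadth-first from the bait.

Exports: GraphML and a TSV edge/node/config triple round-trip losslessly
(numbers are written at 17 significant digits precisely so that a
re-import reproduces every score bit-exactly); SIF keeps topology only.
`tidy()` returns the edge table with endpoint groups, `glance()` a
one-row summary, `autoplot()` the conventional group-coloured,
LIS-weighted rendering.

## PEV pigmentation

`measure_eye()` takes an RGB raster with two user-supplied binary masks
and computes the arithmetic mean of the *red* channel over each. The
published wording — the eye value "subtracted from the background" — is
taken literally: `corrected = background_mean - eye_mean` by default, so
more pigment (a darker eye) gives a larger corrected value; the
`convention` flag covers the opposite reading since the direction is
genuinely ambiguous in prose. No segmentation is attempted: the method
gives none, so masks are inputs. Genotype fold changes are ratios of
group-mean corrected intensities (ratio of means, not mean of per-fly
ratios — the per-fly ratios and their mean are reported alongside), with
the control genotype pinned at 1. Both green and blue channels are
carried but provably never influence a measurement.

## What the generators emulate — and what they do not

The study's raw inputs (MS runs, AFM outputs, photographs) are not
deposited, so the generators plant known truth at the same decision
margins the real pipeline faces:

* **Spectral counts** are Poisson: control counts at `background_rate`
  (default 5), bait counts at `background_rate * fold` for planted preys.
  Poisson is the simplest model consistent with count data — the study
  describes no replicate noise model, so this is a package choice, with
  negative-binomial overdispersion (`dispersion`) as an option. Real
  IP-MS additionally has shared-peptide ambiguity, saturation and
  batch structure that the generator does not attempt.
* **PAE maps** plant a mirrored 60 × 60 low-error patch (values 2–8 Å)
  on 100-residue chains against a 20–31.75 Å background, so a planted
  pair scores `LIA = 7200 >= 3432` and `LIS >= (12 - 8)/12 = 1/3 >=
  0.203` while decoys score exactly (0, 0): the planted margin clears the
  *printed* thresholds without rescaling them. 31.75 Å is the
  conventional ceiling of AFM PAE dumps. Real PAE maps have graded,
  spatially correlated error and borderline cases; the generator's sharp
  two-level structure tests the decision logic, not the calibration of
  the thresholds on real structures.
* **Eye images** are a constant-background frame and a central eye disc
  with Gaussian pixel noise on the red channel, clipped to 8-bit. Real
  photographs add illumination gradients, specular highlights and mask
  imprecision that the generator omits.

Passing tests on these inputs therefore demonstrate that the *decision
rules and bookkeeping* are implemented exactly — recovery of planted
truth at the stated margins, oracle-exact scores, lossless round trips —
not that the thresholds themselves generalise to any particular new
protein pair.

## Problem sizes and numerical notes

The test-suite and acceptance runs use: 200 random PAE maps (chain
lengths 5–50) for oracle equivalence (LIA exact, LIS within 1e-12 — pure
floating-point summation noise); 100 planted interactomes of 1 bait + 20
candidates (5 direct, 3 bridges, 12 decoys) for screen recovery; 1000
fuzzed count tables for filter monotonicity and scale invariance; and 100
simulated image sets of 10 flies per genotype at `noise_sd = 2` grey
levels for pigmentation recovery, where the planted corrected-intensity
ratio of 0.5 is recovered within 2% on average and exactly in the
noiseless case. All generators take explicit integer seeds and leave the
caller's RNG state untouched; sub-streams (per pair, per model) are
derived deterministically from the seed and a string key.

## Known limitations

* Rebuilding any *real* bait interactome still requires GPU-scale AFM
  runs; this package consumes their outputs and is validated on
  synthetic surrogates.
* The LIS/LIA formulas and PAE cutoff reproduce the cited scoring
  method's decision boundary; studies using other calibrations must set
  `score_config()` accordingly.
* The screen treats predictions as exchangeable evidence: no per-model
  quality weighting beyond the chosen aggregation.
* Pigmentation assumes user masks and a red-channel readout; it performs
  no illumination correction.
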