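---
title: "Static and dynamic graph analysis of windowed EEG connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic graph analysis of windowed EEG connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`dynfc` treats a parcellated EEG recording as a set of epochs, each an
ROI x sample matrix. Functional connectivity (FC) is the Spearman rank
correlation between ROI series; *dynamic* FC is that correlation recomputed
in sliding windows. Two indicators summarize each graph metric's trajectory
across windows:

* **static**: the mean over windows — the average network organization;
* **dynamic**: the coefficient of variation, CV = sigma/mu x 100 — how much
  the organization fluctuates, in units that are comparable across metrics
  because the ratio is dimensionless.

Groups are compared per (condition, network, metric, indicator) cell with a
linear mixed model: indicator ~ group * threshold + (1 | participant),
REML-fitted, with the binarization threshold treated as a categorical
six-level factor so no monotone dose-response shape is imposed. F tests are
Type III with Satterthwaite denominator degrees of freedom; post hoc group
contrasts are estimated marginal means at each threshold. A
participant-level permutation test (group F from the ordinary two-way fit;
labels permuted across participants so each participant's thresholds travel
together) provides a distribution-free cross-check, exact by enumeration
when the number of balanced relabelings is small. Benjamini-Hochberg FDR is
applied within a (condition, indicator) stratum for the omnibus tests and
across thresholds within a metric for the post hocs; both families are
configurable because the appropriate family is a genuine modelling choice.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `window_ms` | 2000 | ms | sliding-window length; 2000 ms at 500 Hz = 1000 samples |
| `overlap_fraction` | 0.9 | — | window overlap; with the defaults a 50 s epoch yields 241 windows |
| `thresholds` | 0.1–0.6 by 0.1 | correlation | binarization sweep; edges require r > tau (strict), negative and undefined correlations never form edges |
| `sd_type` | `"sample"` | — | CV's sigma uses the n−1 denominator; a population variant exists for sensitivity analysis |
| `alpha` | 0.05 | — | significance level for the diamond rule |

The strict tie rule (r exactly equal to tau is excluded) and the rounding of
the window step (`round(window * (1 - overlap))`) are fixed conventions:
ties are measure-zero for continuous data, but determinism requires picking
a side.

## Disconnected graphs and other numerical conventions

Low thresholds on small networks routinely disconnect graphs, so every
metric has an explicit convention, all of them exercised by tests:

* characteristic path length averages *finite* distances only (NaN when no
  pair is reachable); global efficiency uses 1/d with 1/Inf = 0;
* eccentricity is the maximal finite distance from a node (0 for isolated
  nodes); the diameter is the largest eccentricity;
* nodes of degree < 2 contribute clustering 0 (they are not excluded);
* assortativity is NaN for empty or regular graphs (zero degree variance);
* betweenness is unnormalized — any normalization constant cancels in group
  comparisons;
* network values are nodal means (transitivity and diameter are inherently
  global); a CV whose mean is numerically zero (|mu| < 1e-12) is NaN rather
  than infinite, and such cells are dropped downstream with a count.

The per-epoch→participant reduction is an unweighted mean of epoch-level
indicators; pooling windows across epochs before summarizing is available
as an option (`pool_epochs = TRUE`) since either reading of "CV across
windows" is defensible.

A singular mixed fit (participant variance estimated at zero) is kept, with
a note, rather than discarded: when participants are exchangeable the zero
estimate is the correct boundary answer, and the F tests remain valid.
Refitting with the permutation engine on singularity is available
(`singular_action = "permutation"`) but would silently swap engines for
most cells of a well-calibrated null, which is why it is not the default.

## The synthetic cohort generator

No public EEG data accompany this problem, so the generator is a first-class
module rather than a fixture. Its design:

* **Latent connectivity states.** ROI activity is zero-mean Gaussian with a
  state-dependent correlation matrix; the active state follows a Markov
  chain with exponential dwell times (default mean 5 s) sampled at signal
  resolution. Additive white noise (default SD 0.25) attenuates observed
  correlations by 1/(1 + noise_sd^2).
* **Iso-density reconfigurations.** Every state has the same correlation
  *magnitudes* — within-community rho (default 0.7) and cross-community
  rho (default 0.1) — but a rotated ROI-to-community assignment. All states
  therefore share the same expected edge density and metric level; they
  differ in *which* pairs cohere. This choice is deliberate: states that
  differ in overall connectivity level would move the static mean and — via
  the CV's mean denominator — contaminate the dynamic indicator with level
  effects. Reconfiguration states dissociate the two indicators by
  construction.
* **Group effects via switching rate.** `switch_rate_scale` multiplies the
  transition rate; halving it halves the expected number of state
  transitions per epoch. Windows that straddle a transition average two
  correlation patterns and dip in their graph metrics, so fewer transitions
  mean fewer dips and a lower window-to-window CV, while the time-averaged
  connectivity is nearly unchanged.
* **Determinism.** Each epoch draws from a substream seeded by
  (master seed, participant, condition, epoch), so cohorts are pure
  functions of their specification and survive partial regeneration.

One dynamical subtlety surfaced during design and is worth recording: the
sign of the switching-rate effect on the CV depends on the regime. When
dwell times are comparable to or shorter than the analysis window, faster
switching *averages* states within windows and lowers variability — the
opposite of the intended effect. The generator's defaults therefore keep the
mean dwell several times the window length and a handful of state visits
per epoch, the regime in which slower switching means a smaller sampled
repertoire and a lower CV.

A second subtlety: windowed estimation leaks a small amount of transition
structure into the *static* mean, because windows containing a transition
have a slightly different edge-density profile across thresholds. The leak
is small (group detection rates on the static mean stay near, though
somewhat above, the nominal level, far below the dynamic detection rate)
but it is not exactly zero; an analysis claiming perfect static silence
under this generative family would be overclaiming.

### What the generator does not emulate

Gaussian emissions with abrupt state switches are a deliberately minimal
stand-in for cortical source activity: there is no 1/f spectrum, no
oscillatory structure, no volume conduction or source-leakage correlation,
no artifacts, and no inter-individual anatomy. Passing tests demonstrate
that the pipeline recovers known dynamical structure from data of this
kind — not that any particular clinical population will show these effects.

## Study conditions used by the simulation checks

The calibration and recovery checks run on scaled-down cohorts chosen to
keep the full Monte-Carlo loops tractable on one CPU: two groups of 10
participants, 8 ROIs in two communities, 5 s epochs at 500 Hz, 250 ms
windows at 80% overlap, the default six-threshold sweep, and brain-network
global efficiency as the probe metric; dwell time 2.5 s (several dwells per
epoch, dwell >> window, mirroring the full-scale ratio); null cohorts use
2 epochs per participant (calibration needs no power), effect cohorts 6
(the participant-level CV stabilizes with epochs much as the reference
design's many segments do). Type-I error of both engines is checked against
[0.02, 0.09] at alpha = 0.05 over 200 null cohorts; recovery requires the
halved-switching group to be detected as lower-CV in at least 80% of 200
cohorts while static detection stays below 0.25 and far under the dynamic
rate.

## Known limitations

* The ten metrics are computed for binary, undirected graphs only; no
  weighted variants, proportional-density thresholding, or additional
  dynamic indicators (state clustering, dwell-time statistics).
* The shipped 68-ROI cortical mapping is a stylized, editable default for
  synthetic work; real analyses must supply the mapping that matches their
  parcellation.
* The permutation engine tests only the group main effect; threshold and
  interaction effects are parametric-only.
* Windowed CV estimates are biased upward by sampling noise that depends on
  window length; comparisons are therefore only meaningful within a fixed
  window plan, which the pipeline enforces by construction.
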