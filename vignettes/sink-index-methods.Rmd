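---
title: "Sink-index methods: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sink-index methods: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinkindex)
```

## The model

`sinkindex` treats a multichannel scalp EEG recording as the observable
state of a linear time-varying network. Within each short window of
duration $T$ the state vector $x(t) \in \mathbb{R}^N$ (one entry per
channel, $N = 19$ for the standard 10--20 montage) is assumed to evolve as

$$x(t+1) = A\,x(t) + e(t),$$

with $A \in \mathbb{R}^{N \times N}$ a state-transition matrix and
$e(t)$ white Gaussian innovation noise. Concatenating the per-window
least-squares estimates $\{A_1, A_2, \dots, A_M\}$ over non-overlapping
windows yields the subject's dynamic network model (DNM). Entry
$A_{ij}$ quantifies how channel $j$'s current activity drives channel
$i$'s next-step activity, so each row collects a channel's *incoming*
influence and each column its *outgoing* influence.

A **sink** is a channel that is strongly driven but drives little: large
row norm, small column norm. For each window the row norms
$rr_i = \lVert A_{i\cdot} \rVert_2$ and column norms
$cr_i = \lVert A_{\cdot i} \rVert_2$ (diagonal included — self-loops are
genuine dynamics) are ranked and normalized onto $\{1/N, \dots, 1\}$,
and each channel is scored by its proximity to the *ideal sink* at
$(rr, cr) = (1, 1/N)$:

$$\mathrm{SI}_i = c - \bigl\lVert (rr_i, cr_i) - (1, \tfrac{1}{N})
\bigr\rVert_2 .$$

With the default constant $c = \sqrt{2}$ the attainable range is
$[\sqrt{2}/N,\ \sqrt{2}]$, i.e. $[0.0744, 1.4142]$ at $N = 19$:

```{r}
sink_index_range(19)[c("min", "max")]
```

**On the constant $c$.** Definitions of this score circulate with the
additive constant printed as $2$, which would shift the attainable range
to $[2 - \sqrt{2}(1 - 1/N),\ 2] \approx [0.66, 2]$. Published displays
of the score, however, use a $0.00$--$1.44$ scale, and cohort-level
means near $1.34$ are only attainable under $c = \sqrt{2}$. We therefore
default to $c = \sqrt{2}$ and expose `eq2_constant` so either convention
can be reproduced exactly. Since the constant is a global shift it
changes no ranking, grouping or classification result — only the scale
of reported values.

Averaging $\mathrm{SI}$ over all valid windows gives one value per
channel per recording; averaging those over the frontal--temporal group
(Fp1, Fp2, F3, F4, F7, F8, T3, T4) and the central--parietal--occipital
group (O1, T5, O2, T6, Cz, Pz, P3, Fz, P4, C3, C4) and taking the FT/CPO
quotient yields the scalar **sink-index ratio**, the headline marker.
Fz sits in the CPO group deliberately: the grouping reproduces the
published electrode split verbatim rather than a purely anatomical one.

## Windowing and estimation choices

* **Window length.** $T = 125$ ms at 250 Hz is 31.25 samples; we take
  `floor` = 31 samples per window (30 regression pairs), non-overlapping,
  dropping a trailing partial window. The convention is explicit so
  reproductions at other rates can state theirs.
* **Conditioning.** 30 pairs against 19 unknowns per row is barely
  overdetermined. The default ridge term, $10^{-6}$ times the mean
  diagonal of the Gram matrix, stabilizes near-singular windows while
  perturbing well-conditioned fits at the $10^{-6}$ relative level;
  `ridge = 0` gives plain least squares, and a rank-deficient window then
  falls back to the minimum-norm (pseudo-inverse) solution and is
  flagged in `cond_flags`.
* **Degenerate windows** (e.g. flatlined segments) are skipped and
  excluded from the time average rather than zero-filled, so no
  fabricated dynamics enter the marker.
* Least squares on this model form is invariant to a common rescaling of
  all channels, so unit mismatches ($\mu V$ vs $mV$) cannot change the
  marker provided they are channel-uniform; per-channel calibration is
  honoured at ingest instead.

## Preprocessing

The chain mirrors standard resting-state practice: per-channel
demeaning, anti-aliased polyphase resampling to 250 Hz, a zero-phase
4th-order Butterworth band-pass 0.5--48 Hz, and zero-phase band-stop
notches (2 Hz wide) at 50 Hz and every harmonic below Nyquist (50 and
100 Hz at 250 Hz). Two realization details are ours, since order and
phase behaviour are usually left unstated:

* the band-pass is realized as a high-pass/low-pass cascade — a direct
  band-pass prototype with a lower edge at 0.004 of Nyquist is
  numerically fragile;
* filtering is forward--backward (zero phase), because phase distortion
  would bias the one-step regression that follows.

Artefact removal (ASR, ICA-based) is *not* reimplemented: the
`artefact_hook` slot of `preprocess_config()` accepts any
recording-to-recording function, so an external cleaning step can be
inserted when reproducing accession-scale analyses. The default is the
identity, and desk-scale results in this package therefore describe
*uncleaned* (synthetic) signals.

## The synthetic cohort generator

`make_planted_A()` constructs ground truth directly in the mechanism the
score measures: starting from a random sparse stable base matrix
(uniform 0.5 self-loops; off-diagonal couplings present with probability
0.5 and s.d. 0.08), a sink of strength $s$ is planted in channel $k$ by
scaling $k$'s off-diagonal column entries by $1 - s$ and rescaling its
off-diagonal row entries so that the row norm moves the fraction $s$ of
the way to 1.1 times the maximal row norm. Two details matter:

* the boost excludes the diagonal, because inflating the self-loop would
  inflate the channel's own column norm and partially undo the planting;
* the base couplings are deliberately dense-and-small rather than
  sparse-and-large, so base-matrix randomness concentrates the row and
  column norms and planted strength, not base noise, dominates the norm
  ordering. With sparser, larger couplings the norm spread of the base
  matrix itself is wide enough that weakly planted channels shuffle.

The final matrix is rescaled to spectral radius $\le 0.95$;
`simulate_recording()` then iterates the model from $x(0) = 0$ with a
2 s burn-in discarded. `generate_cohort()` plants FT-channel sinks in
FTD-like subjects, CPO-channel sinks in AD-like subjects and none in
HC-like subjects, with per-subject jitter of the planted strength.

Generator defaults are the study conditions the pipeline targets:
19 channels at 250 Hz, cohort sizes 23/36/29 (FTD/AD/HC), 12-minute
recordings, effect size 0.8, innovation s.d. 0.3 $\mu V$, subject jitter
10 %. What the generator does *not* emulate: 1/f spectra, alpha rhythms,
eye/muscle artefacts, volume conduction, nonstationarity beyond the
planted schedule. Passing tests therefore demonstrate that the pipeline
recovers planted linear network structure under Gaussian innovations —
not that real EEG satisfies the model.

## Problem sizes used by the test-suite

Tests and the acceptance checks scale the study conditions down to desk
size, as their documented problem sizes: cohorts of 10/10/10 subjects
with 15--20 s recordings (about 160 windows each) for ordering and
classification checks, 120 s single recordings for planted-strength
recovery (20 seeds), and $10^4$-sample windows for the noisy
least-squares consistency check. At these sizes the group-median ratio
ordering (FTD-like > HC-like > AD-like) held in 20 of 20 seeds, and
group separation is already statistically visible; the full-length
defaults only sharpen the averages.

Two test-design choices deserve a note:

* *Identifiability in noise-free oracles.* A decaying stable system
  excited only once loses rank along its trajectory, so noise-free exact
  recovery is checked on rotation-like systems (all eigenvalue moduli
  equal), which stay persistently excited without noise.
* *Null-calibration classifier.* Under label permutation,
  leave-one-out plug-in Gaussian discriminants (LDA/QDA/naive Bayes) are
  known to be pessimistically biased (the training mean shifts away from
  the held-out point), giving null micro-AUCs near 0.39 rather than 0.5.
  Chance-level checks therefore use the local kNN scorer, which is
  unbiased under the null; the bias is a property of LOOCV itself, not
  of this implementation.

## Baseline features

* **Band power**: squared FFT magnitudes of Hann-windowed 8 s segments
  (50 % overlap) averaged across the recording, summed in the delta
  (1--4), theta (4--8), alpha (8--12) and beta (12--30 Hz) bands; group
  means over FT and CPO and the per-band ratio. The classification
  feature is the alpha-band FT/CPO ratio. Segmented averaging is used
  for both spectral and time-frequency streams for symmetry, though a
  single whole-recording periodogram would also be defensible.
* **Time-frequency**: per 8 s window and channel, a 5-level dyadic
  wavelet decomposition (db4 default; sym4, coif2, haar selectable) with
  the Hjorth triplet (activity, mobility, complexity) on each detail
  subband, averaged over windows: $19 \times 5 \times 3 = 285$ features,
  reduced to 5 by PCA. The 285-feature composition is the only one
  consistent with the stated ingredient counts; we adopt it and flag it
  as interpretation. PCA is fitted inside each training fold only, a
  leakage control the original description leaves unstated.
* The wavelet transform uses periodic signal extension and hard-coded
  standard orthogonal filter banks (no wavelet package exists in the
  supported R dependency set); boundary conventions do not affect the
  Hjorth statistics of interest.

## Classification and statistics

Eight classifier families (LDA, QDA, kNN, naive Bayes, decision tree,
random forest, multinomial logistic, SVM) sit behind one interface; all
return per-class probability-like scores so one-vs-rest ROC curves can
be ranked. Evaluation is leave-one-out: $n$ folds, each subject tested
once; per-class ROCs come from the pooled scores, and the micro-averaged
ROC pools true/false-positive counts across classes at every threshold.
The confusion matrix and precision use the arg-max rule. `k_neighbors`
defaults to 2, surfacing a small-$k$ convention without asserting it as
canonical. Repeated LOOCV (default 8 repetitions with distinct seeds)
gives AUC/precision distributions for benchmark comparisons.

Group comparisons are nonparametric throughout: Mann--Whitney U
(reported as $U = \min(U_a, U_b)$, so complete separation prints
$U = 0$), Kruskal--Wallis with tie correction and $k-1$ degrees of
freedom, and Dunn's post hoc $z$ tests with Bonferroni correction over
the pairs actually compared. The exact Mann--Whitney path uses the
permutation distribution — closed form when tie-free, full enumeration
with ties when both samples have at most 12 observations and the
combination count is workable — and otherwise the tie-corrected normal
approximation. Published two-sided conventions vary; ours is documented
rather than inferred. Significance tiers: `***` $p<0.001$, `**`
$p<0.01$, `*` $p \le 0.05$ (boundary inclusive), else `n.s.`.

## Known limitations

* The linear one-step model is a deliberate simplification; sink scores
  summarize rank geometry of fitted matrices, not causal anatomy.
* Rank normalization makes SI insensitive to overall coupling scale —
  robust, but also unable to distinguish "all channels weakly coupled"
  from "all strongly coupled".
* The EDF and MAT-v5 readers cover the continuous single-trial layouts
  produced by common acquisition and EEGLAB exports; epoched datasets,
  big-endian MAT files and EDF+ discontinuous records are out of scope.
* Real-data cohort reproduction additionally requires the accession
  dataset and an external artefact-cleaning hook; desk-scale synthetic
  results cannot stand in for it.
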