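---
title: "From overnight polysomnography to ordinal risk groups: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From overnight polysomnography to ordinal risk groups: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnotype)
```

somnotype implements a complete pipeline for stratifying patients by the
physiological content of an overnight sleep study (polysomnogram, PSG):
signal preprocessing, self-supervised-style epoch embeddings from a
multi-task transformer, distributional-distance clustering of whole-night
embedding matrices into ordinal risk groups, a spectral sleep-fragmentation
statistic, gradient-boosted prediction of cluster membership from standard
summary metrics, and propensity-weighted survival analysis of the resulting
groups. Because clinical PSG registries are access-restricted, the package
ships a synthetic cohort generator with planted group structure; every
stage of the pipeline is exercised and tested against it.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated. Two layers are simulated independently.

**Recordings.** A hypnogram is a first-order Markov chain over
{W, N1, N2, N3, REM} at one state per 30-s epoch. The per-epoch switch
probability is `stage_transition_rate / 120` (the rate is expressed in
expected switches per hour); on a switch the next stage is drawn from a
depth-adjacent proposal kernel, so deep sleep is reached through N1/N2
rather than by teleporting from wake. Respiratory, desaturation, and
arousal annotations are homogeneous Poisson processes restricted to sleep
epochs — the simplest generative model consistent with the semantics of
the apnea-hypopnea index (AHI = events per hour of sleep) — with durations
uniform on 10–60 s (3–15 s for arousals). Signals are synthesized per
channel class with stage- and event-dependent structure: EEG delta
amplitude rises from wake to N3 and an alpha component marks wake; EMG
tone collapses in REM; respiratory channels are a 0.25 Hz breathing
oscillation whose amplitude drops by 85% during respiratory events; SpO2
dips by 4–9% during desaturation annotations. These signals are
caricatures: they carry the class-conditional structure the downstream
model is supposed to discover, but no realistic EEG microstructure, EKG
morphology, or apnea subtypes. A passing end-to-end test therefore shows
that the pipeline recovers planted distributional structure — not that it
would reproduce any particular clinical result.

**Subjects.** Survival outcomes follow an exponential proportional-hazards
model: subject $i$ in group $g$ dies at rate
$\lambda_0 \exp(\beta_g + x_i^\top\gamma)$, with the reference group fixed
at $\beta_1 = 0$ and covariate effects $\gamma$ zero by default (but
configurable, so adjusted and unadjusted fits are distinguishable).
Censoring is the minimum of an independent exponential and an
administrative horizon (default 15 years, matching a long-running clinical
registry). Proportional hazards holds by construction, which is what makes
parameter-recovery tests meaningful. Default group proportions for five
groups are (0.38, 0.22, 0.18, 0.14, 0.08): a large low-risk reference and
a small high-risk tail. Covariates (age, sex, BMI, six cardiometabolic
comorbidities, AHI, PAP prescription, years of prior medical history) are
drawn from fixed, realistic marginal distributions.

## Preprocessing

All channels are resampled to a common 128 Hz (windowed-sinc rational
resampling, symmetric kernel, cutoff at the lower Nyquist frequency) and
filtered with elliptic IIR designs: order 16, at most 1 dB passband
ripple, at least 40 dB stopband attenuation, as *single-pass* targets —
filters are applied forward and backward for zero phase, which squares the
magnitude response and doubles attenuation in dB. Cutoffs per channel
class: EEG/EOG band-pass 0.3–45 Hz; EMG high-pass 10 Hz; EKG high-pass
0.3 Hz; nasal pressure high-pass 0.1 Hz; airflow and effort belts
band-pass 0.1–15 Hz; SpO2 unfiltered. Snore and EtCO2 have no published
specification and are assigned the airflow band-pass — an explicit
assumption.

"Order 16" is read as the *total* filter order (a band-pass is realized
from an order-8 low-pass prototype). An order-16 elliptic transfer
function is numerically unusable in polynomial (b, a) form, so the design
is kept in zero-pole-gain form — the analog Cauer prototype and the
low-pass-to-band-pass/high-pass transforms come from the `signal`
package — and realized as cascaded second-order sections, poles ordered by
radius and paired with their nearest zeros. Amplitudes are then normalized
so the 5th and 95th percentiles map to −1 and +1 (a robust range
normalization), except SpO2, which is mapped fixed: 60% → −1, 100% → +1.
Degenerate channels (5th = 95th percentile) are zeroed with a warning
rather than amplified.

## The epoch-embedding transformer

Each 30-s epoch at 128 Hz is cut into ten non-overlapping 3-s patches per
channel (384 samples each), projected by a single shared linear layer into
the model dimension. Per channel, the ten patch tokens are followed by a
learned SEP delimiter; one learned CLS token closes the sequence, so a
C-channel epoch is a sequence of 11C + 1 tokens. Learned absolute position
embeddings supply channel identity (a design choice; per-channel
projections would be the alternative). The encoder is a standard
post-layer-norm transformer (multi-head attention, GELU feed-forward,
residual connections), the convention of the RoBERTa family. The CLS
output feeds three linear heads: 5-class sleep stage (softmax
cross-entropy), respiratory-event flag and desaturation flag (one logit
each, binary cross-entropy). The training loss is the *arithmetic mean* of
the three task losses; the optimizer is Adam.

Supervision labels come from the technologist-style annotation rule: an
epoch is flagged for an event type when annotations of that type overlap
it by at least five seconds in total. The rule is applied per epoch to raw
intervals (events longer than 30 s flag every epoch they cover by ≥ 5 s).
The stage head includes wake by default; hypnograms contain wake and total
sleep time needs it, even though evaluation discussions sometimes list only
the four sleep stages. Setting `stage_classes = 4` masks wake out of the
staging task: wake epochs receive no stage code and are excluded from
training batches.

The desk-scale default configuration — 64 dimensions, 2 layers, 4 heads,
batch 128, learning rate 1e-3, 5 training epochs — trains from scratch in
minutes on one CPU. The learning rate deserves a note: fine-tuning a large
pre-trained backbone is done at rates around 1e-5, but a small model
trained from scratch for a few epochs needs a larger step to move at all;
1e-3 is the standard Adam default regime for this size. The full-scale
768-dim / 12-layer configuration is constructible with the same fields but
is never trained in the test suite. Forward and backward passes are
hand-written in C++ (RcppArmadillo); the analytic gradients are verified
against central finite differences in the test suite, which is the
load-bearing correctness check for everything the model does.

An *embedding matrix* for a recording stacks the per-epoch CLS vectors
into an `embed_dim` × `n_epochs` matrix. Epoch counts differ between
recordings, which is the whole reason for the distributional machinery
below.

## Distributional distances and consensus clustering

Two recordings' embedding matrices cannot be compared elementwise when
their epoch counts differ. Instead, for each embedding dimension the two
time series are treated as unordered samples and compared with a
distance between distributions; the per-dimension distances are averaged.
(The transpose reading — comparing fixed time points across recordings —
is impossible for unequal lengths and is rejected.) Two metrics are
implemented:

* **Energy distance**: $2\,\mathbb{E}|X-Y| - \mathbb{E}|X-X'| -
  \mathbb{E}|Y-Y'|$ over all ordered pairs including self-pairs, computed
  with O(n log n) sorted-sample identities.
* **1-D earth mover's distance**: the L1 area between the empirical CDFs.

Both are validated against literal brute-force double-sum /
quantile-integral oracles to 1e-12, are symmetric, vanish on identical
multisets, and scale linearly under positive rescaling of the embeddings.

Each sample's feature vector is its row in the full pairwise distance
matrix ("projection onto all samples"; the zero self-entry is retained so
rows have equal length — it is harmless to k-means). k-means (10 restarts,
300 iterations, seeded) runs on these feature vectors; partition quality
is the mean silhouette, with conventions fixed for degenerate cases:
singleton clusters and all-identical points score 0, and zero
within-cluster distance with positive separation scores 1.

Stability is assessed with a consensus matrix: 100 iterations, each
drawing 80% of samples *and* 80% of feature columns without replacement,
re-running k-means, and recording co-assignment. The consensus value of a
pair divides by the number of iterations in which the pair was *co-sampled*
— not by the total iteration count — so rarely co-sampled pairs are not
deflated; pairs never co-sampled are reported as 0 with a zero count flag
(at 100 iterations and 80% subsampling the probability of that is
negligible for N ≥ 20). The matrix is ordered by Ward hierarchical
clustering (`ward.D2` on 1 − consensus) for heatmap rendering.

Clusters become *risk groups* a posteriori: clusters are sorted by crude
all-cause mortality (deaths per person-year) ascending and labeled RG1
(lowest risk) through RGk, ties broken by cluster id. A flow table across
the k = 2..5 solutions (the data behind a Sankey diagram) tracks how the
high-risk group persists across solutions.

## Sleep fragmentation

The hypnogram, encoded numerically and mean-removed, is treated as a time
series at 1/30 Hz and its periodogram computed; *sleep fragmentation* is
the fraction of spectral power at frequencies above 1/600 Hz — stage
transitions faster than 10 minutes. The encoding is an ordinal depth scale
(W = 0, N1 = 1, N2 = 2, N3 = 3, REM = 1.5) and is configurable, since the
statistic is invariant to affine but not arbitrary re-encodings; a
binarized transition-indicator variant (invariant to any relabeling) is
available, with the encoded-hypnogram variant as the asserted default.
A plain rectangular-window periodogram is used rather than an averaged-
segment estimator: hypnograms are short (a few hundred samples) and the
statistic is a band-power *ratio*, so the periodogram's variance largely
cancels. The cutoff bin is assigned by strict comparison (f > 1/600 Hz).
Anchor cases pin the definition: a constant hypnogram scores 0; an
every-epoch alternation (a single spectral line at 1/60 Hz) scores 1; a
40-minute square wave keeps > 80% of its power in the fundamental and
third harmonic below the cutoff and scores < 0.2.

## Predicting clusters from summary metrics

A gradient-boosted tree classifier (xgboost: 300 trees, depth 4, learning
rate 0.1, single thread, seeded) predicts cluster membership from the
summary-metric table (TST, stage percentages, AHI, arousal index, SpO2
summaries, fragmentation). Features are ranked by total gain; the model is
refit on the top-1 and top-5 features, and held-out accuracy is reported
for each under a stratified 80/20 split. Accuracy is plain top-1
classification accuracy.

## Outcome analysis

Eligibility for each outcome requires at least five years of pre-study
medical history and no prevalent occurrence of the outcome. Six Cox
proportional-hazards models probe robustness: (1) unadjusted; (2) age,
sex, BMI; (3) plus six comorbidities (hypertension, type-2 diabetes, heart
failure, atrial fibrillation, coronary artery disease, hyperlipidemia);
(4) plus AHI; (5) model 3 excluding PAP-prescribed patients; (6) model 3
restricted to age ≥ 55. The exposure is the ordinal risk group (reference
RG1), or, for the sensitivity analysis, AHI severity bands (normal < 5,
mild 5–<15, moderate 15–<30, severe ≥ 30; reference normal). Ties use the
Efron approximation (the lower-bias default; the data are continuous, so
the choice rarely matters). Wald 95% CIs are reported; a group with zero
events is flagged as having an unbounded interval. A Schoenfeld-residual
global test of proportionality is attached to every fit as an advisory
diagnostic at α = 0.05, never as a gate.

Propensity weights are stabilized inverse probabilities from a multinomial
logistic model of group on age, BMI, sex, the comorbidities, and history
years: $w_i = \hat P(G = g_i) / \hat P(G = g_i \mid x_i)$. Weights are
trimmed at their empirical 5th and 95th percentiles — by default *clipped*
to the percentile values, which preserves the analysis sample size; an
exclusion variant is available. Weighted Cox and Kaplan-Meier fits use
robust (sandwich) variances. Kaplan-Meier disease-free survival is
evaluated at 2, 4, and 6 years with pairwise log-rank tests against the
reference group; under weighting, the pairwise test is the robust score
test of the corresponding weighted Cox fit.

## Problem sizes, numerical choices, limitations

The test suite validates the pipeline at deliberate desk scale: the
end-to-end study uses 200 recordings of 240 epochs (2 h) over three
channels (C4, nasal pressure, SpO2), a 64-dim 2-layer model trained 5
epochs, and requires adjusted Rand index ≥ 0.9 against the planted
regimes; survival parameter recovery uses cohorts of 2 000–7 000 subjects
with hazard ratios planted at published-magnitude values (1.43–2.38
adjusted gradient; 4.83 unadjusted two-group split) and checks that fitted
CIs cover the planted truth; null calibration uses 200 simulated null
cohorts for log-rank uniformity and 100 for CI coverage. These sizes make
the Monte-Carlo error small relative to the assertions without requiring
cluster hardware.

Known limitations: the synthetic signals are spectral caricatures, so
classification F1/AP values on them say nothing about clinical
performance; the generator plants regimes whose *within-regime*
composition is moderately homogeneous, whereas real sleep studies vary
continuously; consolidated-sleep recordings have genuinely variable stage
composition at 2 h, which is why the end-to-end study uses recordings long
enough for stage mixtures to stabilize; the trained-from-scratch model
replaces the fine-tuned pre-trained backbone a production system would
use (a weight-loading hook exists but no pre-trained weights ship);
competing risks, time-varying covariates, and multiplicity correction
across outcome panels are out of scope.
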