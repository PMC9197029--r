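---
title: "Priority-based transformations in working memory: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Priority-based transformations in working memory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmpriority)
```

## The scientific question

In a 2-back continuous-performance task, every remembered item passes
through a predictable sequence of functional states. When item $n$ is
presented it is a *probe*, compared against item $n-2$. During the next
delay it is an *unprioritized memory item* (UMI): it must be retained but
must not interfere with the imminent $n-1$-vs-$n+1$ decision. After that
decision it becomes the *prioritized memory item* (PMI), the template for
the upcoming comparison with $n+2$. A central hypothesis about
prioritization is that the neural code of an item is actively
*transformed* — possibly reversed — as its priority status changes, rather
than merely attenuated.

`wmpriority` implements a complete, testable pipeline for this question:
it trains small LSTM networks on the 2-back task, extracts their
hidden-state dynamics, identifies stimulus- and decision-specific
subspaces with a reduced-rank-regression form of demixed PCA, and
quantifies the transformation with a scalar-transform trace, subspace
alignment angles, and a bootstrap test for the disappearance of stimulus
information. A synthetic EEG-like generator with planted ground truth
exercises the identical millisecond-resolution code path that channel data
would follow.

## Task and sequence generation

Blocks are sequences of 20 stimuli drawn uniformly from six identities.
Position $p \ge 3$ is a *match* when the identity equals that at $p-2$; a
20-stimulus sequence therefore has 18 match-eligible positions. To mimic
the roughly 1:2 match:non-match ratio of the human task, whole sequences
are rejection-sampled until at least 5 matches occur. Conditional on
acceptance, the match count follows a truncated Binomial$(18, 1/6)$
distribution with mean $\approx 5.55$, which the generator reproduces
(`sequence_match_stats()`); the test suite checks this against an
enumeration oracle.

Each stimulus presentation is followed by two all-zero "delay" timesteps
(none after the last stimulus), so a 20-stimulus block spans
$3 \times 19 + 1 = 58$ timesteps. Three input encodings are provided:
one-hot (6 units), circular `[cos 2θ, sin 2θ]` (2 units; the doubled angle
matches the 180° periodicity of oriented gratings), and a graded
$\sin^6$ basis-function code. The target output is 1 at the presentation
timestep of a match and 0 elsewhere. Targets at delay timesteps and at the
first two presentations (which have no 2-back comparison) are set to 0:
the loss is averaged over *all* timesteps, so a target must be defined
everywhere, and 0 is the output's resting level. This is a modeling choice
— only targets during presentations are dictated by the task.

A *trial* tracks one item across two consecutive stimulus events, from its
presentation through the second delay and the decision at $n+2$. Of the 18
trials in a block, 16 are analyzed (items presented at positions 3–18;
earlier positions lack a decision of their own). `label_trials()` returns
a 13-timestep window per trial: three pre-presentation timesteps (used as
a no-information baseline by the dispersion test), the 9-timestep core
(`n`, `d1.1`, `d1.2`, `n+1`, `d2.1`, `d2.2`, `n+2`, `d3.1`, `d3.2`), and
the presentation of $n+3$. The last trial of a block has no third delay;
those cells are `NA` and are excluded from averages.

## Network model and training

The model is a single-layer LSTM (7 hidden units with one-hot inputs, or
60 with circular inputs) whose hidden state is linearly rectified and read
out by a linear layer to one output unit. Training minimizes the mean
squared error between output and target across all timesteps with Adam
(learning rate $10^{-3}$, $\beta = (0.9, 0.999)$, $\epsilon = 10^{-8}$),
drawing 20 of the 200 training sequences with replacement each iteration —
5000 iterations for 7-unit networks, 1500 for 60-unit. All parameters are
initialized uniformly on $(-1/\sqrt{H}, 1/\sqrt{H})$ (the standard fan-in
scheme for LSTM layers), and the initial recurrent state is zero. The
forward pass, backpropagation through time, and Adam are implemented in
compiled code (RcppArmadillo); training a 7-unit network takes a few
seconds on one CPU core.

Two seeds govern a run: `init_seed` (weight initialization) and
`batch_seed` (mini-batch sampling). An ensemble shares training/testing
sequences, hyperparameters, and `batch_seed`, so its members differ *only*
in initialization. A network "passes" when its held-out accuracy on 200
fresh sequences reaches 99.5%, where a response is correct if the output
is strictly within 0.5 of the target at a decision timestep (presentations
from position 3 on). In our hands roughly 25–50% of initializations reach
criterion after 5000 iterations (the remainder plateau lower), so
`train_ensemble()` keeps training with successive seeds until the
requested number pass; the attempt cap is configurable.

The analyzed "activity" is the raw LSTM hidden state $h_t$, before the
readout rectification (which we regard as part of the readout); a
`rectified = TRUE` switch records $\max(h_t, 0)$ instead. With 200
training sequences, `record_hidden_activity()` yields the standard
$16 \times 200 = 3200$ trials.

## Demixed PCA by reduced-rank regression

Let $x^s_t$ be the trial-averaged activity for condition $s$ at time $t$
inside a fitting window, $\bar x_s$ its time average, and $\bar x$ the
global mean over all trials and timepoints. The stimulus (UMI or PMI) dPCs
are the rank-2 encoder/decoder pair minimizing

$$\sum_{s,t} \left\| (\bar x_s - \bar x) - V W^\top (x^s_t - \bar x) \right\|^2,$$

i.e. they capture activity fluctuations attributable to the remembered
stimulus and stable over the window. This is reduced-rank regression and
is solved in closed form: the ordinary least-squares map
$B = Y X^{+}$ followed by an SVD of the fitted values $BX$; the encoder
$V$ takes the top-2 left singular vectors (unit norm by construction) and
the decoder $W = B^\top V$ absorbs the scale. The decision dPCs replace
the target by the decision-specific fluctuation
$x^{s,d}_t - \bar x^{s}_t$, with $\bar x^s_t$ the unweighted mean of the
match and non-match cell means for probe condition $s$.

Fitting windows follow the convention that memory subspaces are defined
late in a delay: the second delay timestep (`d1.2` for the UMI, `d2.2` for
the PMI) and the probe presentation (`n+2`) for network data; the
half-open intervals $[-1400, 0)$ ms (UMI), $[2150, 3550)$ ms (PMI), and
$[200, 700)$ ms (decision) relative to stimulus $n+1$ onset for
millisecond data, with all timepoints in a window pooled as samples.
Projections are $z = W^\top (x - \bar x)$ with the global mean stored at
fit time.

Per-component percent variance explained (PEV) is reported against both
the raw centered data ("global") and the marginalized targets
("stimulus"), together with cumulative top-2 values; trained networks
concentrate 97–99% of stimulus variance in two dPCs.

Numerical choices: singular or exactly collinear least-squares systems
(routine for single-timepoint fits on six conditions) are handled by a
pseudoinverse with relative cutoff $10^{-10}$; no ridge regularization is
applied by default, but a `ridge` argument is exposed for noisy channel
data. Components are ordered by descending marginalized PEV, and each
encoder column's largest-magnitude coordinate is made positive (decoder
flipped jointly) — the objective is sign- and order-invariant, and tests
need determinism. If the marginalized variance supports fewer directions
than requested, the remaining encoder columns are an arbitrary orthonormal
complement carrying near-zero decoder weight.

## Scalar-transform trace

To characterize how the stimulus geometry evolves, the early first-delay
condition means $\bar x_s$ (timestep `d1.1`, or $[-2800, -1400)$ ms)
define a reference, and at every timepoint the best scalar $k$ mapping the
reference onto the current geometry inside a fixed subspace is

$$\hat k_t = \frac{\sum_s \langle a_{ts}, b_s \rangle}{\sum_s \|b_s\|^2},
\qquad a_{ts} = W^\top (x^s_t - \bar x_t), \quad
b_s = W^\top (\bar x_s - \bar x),$$

with $\bar x_t$ the across-condition mean at $t$, so only the *relational*
geometry matters. $\hat k \approx 1$ means the code is unchanged; a sign
reversal means the stimulus-activity mapping has flipped. The closed form
is checked against a 1-D numerical minimization oracle. The reported zero
crossing is the first sign change at or after the trace's peak — ignoring
near-zero jitter before the representation is established — with linear
interpolation additionally reported for millisecond data. In passing
7-unit ensembles, $\hat k$ in the UMI subspace stays near 1 through the
first delay and reverses sign across the second delay, with the crossing
at `d2.1`–`d2.2`; 60-unit ensembles show the same pattern in most, but not
all, initializations (some instead rotate the code into a new plane
without an in-plane reversal — solution geometry is an emergent property
of training and varies with initialization and sequence set).

## Subspace alignment

The relationship between two fitted planes is summarized by the
product-of-cosines alignment of corresponding unit-norm encoder columns,
$|v_1^a \cdot v_1^b|\,|v_2^a \cdot v_2^b|$, mapped to an angle by the
inverse cosine (0° aligned, 90° orthogonal). Note this metric depends on
the component *bases*, not only on the planes; basis-invariant principal
angles are available as an internal diagnostic (`principal_angles()`) and
are what the synthetic recovery tests assert on. In our trained 60-unit
ensembles the decision plane overlaps substantially with the PMI plane
(~35°) while the UMI plane is nearly orthogonal to both the decision plane
(~87–90°) and the PMI plane (~89°) — the configuration expected if the
unprioritized code is kept out of the way of ongoing processing.

## Bootstrap dispersion test

To decide whether a timepoint still carries stimulus information in the
PMI subspace, the *dispersion* — the sample variance across the six
projected condition means, summed over the two projection dimensions — is
compared against an empirical null built from timepoints that cannot
contain information about the item: the three timesteps preceding its
presentation. Each of the (by default 10,000) bootstrap iterations
resamples trials with replacement within each stimulus condition, refits
the PMI dPCA on the resampled data (global mean recomputed from the
resample), and records the *maximum* dispersion over the three baseline
timepoints, making the null conservative. A test timepoint is declared
informative when its full-data dispersion exceeds the null's 95th
percentile (one-tailed). Observed values use the full-data fit; bootstrap
fits serve only the null. On passing networks, information about an item
typically persists for one timestep after its final use and is
undetectable thereafter; on pure-noise synthetic data the flag rate stays
at or below the nominal level.

Aggregation of the two projection dimensions is not uniquely determined by
the verbal definition of dispersion ("the variance of the projected
condition means"); we sum the per-dimension sample variances, which equals
the trace of the projected covariance and is invariant to the in-plane
basis.

## Synthetic EEG-like generator

`generate_synthetic_dataset()` produces trial-epoched, 60-channel data on
a 50 ms grid from $-2800$ to $3550$ ms around stimulus $n+1$ onset —
the layout of trial-aligned scalp recordings from the human version of the
task (one stimulus event lasting 3550 ms, 1:2 match ratio, six orientation
conditions entering only through $[\cos 2\theta, \sin 2\theta]$). Each
trial is a sum of planted low-rank signals plus i.i.d. (optionally AR(1))
Gaussian channel noise:
a UMI plane carrying the current item with gain $g_{\mathrm{UMI}}(t)$
(ramps in early, holds at 1, declines after probe onset, crosses zero at
$\approx 1077$ ms, fades); a PMI plane carrying the previous item before
probe onset and the current item after (ramping to 1 by 2150 ms); and a
decision plane active over $[0, 900]$ ms whose code rotates through the
window so that decision variability genuinely spans two dimensions. The
three planes are isoclinic pairs at configurable angles, by default
84°/81°/35° (UMI–PMI / UMI–decision / PMI–decision), mirroring the
geometry of trained networks; the third angle must lie within the
feasible range implied by the other two. Default trial count is 80 per
condition (the order of a human session) and default noise SD is 0.25,
which leaves single-trial SNR low but condition averages usable.

What passing tests on these data do show: the pipeline recovers planted
planes (pairwise-angle error well under 5°), planted gain trajectories
($r > 0.95$, zero crossing within one bin when planes are orthogonal),
and a calibrated dispersion null. What they do not show: anything about
volume conduction, electrode geometry, artifacts, autocorrelated
physiological noise beyond AR(1), inter-subject heterogeneity, or
preprocessing — real scalp data are far harsher. One deliberate property:
with oblique planted planes, the PMI gain leaks $\cos(\angle)$ of itself
into the UMI projection, biasing the recovered zero crossing late by a few
tens of ms; the crossing-recovery test therefore uses the orthogonal
configuration, and oblique-geometry results should be read with this in
mind.

## Orchestration and problem sizes

`run_experiment()` executes the three study configurations (`rnn7`,
`rnn60`, `synthetic_eeg`) end to end from one master seed, which fans out
to per-stage seeds through a seeded draw; deterministic stages are
byte-reproducible given the seed. Reports carry sequence statistics,
per-attempt accuracies, PEV tables, alignment angles with ensemble SD,
scalar-trace means with SEM, and the dispersion report; CSV tables are the
canonical outputs. The package exposes no shell entry point — the R
functions and this vignette are the interface.

The test suite trains 5-network ensembles per architecture and reduces
bootstrap draws (hundreds rather than 10,000) and calibration replicates;
`scripts/acceptance.R` uses 10-network ensembles and the full sequence
replication. These sizes were chosen so a complete run stays in the
minutes range on a single core while leaving ensemble means stable to the
tolerances asserted.

## Known limitations

* Solution geometry is emergent: the share of initializations that reach
  the 99.5% criterion, the fraction of 60-unit networks showing an
  in-plane sign reversal, and the exact UMI–decision angle all vary with
  initialization and with the shared sequence set. Our ensembles place the
  UMI–decision angle at ~87–90°.
* The product-of-cosines angle is basis-dependent; cross-study comparisons
  should bear in mind that equal planes with rotated component bases do
  not score 0°.
* The generator's planted structure is linear and low-rank by design;
  it validates the estimators, not the biology.
* Only single-layer LSTMs are implemented; no GPU support.
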