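---
title: "Methods: pairwise entropy, coding efficiency and the two-neuron LIF model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise entropy, coding efficiency and the two-neuron LIF model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neff)
```

This vignette is the package's account of its science: what the binary
population code assumes, how each estimator is defined and corrected, why
the open design choices were settled the way they were, and what the
synthetic data can and cannot stand in for.

## The binary population code

Trial-structured spike trains (1 ms resolution, time zero at stimulus
onset) are reduced to one bit per neuron, trial and analysis time: the
state is 1 when the spike count in a half-open window $[t - W/2, t + W/2)$
*strictly* exceeds that neuron's across-trials mean count. The strict
inequality is deliberate: with a non-integer mean ties are impossible, and
in the degenerate all-equal case every state is 0 rather than an arbitrary
split.

Two assumptions matter. First, trials are exchangeable within a condition
— the across-trials mean is a meaningful reference. Second, what carries
information is the trial-by-trial fluctuation around that reference, not
the mean rate itself. For very short windows the state is essentially
"was there a spike", and its probability $p_1$ tracks the firing rate
monotonically; for longer windows $p_1$ reflects the skewness of the count
distribution. For an exactly Poisson count with mean $\mu$ the theoretical
curve is $p_1 = P(N > \mu) = 1 - F(\lfloor\mu\rfloor)$
(`expected_poisson_p1()`), which approaches $1/2$ as the distribution
symmetrises but is *sawtoothed*: each integer crossing of $\mu$ moves the
effective threshold by one count. This matters repeatedly below.

**Threshold pool.** Whether the reference mean should pool GO and NOGO
correct trials or be computed per condition is genuinely open. The default
pools all correct trials (`pool = "all_correct"`), so that binarization
itself cannot manufacture condition information; `"per_condition"` is
available, and the two differ only where evoked rates move the pooled
mean. Note one consequence of pooling: at post-stimulus times the pooled
threshold absorbs the GO-evoked counts, so even statistically stationary
NOGO trials shift their operating $p_1$ there. Analyses that need NOGO
stationarity across times should use per-condition pooling.

## Window selection by stimulus information

`select_window()` computes, per neuron and per (window, time) point, the
plug-in mutual information between the binary state and the stimulus label,
subtracts a shuffle bias (mean over 30 label permutations — enough to
estimate a bias that is itself only a second-order quantity), averages the
*corrected* values over neurons and times, and returns the shortest window
reaching 80% of the best $\langle I\rangle$. Correction-before-averaging
was chosen because the bias depends on per-neuron occupancy; averaging raw
values first would mix biases of different sizes. Grid defaults are 20 ms
steps for $W \in [0.1, 0.6]$ s and 50 ms steps for $t \in [0, 0.5]$ s —
fine enough that a 320 ms optimum is representable. Corrected information
may be slightly negative; it is not clipped (the raw value is non-negative
by construction and is clamped only against floating-point dust).

## Pairwise entropy, correlation and bias

A binary pair is fully described by $(p_{1i}, p_{1j}, p_{11})$ subject to
the Fréchet bounds $\max(0, p_{1i}+p_{1j}-1) \le p_{11} \le
\min(p_{1i}, p_{1j})$. Entropy and correlation use the closed forms over
the four cell probabilities, with $0\log 0 := 0$; the test suite verifies
both against their definition-level forms (explicit state summation;
trial-sum Pearson) to $10^{-12}$. Entropy is maximal (2 bits) only at
$(\tfrac12, \tfrac12, \tfrac14)$, and — important later — at *fixed
marginals* it is maximal at independence, $p_{11} = p_{1i}p_{1j}$.

Plug-in entropies are corrected by the first-order analytic bias term
$(\bar R - 1)/(2N\ln 2)$, added to the estimate (the plug-in estimator is
biased downward), with $\bar R$ counted naively as the number of occupied
cells. At the trial counts the pipeline targets (tens to a couple of
hundred trials) the correction is a few percent of the raw value. Entropy
differences are computed corrected-at-both-times; when trial counts and
occupancy match at the two times the corrections cancel exactly, so the
alternative (correcting the difference) coincides to first order.

## Efficiency and its bootstrap

Efficiency is the OLS slope of $\Delta H^{ij}$ on
$\Delta p_{1ij} = \Delta p_{1i} + \Delta p_{1j}$ across pairs, between a
baseline time ($t_0 = -1$ s) and an analysis time ($t_1 = +0.5$ s), with
an intercept (a slope-only variant is available via `intercept = FALSE`).
The 95% CI is a percentile bootstrap over pairs (default 1000 resamples).
Pairs are not independent — they share neurons — so the bootstrap CI is an
approximation that understates correlation between pairs; this is the
standard practice the analysis follows, not a claim of exactness.

Two analytic facts shape what efficiency can show on synthetic data.
Under stationarity, sampling noise in $\hat p_1$ moves $\Delta H$ and
$\Delta p_{1ij}$ together along the entropy surface's *tangent*, so the
regression sits near $h'(p_1)$ (the binary entropy derivative) — a
positive "noise slope", not zero. Genuine rate modulation moves pairs
along *chords* of the concave entropy curve, which lie below the tangent.
Hence independent rate gains alone lower the efficiency slope relative to
the stationary band; an efficiency *rise* requires coordinated changes in
the coincidence structure. That is precisely the question the surrogate
null addresses, and the reason the package's tests assert a post-onset
*departure* of the GO regression rather than a rise.

## The coincidence-permutation surrogate

Each pair's stimulus-period coincidence is summarised by
$f = p_{11}/(p_{1i} p_{1j})$. A surrogate permutes the $f$ values among
the pairs of the same session (never across sessions) and rewrites
$p_{11}^\ast = f_{\text{perm}}\, p_{1i} p_{1j}$; baseline triples and all
marginals are untouched, so every $\Delta p_{1ij}$ is preserved exactly
and only $\Delta H$ moves. With 1000 surrogates the one-sided empirical
p-value uses the $(r+1)/(n+1)$ convention (never exactly zero); one-sided
because the scientific hypothesis is that the observed arrangement is
*more* efficient than chance. Numerical choices:

* a permuted $f$ can imply an infeasible $p_{11}^\ast$; it is clipped to
  the nearest Fréchet bound and the clip rate reported (clipping slightly
  breaks the $f$-multiset invariance, which is exact whenever no clip
  occurs);
* sessions contributing a single pair can only permute to themselves and
  are flagged;
* degenerate marginals give undefined $\rho$; those pairs are dropped from
  the $\rho^\ast$ mean only.

## The end-of-trial control

`event_split_analysis()` sorts correct trials by the sign of the
population rate change between a baseline window and a window at a
task-unrelated event, then compares per-pair $\Delta H$ between the
Increasing and Decreasing groups (exact two-sided sign test) and the
groups' efficiency slopes (bootstrap CI overlap). One subtlety is
inherent to the design: because the split uses the same counts that the
states are built from, regression-to-the-mean selection couples the
groups' entropy changes to the sort even when the event modulates
nothing. The control's value is therefore the *contrast* it provides:
entropy changes follow any rate sorting, while the efficiency slopes of
the two groups remain compatible — so an efficiency effect at the
reward-predicting cue is not explained by generic rate changes.

## What the synthetic generator emulates

`synthetic_spec()` defaults define the study conditions: 20 neurons per
session, 60 trials per condition, 5 Hz mean baseline with a lognormal
spread across neurons (sdlog 0.5 — cortical rate distributions are
right-skewed), a sustained 1 s tone doubling the rate of tone-excited
neurons in GO trials, a minority-responsive population (30% excited,
12.5% suppressed), weak pairwise correlations from a shared mother
Poisson process (thinning probability 0.2), 85% behavioural performance,
and an end-of-trial relay event at +3 s. These were chosen once, as a
realistic low-rate PFC regime, and are not tuned per analysis.

The correlation mechanism is the standard thinning construction: one
stationary mother process at the session-mean baseline rate per trial;
each neuron keeps each mother spike with probability $a$ and fills up
with an independent inhomogeneous process at its own profile minus the
shared component. Marginal rates follow each neuron's profile; the
binary-state correlation rises monotonically with $a$ and vanishes at
$a = 0$.

What the generator does **not** emulate — and therefore what green tests
do not certify about real recordings: non-Poisson count dispersion
(refractoriness, bursting), rate drift across a session, condition-
dependent correlation changes, and any *intrinsic* coupling between
behavioural performance and entropy (the performance field is a parameter,
so the performance–entropy regression on synthetic sessions measures the
pipeline, not a biological effect). The Poisson sawtooth in
$p_1(\mu)$ also makes some rate-driven signatures (e.g. the $p_1$–rate
Spearman correlation at a 320 ms window) weaker and noisier than in real,
overdispersed data; analyses that need a monotone $p_1$–rate regime use
short (100 ms) windows where per-window counts stay sub-integer.

## The two-neuron LIF model

Between inputs each membrane obeys $\tau\,dV/dt = E_\text{rest} - V$
($\tau = 10$ ms, $E_\text{rest} = -70$ mV), integrated by forward Euler at
$dt = 0.1$ ms; crossing $-55$ mV emits a spike and resets to $-80$ mV, with
no refractory period (none is part of the model). Synapses are
*delta-pulse*: each afferent spike instantaneously shifts the membrane by
$w_\text{Ex} = +10$ mV or $w_\text{Inh} = -20$ mV, each partner spike by
$W_r$ (one-step delay), and simultaneous inputs add linearly. Under this
reading the membrane resistance in the current-based equation is inert —
no continuous current is ever integrated — which also sidesteps its
ambiguous printed units. Afferents are 400 excitatory plus 100 inhibitory
independent Poisson sources per neuron; a common pool of 40 (split 32/8 to
preserve the 4:1 ratio, the composition being otherwise unconstrained)
drives both neurons, and per step each branch delivers a Poisson count
with mean $N\lambda\,dt$ — exact for independent Poisson afferents — with
the common branch drawn once. The integrator is Rcpp-compiled; identical
configurations and seeds give identical spike counts, and the free
membrane relaxation matches the closed-form exponential to the first-order
Euler error $\sim dt/(2\tau)$.

Whole-trial (300 ms) counts are binarized with the same strict
above-the-mean rule, per grid point (sharing thresholds across points
would let one parameter setting contaminate another's reference). The
sweep grid, $W_r \in [0, 8]$ mV by 1 mV and $\lambda_{Ex} \in [1, 10]$ Hz
by 1 Hz at 200 trials per point, straddles the fluctuation-driven regime
under these strong synaptic weights: mean drive crosses zero at
$\lambda_{Ex} = 10$ Hz, and output rates rise steeply around 5–6 Hz, where
entropy and $p_{1ij}$ saturate (near 2 bits and 2, respectively). Level
curves use marching squares (`grDevices::contourLines`) on the grid.

**Trajectory efficiency.** The model has one pair, so the cross-pair
regression defining $E$ does not transfer; the package defines the model's
efficiency between consecutive trajectory points, per repetition, as
$\Delta H/\Delta p_{1ij}$, excluding (and counting) repetitions with
$\Delta p_{1ij} = 0$. Point-to-point comparisons across the 30 paired
repetitions use exact two-sided sign tests. The shipped trajectories are
a "red" path ($\lambda_{Ex}$ rising at fixed $W_r$: entropy rises but
efficiency falls as the cost grows faster) and a "blue" path
($\lambda_{Ex}$ rising while $W_r$ falls: entropy rises along the path).
A caveat the sweep itself exposes: with 10 mV afferent jumps the recurrent
weight's leverage on $p_{1ij}$ is small compared to the afferent drive, so
constant-cost level curves run nearly parallel to the $W_r$ axis and a
blue path cannot *gain* efficiency here — the package asserts only the
orderings the model reproduces (entropy rise along blue, efficiency fall
along red, both at sign-test resolution).

## Numerical conventions and problem sizes

* $0\log 0 := 0$ everywhere; entropies clamped only against negative-zero
  cell masses from float subtraction.
* Empirical p-values: $(r+1)/(n+1)$.
* Sign tests: exact binomial, two-sided, zero differences dropped.
* Every stochastic routine takes an explicit integer seed; bootstrap and
  permutation streams are seeded separately by callers.
* Timestamps are integers (ms) internally; file round trips are
  bit-exact.
* Test and acceptance problem sizes — chosen so each check's sampling
  error is far below the asserted tolerance: closed-form comparisons on
  dense grids at $10^{-12}$; Monte-Carlo checks at $10^4$ draws with
  3-standard-error bands; efficiency recovery at 500 pairs × 100
  replications; surrogate ensembles of 100–1000; LIF contrasts at the
  model's native 200 trials × 30 repetitions.

## Known limitations

* Pairs sharing a neuron are treated as independent by the bootstrap.
* The bias correction is first-order; at very small trial counts (< ~20)
  it under-corrects.
* The surrogate clip rule preserves marginals at the cost of exact
  $f$-multiset preservation when a draw is infeasible.
* The generator's Poisson counts understate real count dispersion; see
  the sawtooth discussion above.
* The LIF model inherits the printed strong-weight regime; conclusions
  about $W_r$ are confined to the weak-leverage behaviour described
  above.
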