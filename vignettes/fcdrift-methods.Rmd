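---
title: "Testing whether functional connectivity structure is homogeneous within brain states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing whether functional connectivity structure is homogeneous within brain states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdrift)
```

## The question

Brain states — wakefulness, NREM and REM sleep — are usually treated as
homogeneous when functional connectivity (FC) between areas is quantified:
one average FC value per state. `fcdrift` implements the opposite research
programme: at 5-second epoch resolution, do some NREM epochs carry an
inter-areal FC *structure* (the whole vector of directed neuron-pair
couplings) that is indistinguishable from REM or wakefulness, and vice
versa? A positive answer means circuit-level integration fluctuates within
states, not only between them — a candidate substrate for phenomena such as
dreaming inside NREM sleep.

Two hypotheses are formalized. H1: among NREM epochs whose epoch-mean
inter-areal FC (aiFC) is high (top 25/15/5% of NREM, and above the 5th
percentile of the other state), a significant fraction has a structure
indistinguishable from REM (or wakefulness). H2 is the mirror: low-aiFC REM
epochs (bottom 25/15/5%, below the NREM 95th percentile) indistinguishable
from NREM.

The package provides the full computational chain: a spiking-network ground
truth, an FC estimator, a synthetic statistical-session generator, the
session-preparation pipeline, and the classifier-plus-permutation engine
with Fisher meta-analysis and resampling power analysis.

## The spiking ground-truth model

The validation network (`architecture()`, `build_connectome()`,
`simulate_network()`) is a four-area conductance-based leaky
integrate-and-fire model with 5000 neurons, 85% excitatory per area
(1062 E / 188 I in each of R1–R4). Membrane dynamics are

$$C_m \dot V = -g_L (V - V_{rest}) + I_{syn}(t),$$

with threshold-reset-refractory handling, and cell-class parameters taken
from layer-2/3 V1 measurements (pyramidal cells for E, PV interneurons for
I). Synaptic input combines background Poisson AMPA drive (930 Hz for E
cells, 1460 Hz for I cells, unit-weight events), recurrent AMPA and GABA-A
conductances with exponential gating ($\tau_{AMPA} = 2$ ms,
$\tau_{GABA} = 5$ ms, $V_E = 0$, $V_I = V_{rest}$), and an optional
constant injected current. We integrate with forward Euler at 0.1 ms in
compiled code; the gating equations are written so AMPA depolarizes and
GABA pulls the membrane toward rest (a unit test asserts a GABA event can
never fire a cell).

Within-area synapses exist with group-pair probabilities and carry the
normalized weight

$$w = G\,\hat s / (N_{send}\, p),$$

with $G = 5$, which keeps network equilibria invariant to size (doubling
the sending population halves each weight — a tested invariant). Between
areas only E→E synapses exist ($p = 0.3$), with per-synapse strengths from
a mesoscale connectivity table scaled by a global constant $G = 50$; the
R1–R2 entries are roughly an order of magnitude above the rest, which is
the structure the estimator is later asked to recover.

Design choices worth knowing: current injection targets all neurons of the
stimulated area (a switch restricts it to E cells); initial membrane
potentials are drawn uniformly in $[V_{rest}, V_{th})$ to avoid startup
synchrony; spikes are detected at the end of each step; all randomness
passes through explicit integer seeds, and identical seeds give
byte-identical rasters.

At these parameters the network sits in an asynchronous, fluctuation-driven
regime at roughly 1.5 Hz spontaneously. A 30 pA injection into R1 raises
R1 to ~12 Hz and, through the strong R1–R2 projection, R2 to ~4 Hz with
much smaller effects elsewhere — the propagation signature used in
validation.

## The FC estimator

`spikes_to_rates()` bins spikes (10 ms), smooths with a Gaussian kernel
(σ = 50 ms), and scales all traces by the *global* maximum absolute rate.
We deliberately do not normalize per unit: the current readout below is a
product of an interaction weight and a source amplitude, so per-unit
normalization would erase exactly the relative-amplitude structure the
method reads out (it also matches what the reference implementation of this
estimator family does).

`fit_rnn()` trains one model unit per recorded unit,
$\dot x = (-x + J r)/\tau$ with $r = \tanh(x)$, by recursive least squares:
the model runs freely from the data's initial condition and every step all
rows of $J$ are corrected with a shared inverse-correlation matrix
(regularizer 1.0), for 30 passes through the epoch. The model time constant
defaults to 20 ms: at 10-ms bins a 100-ms unit cannot track the smoothed
traces at all (self-consistency recovery drops from pVar ≈ 0.97 to ≈ 0.78
even on data the model class generated). Goodness of fit is
$\mathrm{pVar} = 1 - \|A - \hat A\|_F^2 / \|A - \bar A\|_F^2$, the
fraction of variance about the data mean reproduced by a free run of the
trained model.

`decompose_currents()` reads the directed current $j \to i$ as
$J_{ij} r_j(t)$; the sum over sources equals each unit's total recurrent
drive exactly (asserted to machine precision). `epoch_fc()` collapses each
directed pair to the time-mean of the absolute current; the alternative
reading (absolute value of the time-mean) discards oscillatory coupling
and is not used, but is a one-line change if needed.

### What validation shows — and what it honestly cannot

`validate_recovery()` repeats (unit sampling → fit → decomposition) on a
simulated raster and compares the six region-pair FC distributions with a
one-way ANOVA and Tukey contrasts. By default every run draws a fresh unit
sample, so the per-pair distributions average over unit choice as well as
fit stochasticity; `resample_units = FALSE` reproduces the alternative
protocol in which one fixed selection is refit under different seeds only.

Post-injection, one unit per area suffices: R1–R2 is the top pair for every
simulation seed we tried, with all Tukey comparisons involving R1–R2 below
$10^{-5}$ at 600+ runs. At baseline the situation is physically different:
a 1.5 Hz unit emits on average 0.75 spikes per 500-ms window, so a single
unit pair carries essentially no information about inter-areal coupling,
and the per-pair means are flat to within a few percent regardless of how
many estimator runs are averaged. We report this configuration faithfully
rather than tune around it; baseline recovery *does* succeed once ~5 units
per area are pooled, and the rank-1 identity of R1–R2 is a tested property
in a regime where its coupling is strong enough (≥10× every other pair)
to shape single-unit dynamics. The practical reading: single-unit baseline
validation certifies estimator *consistency*, not pair identification.

The unit-count analysis (pVar versus units fitted, subsampling a 24-unit
session pool on a stimulus-evoked window) shows the expected qualitative
shape — a steep rise up to about 10 units, then much slower growth — but
pVar keeps creeping upward with unit count
(≈0.15 between 10 and 24 units) because every added model unit enlarges
the regressor space. We do not claim a plateau tighter than that.

## The synthetic statistical sessions

`generate_fc_session()` draws labeled epochs × directed-pair FC tables
directly, bypassing simulation: per state a lognormal pattern vector
(structure), a coupling scale (amplitude; defaults WAKE 1.0, NREM 0.6,
REM 0.9, encoding the expected global NREM drop), multiplicative lognormal
epoch noise (σ = 0.3) plus per-pair jitter (σ = 0.25) — nonnegative,
right-skewed magnitudes whose state distributions overlap, as epoch-level
FC does in practice — and a state-invariant intra-areal component (the
intra-areal exchangeability across states is a tested property). With
probability `f_atypical` an epoch keeps its label but is generated from the
partner state's full pattern, not just its amplitude: the hypotheses
concern structure, so atypical epochs must swap structure. The generating
state is always recorded (`gt_state`) so recovery is checkable. Because
REM's scale exceeds NREM's, REM-generated epochs inside NREM land
preferentially in the NREM high tail — exactly the configuration H1
postulates.

What the generator does not emulate: temporal autocorrelation between
consecutive epochs, area-specific state effects (e.g. preserved
hippocampal-cortical coupling in NREM), estimator noise correlated across
pairs, and any LFP-derived covariates. Passing tests on these sessions
therefore certify the statistical machinery, not the estimator's behavior
on real recordings (the spiking path above covers that separately).

`generate_spiking_session()` instead runs the spiking model
piecewise-stationary with all inter-areal weights multiplied by a per-state
gain, which exercises the whole chain end to end; the recovery test uses
inter-areal couplings 10× the default table because at the default
strengths the state gain moves single-unit statistics by less than
sampling noise.

## Session preparation

`apply_exclusions()` applies, in order: sessions with fewer than 10 total
units (below the unit-sufficiency knee of the pVar analysis); epochs with
fewer than 2 firing units; stimulation epochs together with both neighbors;
sessions with no positive FC anywhere. The report attributes each drop to
exactly one rule and the operation is idempotent.

`state_magnitude_test()` gates on per-state Shapiro normality of epoch-mean
aiFC, then runs Kruskal–Wallis (or one-way ANOVA if all states pass
normality, which epoch-level FC magnitudes essentially never do); sessions
without a significant state effect are flagged out, since tail selection
presupposes that amplitudes differ across states.

`select_tail()` implements the guarded percentile selection. Percentiles
interpolate linearly between order statistics (type-7 quantiles); "top
25%" means strictly greater than the 75th-percentile value, so boundary
ties are excluded deterministically. The guard keeps only epochs beyond
the partner state's 5th (top side) or 95th (bottom side) percentile.
Selections nest across 5/15/25 cutoffs and every selected epoch satisfies
its guard — both asserted per call in tests. `overlap_summary()` reports
quartile occupancy of one state's epochs in the other's distribution and
the tail cross-threshold percentages.

## The hypothesis engine

`loo_ground_truth()` scores a modified leave-one-out scheme: only the tail
epochs of the focal state are individually held out; the classifier is a
linear support vector machine (cost 1) with features standardized by
training-fold statistics — a maximum-margin linear rule is the conservative
choice for few epochs in a high-dimensional pair space, and all settings
are exposed.

`stratified_shuffle_null()` builds the null: N comparison epochs are
matched into the aiFC range of the N tail epochs (fewer than N in range
aborts the session — the infeasible-matching path), the matched aiFC range
is cut into 10 equipopulated bins (reduced to `max(2, floor(N/2))` with a
warning when N is small), and labels are permuted within bins so the null
preserves amplitude matching and destroys only structure. The ground truth
entering the p-value is computed on the same matched task, making the
procedure an exact permutation test; on exchangeable synthetic sessions the
p-value is uniform (Kolmogorov–Smirnov over 200 independent sessions — a
tested acceptance property). The p-value is the fraction of shuffled
accuracies strictly greater than ground truth (a `(k+1)/(n+1)` option
avoids exact zeros); "indistinguishable" is declared when ground truth
does not exceed the null's 95th percentile. No class rebalancing is
applied: the epoch counts per state are genuinely unbalanced in this kind
of data and the null is computed under the same imbalance.

`sufficiency_check()` (all epochs, plain label shuffling — stratification
is unnecessary when amplitude is part of what the classifier may use) and
`control_extremes()` (bottom-5% vs top-5%, two-sided shuffled interval)
guard against reading "indistinguishable" into sessions that simply lack
discriminative power. `fisher_combine()` aggregates session p-values
($-2\sum\ln p \sim \chi^2_{2k}$), overall and per animal.
`power_resample()` resamples pilot-session null distributions into
surrogate 7-session datasets, evaluates each sampled session at its
source's 95th-percentile accuracy threshold, Fisher-combines, and reports
the fraction of surrogates below α = .05; the analysis proceeds when power
exceeds 80%.

One underdetermined point: whether the modified LOO accuracy should also
score comparison epochs. We score focal-tail epochs only, which is the
literal reading of the procedure; the sufficiency and control classifiers
score all epochs.

## Numerical and scale choices

Problem sizes in the shipped tests and acceptance script were chosen as the
smallest that leave the statistical conclusions stable: 200–1000 estimator
repetitions (the validation analyses used 500–1000), 50–200 label shuffles
per null in tests with 1000 as the analysis default, 20-seed recovery
batches, and 1000-neuron networks for integration tests (the weight
normalization makes dynamics size-invariant; full 5000-neuron networks are
used for the validation analyses proper). Epochs are half-open 5-s windows
`[t0, t0 + 5)`, times in seconds throughout. Degenerate inputs are handled
explicitly: zero-variance states are non-normal and non-different, all-zero
rate rows stay zero through normalization, p = 0 is clamped with a warning
in the Fisher combination, and non-finite membrane potentials or
interaction matrices abort with the offending step named.

## Known limitations

The spiking model is a validation toy: no plasticity, no conductance
heterogeneity, no layered structure, homogeneous areas. The estimator's
single-unit baseline limitation discussed above is a property of this
operating point, not of the code path. The synthetic session generator is
deliberately simple (independent epochs, one global pattern per state);
the hypothesis tests inherit whatever realism it lacks. HDF5 outputs of
the original toolchain are replaced by TSV/JSON serializations carrying
the same fields.
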