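---
title: "Methods: phase-lag connectivity reliability across epoch schemes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-lag connectivity reliability across epoch schemes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

EEG functional connectivity in infants must be estimated from small amounts
of artefact-free signal: infants move, attend briefly, and produce noisy
recordings, so the clean data per session come as a handful of
variable-length segments. Those segments can be cut into many short epochs
or few long ones, and the choice interacts with the connectivity estimator.
Phase-lag-based estimators are the standard choice because they ignore
zero-lag (volume-conducted) coupling, but the phase lag index (PLI) is
positively biased at small epoch counts while the debiased weighted PLI
(dbWPLI) removes that bias at the cost of down-weighting small lags.
Whether a *subject-level* connectivity score is usable for individual
differences research is a question of test–retest reliability: the
intra-class correlation of the score across two recording sessions.

`eegicc` implements the full chain — synthetic two-session recordings with
known coupling, epoch segmentation designs, spectral phase-lag estimation,
surrogate-normalised weighted graph metrics, and ICC(3,1) — so that the
reliability behaviour of each design cell can be studied under a generator
whose ground truth is known by construction.

## The synthetic generator

### Coupling model

Each subject $s$ has a symmetric pairwise coupling matrix on $[0,1]$:

$$c_{ij}^{(s)} = \mathrm{clip}_{[0,1]}\!\left(\mu + T_{ij} + g_s\right),$$

with population mean $\mu$ (`coupling_mean`, default 0.5), a topology
pattern $T_{ij} \sim N(0, \sigma_T^2)$ drawn **once per population**
(`coupling_sd_pairs`, default 0.08) and shared by all subjects, and a
subject trait offset $g_s \sim N(0, \sigma_b^2)$ (`coupling_sd_between`,
default 0.1). Sharing $T$ across subjects keeps the zero-variance case
degenerate in the right way (all subjects identical when $\sigma_b = 0$)
and makes the between-subject SD of mean coupling exactly $\sigma_b$.
Each session adds a session-state offset
$e \sim N(0, \sigma_w^2)$ (`session_noise_sd`) to the whole matrix. The
designed reliability ceiling for any affine function of mean coupling is
therefore

$$\rho = \frac{\sigma_b^2}{\sigma_b^2 + \sigma_w^2},$$

and `design_session_noise(rho, sd_between)` inverts this. The default
`session_noise_sd = 0.065` puts the ceiling at $\rho \approx 0.7$, i.e. at
the good/excellent boundary where reliability questions are interesting.
Because ICC(3,1) is invariant under affine transformations of the score,
$\rho$ passes through the (locally approximately affine) coupling-to-dbWPLI
mapping and is recoverable from the pipeline when epoch counts are large —
the basis of the parameter-recovery test.

### From coupling to signals

All channels share a common oscillator at `oscillation_freq` (7 Hz, the
infant-alpha centre; analysis band 6–8 Hz). Channel $i$ carries

$$x_i(t) = \cos\!\big(2\pi f t + \theta_0 + \delta_i + \varepsilon_i(t)\big)
           + \text{noise},$$

with a per-segment random start phase $\theta_0$, a fixed channel offset
$\delta_i$, and slowly varying phase jitter $\varepsilon_i(t)$. Coupling
strength maps to jitter through the resultant-length identity for wrapped
normals: a pair whose phase-difference jitter has variance $v$ has
phase-locking $e^{-v/2}$, so we set

$$v_{ij} = -2 \log \max(c_{ij}, 0.02).$$

The floor at 0.02 bounds $v$; a resultant of 0.02 is indistinguishable
from independence at realistic epoch counts. A channel-level covariance
$\Sigma$ with $\mathrm{Var}(\varepsilon_i - \varepsilon_j) = v_{ij}$ is
solved by setting $\Sigma_{ii}$ to half the row means of $v$ and
$\Sigma_{ij} = (\Sigma_{ii} + \Sigma_{jj} - v_{ij})/2$; negative
eigenvalues (possible only for strongly heterogeneous targets) are clipped
to zero, which smooths extreme coupling contrasts slightly.

Jitter is **piecewise constant** over coherence windows
(`coherence_time`, default 1 s) and redrawn independently at window
boundaries. Windows align with the epoch grid, so 1-s epochs see exactly
one phase state and the per-window phase-difference resultant equals
$c_{ij}$ exactly; longer epochs average several states, which penalises
long epochs the way real non-stationarity does. An earlier design that
interpolated jitter between knots was rejected because interpolation halves
the mid-window variance and leaks spurious phase locking into the
uncoupled case.

Volume conduction is abstracted as instantaneous linear mixing: each
channel is replaced by $(1-m)\,x_i + \tfrac{m}{n-1}\sum_{j \ne i} x_j$
(`mixing_strength` $m \in [0, 1)$). Mixing is purely real and so creates
zero-lag dependence only — exactly what phase-lag estimators must reject.
Sensor noise is white Gaussian per sample (`sensor_noise_sd`, default 2 in
units of the unit oscillation amplitude, i.e. strongly noise-dominated
single samples, as in infant EEG); a $1/f$-shaped alternative is available
(`pink_noise = TRUE`) but secondary, since the analysis is band-limited.

### Pair lags and what is realisable

Because signals are generated per channel from a common driver, the mean
phase difference of a pair is necessarily $\delta_i - \delta_j$: lag
matrices are constrained to additive (outer-difference) structure, and no
per-channel construction can realise an arbitrary per-pair lag matrix.
Rather than pretend otherwise, channel offsets are drawn in two clusters
(0 and $\pi/2$, each jittered by $\pm\pi/8$): cross-cluster pairs (about
half) sit near the maximally informative $\pi/2$ lag, within-cluster pairs
sit near zero lag, where the dbWPLI deliberately assigns little weight —
a realistic mixture of informative and conduction-like pair geometry. The
`pair_lags` field stores the realised antisymmetric matrix, and in the
noiseless case the circular mean of per-epoch phase differences equals it
exactly.

### Clean segments

`segment_lengths` defaults to a mixture of 12–30-s blocks totalling 180 s
per session, enough for the 20 × 6 s constant-amount design and the
150 × 1 s short-epoch maximum. The most demanding long-epoch combinations
(60 × 5 s needs 300 s) are deliberately *not* always satisfiable: subjects
lacking epochs for a combination are excluded from that combination only,
reproducing the per-design subsamples that real data quantity limits
force.

## Estimators

From each epoch (per-channel demeaned, periodic Hanning taper, FFT; one
taper per epoch) we keep the complex coefficients $z$ up to Nyquist. The
per-epoch cross-spectrum of a pair is $X = z_i \bar z_j$; its imaginary
part $\Im\{X\}$ encodes lagged coupling. Per frequency bin:

* **PLI** $= \left|E\{\mathrm{sgn}\,\Im\{X\}\}\right|$, with
  $\mathrm{sgn}(0) = 0$.
* **WPLI** $= |E\{\Im\{X\}\}| \,/\, E\{|\Im\{X\}|\}$ (provided as the
  printed, biased estimator).
* **dbWPLI**: the debiased WPLI-square estimator built from products of
  distinct epochs,
  $\big[(\textstyle\sum_e I_e)^2 - \sum_e I_e^2\big] \big/
   \big[(\sum_e |I_e|)^2 - \sum_e I_e^2\big]$ with $I_e = \Im\{X_e\}$.
  A degenerate denominator (fewer than two non-zero epochs) yields 0, and
  at least two epochs are required.

Per-bin matrices are averaged over all bins inside the band (inclusive
endpoints; 6–8 Hz covers three bins at 1-s epochs, five at 2-s).
Whole-brain connectivity is the mean over the strict upper triangle —
**signed** values for the dbWPLI; absolute values are taken only where the
graph metrics require non-negative weights, which is the one place the
reference analysis states absolute values were used. Under independence
the PLI's expectation is the mean absolute Rademacher average
$\sqrt{2/(\pi n)}$ — the small-sample inflation — while the dbWPLI is
unbiased at any $n$; both facts are checked by Monte-Carlo tests.

## Graph metrics

Graph metrics operate on rescaled non-negative weights (division by the
maximum weight). The weighted clustering coefficient uses the
geometric-mean (Onnela) triangle intensity
$(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$ normalised by
$k_i(k_i-1)/2$ possible triangles, averaged over nodes; degree counts
non-zero-weight neighbours and nodes of degree < 2 contribute 0. The
characteristic path length averages Dijkstra shortest paths over inverse
weights across all ordered pairs; disconnected pairs (which dense
phase-lag matrices never produce) are dropped from a node's average with a
warning.

Both metrics are normalised by their means over surrogate matrices that
permute the strict-upper-triangle weights uniformly and mirror back:
the conventional weight-distribution-preserving, topology-randomising null
for weighted small-world normalisation (the null-model routine was an open
choice; degree sequences are not preserved). The small-worldness index is
the exact ratio $C^w_{norm} / L^w_{norm}$. The package default is 1000
surrogates, matching the reference analysis; the pipeline and test
problem sizes use 50–200, which the surrogate-SD bookkeeping shows is
enough for the normalisation means at these matrix sizes.

## Reliability

ICC(3,1) — the two-way fixed-model single-measure consistency ICC — is
computed from first-principles sums of squares:
$(MS_R - MS_E)/(MS_R + (k-1)MS_E)$. Confidence intervals and the p-value
against ICC = 0 use the standard F-based theory with df $(n-1)$ and
$(n-1)(k-1)$ (the reference analysis reports CIs and p-values without
printing formulas; this is the textbook machinery for the named model).
Negative estimates are retained in `icc` and clipped to 0 in
`icc_clipped`; categories use poor < 0.40 ≤ fair < 0.60 ≤ good < 0.75 ≤
excellent. The printed convention leaves (0.59, 0.60) and (0.74, 0.75)
unassigned; contiguous half-open intervals close the gaps. All values
identical across subjects and sessions is flagged and defined as ICC 1
with a degenerate CI; fewer than 3 complete subjects is an error (the
pipeline marks such cells unavailable instead of failing the run).

## Segmentation designs

Three designs are tabulated by `segmentation_schemes()`: low numbers of
longer epochs ({20,…,60} × {1,…,5} s), high numbers of shorter epochs
({30,…,150} × {1,2} s), and a constant total amount of data (120 × 1 s,
60 × 2 s, 40 × 3 s, 20 × 6 s — all 120 s). For the constant-amount design
twenty 6-s parents are selected once and re-cut into 1/2/3-s children, so
every cell of that design uses *identical* underlying samples. (Source
descriptions of this design disagree internally about 10 vs 20 parents;
20 parents is the only count consistent with 120 × 1 s = 120 s and is
used throughout.) Epoch cutting is contiguous from the start of each
clean segment with end remainders discarded; selection is uniform without
replacement from a stream independent of the data-generation stream.

`run_experiment(selection = "nested")` additionally offers a
common-random-number sweep: one selection at the largest epoch count per
length, with smaller counts using its prefix. This pairs the ICC sweep
across epoch numbers within a replicate and is used where the quantity of
interest is the *trend* of ICC with data amount, for which independent
redraws would waste most of the replicate budget on shared subject-level
noise.

## Problem sizes and what the tests show

The test suite exercises the full pipeline at sizes chosen to make the
Monte-Carlo error small relative to the effects asserted: parameter
recovery uses ten replicate populations of 40 subjects × 32 channels at
64 Hz with 1-s epoch sweeps up to 150 epochs; the metric-ordering
comparison uses twenty replicate populations of 15 subjects × 16 channels
with 50 surrogates per matrix; null-bias checks use ≥ 1200 coefficient
sets per epoch count. The 64 Hz rate keeps the 6–8 Hz band fully resolved
at 1-s epochs while keeping the simulations quick; the generator default
remains 512 Hz, the post-downsampling rate typical of the recordings the
generator emulates.

Passing these tests shows that the estimators, normalisations and the ICC
machinery behave as designed *under this generator*. The generator
emulates coupling strength, session state drift, volume conduction,
sensor noise and segment scarcity; it does not emulate blink/muscle
artefacts, electrode geometry, heterogeneous individual alpha peaks,
finite topography of real networks, or non-stationarity beyond the 1-s
coherence windows. Conclusions about real infant EEG therefore rest on the
estimators' analytic properties, not on these simulations alone. One
consequence worth naming: the reliability advantage of the dbWPLI over
the PLI at many short epochs is small here (their replicate-mean ICCs
typically differ by less than the Monte-Carlo error), because the PLI's
small-sample bias is a nearly common shift across subjects which
consistency ICC ignores; the pattern direction matches the reference
findings but is not asserted as a test.

## Numerical conventions

* Periodic Hanning window ($0.5 - 0.5\cos(2\pi k/N)$); per-epoch,
  per-channel demeaning before tapering.
* $\mathrm{sgn}(0) = 0$; exactly-real cross-spectra give PLI, WPLI and
  dbWPLI of 0.
* Connectivity matrices are exactly symmetric by construction (both
  orientations of a pair are computed from identical products), with zero
  diagonals.
* Band endpoints are inclusive with a $10^{-9}$ Hz tolerance.
* Seeds: one global seed expands into named substreams
  (`substream_seed(seed, "session", subject, session)`, …) via an exact
  integer hash below $2^{31}$; populations, sessions, selections and
  surrogates each have their own stream, so subject-level results are
  reproducible independently of evaluation order.
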