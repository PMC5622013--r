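---
title: "Kernel Granger causality and directed EEG networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel Granger causality and directed EEG networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcnet)
```

This vignette is the package's account of its science: the estimator, the
network summaries, the group statistics, the synthetic cohorts used to
validate them, and the design decisions taken where the methodology was
genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The estimation problem

Functional connectivity (correlation, coherence, phase synchronisation) is
symmetric: it says two electrodes covary, not who drives whom. Effective
connectivity asks the directed question. Granger's answer: a driver $Y$
causes a target $X$ if the past of $Y$ improves the prediction of $X$
beyond what $X$'s own past achieves. EEG interactions need not be linear,
so the package uses a kernelised formulation in which the prediction is a
projection in a reproducing-kernel feature space.

### The filtered kernel index

With embedding order $m$, each sample $x_t$ is paired with the state
$(x_{t-1}, \dots, x_{t-m})$; the restricted model uses the target's own
states, the full model appends the driver's. Write $U_r$ for an orthonormal
basis of the centred restricted feature span (eigenvectors of the centred
Gram matrix above the eigenvalue floor) and $e$ for the restricted residual
of the centred target. The full span decomposes into the restricted span
plus an orthogonal complement with basis $\{t_i\}$; the index is

$$\delta \;=\; \sum_{i \in \mathcal{S}} r_i^2, \qquad
  r_i = \operatorname{cor}(e, t_i),$$

where $\mathcal{S}$ keeps only directions whose correlation is significant
at level $\alpha$ Bonferroni-corrected over the number of directions tested
(the *filter*). $\delta \in [0, 1)$ is the fraction of residual variance
the driver explains. Three kernels are provided:

* **linear** — with the filter disabled, $\delta$ equals the classical OLS
  Granger variance ratio exactly (this identity is a test invariant, checked
  to $10^{-6}$ against an independent `lm`-based oracle);
* **inhomogeneous polynomial, degree 2** — adds squares and cross-products,
  so purely quadratic couplings (invisible to any linear regression of a
  zero-mean driver) become detectable;
* **gaussian** — fully nonparametric, width $\sigma$ defaulting to the
  median pairwise state distance.

For the linear and polynomial kernels the implementation works with
explicit feature maps: the span of the centred Gram matrix's eigenvectors
is identical to the column space of the centred feature matrix, so an SVD
of an $n \times d$ matrix ($d$ small) replaces an $n \times n$
eigendecomposition. The complement directions are obtained from the feature
columns the driver adds beyond the restricted span (for the degree-2
polynomial: driver lags, their squares and products, and driver × target-lag
cross terms). The Gaussian kernel keeps the Gram route. Degenerate inputs —
a constant target, or a driver adding nothing to the span (e.g. a duplicate
channel) — return $\delta = 0$ with a flag rather than failing.

**Transfer entropy.** For Gaussian linear processes, transfer entropy and
the Granger ratio are equivalent: $\mathrm{TE} = -\tfrac12\ln(1-\delta)$
nats. The package computes TE through this mapping rather than a separate
binned estimator, treating GC and TE as one analysis; a histogram plug-in
estimator exists in the test suite as an independent oracle and agrees
loosely (binned estimators are biased) on a long Gaussian pair.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `m` | 5 lags (~20 ms at 256 Hz) | embedding order of both models |
| `kernel` | linear | feature space (`poly` degree 2, `gaussian` σ = median heuristic) |
| `eigenvalue_floor` | 1e-6 × largest eigenvalue | numerical span membership |
| `alpha` | 0.05 | per-direction filter level, Bonferroni over directions |
| `conditioning` | bivariate | `conditional` appends all other channels' lags to both models |

Bivariate estimation is the default: with 62 electrodes, conditional fits
of $61 m$ regressors per target are disproportionate to scalp-level
analyses, and pairwise flow maps are the object of interest. The trade-off
is explicit: in a coupling chain $1 \to 2 \to 3$, channel 1 *does* carry
pairwise predictive information about channel 3, so bivariate maps contain
indirect links that are genuine bivariate information flow, not estimator
errors. Conditional mode (small montages) explains such links away; the
edge-recovery test on a 10-node, 12-edge graph reaches sensitivity 1.0 at a
false-positive rate within the binomial margin of its 0.05 level only in
conditional mode for exactly this reason.

### Per-link significance

Each ordered pair gets a null distribution by circularly time-shifting the
driver channel by random offsets of at least $m$ samples — this preserves
the driver's autocorrelation while destroying its alignment with the
target — and re-estimating $\delta$; the observed epoch-averaged index must
exceed the $1-\alpha$ surrogate quantile. Nineteen surrogates are the
minimum for $\alpha = 0.05$; the package refuses fewer. Estimation is
per-epoch and averaged (never concatenated), so the boundaries created by
artifact rejection are respected.

## Preprocessing

Recordings are zero-phase FIR band-pass filtered (forward–backward Hamming
`fir1`, order from the 3.3/transition-width rule, transition ≤ 1 Hz below
8 Hz and ≤ 2 Hz above), so band-limited causality is not distorted by
filter phase. Band defaults: delta 0.5–3.5 Hz, theta 4–7 Hz, alpha
8–12 Hz, beta 13–30 Hz. The delta upper edge and the alpha edge are
configurable (laboratory conventions differ; alpha is sometimes taken to
12.5 Hz).

Epochs default to 4 s (1024 samples at 256 Hz) without overlap: long
enough for stable Gram spectra at $m = 5$, short enough that per-band
stationarity within an epoch is plausible. An epoch is rejected iff any
scalp channel exceeds 150 µV in absolute amplitude, or any channel's
absolute Pearson correlation with the epoch's EOG trace exceeds 0.7 (the
operationalisation of "similarity to the EOG channel"). Rejection is
decided on the *broadband* epochs and the mask is carried onto every
band-filtered epoch set — a blink is low-frequency and high-amplitude, so
it is invisible to the criteria after alpha-band filtering although its
influence is not. Drowsiness/sleep screening is not automated; a manual
per-epoch exclusion list is accepted instead.

## Networks and their features

The significant links form a directed weighted graph (weight = $\delta$ or
TE; weight 0 ⇔ no edge). Metrics use the reciprocal weight as edge length
(the Brain Connectivity Toolbox convention — a strong link is a short
path); $-\ln w$ is a documented alternative the user can apply by
transforming weights before `info_network()`. Networks stay directed
throughout; no binarisation is applied by default (max-normalisation is
available).

* **Integration** — characteristic path length `lambda` (mean finite
  directed pairwise distance), per-node eccentricity (largest finite
  distance from the node) and diameter (largest eccentricity). Unreachable
  pairs are excluded from means and reported as a disconnection fraction.
* **Segregation** — directed weighted clustering (geometric-mean triangle
  weights over the number of possible directed triangles); global and
  zone × zone efficiency (mean inverse distance; unreachable pairs count
  zero, making efficiency robust to disconnection), zones being frontal /
  central / temporal / parietal / occipital with optional hemisphere split.
* **Centrality** — vertex and edge shortest-path betweenness with
  fractional credit for ties, endpoints excluded.
* **Resilience** — degree assortativity over directed edges (out-degree of
  source vs in-degree of target) plus a targeted-attack efficiency-decay
  curve. The resilience *class* needs an operationalisation because no
  single canonical measure exists; assortativity is this package's
  documented choice.

Every scalar feature is z-scored against an ensemble of degree-preserving
surrogates (pairwise directed edge swaps, 10 per edge, 100 surrogates by
default, weights shuffled onto the rewired edges). On graphs drawn from the
null family itself the observed clustering z-score stays within ±3 — a
property test.

All closed-path metrics agree exactly (1e-12) with exhaustive-enumeration
oracles on suites of random ≤ 5-node digraphs, and satisfy the scale laws
(weights × c ⇒ distances / c; clustering and betweenness rankings
invariant).

## Group statistics

The per-subject quantity compared across groups is the per-electrode count
of significant links by direction: `in` counts links received (row of the
mask), `out` links sent (column). A mean-link-weight alternative can be fed
through the same machinery (the maps accept any per-subject per-electrode
table). Counts sum correctly by construction: total in = total out = number
of significant links.

Comparisons use the classical pooled-variance Student t (Welch by flag),
evaluated on *both* tails, each at the per-tail level — the "alternating
left and right" one-tailed scheme. The Bonferroni factor is
$b = n_\text{couples} \times (n_\text{stims} - 1) = 3 \times 2 = 6$ for
three groups and three stimulation conditions, lowering 0.05 to
$0.05/6 \approx 0.008$ two-tailed, 0.004 per tail. The package works in
probability units throughout. A Kolmogorov–Smirnov gate (one-sample test
against a normal with the cell's moments) annotates each cell; non-normal
cells additionally get a Wilcoxon rank-sum p as a clearly-labelled
extension — the gate never silently replaces the t decision. Maps carry the
signed relative percent difference
$100(\bar{a}-\bar{b})/\operatorname{mean}(\bar{a},\bar{b})$, displayed
hot (first group prevails) vs cold on the montage schematic. One-way
fixed-effects ANOVA compares scalar network features across groups,
Bonferroni-corrected over features.

## The synthetic cohorts

No EEG data are distributed with studies of this kind, so validation rests
on a generator whose ground truth is known. Each channel is a stochastic
AR(2) resonator: poles at modulus $e^{-\pi\,bw/f_s}$ and angle
$2\pi f_0/f_s$ give a spectral peak at $f_0$ (default 10 Hz, the posterior
alpha rhythm) with half-power bandwidth $bw$ (2 Hz). Directed couplings add
$c_{ij} f(x_j(t-1))$ with $f$ identity or squaring; an EOG surrogate — a
slow AR(1) drift plus Poisson blinks of ~250 µV, a fraction of which leaks
into frontopolar channels — gives artifact rejection something real to
reject. Channels are scaled to 25 µV RMS, so typical excursions are
50–100 µV and the 150 µV criterion fires on blink leakage and rare extreme
epochs rather than on every clean epoch.

Stability is structural: dense motifs (the posterior cluster) are sampled
in feed-forward orientation, which leaves the linearised spectral radius at
the resonator value; as a safety net, whole graphs are scaled (relative
strengths preserved) until the radius is ≤ 0.99, and an explicitly unstable
user-supplied graph is an error at construction.

The default cohort mirrors a three-group visual-stimulation design: 19 + 19
+ 11 subjects × (rest, 0.5 cpd, 2.0 cpd), a shared random background graph,
stimulation conditions adding posterior → frontal couplings, the MA-like
group adding a segregated posterior cluster under stimulation (two of its
couplings quadratic), and the MO-like group globally down-weighted. Effect
sizes are free parameters of the generator, chosen once to be detectable at
realistic recording lengths — they are not estimates of any real cohort.
What passing tests show is therefore that *the analysis chain recovers
known directed structure of this kind at these SNRs*; they cannot show that
real EEG satisfies the generator's assumptions (no volume conduction, no
1/f background, no non-stationarity beyond epoch boundaries, Gaussian
innovations).

## Problem sizes in the validation suite

The test and acceptance runs use scaled designs chosen as the package's own
compromise between statistical resolution and a desk-scale run: 50-seed
Monte-Carlo for the closed-form VAR recovery (T = 2000), 100 seeds for
nonlinearity detection (T = 1000), ten 5-channel zero-coupling recordings
(200 links) with 99 surrogates for the null false-positive rate, 200
replicates of 19-vs-19 null group maps on the 16-channel montage for the
map-level type-I error, and 6-subject groups on the 16-channel montage
(20 s recordings, 19 surrogates) for the qualitative stimulation and
posterior-cluster scenarios. The cluster scenario scores the posterior
*share* of vertex betweenness (mean posterior VBC over mean scalp VBC per
subject): raw betweenness scales with each subject's network density, and
the share is the density-normalised statement of "posterior areas are more
central". The full 62-channel, 19/19/11 design remains
the generator default.

## Numerical choices and degenerate inputs

* Eigenvalue floor $10^{-6}$ × largest eigenvalue for span membership on
  both models; complement directions kept above $\sqrt{\text{floor}}$ after
  projection, which makes the index invariant (to 1e-8) under affine
  rescaling of any channel.
* $\delta$ is clamped to $[0, 1-10^{-12}]$ before the TE mapping.
* Ties in shortest paths receive fractional betweenness credit (igraph's
  Brandes implementation).
* All-zero networks: efficiency 0, path metrics refuse with an explicit
  error; assortativity on degree-regular graphs reports "undefined" rather
  than a number.
* Every stochastic stage (graph sampling, recordings, surrogates,
  rewiring) takes an explicit integer seed and is bit-reproducible;
  sub-seeds are derived with a 32-bit LCG step so user seeds stay small.

## Known limitations

* The generator has no volume conduction or common reference; real scalp
  EEG mixes sources instantaneously, which inflates bidirectional
  apparent coupling in ways these tests do not probe.
* Band-pass filtering before causality estimation temporally smears
  information; surrogate calibration compensates under the null, but
  band-limited $\delta$ values should be compared within, not across,
  bands.
* Bivariate maps contain indirect links by design (see above); conditional
  mode is exact but quadratic in montage size and intended for small
  arrays.
* The Gaussian-equivalence TE is exact only for Gaussian linear processes;
  for strongly nonlinear couplings it is a monotone index, not an
  information measure in nats.
* EDF support covers the 16-bit, single-rate, one-second-record subset the
  fixtures use — it is not a general EDF implementation.
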