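---
title: "Methods: punctum detection, diffusion deconvolution, and single-cell photocurrents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: punctum detection, diffusion deconvolution, and single-cell photocurrents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctakin)
```

punctakin quantifies the spatial reorganization of an inner-membrane
electron-transfer protein into condensate-like puncta in rod-shaped
bacteria, and the functional consequences of that reorganization for
extracellular electron transfer (EET). This vignette is the package's
account of the underlying models, the choices that were genuinely open,
and what the synthetic-data generator does and does not emulate.

## The punctum statistic

A cell whose tagged protein is spread homogeneously over the envelope
produces a roughly symmetric pixel-intensity histogram inside the cell
mask. A punctum — a localized enrichment a few hundred nanometres across
— adds a prolonged tail at the high-intensity end. `cell_skewness()`
computes the third standardized moment

$$\tilde{\mu}_3 = \frac{m_3}{m_2^{3/2}}$$

over the masked pixels, using *population* central moments (no
small-sample correction: a cell mask contains hundreds to thousands of
pixels, and the plain definition keeps the statistic exactly invariant
under affine intensity rescaling $I \to \alpha I + \beta$). A zero
pixel variance leaves the statistic undefined and is an error, not a
zero.

`classify_punctum()` thresholds the skewness; a value exactly at the
threshold is *not* punctate (strict inequality, so a degenerate
threshold of 0 never fires on a perfectly symmetric cell). No numeric
threshold is inherent to the statistic, so the default calibration
(`skewness_threshold()`) takes an upper quantile — the 99th percentile
— of the skewness of simulated punctum-free cells under the same
geometry and optics. On synthetic populations this bounds the
false-positive rate near 1% while punctate cells (enrichment fraction
0.3 in a 0.25 µm patch) sit far above any plausible threshold.

Population fractions (`fraction_with_puncta()`) pool counts: the point
estimate is total punctate cells over total cells, i.e. per-image
fractions weighted by their cell counts, with the cell-count-weighted
s.d./s.e.m. across images as the dispersion.

## Sigmoidal formation kinetics

Formation time courses — the fraction of punctate cells versus
anaerobic growth time, a single cell's normalized skewness trajectory,
Fe(II) production, menaquinone levels — are all fitted with the same
four-parameter logistic

$$f(t) = a + \frac{b}{1 + e^{-(t-c)/d}},$$

whose derived summaries are the **transition time** $4d$ (the window
straddling the inflection point $c$) and the **lag time** $c - 2d$
(time from zero to the start of that window). These identities hold
exactly for every fit object by construction.

Numerical choices: initialization $a = \min y$, $b = \mathrm{range}(y)$
(signed by the overall trend), $c$ at the first half-range crossing,
$d = \mathrm{span}/10$, with $d$ bounded in $(0, \mathrm{span}]$; the
Levenberg–Marquardt optimizer (`minpack.lm::nls.lm`) is used directly
because the `nls` model-object construction can declare a saturated,
noiseless sigmoid numerically singular even at the exact solution.
Three flags qualify a fit: `no_transition` when $|b|$ is
indistinguishable from 0 at the 95% level, `dissipation` when $b$ is
significantly negative (puncta can dissolve; the lag of a dissipation
event is not a formation lag and is withheld), and `censored` when the
fitted midpoint lies beyond the record (the transition was not
captured). Per-cell trajectories are min–max normalized before fitting
— the raw skewness scale varies with expression level, normalization
makes amplitudes comparable — and the raw values are retained by the
caller.

## Confinement-corrected diffusion-state inference

Single-molecule tracks are acquired stroboscopically: a 4 ms laser
exposure every 60 ms, so motion blur within the exposure is negligible
relative to the frame-to-frame displacement (a documented
approximation). The projected displacement length $r$ between
consecutive localizations mixes three effects: the intrinsic Brownian
step, the wrap of that step around the closed cell envelope, and the
orthographic projection onto the image plane. For an unconfined 2-D
Brownian state the step lengths are Rayleigh,

$$p(r) = \frac{r}{\sigma^2} e^{-r^2 / 2\sigma^2}, \qquad
  \sigma^2 = 2 D t_{\mathrm{lag}} + 2\varepsilon^2,$$

with the static localization error $\varepsilon$ entering once per
endpoint coordinate (no motion-blur term).

**The confinement operator.** `build_confinement_operator()`
reconstructs the forward map from true step length to observed length
as a column-stochastic matrix: emitters are placed area-uniformly on
the spherocylinder surface and walked a geodesic distance equal to each
true-bin midpoint in a random, parallel-transported tangent direction
(sub-stepped so each move is small against the radius); endpoints are
projected and perturbed with localization error, and the observed
length is binned on the same grid (overflow accumulates in the last
bin, so every column sums to exactly 1). On the cylindrical body this
is exact for Brownian steps — a cylinder is developable, so Brownian
motion on it is planar Brownian motion rolled up and a geodesic step of
length $r$ is precisely a planar step of length $r$. The spherical caps
(about a quarter of the envelope area at the default 3 × 0.4 µm
geometry) have positive curvature and contribute a bias of order
$(r/R)^2$, relevant mainly to the fast state.

One property deserves emphasis: the *projected* operator does **not**
tend to the identity as the cell grows, because orthographic projection
compresses azimuthal steps by the surface tilt regardless of radius.
The unconfined limit is recovered by the chord-length variant
(`project = FALSE`), which omits the projection and is used to verify
the limit; the projected operator remains the default because it is
what the microscope records.

**Deconvolution.** `deconvolve_confinement()` solves
$M x = y$ by nonnegative least squares with a Tikhonov penalty
$\lambda \lVert L x \rVert^2$. The default $L$ is the second-difference
operator: unregularized NNLS deconvolutions are characteristically
spiky (few nonzero bins), which leaves parametric fits intact but
corrupts the distribution shape; a smoothness prior with
$\lambda = 0.01$ (on the normalized-histogram scale) keeps the
round-trip total-variation error below 0.05–0.08 across two decades of
$\lambda$. With $\lambda = 0$ an ill-conditioned operator triggers
automatic L-curve selection. The corrected distribution is rescaled to
the observed total count and carries $\varepsilon = 0$, since the
operator already absorbed the localization error.

**Mixture fitting.** `fit_diffusion_states()` maximizes the multinomial
likelihood of a $K$-component Rayleigh mixture over the histogram bins
(last bin extended to infinity), with $\log \sigma_k^2$ and softmax
weights as free parameters, ten random restarts, and delta-method 95%
CIs from the observed information. `K = "auto"` compares $K = 1..3$ by
BIC subject to resolvability constraints (no state below 5% population,
adjacent $\sigma^2$ separated by at least a factor 3): deconvolved
histograms carry small correlated artefacts that plain BIC can mistake
for additional tiny states, and states closer than these bounds are not
scientifically resolvable at realistic counts anyway. When the science
dictates the state count — two states here, a dominant mobile membrane
population near 0.15 µm²/s and a minor fast periplasmic one — pass `K`
explicitly.

On synthetic two-state data at the study conditions (1000 tracks,
80%/20% at 0.15/6 µm²/s, 30 nm error), the full
operator–deconvolution–mixture pipeline returns the slow D within a few
percent and the slow fraction within ~2 points.

## Condensate residence kinetics

`fit_punctum()` fits a symmetric 2-D Gaussian to the punctum image (or
a moment fit to a localization cloud) and reports the condensate radius
as $R = 2\sigma$, roughly the $1/e^2$ radius — consistent with the
400–600 nm apparent size of diffraction-limited puncta; the factor is
configurable because "fitted radius" admits several conventions.
`residence_times()` thresholds a molecule's distance-to-center
trajectory at $R$ (boundary inclusive) and extracts maximal inside
runs; runs separated by at most one frame outside are merged by
default, absorbing boundary flicker from localization noise. A dwell
still in progress when the track ends is right-censored.

Observed dwells end either by escape (rate $k_e$) or by photobleaching.
With bleaching confined to the exposure, the bleaching hazard per unit
wall-clock time is $k_{bl} \, t_{int} / t_{tl}$, and the observed decay
rate is

$$k_{\mathrm{eff}} = k_{bl} \frac{t_{int}}{t_{tl}} + k_e.$$

Both exits are *events* for the $k_{\mathrm{eff}}$ fit — that is
precisely why the bleaching term is subtracted afterwards — while the
censoring flag marks only observation-window truncation, which enters
the likelihood as a survival term. Because dwells are recorded as whole
frames, the exponential likelihood is evaluated at the frame
resolution: the dwell frame count is geometric with
$p = 1 - e^{-k_{\mathrm{eff}} t_{tl}}$, and
$\hat{k}_{\mathrm{eff}} = -\log(1 - \hat{p}) / t_{tl}$. A
continuous-exponential MLE on the discretized dwells would be biased
upward by roughly $k_{\mathrm{eff}} t_{tl} / 2$ (≈ 13% at the study's
rates), which alone would consume the recovery tolerance. Simulation
audits (400 replicates per condition) show relative bias below 0.5% and
CI coverage of 94–96% across $k_e \in \{0.5, 3.1, 10\}$ s⁻¹.

The bleaching rate itself is estimated from track durations outside
puncta (`estimate_bleach_rate()`): track length in frames is geometric
with per-frame survival $e^{-k_{bl} t_{int}}$; tracks reaching the
movie end are censored. The entry rate follows from quasi-equilibrium
bookkeeping (`entry_rate()`): $k_c \, n_{out} = k_e \, n_{in}$ with
$n_{in}/n_{out}$ the time-averaged localization counts inside/outside
— one explicit convention for a balance the source analyses leave
implicit.

## Single-cell photocurrents

Chopped-light chronoamperometry traces (15 s on / 10 s off, three
cycles) are analyzed per dark-to-light transition $t_{on}$: the current
in $(t_{on}-3, t_{on}-1)$ s and $(t_{on}+1, t_{on}+4)$ s is fitted with
two separate linear functions and the photocurrent is their difference
at $t_{on}$. This estimator is exactly linear in the trace and exactly
invariant to any single global linear drift; the asymmetric windows (2 s
and 3 s) follow the source protocol verbatim. The cell-induced
photocurrent $\Delta i$ is the mean per-cycle photocurrent on-cell
minus off-cell; cathodic currents are negative throughout, so an
electron-uptaking cell has $\Delta i < 0$. Group comparisons
(punctum-containing vs punctum-free vs blank film) use Welch's
two-sample t-test. The 20-point moving average exists for display only;
analysis always reads raw samples.

One statistical caveat the package's tests make explicit: with
per-cell scatter consistent with the reported group s.e.m. values
(s.d. = s.e.m. × √n at n ≈ 50), the analytic Welch power to detect a
0.2 nA group difference is only ~0.6 per experiment; the test suite
therefore checks the observed significance rate against that analytic
power rather than expecting near-certain significance.

## Copy number and concentration

Copy number is whole-cell integrated intensity, background-subtracted,
divided by the single-molecule intensity (the median localization
intensity from tracking — a robust estimate under the heavy-tailed
EMCCD intensity distribution). Concentration uses the spherocylinder
volume $V = \pi r^2 (L - 2r) + \tfrac{4}{3}\pi r^3$ of the fitted
geometry; at 4.0 × 10³ copies in a ≈ 1.25 µm³ cell this gives ≈ 5.3 µM.
Integration should use a generous mask (for an isolated cell, the whole
field with the known background level): a tight outline mask clips the
PSF tails of emitters at the cell boundary and biases the count low by
several percent.

## What the generator emulates — and what it does not

The synthetic module generates every input modality the pipeline
consumes: wide-field images of membrane-distributed emitters with an
optional punctum patch, rendered through an integrated-Gaussian PSF and
a Poisson–gamma–Gaussian EMCCD model (photon shot noise, electron
multiplication at gain 250, Gaussian read noise); stroboscopic
single-molecule tracks under a state mixture — membrane states diffuse
on the surface by tangent-plane steps re-projected after ≥10 sub-steps
per frame (keeping curvature bias controlled and the planar closed form
testable), volume states diffuse in 3-D inside the body — with
geometric bleaching and i.i.d. localization error; exponential
condensate dwells under competing escape/bleach clocks, discretized to
frames; sigmoidal time courses with Gaussian noise; and drifting,
light-chopped current traces. Every generator is bit-reproducible under
a fixed seed and emits its ground truth (emitter counts, punctum
membership, state labels, true dwells) alongside the observations.

Default geometry is a 3 µm × 0.4 µm spherocylinder — typical for
*Shewanella oneidensis* rods; the source material never prints cell
dimensions or the object-space pixel size, so both are exposed as
configuration with these defaults.

Deliberately not emulated: realistic (vectorial, aberrated) PSFs, 3-D
astigmatic localization, blinking photophysics beyond a single
effective bleaching rate, motion blur within the 4 ms exposure,
cell-to-cell optical variability, and chromatic or stage drift.
Passing tests on this generator therefore demonstrate that the
*analysis* recovers the *modeled* physics at realistic sizes and noise;
they do not certify performance against optical artefacts the model
excludes.

## Problem sizes

The shipped tests and acceptance analyses run at sizes chosen to keep
Monte-Carlo error comfortably inside the stated tolerances while
remaining quick on a laptop: ~1000 tracks (~1.5 × 10⁴ displacement
pairs) and 10⁴ Monte-Carlo walks per operator bin for the diffusion
pipeline, 2000 dwells for the escape rate, 50 trace pairs for Δi,
4000 emitters for the copy-number check, and 150 replicates per
condition for CI-coverage audits. All complete in well under a minute
apiece.
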