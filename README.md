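# punctakin

Single-cell quantification of membrane-protein punctum (condensate)
formation and its coupling to extracellular electron transfer (EET) in
rod-shaped bacteria.

In electroactive bacteria such as *Shewanella oneidensis*, the
inner-membrane electron-transfer hub protein reorganizes from a
homogeneous envelope distribution into localized, condensate-like
puncta when cells engage in EET. punctakin implements the quantitative
single-cell analyses behind that observation, for microscopists and
bioelectrochemists working with:

- **wide-field fluorescence images** of tagged membrane proteins
  (punctum detection per cell via the pixel-intensity skewness
  statistic μ̃₃ = m₃/m₂^{3/2}; copy number and concentration from
  integrated intensity / single-molecule intensity),
- **formation time courses** (sigmoid fits f(t) = a + b/(1 + e^{−(t−c)/d})
  with the derived lag time c − 2d and transition time 4d),
- **stroboscopic single-molecule tracks** (displacement-length
  distributions; Monte-Carlo cell-confinement operator and its
  regularized nonnegative inverse; maximum-likelihood Rayleigh-mixture
  resolution of Brownian diffusion states σ_k² = 2D_k t + 2ε²;
  displacement-filtered super-resolution rendering),
- **condensate exchange kinetics** (residence times thresholded at the
  fitted punctum radius R; escape rate via
  k_eff = k_bl·(t_int/t_tl) + k_e with photobleaching correction;
  quasi-equilibrium entry rate k_c = k_e·n_in/n_out),
- **chopped-light chronoamperometry** (per-cycle photocurrent from the
  dual linear fits around each light-on transition; cell-induced Δi;
  Welch group comparisons).

A first-class synthetic-data module (spherocylindrical cells, membrane
Brownian motion, EMCCD camera model, exponential dwells, drifting
current traces — all seed-reproducible with ground truth attached)
generates every input modality, so the entire pipeline is testable with
no external data.

## Worked example

Render a punctate cell, classify it, and fit single-cell formation
kinetics:

```r
library(punctakin)
geom <- cell_geometry(length = 3, radius = 0.4)   # typical rod, µm
opt  <- optics_camera()                           # 4 ms / 60 ms, gain 250

em  <- sample_emitters(geom, 400, punctum_radius = 0.25, phi = 0.3, seed = 1)
img <- simulate_cell_image(geom, em, opt, seed = 1)
classify_punctum(img, threshold = 0.8, cell_id = "cell-1")
#> # A tibble: 1 × 4
#>   cell_id skewness threshold is_punctate
#>   <chr>      <dbl>     <dbl> <lgl>
#> 1 cell-1      2.49       0.8 TRUE

tc <- simulate_formation_timecourse(a = 0, b = 1, c = 3.4, d = 0.35,
                                    sample_times = seq(0, 10, 0.5),
                                    noise_sd = 0.03, seed = 2)
glance(fit_sigmoid(tc))
#> # A tibble: 1 × 8
#>          a     b     c     d lag_time transition_time flag      n
#>      <dbl> <dbl> <dbl> <dbl>    <dbl>           <dbl> <chr> <int>
#> 1 0.000226  1.01  3.38 0.339     2.70            1.36 ok       21
```

The cell's intensity histogram is strongly right-skewed (μ̃₃ ≈ 2.5, far
above the punctum-free calibration threshold), so it is called
punctate; the fitted trajectory gives a lag of 2.70 h before punctum
formation and a 1.36 h transition window.

Resolve the two diffusion states from confined single-molecule tracks:

```r
states <- diffusion_states(D = c(0.15, 6), f = c(0.8, 0.2), epsilon = 0.03,
                           mode = c("membrane", "volume"))
trk <- simulate_membrane_tracks(geom, states, n_tracks = 1000, optics = opt,
                                k_bl = 15, seed = 3)
dd  <- displacement_distribution(trk, bins = 50, t_tl = 0.06, epsilon = 0.03)
op  <- build_confinement_operator(geom, dd$edges, epsilon = 0.03,
                                  n_mc = 1e4, seed = 4)
fit <- fit_diffusion_states(deconvolve_confinement(dd, op), K = 2, seed = 5)
tidy(fit)
#> # A tibble: 2 × 7
#>   state     D     f  D_lo  D_hi  f_lo  f_hi
#>   <int> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1     1 0.154 0.789 0.151 0.158 0.781 0.796
#> 2     2 5.44  0.211 5.22  5.66  0.204 0.219
```

After confinement deconvolution, the mixture fit recovers the dominant
mobile membrane state (D ≈ 0.15 µm²/s, ~80%) and the minor fast
periplasmic state from tracks simulated at exactly those conditions.
Every fit object supports `tidy()`, `glance()` and `autoplot()`.

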