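---
title: "Baseline correction, peak detection and profile decomposition with specdecon"
author: "specdecon authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Baseline correction, peak detection and profile decomposition with specdecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdecon)
```

# The problem

A measured spectrum is the superposition of the physics of interest —
a set of lines or bands with characteristic positions, heights and
widths — with a slowly varying instrumental or physical background and
noise. specdecon factors a spectrum back into those three parts in a
fixed stage order: resample onto a uniform grid, denoise, estimate and
subtract a baseline, detect peaks, and fit a sum of line profiles.
The order is enforced by the pipeline driver because each stage
consumes the previous stage's output; running decomposition without
detected peaks, for instance, has no well-posed initialization.

# Baseline model

A baseline is any smooth function whose subtraction leaves the
structure of interest sitting on the x-axis; it is deliberately
non-unique, and the three estimators here span the useful range of
aggressiveness.

The *linear* method draws the chord through the first and last point:
fast, shape-preserving, blind to curvature.

The two penalized least-squares (PLS) methods minimize

$$S(\mathbf z) = \sum_i w_i (s_i - z_i)^2 + \lambda \lVert D\mathbf z\rVert^2,$$

with $D$ the $(n-2)\times n$ second-difference operator. The
stationary condition gives the sparse banded system
$(W + \lambda D^{\top}D)\,\mathbf z = W\mathbf s$, solved here by a
sparse Cholesky factorization (the `Matrix` package); the contract is
the solution, not the factorization, and the test suite pins it
against a dense direct solve to 1e-8.

Both iterative methods start from unit weights:

* **airPLS** sets $w_i = 0$ where $s_i \ge z_i$ (whatever is already
  above the baseline is preserved) and
  $w_i = \exp(t\,\lvert d_i\rvert / \lVert d^-\rVert_1)$ below it,
  with $t$ the iteration number and $d^-$ the negative residuals; the
  first and last weight are anchored positive so the ends stay tied
  to the data. It stops when
  $\lVert d^-\rVert_1 < \text{ratio}\cdot\lVert s\rVert_1$.
* **arPLS** computes the mean $\mu$ and standard deviation $\sigma$
  of the negative residuals and applies the logistic weight
  $w_i = 1/(1+\exp(2(d_i - (2\sigma - \mu))/\sigma))$, which is close
  to 1 at or below the baseline and decays to 0 for samples far above
  it. Peaks therefore cannot drag the baseline upward, and the
  detrended signal is primarily positive — the behavior a
  spectroscopist expects. It stops when the relative change of the
  weight vector drops below `ratio`; if no negative residuals remain
  the current baseline is returned as a degenerate success.

Both share the knobs λ (default 200) and `ratio` (default 1e-6).
λ is the parameter worth tuning: its useful magnitude grows with the
smoothness of the drift relative to the peak widths. The defaults
suit signals with few features; the drift stress cases in the test
suite use λ = 1e5–1e6, and the broad-band suite shows why the choice
matters — at λ ≳ 1e7 the baseline is too stiff to follow the drift
(positivity degrades), while well below 1e6 it is flexible enough to
swallow a weak band that overlaps a stronger one.

# Peak detection

Candidates are indices where $-y''$ (central second differences on
the uniform grid) is a strict local maximum with positive curvature.
Using curvature rather than intensity maxima is what resolves
shoulders: a weak component overlapping a strong one deforms the
curvature into a second extremum long before it produces a second
maximum of $y$ itself. A curvature floor of
$10^{-9}\max\lvert y\rvert/h^2$ guards against floating-point jitter
on exactly smooth segments.

The window of `windowSize` samples is then propagated along the grid.
A candidate becomes a peak when

1. no candidate of higher intensity lies in the window centered on it
   (exact ties break toward the smaller index),
2. the in-window amplitude range $\max y - \min y$ reaches
   `threshold`, and
3. its intensity reaches `minAmplitude`.

Smaller windows let more candidates dominate their own neighborhood,
so the count is non-increasing in window size; it is always
non-increasing in the two filters. One interaction deserves note: the
amplitude range inside a window grows with the window, so the
threshold filter *relaxes* as windows grow. The window-size
monotonicity is therefore a property of the regime where every peak
of interest already passes the threshold at the smallest window —
thresholds at or below the smallest-window noise range — and that is
the regime the acceptance grid tests. Conversely, a threshold sized
against a window much narrower than a band's width will reject the
band (the range near a broad top is tiny); window sizes near the
FWHM of the narrowest feature of interest, with thresholds well under
the band heights, are good defaults.

`minAmplitude` is applied to the detrended intensity at the peak, not
to prominence; it is the practical filter for noise-induced bumps on
experimental data.

# Profile decomposition

Each detected peak seeds one component. Three height-parameterized
families are supported; height (not area) parameterization matches
the initialization from detected peak intensities, and areas can be
derived downstream ($A\sigma\sqrt{2\pi}$ for a Gaussian,
$\pi A \gamma$ for a Lorentzian).

The Voigt profile is evaluated through the Faddeeva function,
$V(x) \propto \Re\,w\!\big((x-c+i\gamma)/(\sigma\sqrt2)\big)$,
computed by Weideman's rational approximation (N = 36), which is
accurate to near machine precision over the closed upper half-plane
including both limiting regimes (γ→0 Gaussian, σ→0 Lorentzian). A
pseudo-Voigt (weighted sum) was rejected: it misstates wing weight at
intermediate σ/γ, which is exactly where family discrimination
matters.

The fit minimizes $S = \sum_i \rho(r_i^2)$ with
$r = \text{model} - \hat s$ and ρ one of `linear` ($u$), `soft_l1`
($2(\sqrt{1+u}-1)$), `huber`, `arctan` (scale fixed at 1 in units of
the — typically max-normalized — signal). The linear loss goes
straight to a bounded Levenberg–Marquardt solve (`minpack.lm`); the
robust losses are handled by iteratively reweighted least squares
with weights $\rho'(r^2)$. Because every ρ here is concave in
$u = r^2$, each reweighted solve minimizes a majorizer, so the robust
objective decreases monotonically; the implementation additionally
never returns parameters costlier than its initialization, and
warm-started calls continue from the previous parameters so a long
optimization can be inspected in slices of `maxIter`.

Numerical choices:

* **Initialization.** Centers at detected positions, heights at
  detected intensities, widths from the detected curvature
  ($\sigma_0=\sqrt{A/\lvert y''\rvert}$, exact for a Gaussian),
  capped by half the distance to the nearest neighboring peak so
  overlapping initializations cannot merge, and clipped to
  [one grid step, 10% of the x span].
* **Bounds.** Centers are box-bounded to ±`windowSize` grid steps
  around their detected position to prevent component swapping during
  joint optimization (`freeCenters = TRUE` lifts this); heights are
  non-negative; widths live in [h/20, span].
* **Determinism.** No random restarts; identical inputs give
  identical fits.
* **Jacobians.** Analytic for Gaussian and Lorentzian components; the
  Voigt family uses the solver's finite differences.

# Miller indexing

For tetragonal lattices the engine enumerates all $(h,k,l)$ with
$0 \le h,k,l \le$ `hklMax` (default 6), predicts 2θ from
$1/d^2 = (h^2+k^2)/a^2 + l^2/c^2$ and $n\lambda = 2d\sin\theta$, and
assigns each observed reflection the triple of smallest 2θ residual.
$d$ is invariant under $h\leftrightarrow k$, so only $h\ge k$
representatives are enumerated and exact-d ties resolve to the
lexicographically smallest triple — deterministic and matching the
conventional form (1 0 1 rather than 0 1 1). Triples whose $d$
implies $\sin\theta > 1$ are geometrically unobservable and skipped.
No structure-factor extinction rules are applied: the assignment is
purely geometric, so systematically absent reflections of a given
space group would still be offered if an observed angle lands on
them. Lattice-constant refinement is likewise out of scope.

# The synthetic generator, and what passing means

`makeSuite()` builds four deterministic families with embedded ground
truth:

```{r suites}
for (nm in c("fig1_multisine", "fig2_test", "narrow_xrd",
             "broad_uvvis")) {
  m <- makeSuite(nm)[[1]]
  cat(nm, ": ", nrow(m$truth@components), " components, baseline ",
      m$truth@baselineSpec$type, ", noise sigma ",
      m$truth@noiseSigma, "\n", sep = "")
}
```

* `fig1_multisine`: four well-separated Gaussians on a strong drift
  summed from three sines with periods ≥ 30% of the span — the stress
  case for baseline estimation. What must hold here is that airPLS
  and arPLS change peak *amplitudes*, not *positions* (argmax
  agreement within one grid step). Exact peak-count recovery is not a
  fair ask on this member: any PLS detrend of so extreme a drift
  leaves residual curvature that forms genuine shoulders on the peak
  flanks.
* `fig2_test`: five mixed-width Gaussians, one clean member and one
  with gentle affine drift and 0.4% noise, used for the detector's
  count-recovery and filter-monotonicity checks.
* `narrow_xrd`: ten and seven sharp reflections (σ < 1% of span,
  including one pair 1.2° apart) on flat background.
* `broad_uvvis`: four strongly overlapping bands (σ 20–28 nm, one
  separation below the sum of widths, the weakest band fully inside
  its neighbor's flank) on a multisine drift, one clean and one noisy
  member, generated over 380–780 nm.

All randomness flows through a seeded Mersenne–Twister, restored on
exit, so each truth object regenerates a bit-identical spectrum.

These families emulate the *shapes* real techniques produce, not
their noise physics: noise is additive i.i.d. Gaussian, with no shot
noise, cosmic spikes, detector nonlinearity or wavelength-dependent
response. Passing the suite shows the algorithms recover what they
claim under those conditions — solver correctness, shoulder
resolution, parameter recovery to optimizer precision, monotone
filter behavior — and says nothing about, e.g., robustness to cosmic
rays, which a user should handle upstream.

Test problem sizes (grids of 1 400–2 000 points, 2–10 components, 50
random solver instances up to n = 200) were chosen as the smallest
sizes at which the asymptotic behaviors under test are clearly
expressed.

# Design decisions on open points

* The denoiser is a centered boxcar mean (truncated at edges, even
  windows left-heavy): the one-parameter filter matching a "window
  size" knob; repeated application with shrinking windows is
  supported both by chaining and a `repeats` argument.
  Savitzky–Golay is a natural extension hook but is not built in.
* Interpolation is linear, not spline: splines overshoot at sharp
  features and would manufacture curvature candidates.
* Duplicate x values are an input error rather than being averaged:
  silently averaging would hide acquisition problems and downstream
  derivative operators require a strictly increasing grid.
* Descending or unordered input x is sorted on ingestion (files in
  descending wavenumber are common).
* The detector evaluates each candidate against the window centered
  on it. A step-1 sliding window that accepts the best candidate of
  *every* placement degenerates — any candidate wins some placement
  that excludes its taller neighbors — which would void both the
  window-size monotonicity and position stability under noise; the
  centered form is the reading under which the documented properties
  hold.
* Robust-loss scale is fixed at 1 in normalized-signal units rather
  than estimated from residuals: estimation couples the loss to the
  data and breaks the reproducibility contract.
* `normalizeSpectrum()` requires a positive maximum; all-zero or
  all-negative intensities have no meaningful unit-maximum scaling.

# Known limitations

* Peak detection on finely sampled noisy data needs denoising first;
  curvature is a second difference and amplifies high-frequency noise
  by $1/h^2$. The pipeline's stage order exists for this reason.
* The second-derivative candidate rule cannot separate components
  whose curvature extrema merge (separation well below σ); those
  require iterating detection on fit residuals, which is left to the
  user's loop.
* Miller indexing covers tetragonal cells only, and reports the
  geometrically nearest triple even where diffraction physics would
  extinguish it.
* Baseline and decomposition interact: a too-flexible baseline
  (small λ) absorbs broad weak bands before the fit ever sees them.
  The λ guidance above, and inspection of the baseline artifact the
  pipeline writes, are the mitigation.
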