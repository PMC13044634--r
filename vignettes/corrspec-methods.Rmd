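---
title: "Models and methods in corrspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in corrspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrspec)
```

corrspec estimates molecular transport parameters — diffusion
coefficients, concentrations, and dark-state (triplet) kinetics — from
fluorescence fluctuation data, in two acquisition modes: point FCS
(fluorescence correlation spectroscopy), where a photon-count trace is
recorded at a fixed confocal focus, and RICS (raster image correlation
spectroscopy), where the scan pattern of a confocal image encodes time in
space. This vignette explains the models the package implements, the
numerical choices behind them, and what the simulation-based validation
does and does not demonstrate.

## The correlation functions

For a photon trace $I(t)$ the temporal autocorrelation is

$$G(\tau) = \frac{\langle \delta I(t)\, \delta I(t+\tau)\rangle}
                 {\langle I \rangle^2},
  \qquad \delta I = I - \langle I \rangle,$$

with $\langle I\rangle$ the mean over the selected analysis window (not
the full trace): restricting the window excludes unstable segments, and
the normalization must be consistent with the fluctuations actually
correlated. `acf_fcs()` evaluates the estimator with a zero-padded FFT,
using the conventional biased ($1/M$) normalization of the numerator;
the FFT path is tested to agree with the direct $O(N^2)$ double sum to
$10^{-10}$ relative error. The zero lag, dominated by detector shot
noise, is not returned.

For a RICS frame $I(x, y)$ the spatial autocorrelation over pixel lags
$(\xi, \psi)$ is the spatial average of $\delta I(x,y)\,\delta
I(x+\xi, y+\psi)$ over all pixel pairs inside the frame, normalized by
the squared mean intensity (`mode = "mean_normalize"`). The raster scan
maps each spatial lag to a temporal lag

$$\tau(\xi, \psi) = \xi\, t_{\mathrm{pix}} + \psi\, t_{\mathrm{line}},$$

with $t_{\mathrm{line}}$ including the flyback dead time. For structured
samples (cells), a per-condition average image can be subtracted first
(`mode = "background_subtract"`); the printed normalization rule for this
variant ("dividing by the squared variance") is ambiguous between the
variance and its square, so `acf_rics()` divides by the variance raised
to `variance_power` (default 1, which makes the zero-lag value
approximately one) and exposes the exponent as a configuration switch
rather than guessing silently.

Sector splitting (`sector_grid()`, `split_sectors()`) supports three
configurations: each sector correlated with itself, a larger concentric
area correlated with itself (better statistics at low photon counts),
and a reference sector cross-correlated against a concentric larger area.
Sector centres are evenly distributed with every correlation area fully
inside the image; the extreme regions touch the borders, and rounding
ties move centres toward the image centre.

## The diffusion models

With a 3D Gaussian PSF $\mathrm{PSF}(\mathbf r) = \exp(-2x^2/\omega_x^2
- 2y^2/\omega_y^2 - 2z^2/\omega_z^2)$ (waists are $1/e^2$ radii, not
FWHM), the effective focal volume is

$$V_{\mathrm{eff}} = \frac{\left[\int \mathrm{PSF}\, dV\right]^2}
                          {\int \mathrm{PSF}^2\, dV}
                   = \pi^{3/2} (s\omega_x)(s\omega_y)(s\omega_z),$$

where $s \in [0, 2]$ is a dimensionless PSF scale factor that can absorb
calibration error. The spatiotemporal correlation model for anisotropic
free diffusion is

$$G(\boldsymbol\Delta, \tau) = \frac{1}{V_{\mathrm{eff}}\langle C\rangle}
  \prod_{i \in \{x,y,z\}} \frac{\omega_i}{\sqrt{4 D_i \tau + \omega_i^2}}
  \exp\!\left(-\frac{\Delta_i^2}{4 D_i \tau + \omega_i^2}\right).$$

**Amplitude convention.** Printed forms of this model sometimes carry
both a $1/V_{\mathrm{eff}}$ prefactor and per-axis
$[\pi(4D\tau+\omega^2)]^{-1/2}$ volume factors, which double-counts the
normalization dimensionally. corrspec implements the standard
fluctuation result $G(0,0) = 1/(V_{\mathrm{eff}}\langle C\rangle)$ —
the bracket above is dimensionless and equals one at $\tau = 0$,
$\boldsymbol\Delta = 0$ — because this is the convention under which
$V_{\mathrm{eff}}$ "determines the molecular occupancy" and
concentrations are recoverable in physical units. No additional
geometric $\gamma$ factor is applied. Concentrations are supplied in nM
and converted internally with $1\ \mathrm{nM} = 0.6022$ molecules/µm³.

Two-component models mix the component contributions linearly with
fraction $f$; identifiability ($D_1 < D_2$) is enforced by sampling in
$(D_1, \Delta D = D_2 - D_1 > 0)$, which removes label switching by
construction. Triplet (dark-state) kinetics multiply the correlation by
$1 + \frac{\mathrm{TSA}}{1-\mathrm{TSA}} e^{-\tau/\tau_T}$. Pixel lags
map to sample-frame displacements through the pixel sizes and a rotation
about the optical axis by the scan angle $\alpha$; anisotropic kinds
support three axial conventions (`free`, `uniaxial` $D_z = D_y$,
`quasi2d` $D_z = 0$). Point FCS is the exact $\boldsymbol\Delta = 0$
special case of the same model.

### Measured PSFs

A measured 3D PSF (bead-stack average) replaces the Gaussian closed form
with the numerical model

$$G(\boldsymbol\Delta, \tau) \propto \int\!\!\int
  \mathrm{PSF}(\mathbf r)\, K(\mathbf r' - \mathbf r, \tau)\,
  \mathrm{PSF}(\mathbf r' - \boldsymbol\Delta)\, d^3r\, d^3r',$$

with $K$ the free-diffusion Green's function (separable Gaussian,
per-axis variance $2 D_i \tau$), normalized by $\langle C\rangle
[\int \mathrm{PSF}]^2$. `g_measured()` evaluates this as a per-axis
Gaussian blur of the grid followed by an inner product with the PSF
shifted by $\boldsymbol\Delta$ (trilinear interpolation off-grid). Three
numerical tolerances matter:

* the grid must cover the PSF support *and* the blurred support at the
  largest lag fitted — edge values above 1% of peak trigger a warning in
  `v_eff()`;
* a blur sigma below half a voxel (but nonzero) falls back to the
  unblurred grid with a warning — at such lags the kernel cannot be
  sampled on the grid;
* trilinear interpolation of the shifted PSF contributes the dominant
  off-grid error.

On a grid sampled from the Gaussian PSF itself, `g_measured()` agrees
with the closed form to better than 2% across the tested $(\tau,
\Delta)$ lattice and converges as the voxel size shrinks. At $\tau = 0$,
$\boldsymbol\Delta = 0$ the identity $G = 1/(V_{\mathrm{eff}}\langle
C\rangle)$ holds exactly by construction (tested).

Bead processing (`build_psf_from_beads()`) localizes peaks above a
threshold, rejects beads closer than twice the exclusion extent,
extracts subvolumes (half-width five fitted waists per axis), aligns
them on Gaussian-fit centroids, averages, and fits the Gaussian
ellipsoid to report equivalent waists. A per-stack median background
subtraction (switchable) removes detector offset. Voxel downsampling
(`downsample_psf()`) is block-mean pooling with floor division —
trailing planes that do not fill a block are dropped, so a 35×35×43 grid
becomes 17×17×21 at factor 2 and 11×11×14 at factor 3 — and preserves
the grid integral up to those dropped planes.

## Error models, fitting, and model comparison

All fitting minimizes or samples around the chi-squared form
$\chi^2(\theta) = r^\mathsf{T} W r$ with $r = y - f(x, \theta)$:

* **OLS** — $W = I$; the common error variance is estimated post hoc as
  $\hat\sigma^2 = \chi^2(\hat\theta)/(n-p)$ (frequentist), or inferred
  jointly as an additional scale parameter with a log-uniform prior over
  $[10^{-6}, 10^{2}] \times \mathrm{sd}(y)$ (Bayesian — a proper
  likelihood needs an explicit noise scale).
* **WLS** — $W = \mathrm{diag}(1/\sigma_i^2)$, with $\sigma_i$ the
  per-lag standard error of the mean across traces or frames (attached
  automatically by `acf_mean()` and `acf_rics()` when at least two
  replicates contribute).
* **GLS** — $W = \Sigma^{-1}$ with the empirical lag covariance
  estimated from $N$ replicate ACFs with the $1/(N-1)$ normalization.
  $\Sigma$ is symmetrized and validated positive definite by Cholesky
  factorization with escalating diagonal jitter up to $10^{-8}$ of the
  mean diagonal (logged; never a silent pseudo-inverse). All quadratic
  forms and the Gaussian likelihood normalization go through the
  Cholesky factor.

**Which covariance for a pooled fit?** The replicate-ACF covariance
describes a *single* trace. When the pooled fit is of the *mean* ACF,
the statistically calibrated choice is $\Sigma/N$
(`estimate_covariance(..., target = "mean")`). The default, however, is
the per-trace matrix (`target = "single"`), because that is the
established workflow convention in this field: it keeps the effective
information content of the GLS fit at the single-trace level, which is
what produces the characteristically broad GLS posteriors relative to
OLS (OLS fits the mean curve, whose residuals are tiny, and therefore
underestimates uncertainty — the motivating failure mode for correlated
error modelling). Both targets are available; goodness-of-fit statistics
under `target = "single"` are deflated by roughly $1/N$ and should be
read comparatively, not absolutely.

GLS is supported for FCS only. For RICS, estimating a stable covariance
of the ~300-point flattened fitting vector would require thousands of
independent frames per condition; `fit_nls()` and `fit_bayes()` refuse
GLS on 2D correlation data with an explanatory error.

**Baseline offsets for small scans.** Subtracting the frame mean biases
the spatial ACF of a finite image by a small negative constant (of order
the correlation area over the image area times the amplitude), and the
per-frame mean and variance estimates add further terms of the same
order. At production image sizes (10⁶ pixels) these are negligible; at
the small scans used for desk-scale validation they are not.
`model_spec(offset = TRUE)` adds an additive constant nuisance parameter
that absorbs the baseline — one offset *per condition* in joint fits,
because the bias and the finite-stack occupancy noise are per-stack
quantities (sharing a single offset lets per-stack baseline differences
masquerade as anisotropy). Working at a concentration where the
amplitude is modest (a few nM, $G(0) \lesssim 0.5$) keeps the residual
bias terms at the percent level.

**NLS.** Bound-constrained Levenberg–Marquardt on the weighted
residuals, from a deterministic multi-start: the prior-box centre, a
±quarter-range offset per parameter (2p+1 grid starts), and one
moment-based start (concentration from the short-lag amplitude,
diffusion coefficient from the half-decay lag). The best chi-squared
wins; active bounds are flagged on the result. Standard errors come from
the weighted Jacobian, scaled by $\hat\sigma^2$ for OLS.

**Bayesian inference.** Priors are independent uniforms on finite boxes
(defaults: diffusion coefficients 0–5000 µm²/s, concentration 0–1000 nM,
TSA 0–1, $\tau_T$ 0.01–10⁴ µs, PSF scale 0–2), adjustable per
parameter — e.g. very dilute samples benefit from a realistic
concentration range, since the posterior mass otherwise occupies a
vanishing fraction of the prior box. Sampling uses a self-contained
static nested sampler: live points in the unit hypercube, likelihood-
constrained replacement by a Gaussian random walk whose proposal
covariance tracks the live set (step size adapted toward a 15–50%
acceptance window), termination when the remaining evidence contribution
falls below `dlogz`, and live-point draining at the final prior volume.
It returns weighted posterior samples, the log-evidence $\log Z$ with
the information-based uncertainty $\sqrt{H/K}$, and posterior-predictive
68.3%/95.5% quantile-range bands. On a conjugate Gaussian-mean toy the
sampler reproduces the analytic evidence within its reported uncertainty
(tested). Exact sampler settings are not prescribed by the field;
defaults (200 live points, `dlogz = 0.05`, 25-step walks) were chosen so
the conjugate-toy check passes with margin.

**Model comparison.** `compare_evidence()` ranks posteriors by $\log Z$
and labels pairwise differences with the conventional bands
(|Δlog Z| < 1 indistinguishable, 1–3 positive, 3–5 strong, > 5 very
strong); it refuses to compare fits with different error models or data.
Nested models can also be compared frequentistly with
`f_test_nested()`, $F = \frac{(\chi^2_s - \chi^2_c)/(p_c - p_s)}
{\chi^2_c/(n - p_c)}$. Goodness of fit reports SSR, $\chi^2$, and
$\chi^2_\nu = \chi^2/(n-p)$; for posteriors these are evaluated at the
posterior median, and residuals are presented in the transform matching
the error model (raw, standardized $r_i/\sigma_i$, or decorrelated
$L^{-1} r$).

## The synthetic-data generator

`simulate_fcs_trace()` and `simulate_rics_stack()` are a
Brownian-dynamics photon-emission simulator, used both for fixtures and
for end-to-end validation. Particles diffuse freely in a periodic box
centred on the focus (periodic boundaries preserve uniform
concentration; the box should exceed ~5 PSF waists per axis, warned
otherwise); per time bin each particle takes an independent Gaussian
step of per-axis standard deviation $\sqrt{2 D_i\, dt}$, and the photon
count is Poisson with mean $dt\,(\mathrm{background} +
\mathrm{brightness} \sum_k \mathrm{PSF}(\mathbf r_k))$ evaluated at the
bin start (no sub-bin integration; $dt$ is far below the diffusion time
at all settings used). The PSF is peak-normalized so brightness is
counts/s per molecule at the focus; the default brightness is
30,000 counts/s, a typical single-fluorophore value. Raster scanning
advances particles through each pixel dwell and through the flyback dead
time, during which no photons are recorded; the scan axes are rotated by
$\alpha$ in the sample frame. The RNG is a dedicated xoshiro256++
stream seeded from the configuration seed, so traces are bit-identical
across runs and platforms and independent of R's RNG state. Ground
truth (all generator parameters and the seed) is stored in the output
metadata.

The reference validation conditions are: single-trace — 100 particles in
a 2.5 × 2.5 × 7 µm box, $D = 100$ µm²/s, 1 µs steps, Gaussian PSF with
waists (0.3, 0.3, 1.1) µm; multitrace — 25 particles in 8 × 8 × 12 µm,
$D = 20$ µm²/s. The generator emulates free diffusion with ideal
Poisson detection only: no detector afterpulsing or dead time, no
photobleaching, no triplet blinking (models can *fit* TSA, but
validation data have TSA = 0), no optical aberrations. Passing the
recovery tests therefore demonstrates correctness of the estimators and
inference under the stated model, not robustness to every artifact of
real hardware.

**Problem sizes.** The validation and acceptance runs use desk-scale
versions of the reference conditions, chosen once: the single-trace
recovery simulates 8 s (analysis window scaled proportionally from the
10–70 s window of the 80 s condition) with three seeds; the multitrace
cohort uses 64 traces of 10 s at a 2 µs bin (the bin is still ~500×
below the diffusion time $\omega_{xy}^2/4D \approx 1.1$ ms); the
initial ACF points of the cohort curves are excluded
(`drop_first = 3`), the standard step for removing short-lag
contamination, which at desk scale also removes the finite-duration
estimator bias that a triplet term would otherwise absorb. The
in-package test suite uses smaller versions of the same scenarios
(8 s trace; 48 traces of 6 s). The multitrace workflow sets
concentration and diffusion prior ranges to 0–50 nM and 0–1000 µm²/s —
system knowledge for a ~0.05 nM sample, applied identically under every
error model.

RICS validation uses 64×64-pixel scans (0.05 µm pixels, 4 µs dwell,
25% flyback) of 50–100 frames at ~5 nM, with the 3.2 µm scan area kept
small against the 8 × 8 × 6 µm simulation box — a scan that spans most
of a periodic box correlates through the wrap and biases the fast-axis
decay. Anisotropy validation fits four scan angles (0°, 45°, 90°,
135°): a symmetric angle set probes the x and y axes with the fast and
slow scan directions equally, so any residual fast-axis estimator bias
cancels in DCx − DCy. Per-point WLS uncertainties understate the
frame-to-frame correlation of RICS ACF points, so the isotropic
control needs an adequate frame budget for the 2-sigma anisotropy flag
to have a low false-positive rate; at the sizes above the flag behaves
correctly in both directions.

## Screening and mapping

`select_stable()` drops leading traces/frames whose smoothed running
mean deviates from the tail mean by more than a stated fraction
(default 10%), floored at three times the shot-noise scatter of the
smoothed tail so that counting noise alone cannot trigger exclusions —
the published workflows describe visual exclusion of unstable
prefixes, so this automated rule is a stand-in and its fraction is an
exposed parameter. `preanalyze_dc_c()` computes quick per-item
(DC, C) values with the simplest compatible model (single-component
isotropic, no triplet, NLS-OLS) and excludes items outside explicit
ranges or beyond 5 MAD of the cohort median; these per-item values are a
screening statistic, not final estimates. Every input item appears
exactly once in the report, kept or excluded with a reason, and
filtering is idempotent.

`map_parameters()` runs the sector → ACF → crop → fit pipeline per
sector and assembles per-parameter maps (row 1 at the image top, centres
in µm). Failed sectors are masked with their reason — maps never
interpolate over failures — and each map cell is exactly the result of
running the single-sector pipeline independently (tested). The default
per-sector error model is OLS, matching common mapping practice; WLS is
available when ≥ 2 frames supply per-point SEMs. `angular_summary()`
tabulates multi-angle fits and flags anisotropy when |DCx − DCy|
exceeds twice the combined uncertainty.

Sectors straddling structural boundaries (e.g. a cell edge) receive no
special handling; their fits simply reflect mixed content.

## Persistence

All containers round-trip losslessly through a self-describing HDF5
layout (`/traces`, `/images`, `/acf`, `/fits`, `/psf`; every object
group carries a layout version, units, and free-form attributes;
simulated objects carry a `ground_truth` subgroup). The layout itself is
package-defined plumbing — published workflows standardize on HDF5 but
no public schema exists, so foreign layouts need a converter.
Posteriors additionally export to NetCDF-4 with `posterior/<parameter>`
variables over `(chain, draw)` dimensions and the evidence as global
attributes, following the ArviZ storage conventions. Bead stacks can be
read from multi-page TIFF.

## Known limitations

* Single-trace Bayesian OLS model comparison on *ideal* simulated data
  discriminates the unused triplet component (|Δlog Z| ≈ 3–5 in favour
  of the simple model, the triplet's prior-volume penalty), rather than
  returning the indistinguishable evidences reported for comparable
  published workflows. Bin-averaged ACF points from a clean
  Poisson-emission simulation constrain the triplet amplitude tightly;
  the published tie reflects far noisier per-point single-trace ACFs
  and real-detector short-lag structure that the triplet term can
  absorb. The companion failure mode that does reproduce is the
  artificially narrow OLS posterior relative to GLS.
* The triplet model's posterior under near-zero triplet amplitude is an
  awkward shape for nested sampling (a degenerate slab where the
  relaxation time is invisible joined to a thin amplitude band); its
  log-evidence carries extra run-to-run scatter beyond the reported
  uncertainty unless live points and walk lengths are increased
  (`n_live`, `n_mcmc`).
* The nested sampler uses a single random-walk walker per replacement;
  strongly multimodal posteriors (e.g. a diffuse noise-dominated mode
  competing with a narrow physical mode under extreme priors) can trap
  it — realistic prior ranges are the practical remedy.
* GLS is unavailable for RICS (by design, see above); shrinkage
  covariance estimators and segmented/randomized ACF decorrelation are
  not implemented.
* The measured-PSF model inherits grid-support and interpolation error;
  fits at lags whose diffusive spread approaches the grid extent are
  biased (warned via the edge check).
* `g_measured()` with a fitted PSF scale factor is not supported (the
  scale would have to rescale the grid coordinates); the scale factor is
  a Gaussian-PSF feature.
* Two-photon/flow/anomalous-diffusion terms, FCCS cross-correlation
  between color channels, and multi-tau hardware-correlator emulation
  are out of scope.
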