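---
title: "Models and methods: quantifying RNA-liposome cluster assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying RNA-liposome cluster assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipoclust)
```

## The system

When RNA is mixed with cationic (e.g. DOTAP) liposomes, the anionic RNA
first adsorbs electrostatically onto individual liposomes; the partially
RNA-coated liposomes then aggregate by diffusive hit-and-stick encounters
into micrometre-scale clusters with irregular, often branched morphology.
`lipoclust` implements the quantitative-imaging side of this problem
(two-channel fluorescence feature metrics) together with the three physical
models that describe the assembly, and a synthetic-scene generator that
renders ground-truth data so every stage can be validated end to end without
microscope data.

## The adsorption stage

The initial stage is modelled as a sequential, irreversible pure-birth
process: a liposome holding $k$ RNA molecules acquires the next one at rate
$\lambda_0 (k+1)$. This is the minimal sequential scheme whose population
law at any time is exactly geometric,
$$P(n) = \frac{1}{1+\langle n\rangle}\left(\frac{\langle n\rangle}{1+\langle n\rangle}\right)^{n},$$
the discrete counterpart of an exponential RNA-per-liposome distribution,
with the mean set by the RNA-to-liposome ratio $r_0/L_0$. Because the
microscopic scheme is not uniquely pinned down by the equilibrium law, a
constant-rate variant (whose law is Poisson) is retained as a labelled
negative control; both are options of `adsorption_model()`. The same
geometric law arises model-independently by maximizing Shannon entropy
subject only to normalization and the fixed mean; `maxent_distribution()`
solves that program numerically (exponential-family dual with the multiplier
found by root finding on a support truncated at $10^{-12}$ tail mass) and the
test suite verifies it coincides with the kinetic equilibrium to total
variation below $10^{-6}$.

`simulate_adsorption()` is an exact stochastic simulation: under the linear
rule the embedded jump chain assigns each successive RNA to a liposome with
probability proportional to $k+1$, which is simulated O(1) per event by an
urn scheme, while waiting times are drawn from the exact exponential law.
The default stopping rule halts when the empirical mean load reaches
$r_0/L_0$, which enforces the stated mean exactly; finite-pool bookkeeping is
available but off by default.

```{r adsorption-example}
mod <- adsorption_model(r0 = 2e4, L0 = 1e4, lambda0 = 1)
sim <- simulate_adsorption(mod, n_liposomes = 5000, seed = 1)
mean(sim$counts)
```

## The aggregation stage

Cluster growth follows the Smoluchowski coagulation equation
$$\frac{dn_k}{dt} = \tfrac12 \sum_{i+j=k} K_{ij} n_i n_j - n_k \sum_j K_{kj} n_j .$$
Three routes are implemented and cross-validated:

* **Closed form** (`constant_kernel_solution()`): for a constant kernel $K$
  and monodisperse start, with $x = t/\tau$ and $\tau = 2/(K n_0)$,
  $n_k = n_0\, x^{k-1}/(1+x)^{k+1}$, so $N = n_0/(1+x)$ and the scaled law
  $n_k/N$ is geometric with mean $1 + x$.
* **Truncated ODE** (`integrate_ode()`): stiff-safe `deSolve::lsoda`
  integration on $k \le k_{\max}$, with $k_{\max}$ doubled until the mass in
  the top decile of bins stays below $10^{-8}$ of the total, and a mass
  audit at every output time (relative drift above $10^{-6}$ is an error,
  not a warning — truncation leakage should never pass silently).
* **Exact stochastic simulation** (`simulate_gillespie()`): the
  Marcus-Lushnikov process, in which each unordered pair reacts at
  propensity $K(k_a, k_b)/V$. For size-independent kernels the process is
  exchangeable, so waiting times (which depend only on the cluster count)
  and the uniformly random merging pairs are pre-drawn in bulk, giving an
  O(1)-per-event loop that handles $10^5$–$10^6$ monomers in seconds;
  size-dependent kernels use a class-aggregated direct method intended for
  small populations.

The Brownian encounter kernel
$K_{ij} = \tfrac23 \frac{k_B T}{\eta} (R_i + R_j)(R_i^{-1} + R_j^{-1})$ with
the fractal radius law $R_k = R_1 k^{1/d_f}$ motivates the constant-kernel
approximation: $K_{ii} = \tfrac83 k_B T/\eta$ for every size, and for
$d_f = 2$ the kernel varies by less than 8% across size ratios up to 2.

Two observational diagnostics connect the model to image data. The size law
maps to a radius-of-gyration distribution through
$R(k) = a\,k^{1/d_f}$ (`rg_distribution_from_counts()` performs the change
of variables and renormalizes numerically). Dynamic scaling is tested with
`collapse_statistic()`: each sample set is divided by its own mean and the
maximum pairwise two-sample Kolmogorov-Smirnov distance is reported. KS was
chosen because it is distribution-free; the collapse itself is assessed at
late scaled times ($x = t/\tau \gtrsim 30$) because at coarse means the
*discrete* geometric law has atoms at different mean-scaled positions and
genuinely does not collapse — the continuum (exponential) limit does. The
test suite demonstrates both regimes.

`fit_growth()` extracts the growth timescale $\tau$ from
$N(t) = N_0/(1+t/\tau)$ (least squares, with the exact linearization
$1/N$ vs $t$ supplying starting values) and the power-law exponent of mean
$R_g$ growth from a log-log fit over a late-time window, defaulting to
$t \ge 3\hat\tau$; the window is configurable because mean-field power-law
behaviour is only asymptotic.

## The patchy-binding stage

Fractional RNA surface coverage $f$ (geometric footprint model,
`coverage_fraction()`: $f = \min(1, n \cdot \text{footprint} / 4\pi r^2)$)
controls whether two touching liposomes can bind: a bare (positive) patch
must meet an RNA-coated (negative) patch, so the binding probability is
proportional to $f(1-f)$ — zero at $f=0$ and $f=1$, maximal at half
coverage. `binding_probability()` exposes both the raw form $f(1-f)$ and the
normalized $4f(1-f)$ (default), which spans $[0,1]$; only the shape is fixed
by the argument, so the normalization is a reporting convention.
`simulate_patchy()` validates the resulting non-monotonic growth-rate curve
in silico by thinning every coagulation propensity by $4f(1-f)$ — a
size-independent multiplicative factor, the minimal well-mixed model
consistent with a growth rate proportional to the binding probability (the
spatial, orientation-resolved version is out of scope). Early-time growth
rates are the slope of $\langle k\rangle(t)$ over the first 20% of the run
or until $\langle k\rangle = 3$, whichever comes first; for the constant
kernel $\langle k\rangle = 1 + t/\tau$ is linear, so the window choice
affects only the noise, not the estimate.

```{r patchy-example, eval = FALSE}
prof <- patchy_rate_profile(seq(0.1, 0.9, 0.1), N0 = 2000,
                            replicates = 50, t_end = 2, seed = 9)
plot(prof$f, prof$rate, type = "b", xlab = "coverage f",
     ylab = "early-time growth rate")
lines(prof$f, growth_rate_curve(prof$f, k0 = max(prof$rate)), col = 2)
```

## The synthetic-scene generator

`generate_ground_truth()` emulates the study's imaging data: fields of
clusters whose per-cluster monomer counts follow a geometric law with a
time-growing mean, rendered into two channels (liposome, RNA) with an
isotropic 2-D Gaussian PSF, a background plane, Poisson shot noise and
Gaussian read noise. Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| pixel size | 0.325 µm/px | typical 20x sCMOS sampling; not stated by any imaging metadata, so configurable |
| PSF sigma | 0.3 µm | epifluorescence diffraction scale; Airy rings ignored |
| background | 100 photons | thresholding nontrivial but solvable |
| read noise | 2 photons | sCMOS-like |
| monomer flux | 2000 photons | spot peak ≈ 370 photons over background, high but realistic SNR |
| monomer radius | 0.1 µm | ~100 nm liposomes (DLS scale) |
| min. cluster separation | 2 µm | keeps diffraction-blurred features resolvable, so ground-truth counts stay meaningful |

Morphologies: `chain` (straight, spacing $2r$, with
$R_g = 2r\sqrt{(k^2-1)/12}$ exactly), `compact` (hexagonal close packing,
mass-radius exponent 2), and `fractal` (off-lattice hit-and-stick growth
with adaptive step lengths, which empirically yields mass-radius exponents
near 1.6). Scenes are deterministic for a fixed seed, and rendering is
photometrically linear before noise. 2-D only: the study analyzes planar
images; 3-D PSFs, photobleaching and stage drift are non-goals.

What passing tests on this generator do *not* show about real data: real
backgrounds are structured rather than planar, real liposomes are
polydisperse in size and brightness, clusters may overlap in projection, and
RNA labelling is not perfectly proportional to copy number. The generator is
a forward model for validating the measurement chain, not a camera
simulator.

## The measurement chain

Following standard practice for such data, the liposome channel is
preprocessed with a morphological white top-hat (disc radius 5 px) then a
Gaussian filter (sigma 1 px); the RNA channel with rolling-ball background
subtraction (grayscale opening with a disc, radius 15 px — the standard
morphological approximation of the rolling ball) then the same Gaussian.
Filtered rasters are used only to build masks; all intensity measurements
are taken on the original raster under the mask, after subtracting a scalar
background estimated as the median of the pixels outside all features
(without this, an additive background of 100 photons/px would bias both the
intensity-weighted $R_g$ and the particles-per-cluster estimator).

Thresholding is global and automatic: Otsu by default, with a triangle
method behind a config tag. Otsu is reliable when feature brightnesses are
comparable; with a wide brightness range (bright many-monomer clusters next
to dim monomers) its threshold migrates upward and drops the dim features,
so the triangle method is recommended for polydisperse scenes — the
pipeline tests use it for count-recovery checks. Connected components use
8-connectivity (4 available), and components below `min_feature_area`
(default 4 px; 8 px ≈ the PSF footprint is a good choice on noisy data) are
discarded. Per feature the package reports intensity-weighted centroid and
radius of gyration
$R_g = s\sqrt{\sum I_p |r_p - r_{cm}|^2 / \sum I_p}$ (pixel size $s$),
circularity $4\pi A/P^2$ clipped to $[0,1]$ with the perimeter measured by
tracing the object contour (unit and $\sqrt2$ steps), particles per cluster
$\hat k = I / I_{\text{monomer}}$ against a monomer calibration, and
two-channel colocalization (Pearson, plus Manders fractions over automatic
per-channel thresholds). Features touching the border or with zero masked
intensity are flagged and excluded from summary statistics, and every
exclusion is counted.

One numerical subtlety: under the two-coordinate $R_g$ definition above, an
isotropic Gaussian PSF of width $\sigma$ adds $2\sigma^2$ (not $\sigma^2$)
to $R_g^2$, because $R_g^2$ is additive under convolution and the 2-D
Gaussian has $R_g^2 = \sigma_x^2 + \sigma_y^2$. Ground-truth comparisons
therefore de-broaden analytically as
$R_g^{\text{corr}} = \sqrt{R_g^2 - 2\sigma^2}$ rather than deconvolving
images. The fractal dimension is the OLS slope of $\log\hat k$ on
$\log R_g$, guarded by preconditions (≥ 10 features, ≥ 4x dynamic range in
$R_g$); chains several PSF widths long are needed before elongation is
measurable, which is why the morphology-contrast checks render 20-monomer
chains of 0.25 µm monomers (10 µm long) rather than diffraction-scale ones.

## Problem sizes and seeds

The validation suite cross-checks the three Smoluchowski routes at
$N_0 = 1000$ with 200 replicate stochastic runs; dynamic-scaling collapse
uses one $N_0 = 6.5\times10^5$ run sampled at scaled times
$x \approx 29, 59, 119$ (5000 $R_g$ samples per time); the adsorption law is
tested at $10^4$ liposomes against a master-equation oracle integrated on
$k \le 200$; patchy growth rates use 50 replicates of $N_0 = 2000$ per
coverage value. All stochastic tests fix their seeds; every simulator and
generator in the package takes an explicit seed and is reproducible given
one.

## Known limitations

* The coverage footprint constants are placeholders: mapping a mass ratio to
  percent coverage requires a calibration the package cannot supply by
  itself (`coverage_model()` flags this in its documentation). Excluded-area
  (RSA jamming) corrections near $f \approx 0.55$ are noted but not
  modelled.
* The patchy thinning is size-independent and well-mixed; no spatial or
  orientation-resolved binding.
* No gelation-prone kernels, fragmentation, or spatially resolved
  coagulation.
* Per-frame analysis only: features are not tracked across frames.
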