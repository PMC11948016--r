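# lipoclust

Quantitative imaging and kinetic modeling of RNA–liposome cluster
self-assembly.

When RNA is mixed with cationic liposomes (e.g. DOTAP), the anionic RNA
adsorbs electrostatically onto the liposome surface, and the partially
coated liposomes then aggregate by diffusive hit-and-stick encounters into
micrometre-scale clusters. `lipoclust` is for researchers who image this
kind of nanoparticle assembly with two-channel fluorescence microscopy and
want to quantify it and test it against physical models. It provides:

* **Synthetic scenes with ground truth** — fields of clusters whose
  monomer counts follow a geometric (discrete-exponential) law, with
  chain/compact/fractal morphologies, rendered through a Gaussian PSF with
  Poisson and read noise into two-channel 16-bit TIFF stacks plus a truth
  CSV.
* **The measurement chain** — top-hat / rolling-ball preprocessing,
  automatic thresholding (Otsu or triangle), connected components,
  intensity-weighted radius of gyration
  R_g = s·sqrt(Σ I_p |r_p − r_cm|² / Σ I_p), circularity 4πA/P²,
  particles-per-cluster k̂ = I / I_monomer, mass–size fractal-dimension
  fits (k ∝ R_g^{d_f}), and Pearson/Manders colocalization.
* **Adsorption model** — the sequential irreversible pure-birth process
  with rate λ₀(k+1), whose load distribution is exactly geometric,
  P(n) = (1/(1+⟨n⟩)) (⟨n⟩/(1+⟨n⟩))ⁿ, with ⟨n⟩ = r₀/L₀; a numerical
  maximum-entropy cross-check; exact stochastic simulation; linear
  mean-versus-ratio fits.
* **Smoluchowski coagulation** — dn_k/dt = ½Σ_{i+j=k}K_ij n_i n_j −
  n_k Σ_j K_kj n_j with constant and Brownian kernels: the constant-kernel
  closed form n_k = n₀ x^{k−1}/(1+x)^{k+1} (x = t/τ, τ = 2/(K n₀)),
  adaptive truncated ODE integration, and exact Marcus–Lushnikov stochastic
  simulation, plus dynamic-scaling collapse diagnostics and power-law
  growth fits of mean R_g.
* **Patchy binding** — fractional RNA coverage f maps the binding
  probability to f(1−f) (zero at f = 0 and f = 1, maximal at half
  coverage); simulated aggregation with f(1−f)-thinned kernels reproduces
  the non-monotonic dependence of growth rate on RNA dose.

## Worked example

```r
library(lipoclust)

# constant-kernel closed form at one growth time (x = t/tau = 1)
constant_kernel_solution(n0 = 1, K = 1, t = 2)
#> Cluster state at t = 2: N = 0.5 clusters, mass M = 1, kmax = 37, <k> = 2

# exact stochastic adsorption run to the target mean r0/L0 = 2
mod <- adsorption_model(r0 = 2e4, L0 = 1e4, lambda0 = 1)
simulate_adsorption(mod, n_liposomes = 5000, seed = 1)
#> Adsorption simulation: 5000 liposomes, 10000 events, empirical mean load 2.0000

# patchy-binding growth rates over a coverage grid
patchy_rate_profile(c(0.1, 0.3, 0.5, 0.7, 0.9), N0 = 2000,
                    replicates = 20, t_end = 2, seed = 9)
#>     f   rate     se  n
#> 1 0.1 0.1784 0.0052 20
#> 2 0.3 0.4297 0.0070 20
#> 3 0.5 0.4954 0.0077 20
#> 4 0.7 0.4147 0.0069 20
#> 5 0.9 0.1795 0.0033 20

# late-time power-law growth of mean R_g (d_f = 2 radius law)
ts <- c(1, 2, 3, 4, 6, 8, 12, 16, 24, 32, 48, 64)
s <- simulate_gillespie(kernel_spec("constant"), N0 = 20000, t_end = 64,
                        seed = 21, record_times = ts, record_events = FALSE)
mean_rg <- vapply(s$snapshots, function(x)
  mean(0.3 * sqrt(rep(seq_along(x$counts), x$counts))), numeric(1))
fit_growth(ts, mean_rg, type = "rg", tau = 2)
#> Power-law growth fit rg = a t^z: z = 0.4418 +/- 0.0083, a = 0.2464 over t in [6, 64] (R^2 = 0.9979)
```

The cluster state confirms the closed form (at x = 1, half the clusters
remain and the mean size is 2). The adsorption run stops exactly at the
target mean load. The rate profile rises to its maximum at half coverage
and falls symmetrically — the f(1−f) signature — with the 0.5/0.1 ratio near
25/9 ≈ 2.78. The fitted growth exponent ≈ 0.44 approaches the mean-field
prediction 1/d_f = 0.5 from below (finite-time correction).

An image-analysis pipeline runs through config-driven commands:

```r
run_generate(list(out = "demo", seed = 1, times = c(0, 5, 10)))
run_quantify(list(stack = "demo/stack.tif", out = "demo_quant",
                  pixel_size = 0.325,
                  params = list(threshold_method = "triangle",
                                min_feature_area = 8)))
run_fit(list(out = "demo_fit", summary = "demo_quant/summary.csv"))
```

or from a shell via `Rscript scripts/lipoclust.R generate --config cfg.json`.
Every run writes its resolved config and an md5 manifest next to its
outputs.

## Package layout

| | |
|---|---|
| `R/synthetic.R` | ground-truth scenes, fractal cluster growth, PSF rendering, TIFF stacks |
| `R/imaging.R` | preprocessing, segmentation, feature metrics, colocalization |
| `R/adsorption.R` | birth-process model, geometric/max-ent laws, simulation, fits |
| `R/smoluchowski.R` | kernels, closed form, ODE, stochastic simulation, scaling diagnostics |
| `R/patchy.R` | coverage model, f(1−f) binding, thinned simulation, rate profiles |
| `R/pipeline.R` | config-driven `run_generate` / `run_quantify` / `run_fit` |

See the vignette (`vignettes/rna-liposome-assembly.Rmd`) for the models,
parameter choices, and numerical details.
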