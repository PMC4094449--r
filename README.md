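# mreitfilter

Noise-adaptive enhancement of conductivity images for magnetic resonance
electrical impedance tomography (MREIT), for researchers developing or
evaluating MREIT reconstruction and denoising methods.

In MREIT, currents injected through boundary electrodes induce a magnetic
flux density whose z-component Bz is measured from the MR phase. The Bz
noise is tied to the magnitude-image SNR Υ by

    sd(Bz) = 1 / (2 γ Tc Υ),        γ = 26.75e7 rad/(T s),

so regions of weak MR signal (short-T2 gels, lungs, gas, bone) produce
locally very noisy conductivity values, while the rest of the image is
trustworthy. This package implements a postprocessing filter that adapts a
spatial averaging kernel to that position-dependent noise level: at pixel r
the conductivity is replaced by the weighted average

    σ_w(r) = Σ_s w_r(s) σ(s),   w_r(s) ∝ exp(−|M(r) − M(s)| / h(r)),

over a disc of radius η(r) pixels, where M is the MR magnitude image and
both h and η grow with the local sd(Bz). Noisy, magnitude-flat regions get
strong averaging; magnitude edges block mixing across tissue boundaries;
and when the whole acquisition is clean the window radius rounds to zero
and the filter is exactly the identity.

Around the filter sits a complete desk-scale pipeline, so every claim is
testable without any external data:

- `make_disc_phantom()` / `make_electrodes()` — a three-inclusion saline
  phantom (0.4 S/m background; 1.5, 0.1, and 1.5-wrapped-in-0.3 S/m
  objects with depressed MR magnitude) and 10 mA electrode pairs;
- `solve_voltage()`, `current_density()`, `bz_from_current()` — a
  conservative finite-volume Neumann solver and an FFT Biot–Savart kernel
  for a conducting slab;
- `simulate_acquisition()`, `extract_bz()`, `noise_std_map()` — the noisy
  complex MR image pair, phase-difference Bz extraction, and the noise
  model above;
- `transversal_j_substitution()` — single-pass conductivity reconstruction
  from two orthogonal injections against a homogeneous reference;
- `filter_params()`, `apply_filter()`, `error_decomposition()` — the
  adaptive filter and its blurring/noise error split;
- `roi_variance()`, `variance_report()`, `reaction_diffusion()`,
  `baseline_comparison()` — the ROI gradient-variance metric
  V = (mean |∇σ|²)^½ and a curvature-flow baseline denoiser;
- `run_pipeline()` / `mreit_cli()` (`inst/cli/mreit.R`) — a YAML-configured,
  bit-reproducible pipeline writing NIfTI-1/CSV artifacts with JSON
  provenance.

## Worked example

```r
library(mreitfilter)
res <- run_phantom_experiment(seed = 1, grid = mreit_grid(64, fov = 0.24))
print(res$report)
#> ROI gradient-variance (V) before/after filtering
#>                        D1         D2         D3
#> Before                146       97.7        116
#> After                8.15       7.14       7.54
#> Reduction (%)        94.4       92.7       93.5
#> Mean reduction: 93.5%
```

The experiment simulates two orthogonal 10 mA injections through the
phantom, extracts noisy Bz images (the inclusions sit at magnitude SNR ≈ 4,
so their data are very noisy), reconstructs conductivity by transversal
J-substitution, and applies the adaptive filter. `Before`/`After` are the V
values (in (S/m)/m) inside the three inclusion ROIs: the filter removes
over 90% of the spurious conductivity variation inside the homogeneous
objects, while the high-SNR background — protected by small windows and the
magnitude-distance weights — is left essentially untouched
(`baseline_comparison()` quantifies this against the reaction-diffusion
baseline, which blurs everything).

The same experiment from the shell:

```sh
Rscript inst/cli/mreit.R pipeline --outdir out --seed 1
```

## Vignette

`vignettes/adaptive-conductivity-filtering.Rmd` documents the model and its
assumptions, the parameter anchoring (and why it is absolute rather than
relative), the forward-model geometry, the error decomposition, the
variance-matching baseline protocol, and known limitations.
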