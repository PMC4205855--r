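# cumarea

Cumulative-area analysis of single-molecule diffusion and conformational
dynamics from time-lapse fluorescence image stacks.

## What it does, and for whom

Single-particle tracking usually works by localizing a fluorophore's
point-spread function with a 2D Gaussian fit in every frame, linking the
centres into a trajectory, and estimating the lateral diffusion
coefficient from the mean square displacement,
`MSD(nΔt) = 4 D nΔt`. That works for point-like emitters but degrades
badly for large flexible molecules (long DNA, polymer chains): the shape
of the molecule fluctuates between frames, the fitted centre wanders and
the tracking breaks on fit outliers, leaving very broad distributions of
single-molecule `D`.

`cumarea` implements the **cumulative-area (CA) method**, which never
localizes anything. Each frame is reduced to the small set of brightest
pixels the molecule occupies (its *footprint*); the estimator watches
the union of footprints grow over time and converts the mean per-frame
area increment ⟨ΔA⟩ into a diffusion coefficient:

    D = ⟨ΔA⟩ / (4 Δt)

Increments that drop to zero because the molecule re-enters
already-claimed territory are rescued by re-running the superimposition
backwards from the last frame. Because no centre is ever fitted, shape
fluctuations are harmless, and the distribution of per-molecule
estimates is substantially narrower than the SMLT-MSD equivalent. The
same per-frame areas, taken with a larger pixel budget, yield the
conformational relaxation time τ_R of a flexible chain from the
single-exponential decay of the area autocorrelation
`G(τ) = ⟨δA(t) δA(t+τ)⟩ / ⟨δA²⟩`.

The package is aimed at single-molecule biophysicists and polymer
scientists analysing widefield movies of isolated diffusing particles
(one molecule per stack/ROI), and includes:

* the full CA pipeline (per-frame Gaussian background fitting,
  `m + 4s` thresholding, noise-pixel removal, 5-pixel footprint
  selection, quality gating, forward/backward superimposition,
  `D = ⟨ΔA⟩/4Δt`) — `ca_pipeline()`, `ca_estimate()`;
* cumulative-area growth curves that distinguish random, directed and
  confined motion — `mode_curve()`, `classify_mode()`;
* occupied-area relaxation analysis — `area_series()`,
  `autocorrelate()`, `fit_relaxation()`;
* the SMLT-MSD baseline (2D Gaussian localization, trajectory assembly,
  MSD slope fitting, theoretical P(D)) — `smlt_pipeline()`,
  `theoretical_pD()`;
* a ground-truth simulator (Rayleigh step lengths with
  `E[r²] = 4DΔt`, uniform angles; drift and circular confinement;
  fixed, random and split pixel footprints; noisy image rendering) —
  `sim_config()`, `simulate_ca_batch()`;
* population statistics (Gaussian fits to `D` histograms, accuracy-band
  checks, Stokes–Einstein reference) — `fit_D_distribution()`,
  `stokes_einstein_D()`.

## Worked example

Simulate a 300-frame Brownian track at `D = 1 µm²/s` under the default
imaging conditions (6.4 ms frames, 160 nm pixels, 5-pixel footprint) and
estimate it back:

```r
library(cumarea)

cfg <- sim_config(D = 1.0, n_frames = 300, seed = 42)
set.seed(cfg$seed)
traj <- simulate_trajectory(cfg)
occ  <- rasterize_footprint(traj, cfg)
ca_estimate(occ)
#> CA estimate: D = 1.013 um^2/s (299 increments)

check_sampling_validity(1.013, cfg$dt, cfg$pixel_size)$message
#> [1] "sampling regime valid"

# population statistics over 100 independent tracks
est100 <- simulate_ca_batch(cfg, n_tracks = 100)
fit_D_distribution(est100)
#> distribution_fit (n = 100): peak 1.093 +/- 0.136 um^2/s (Gaussian); mean 1.074 +/- 0.132
```

The single-track estimate recovers the preset within ~1%; over 100
tracks the Gaussian-fit peak of the distribution is 1.09 µm²/s with a
relative spread of ~13% — the statistical floor of the method at this
track length. `check_sampling_validity()` confirms the r.m.s. per-frame
displacement (here exactly 1 pixel) lies in the validated 0.55–1.4
pixel window.

A thin command-line front end is installed with the package
(`system.file("scripts", "ca", package = "cumarea")`), with subcommands
`estimate`, `msd`, `relax`, `curve`, `simulate` and `batch` over TIFF
stacks, e.g.

```sh
ca simulate --d 1.0 --frames 300 --n 100 --seed 7 --out work/
ca batch --in work/ --method ca --out results/
```

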