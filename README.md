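# phaseCT

Quantitative evaluation of single-distance phase retrieval for
propagation-based phase-contrast CT (PBI) of lung-like samples, as an
end-to-end synthetic pipeline in R.

## The problem

Lung tissue is nearly transparent to hard X-rays, but its dense air–tissue
interfaces make it an ideal subject for in-line (propagation-based)
phase-contrast imaging: letting the beam propagate a distance *R* behind
the sample converts phase gradients into bright/dark interference fringes
at every interface. Those fringes sharpen the *appearance* of edges but
ruin threshold-based segmentation and quantitative analysis. The remedy
studied here is single-distance transfer-of-intensity (TIE, Paganin-type)
phase retrieval: under the homogeneous-object assumption that the
refractive index n = 1 − δ + iβ has a constant ratio γ = δ/β (≈1950 for
lung soft tissue at 22 keV, ≈250 for bone), each flat-field-normalized
projection I is converted to a projected attenuation map by a single
Fourier-domain low-pass filter

    A(x, y) = −ln( F⁻¹[ F[I] · G(f) ] ),
    G(f)    = 1 / (1 + π λ R γ |f|²),

with λ the wavelength and f spatial frequency in cycles per unit length.
Filtered back-projection of A yields a μ (attenuation) volume; the same
data reconstructed from −ln I directly gives the fringed PBI volume.

The package provides every stage as tested, reusable code:

* **Phantoms** — seeded complex-refractive-index volumes: air vesicles in
  soft tissue (γ = 1950), an airway, a bone rod (γ = 250), an agarose
  shell, a γ-preserving fine density texture, plus analytic edge/disk
  fixtures. Partial-volume (antialiased) rasterization throughout.
* **Forward simulation** — parallel-beam, monochromatic projection by
  volume rotation, angular-spectrum Fresnel propagation
  (H(f) = exp(−iπλR|f|²)), Poisson detector noise, optional supersampled
  rasterization with integer detector binning (a physical pixel integrates
  sub-pixel fringes; the reference acquisition binned 2×2).
* **Phase retrieval** — the TIE filter above, exactly inverting the
  linearized forward model; γ = 0 reduces to plain −ln I.
* **Reconstruction** — band-limited ramp FBP (Shepp-Logan/Hann windows
  optional) scaled so a disk of known μ reconstructs to μ, plus an
  independent brute-force Radon oracle for testing.
* **Registration** — slice matching by zero-normalized cross-correlation
  and a Fourier–Mellin estimate of in-plane scale/rotation/translation,
  with the 3×3×3 mean pre-filter applied to PBI volumes for registration
  only.
* **Metrics** — ROI statistics, contrast-to-noise ratio
  CNR = |μ̄₁ − μ̄₂| / √((σ₁² + σ₂²)/2), edge-enhancement index
  EEI = (P − L) / √((σ_air² + σ_tissue²)/2), averaged 0.2 mm edge
  profiles, logistic edge fits f(x) = k₁ + k₄/(1 + e^(−k₂(x−k₃))) with
  steepness k₂ normalized to the best edge (steepness-of-fit, %), and the
  iterative Gaussian steepness-matching experiment showing retrieval is
  not equivalent to low-pass filtering.
* **Pipeline + CLI** — `run_full_experiment()` drives
  simulate → retrieve → reconstruct → register → measure from one config;
  `inst/cli/phasect.R` exposes `simulate`, `retrieve`, `reconstruct`,
  `register`, `evaluate`, `run-all` subcommands with YAML configs.

## Worked example

```r
library(phaseCT)
beam   <- beam_spec(energy_kev = 22, photons_per_pixel = 5000)
params <- retrieval_params(gamma = 1950, distance_cm = 30,
                           energy_kev = 22, pixel_size_um = 9)
tie_filter_gain(0.01, params)
#> [1] 0.08804857

cfg <- experiment_config(
  phantom = phantom_spec(shape = c(16L, 96L, 96L), vesicle_count = 60L,
                         seed = 1),
  beam = beam, distances_cm = c(7, 30), n_angles = 64L,
  profile_length_mm = 0.1, preset = "desk", roi_side_px = 8L, seed = 1)
res <- run_full_experiment(cfg)
res$report[, c("label", "cnr", "eei", "k2", "steepness_percent")]
#>    label        cnr       eei       k2 steepness_percent
#> 1  PBI_7  0.5728007  1.342112       NA                NA
#> 2  PhR_7 10.2295069  9.045757 192.2789          43.26275
#> 3 PBI_30  0.3016946  1.898868 444.4444         100.00000
#> 4 PhR_30 14.4989879 14.306503 199.4331          44.87246

round(res$invariance, 4)
#>         7cm   30cm
#> 7cm  0.0000 0.0424
#> 30cm 0.0424 0.0000
```

Reading the table: the filter gain 0.088 at f = 0.01 cycles/µm shows how
strongly the 30 cm retrieval damps 100 µm-period structure. In the
comparison table, retrieval multiplies the air–tissue CNR by ~30–50 at
this noise level (0.57 → 10.2 at 7 cm, 0.30 → 14.5 at 30 cm) while PBI
CNR *falls* with distance as tissue-texture phase noise grows. The PBI
edge is nominally steeper (k₂ = 444 /mm = 100%) than the retrieved one
(k₂ ≈ 199 /mm ≈ 45%) — but that steepness is interference fringing, not
resolution; at 7 cm the noisy PBI profile cannot be fitted at all (NA),
and the PhR reconstructions at the two distances agree to 4.2% NRMSE.
(This 96²-pixel example is deliberately small; the acceptance
configurations below use larger fields of view.)

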