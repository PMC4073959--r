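---
title: "Methods: simulating and quantifying single-distance phase retrieval for lung phase-contrast CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The physical model

A parallel, monochromatic, fully coherent X-ray beam (energy $E$,
wavelength $\lambda = hc/E$ with $hc = 12.39842$ keV·Å) crosses a sample
described voxelwise by the complex refractive index
$n = 1 - \delta + i\beta$. Under the projection approximation the exit
wave at view angle $\theta$ is

$$t(x,y) = \exp\!\Big(-\tfrac{2\pi}{\lambda}\!\int\!\beta\,dz\Big)\,
           \exp\!\Big(-i\tfrac{2\pi}{\lambda}\!\int\!\delta\,dz\Big),$$

with the line integrals taken along the beam after in-plane rotation of
the voxel grid (bilinear interpolation, summation along the column axis).
Free-space propagation over the sample-to-detector distance $R$ uses the
angular-spectrum transfer function $H(f) = e^{-i\pi\lambda R |f|^2}$
($f$ in cycles per unit length), which is unitary and reduces to the
identity at $R = 0$. The detector records $I = |U_R|^2$; with a finite
photon budget $N$ per pixel each value is replaced by
$\mathrm{Poisson}(N I)/N$ (zero counts clamped to $0.5/N$ so the
downstream logarithm stays defined).

Single-distance TIE (Paganin-type) retrieval assumes a homogeneous
object, $\delta/\beta = \gamma$ everywhere, and inverts the linearized
forward model with one Fourier filter,
$G(f) = 1/(1 + \pi\lambda R\gamma|f|^2)$, giving the projected
attenuation $A = -\ln \mathcal{F}^{-1}[\mathcal{F}(I)\,G]$. With the
sign conventions above the forward edge enhancement is exactly
$(1 + \pi\lambda R\gamma f^2)$ in the weak-object limit, so retrieval
analytically inverts simulation; the package's round-trip test verifies
the agreement at weak contrast (NRMSE under 2% outside a 3 px interface
band). Filtered back-projection (band-limited
ramp kernel, optional Shepp-Logan/Hann windows, linear-interpolation
back-projection over the full 360°) turns $-\ln I$ into the fringed PBI
volume and $A$ into the retrieved (PhR) $\mu$-volume, in units of 1/µm.

### Assumptions and their limits

* Parallel beam, magnification 1, no source blur, no detector PSF beyond
  optional pixel binning, monochromatic: the synchrotron setting this
  emulates approximates all of these.
* The TIE filter is exact only in the near field for structure resolved
  by the detector. At 9 µm pixels the first Fresnel fringe
  $\sqrt{\lambda R}$ is sub-pixel at all three standard distances
  (2.0/4.1/7.5 µm at 7/30/100 cm) — the simulator warns about this, and
  the original acquisition had the same property. A real pixel
  *integrates* these fringes; a point-sampled simulation aliases them.
  `simulate_scan(bin = k)` therefore supports rasterizing the phantom at
  `voxel_size/k` and mean-binning the intensity back to the detector
  pitch. Pixel integration substantially reduces the spurious
  distance-dependence that aliased fringes would otherwise inject, and
  the distance-invariance acceptance configuration uses 2× supersampling
  (the acceptance script reports the resulting pairwise NRMSE).
* At realistic lung contrast a sharp air–tissue edge carries tens of
  radians of phase; retrieval then leaves a residual blur on the scale
  $\ell = \sqrt{\lambda R \gamma / 4\pi}$ (25/51/94 µm at 7/30/100 cm)
  around interfaces — the "slight increased blurring" the reference data
  shows. Tolerances that ignore a band of only ±3 px around edges can
  only be met in the weak-object regime, where the corresponding unit
  test is pinned.

## The synthetic lung phantom

`phantom_spec()`/`make_lung_phantom()` build a soft-tissue cylinder
(radius 0.44·n in-plane voxels) wrapped in an agarose shell (0.04·n),
containing a large airway (radius 0.18·n, offset (0.10, −0.12)·n), an
optional bone rod (radius 0.08·n at (−0.22, −0.22)·n), and seeded
spherical air vesicles (default radii 27–54 µm) placed uniformly in the
parenchyma with rejection against the airway (plus a 0.10·n vesicle-free
collar that keeps the measurement interface clean), the bone, the
reserved solid-tissue ROI patch (half-width 0.11·n at (−0.19, 0.19)·n)
and the sample boundary. Overlapping vesicles union; air wins over
tissue. All surfaces are rasterized with 4×4 partial-volume supersampling
so they carry no artificial stair-step content; a voxel is labeled air
only when it contains no material, so air voxels have exactly
$\delta = \beta = 0$ and every material voxel has exactly one material's
$\gamma$. Vesicle geometry is drawn in scale-free units, so rasterizing
the same spec at a finer voxel size (for detector binning) carves the
identical physical sample.

Two deliberate choices deserve justification:

* **Density texture.** Real tissue has intrinsic small density
  variations; these generate additional phase "noise" that grows with
  distance and is the accepted explanation for PBI CNR *decreasing* with
  distance in biological samples. The phantom therefore applies a
  multiplicative Gaussian texture (default 3% RMS, ~1-voxel correlation)
  to $\delta$ and $\beta$ jointly, preserving $\gamma$ voxelwise. Without
  it, PBI CNR would be flat in distance and the comparison would miss the
  documented behaviour.
* **Photon budget.** 5000 photons/pixel/projection (1.4% relative noise)
  was chosen once as a typical synchrotron microCT fluence. It is *not*
  tuned: the acceptance script reports the resulting PBI and PhR CNR
  values per distance and their ratio, and the >10× retrieval gain
  appears at this setting without calibration.

What the generator does **not** emulate: anatomically realistic airway
trees, alveolar septal geometry, beam-hardening/polychromaticity, partial
coherence, ring artifacts, sample drift. A green test therefore
establishes internal consistency of the method chain and the direction
of the documented effects, not agreement with any particular animal scan
(whose absolute Table-style values depend on the sample and are not
reproducible from the publication alone).

## Measurement protocol

The analysis mirrors the published protocol at a reduced field of view:

* **ROIs** — homogeneous regions "solely containing air or soft tissue,
  away from tissue interfaces". The paper's 0.4 mm² ROIs (≈4938 px at
  9 µm, see `roi_from_area()`) do not fit a millimetre-scale phantom;
  the desk profile uses 12×12 px ROIs centered in the airway (air) and
  in the reserved tissue patch, pooled over six slices. Being "away from
  interfaces" is quantitative: the retrieval blur kernel is a Lorentzian
  in frequency whose real-space tails decay on the scale $\ell$ (10.4 px
  at 100 cm), so ROI clearance must be several $\ell$. That requirement
  sets the in-plane size (320²) of the CNR-trend reproduction world; at
  128² the 100 cm air ROI is provably contaminated by wall shading.
* **Profiles** — five parallel 0.2 mm profiles (23 samples at 9 µm),
  2 px apart, crossing the airway wall radially; their pointwise mean is
  analysed. (The alternative 0.1 mm length mentioned alongside the EEI
  definition is available via `profile_length_mm`.)
* **Noise for CNR/EEI** is always measured on original, untransformed,
  unfiltered slices; registration results are never resampled into the
  metric path. The EEI noise terms default to the same ROIs; profile
  end-segment estimates are available via `profile_end_sds()`.
* **Sigmoid steepness** $k_2$ is fitted by `nls` (port algorithm, optim
  fallback) with data-driven initialization; descending profiles are
  mirrored so $k_2 > 0$ and the orientation recorded. The steepness table
  normalizes to the *highest converged* $k_2$ (=100%), as in the source
  protocol where PBI 30 cm is the reference. Unconverged fits are
  reported as missing, not zero. At the desk-scale photon budget the
  unfiltered noisy PBI edge cannot be fitted at all (its edge
  signal-to-noise is ~6× below the published setting), so steepness and
  edge morphology are measured on the noise-free reconstruction of the
  same slice, which the pipeline computes alongside; CNR and EEI stay on
  the noisy data.
* **Overshoot detection** counts sign changes of the second difference
  within ±6 samples of the interface, ignoring excursions below 10% of
  the edge step: diffraction fringes are of the order of the step itself,
  tissue texture is not. A monotone retrieved edge scores 0–1, a fringed
  PBI edge scores ≥2.
* **Histogram modality** is assessed inside the lung region (sample
  interior minus the bone rod's neighborhood, `lung_region_mask()`): a
  histogram is bimodal when two local maxima survive a valley deeper than
  half the smaller peak. The bone tail otherwise stretches the bin range
  and hides the air/tissue separation that matters for segmentation.

## Registration

The reference volume is PBI at the smallest distance. PBI volumes are
mean-filtered (3×3×3, reflect boundaries) for registration *only* — the
fringes otherwise derail the similarity metric. Slice correspondence
comes from zero-normalized 2D cross-correlation (ties to the lowest
index); in-plane scale/rotation from phase correlation of log-polar
resampled (360×256), Hann-windowed, radially high-pass-weighted magnitude
spectra with parabolic sub-pixel peak refinement; translation from a
second phase correlation after applying the scale/rotation estimate. The
180° rotation ambiguity inherent to magnitude spectra is resolved by
scoring both candidates on the final aligned overlap and keeping the
better one. The log-polar estimate alone is accurate to roughly the
angular bin (0.5°); a local coordinate search over rotation and scale
maximizing the aligned overlap correlation (translation re-estimated at
each trial) then polishes it by an order of magnitude. Transforms with a
final score below 0.2 are flagged (warning and `converged = FALSE`
attribute), not errors.

## Numerical choices

* Units: everything internal is µm; cm (distances) and Å (wavelengths)
  convert at the API boundary. Frequencies are cycles/µm.
* One Fourier convention everywhere: $H = e^{-i\pi\lambda R|f|^2}$ with
  $t = e^{-B - i\Phi}$, matched to $G = 1/(1+\pi\lambda R\gamma|f|^2)$ so
  that retrieval inverts simulation; a sign slip here silently turns the
  deconvolution into extra blurring.
* FFT padding: symmetric (edge-repeating) reflection to the next power of
  two with ≥64 px margin, cropped after the transform; shared by the
  propagator and the retrieval filter.
* Full-360° scans with even angle counts exploit the exact point-reflection
  symmetry of opposing views: only half the projections are computed and
  propagated (the mirror identity is machine-exact and unit-tested).
* FBP uses the spatial-domain band-limited ramp kernel (correct DC
  handling), zero-padding to twice the next power of two; output scale is
  fixed by the disk oracle (2% tolerance), not calibrated against it.
* Degenerate inputs: all-equal angle sets and single-angle sinograms are
  rejected; flat profiles return unconverged fits; zero-noise CNR with
  unequal means returns `Inf` with a warning; empty volumes error.
* Seeds: every stochastic stage (phantom, noise streams) takes an integer
  seed and restores the caller's RNG state; identical config + seed gives
  digest-identical stacks and reconstructions (tested).

## Known limitations

* The absolute $\delta$ scale of lung tissue at 22 keV is not published;
  the default 4.06e-7 is a plausible soft-tissue magnitude, configurable,
  and only the ratio $\gamma$ affects retrieval correctness.
* The fringe structure beyond the first maximum is undersampled at 9 µm
  (as in the original data); simulated PBI steepness values at large
  distances are therefore detector-limited, not physics-limited.
* Fourier–Mellin registration assumes in-plane similarity transforms
  only, per the slice-wise protocol; no nonrigid or 3D rotation recovery.
* The comparison-table layout mirrors the published quantitative summary,
  but its absolute values depend on the phantom and noise choices above;
  only directions and orders of magnitude are meaningful.
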