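---
title: "Mapping intracellular crowding with EGFP anisotropy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping intracellular crowding with EGFP anisotropy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdscope)
```

## The measurement and its model

Macromolecular crowding (MMC) — the excluded-volume pressure of the dense
cytoplasmic cosolute background — modulates reaction rates, folding and
phase behaviour, but is hard to read out in live cells. `crowdscope`
implements an imaging readout built on the steady-state fluorescence
anisotropy of free EGFP,

$$ r = \frac{I_\parallel - g\,I_\perp}{I_\parallel + 2\,g\,I_\perp}, $$

where $I_\parallel$ and $I_\perp$ are the co- and cross-polarized emission
intensities and $g$ is a per-pixel instrumental correction. The physical
bridge is the Perrin equation, $r = r_0 / (1 + \tau/\theta_C)$ with
$\theta_C = \eta V / k_B T$: EGFP is a slow rotor
($\theta_C \approx 16$ ns $\gg \tau \approx 2.6$ ns), so its $r$ is nearly
insensitive to viscosity but rises with refractive index, which in cells
tracks total macromolecule density — via the Strickler–Berg dependence
$\tau \propto 1/n^2$ and $r \propto 1/\tau$. At high EGFP concentration
($>10\ \mu M$) homo-FRET between EGFP molecules depolarizes the emission
and lowers $r$; the package provides a paired photobleach test
(`homo_fret_bleach_test()`): if bleaching raises $r$ while intensity
falls, the cell sits in the homo-FRET regime and its $r$ is not a clean
crowding readout.

## Pipeline stages and the choices behind them

**Dual-view geometry.** One camera frame carries both polarizations side
by side; by default the left half is the perpendicular channel
(configurable, since the layout is hardware-dependent). Pixel coordinates
are 0-based, x along columns, origin top-left — fixed so registration is
reproducible.

**Registration.** Sub-resolution beads imaged in both halves give point
correspondences; mutual-nearest-neighbour matching (20 px default radius)
feeds a consensus loop (200 random minimal samples, 1 px inlier
threshold) and a least-squares refit. The default transform family is
similarity (translation + rotation + scale): it covers what misaligned
relay optics actually do while staying safe on bead fields with no
orientation cues; affine is a flag away for sheared paths. The
perpendicular half is resampled onto the parallel grid with bilinear
interpolation; out-of-field pixels become `NA` and never enter
statistics.

**G-factor.** $g(x,y)$ is the ratio of mean parallel to mean
perpendicular intensity over frames of a freely rotating dye (100 nM
fluorescein, $r \approx 0$), so detection-path polarization bias and
vignetting cancel per pixel. A 3×3 median filter regularizes the map —
the calibration literature leaves the smoothing unspecified, and a
single-pixel median is the mildest choice that removes shot-noise
speckle; it is switchable off. No separate flat-field correction is
applied: optical nonuniformity is already inside $g$.

**Background.** A blank-medium frame is subtracted from the full
dual-view frame *before* splitting, which removes each channel's
background in its own ratio; differences clip at zero. Camera dark offset
is not modelled separately — it rides inside the blank frame.

**Thresholding.** The anisotropy map keeps pixels whose parallel-channel
count lies in 15,000–50,000 (16-bit): below, shot noise dominates; above,
saturation distorts the ratio. The window can instead be applied to the
total intensity $I_\parallel + 2gI_\perp$.

**Modal statistic.** Per cell, the readout is the mode of a
Gaussian-kernel density of valid $r$ values on a fixed grid (0–0.4, step
$10^{-4}$ — spanning all physiological EGFP anisotropies with margin),
bandwidth by Silverman's rule per cell. The mode tracks the predominant
cytoplasmic state and resists the morphology-driven tails that bias the
mean; cells with fewer than 200 valid pixels yield an NA record with a
warning rather than vanishing from counts.

## Photophysics, FCS and mobility

The decay fits are plain nonlinear least squares
(`minpack.lm::nlsLM`) on $r(t) = r_0 e^{-t/\theta_C}$ and
$A e^{-t/\tau} + c$, seeded by log-linear regression; a trace with no
measurable decay is flagged non-rotating ($\theta_C = \infty$) instead of
diverging. Phasor coordinates are the discrete first-harmonic projection
$g = \sum I \cos\omega t / \sum I$, $s = \sum I \sin\omega t / \sum I$
with $\omega$ defaulting to $2\pi/T$; mono-exponentials land on the
universal semicircle, mixtures on chords — no model assumptions.

The FCS model is the 3D anomalous-diffusion autocorrelation with triplet
term; fits fix the anomaly exponent at 1 and the triplet fraction at 0
(the appropriate treatment for dilute EGFP solutions), both freeable. The
aspect ratio is fixed to $S = \omega_Z/\omega_{XY} = 3.633$ from the
diffraction-limited radii $\omega_{XY} = 0.61\lambda/\mathrm{NA}$,
$\omega_Z = 2n\lambda/\mathrm{NA}^2$. Radii are interpreted as $1/e^2$
half-axes with effective volume $(\pi/2)^{3/2}\omega_{XY}^2\omega_Z$ —
the one standard convention that reproduces 0.109 fL from 248/901 nm, and
thence ~540 nM from $G_0 = 1.028$ through $N = 1/(G_0-1)$ and
$C = N/(N_A V)$.

FRAP recovery uses the uniform-disk closed form
$f(t) = e^{-2\tau_D/t}[B_0(2\tau_D/t)+B_1(2\tau_D/t)]$ (modified Bessel
functions, computed exponentially scaled for stability), with
$D = w^2/4\tau_D$ and mobile fraction $(F_\infty-F_0)/(1-F_0)$; the model
sits behind one function so a different bleach profile can be swapped in.
MSD analysis time-averages within each track and then averages across
tracks; the log–log slope is fitted over 0.1–1 s by default, matching the
1 s timescale at which apparent diffusivities are reported
($D_{app} = \mathrm{MSD}(\tau)/4\tau$).

## Morphology and osmotic modeling

Cell volume counts suprathreshold voxels times the voxel volume; the
height map converts each binarized column to $dz \times$ count, so the
height-map integral equals the volume *exactly* (both count the same
voxels — this identity is a standing test). The threshold is manual per
stack with Otsu's method as the automatic default. Circularity is
$4\pi A/P^2$ with the perimeter taken from the marching-squares contour
of the mask after light Gaussian presmoothing ($\sigma = 1$ px): the raw
binary contour overestimates a digitized disk's perimeter by ~6%
(circularity 0.89), while the presmoothed contour gives 0.99 for a disk
and $\approx \pi/4$ for a square.

Spatial heterogeneity is profiled on geodesic — not Euclidean — distance
maps computed inside the cell mask (iterated 8-neighbour chamfer sweeps
in C++), so concave and C-shaped cells are measured along in-mask paths.
Each cytoplasmic pixel gets a normalized distance
$f = d_{nuc}/(d_{nuc}+d_{cell}) \in [0,1]$ between the nucleus and cell
boundaries; five equal-$f$ sectors (0–20% … 80–100%) are the default, and
sector means are normalized to the innermost *populated* sector (very
thin geometries can leave the 0-band empty). Normalizing to the innermost
sector rather than the whole-cell mean was an open choice; it makes the
profile read directly as "relative to perinuclear".

The osmotic module normalizes per-condition (osmolarity, volume, modal
$r$) series to Boyle–van't Hoff coordinates $x = \Pi_{iso}/\Pi$
(osmolarity ratio; the isotonic total defaults to 300 mOsm and is
configurable), $y = V/V_{iso}$, and fits the one-parameter line forced
through $(1,1)$; the $x = 0$ intercept is the osmotically inactive
fraction. The reciprocal-crowding track $r_{iso}/r$ is fitted the same
way; note it is exactly linear only when the zero-crowder anisotropy
$\alpha$ is 0, so its intercept is a slightly conservative estimate of
the limiting $r$ — the tests document this bias rather than hiding it.
The concentration-dilution law
$(r - \alpha)V = \text{const}$ gives
$\alpha = (r_2V_2 - r_1V_1)/(V_2 - V_1)$ from any two conditions, and
deviations of measured $r$ from
$r(V) = (r_{iso}-\alpha)V_{iso}/V + \alpha$ are reported in anisotropy
units (converting to concentration needs a crowder calibration and is
optional). The RVI index is
$100\,(V(t_{final}) - V(t_{shrink}))/V(t_{shrink})$ with the nadir read
at 10 min post-shock.

## The synthetic-data module

Every generator is the exact inverse of its analysis counterpart:
polarized scenes are built as $I_\parallel = I(1+2r)/3 + bg$,
$I_\perp = I(1-r)/(3g) + bg$ with the perpendicular half displaced before
assembly; traces come from the forward model of each fit equation;
trajectories use Gaussian increments of variance $2D\,dt$ per axis;
osmotic series come from the constrained line plus the dilution law. At
zero noise, analysis ∘ synthesis is the identity to numerical tolerance —
the backbone of the test suite. Noise defaults follow the physics:
Poisson for photon-counting modalities, 1% multiplicative Gaussian for
correlation and recovery curves. Defaults encode the study conditions the
package targets (FCS $N = 35.714$, $\tau_D = 170\ \mu s$, $S = 3.633$;
decay $r_0 = 0.38$, $\theta_C = 16$ ns, $\tau = 2.6$ ns; dilution
$\alpha = 0.169$; isotonic 300 mOsm). Every dataset carries its ground
truth and is byte-deterministic for a given seed (generators restore the
caller's RNG stream).

What the generators do *not* emulate: realistic PSFs, camera read noise
and gain, segmentation errors (masks are inputs), motion blur, or
biological heterogeneity beyond what is imposed. Passing tests therefore
demonstrate that the *computations* invert their models at the stated
noise levels — not that the models capture every property of real
microscope data.

## Problem sizes and numerical notes

The test suite and the acceptance script use desk-scale problems chosen
to keep every stochastic check well-conditioned: 150×200–512×512 px
scenes, 100-replicate fit ensembles at 1% noise, 100 Brownian tracks of
10⁴ steps, 0.1 µm voxel phantoms (~5×10⁵ suprathreshold voxels). Ties in
the modal density argmax resolve to the lowest grid value (`which.max`);
zero anisotropy denominators invalidate pixels rather than throwing;
bead consensus and all generators take explicit seeds, so the whole
pipeline is reproducible end to end.

Known limitations: no IRF deconvolution or multi-exponential global
analysis in the decay fits; no raw photon-stream correlation (curves are
inputs); no particle detection/linking (trajectories are inputs); the
wide-field instrumental scale between reconstructed and measured $r$ is a
free parameter estimated by least squares (`instrumental_scale()`), not a
calibrated constant.
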