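---
title: "Quantifying nuclear signalling gradients and explant morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear signalling gradients and explant morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(explantr)
```

## The measurement problem

Zebrafish embryos and blastoderm explants form graded domains of nuclear
signalling activity — nuclear pSMAD2/3 as the readout of Nodal/TGF-beta
signalling, nuclear beta-catenin as the readout of dorsal determinant
activity — anchored at a spatial reference: the YSL nuclei at the
blastoderm margin in the intact embryo, or the wounding site (the former
margin) in an excised explant. Commercial spot-detection tools export one
row per detected nucleus: 3D coordinates and per-channel mean intensities.
Everything downstream of that export is what this package implements:

1. **Geometry** — project the 3D point cloud into a 2D plane along a chosen
   axis (embryos: the imaging z axis), optionally re-center an explant on
   its wounding site, and measure each nucleus's distance to the nearest
   reference point, expressed in micrometres or in *cell tiers* (multiples
   of the mean cell diameter).
2. **Nuclear scoring** — exclude EVL, dividing and poorly counterstained
   nuclei, restrict to a 100 µm depth window and to 150 µm from the
   reference, subtract the mean signal of the 120–150 µm band as
   background, normalize by the DAPI mean to cancel depth attenuation, call
   nuclei positive at a ratio strictly above 0.1, select the top 30%
   brightest positives, and classify the domain as *present*, *strongly
   reduced* (bright count at or below half the wildtype control mean — 22
   for explants, 81 for embryos) or *absent* (no bright nuclei).
3. **Morphometrics** — outline circularity $4\pi A/P^2$, extension
   classification and normalized extension length, a 70% batch-QC gate on
   control extensions, cavity position, binary 10-bin expression-domain
   profiles, domain areas with a half-of-control reduction class, SUM-projected
   ROI intensities, and cell-diameter summaries.
4. **Clone dispersal** — mean pairwise distance between labelled nuclei and
   mean distance to their center of mass, per timepoint.

A seeded synthetic generator produces inputs with the statistical structure
these analyses assume, so the full chain is testable without microscopy
data.

## The scoring model and its assumptions

For nucleus $i$ at distance $d_i$ from the nearest reference point, the
scoring chain computes

$$r_i = \frac{S_i - \bar S_{\text{band}}}{D_i}, \qquad
  \bar S_{\text{band}} = \operatorname{mean}\{S_j : 120 \le d_j \le 150\ \mu m\},$$

where $S_i$ and $D_i$ are the signal and DAPI mean intensities. The DAPI
division assumes that depth-dependent attenuation acts multiplicatively and
equally on both channels, so it cancels in the ratio; the synthetic
generator implements exactly this structure, and a test verifies that the
ratio decorrelates from imaging depth while the raw signal does not.
Nuclei with non-positive background-subtracted signal are excluded before
positivity calling; positivity is strict ($r_i > 0.1$, so a ratio of
exactly 0.1 is negative).

### Tunable parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `z_window` | 100 | µm | depth window, anchored at the imaging-side z-minimum of the flag-passing nuclei |
| `max_dist` | 150 | µm | maximal distance from the reference (avoids edge artefacts) |
| `bg_band` | [120, 150] | µm | closed band whose mean signal is the background |
| `ratio_threshold` | 0.1 | — | strict positivity threshold on the DAPI ratio |
| `bright_fraction` | 0.30 | — | fraction of positives taken as "brightest" |
| `control_bright_mean` | explant 22, embryo 81 | count | wildtype control bright counts |
| `reduction_fraction` | 0.5 | — | boundary of the *strongly reduced* class |

## What the synthetic generator emulates

`generate_nuclei()` draws nuclei uniformly in an explant-like ball (radius
100 µm — consistent with roughly 500 deep cells of 25 µm diameter) or an
embryo-like blastoderm cap (a spherical shell of thickness three cell
diameters spanning the animal hemisphere, radius 350 µm). References are a
margin ring of 36 points at the cap rim (embryo) or a wound disc of radius
two cell diameters whose rim lies on the sphere (explant) — a disc rather
than a single point, because a wounding site is an extended region. The
signal channel is $A\,e^{-d/\lambda}$ plus Gaussian noise; defaults
$A = 100$, $\lambda = 40$ µm, noise sd 5 (amplitude/noise 20). The
exponential is the simplest one-parameter monotone profile consistent with
a graded nuclear readout, and it makes $\lambda$ recoverable, which is what
the recovery tests need; it is a modelling convenience, not a mechanistic
claim. Both channels are attenuated by $(1-\alpha)^{\text{depth}}$ with
$\alpha = 0.001$/µm so that the DAPI ratio cancels depth by construction.
Setting $A = 0$ emulates samples whose instructive signal source has been
removed; the only "positives" are then the noise tail. The outermost 10% of
nuclei by radius are flagged EVL and 5% dividing, exercising the exclusion
filters. The true nearest-reference distance of every nucleus is stored as
`true_dist_um`, the ground truth for recovery tests.

What the generator does **not** emulate: segmentation errors and merged
nuclei, anisotropic point-spread functions, spatially correlated noise,
cell-size gradients, and curvature of the real blastoderm sheet. Passing
tests therefore demonstrate that the *quantification chain* is correct and
well-conditioned under the stated geometric and intensity structure — not
that the chain is robust to detection artefacts upstream of its input
contract.

## Numerical choices

- **Top-30% count.** $k = \max(1, \lfloor 0.3\,n_{\text{pos}} + 0.5\rfloor)$
  (round half up), empty when there are no positives; ties broken by
  nucleus id so the selection is deterministic.
- **Class boundaries.** A bright count exactly at half the control mean is
  *strongly reduced* (boundary inclusive); a domain area exactly at half
  the control mean is *normal* (strict `<` for *reduced*). Both boundaries
  are stated conventions where the verbal rules ("a 50% reduction", "50%
  smaller") leave the tie unspecified.
- **Depth window anchoring.** "Within a Z-volume of 100 µm" is anchored at
  the z-minimum of the nuclei surviving the flag filters — the
  imaging-side surface — and extends 100 µm inward.
- **Background band membership** uses the closed interval [120, 150] µm.
- **Bin convention.** The 10 expression bins are half-open
  $[i/10, (i+1)/10)$ with the last bin closed, ordered tip to back
  (distances are measured from the extension tip); zero-length touches do
  not count as presence; multiple domains in one sample are OR-combined.
- **Re-centering** is a rigid transform: the wound centroid moves to the
  origin and the direction towards the operator's re-centering point maps
  onto the +u axis. A pure translation would give identical distances (the
  quantity the analysis consumes); the rotation only standardises
  orientation for display and angle measurements.
- **In-plane basis.** Gram–Schmidt from the world X axis (Y when the
  projection axis is parallel to X), so raw (u, v) coordinates are
  reproducible, not just distances.
- **Cell tiers** are continuous quotients $d/\bar c$; flooring happens only
  when counting nuclei per tier.
- **Decay-length fitting.** `fit_decay_length()` defaults to a nonlinear
  exponential-plus-offset fit (Levenberg–Marquardt). The offset matters:
  subtracting the 120–150 µm band mean from a slowly decaying gradient
  (e.g. $\lambda = 80$ µm, where the band still holds 18% of the
  amplitude) shifts the whole profile down by a constant, and a pure
  log-linear fit of the shifted profile underestimates $\lambda$ by tens
  of percent. The offset term absorbs the shift exactly. The log-linear
  mode (count-weighted, bins below 5% of peak discarded) is retained for
  raw, unsubtracted signal.
- **Gradient recovery uses true 3D distances.** The generator stores each
  nucleus's true 3D distance, and recovery tests feed those to the tier
  profile. Projected 2D distance systematically compresses 3D distance
  (for a ball viewed from the side, points at projected distance $d$ from
  the wound spread over a chord perpendicular to the plane), which is a
  property of the projection step itself, not of the scoring chain;
  `distance_to_reference()` accepts either 2D projected or 3D coordinates,
  and the pipeline follows the projected route.
- **Normalized intensity** of bright nuclei is scaled to the per-sample
  maximum bright ratio, mapping profiles into (0, 1]. The normalization
  constant is a free choice; per-sample maximum keeps profiles comparable
  across samples with different absolute staining levels.
- **Automatic extension detection** (optional, heuristic — the reference
  path is the operator's landmark call) uses the relative convexity
  defect: the area between the outline and its convex hull, over the
  outline area, thresholded at 1%. On seeded synthetic shapes this
  separates indented pears (defect ≥ 3%) from jittered circles and
  ellipses (≤ 0.5%) cleanly.
- **The 150 µm distance filter is applied uniformly** to both the
  pSMAD2/3-like and the beta-catenin-like analyses (configurable); nothing
  in the chain is channel-specific beyond column naming.
- **ROI shape.** The 400.90 µm² central ROI for surface-reporter intensity
  is a square of side $\sqrt{400.90}$ µm centred on the image; the
  background ROI is a corner square of side 24.91 µm.

## Problem sizes in the tests

Recovery and contrast properties run at $n = 500$ nuclei over 20 seeds for
each condition ($\lambda \in \{20, 40, 80\}$ µm; amplitude 100 vs 0), the
scale at which binned profiles are stable while the whole suite stays
interactive. The oracle-equivalence checks use 1000 query points against
50 references; closed-form checks are exact.

## Known limitations

- The scoring chain is only as good as its input contract: nuclei must
  arrive as one row each with trustworthy flags; no attempt is made to
  detect double-detections or missed nuclei.
- Distances are planar after projection (or true 3D on request); geodesic
  distances along the curved blastoderm are out of scope.
- The automatic extension classifier is a convexity heuristic benchmarked
  only against the package's own synthetic shapes; operator landmarks
  remain the reference path.
- The synthetic amplitude scale is arbitrary (no absolute intensity
  calibration exists for the immunostaining), so only ratios, counts and
  classifications — never raw intensities — should be compared across
  datasets.

## A minimal walk-through

```{r example, eval = FALSE}
cfg <- synthetic_nuclei_config("explant", n_nuclei = 500, seed = 1)
sim <- generate_nuclei(cfg)
frame <- projection_frame(c(0, 0, 1))
proj <- project_and_measure(sim$nuclei, sim$refs, frame,
                            recenter_point = attr(sim, "recenter_point"))
res <- quantify_sample(sim$nuclei, proj, sample_kind = "explant")
res
```
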