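# explantr

Quantification of nuclear signalling gradients, tissue-shape morphometrics
and clone dispersal in zebrafish embryos and blastoderm explants, starting
from the tables that microscopy spot-detection tools export (one row per
detected nucleus: 3D coordinates in µm and per-channel mean intensities).

The package is for developmental biologists who already have
spot-detection exports and outline/landmark measurements and need the
downstream numbers to be computed reproducibly: percentages of
signal-positive nuclei by distance from a reference, signalling-domain
classifications, explant shape descriptors, expression-domain profiles and
cell-dispersal statistics.

## What it computes

**Geometry.** Nuclei are projected into a 2D plane along a chosen axis
(embryos: the imaging z axis); explants can be rigidly re-centered on
their wounding site. Each nucleus gets its distance to the nearest
reference point (YSL nuclei at the margin, or wound-site points), in µm or
in *cell tiers* (multiples of the mean cell diameter).

**Nuclear scoring.** With signal mean `S`, DAPI mean `D` and distance `d`
per nucleus, the chain excludes EVL/dividing/low-DAPI nuclei, keeps nuclei
within a 100 µm depth window and within 150 µm of the reference, and
computes the background-subtracted, DAPI-normalized ratio

```
r = (S - mean{S : 120 <= d <= 150 um}) / D
```

A nucleus is positive when `r > 0.1` (strict). The top 30% brightest
positives are the "bright" nuclei; a sample is classified `present`,
`strongly_reduced` (bright count at or below half the wildtype control
mean: 22 for explants, 81 for embryos) or `absent` (none). The same
machinery yields beta-catenin tier counts and the angular dispersion
(circular mean and mean resultant length) of positive nuclei about a
wound-anchored axis.

**Morphometrics.** Circularity `4*pi*A/P^2`, extension classification and
normalized extension length, a 70% batch-QC gate on control extensions,
normalized cavity position (largest lumen), binary 10-bin
expression-domain profiles with averaging, domain areas with a
half-of-control `reduced` class, SUM-projection ROI intensities (400.90 µm²
central ROI, 24.91 µm background square), and per-stage cell-diameter
summaries.

**Clone dispersal.** Mean pairwise distance between labelled nuclei and
mean distance to their center of mass, per timepoint.

**Synthetic data.** A seeded generator produces nucleus tables with an
exponential signal gradient anchored at a margin ring (embryo) or wound
disc (explant), multiplicative depth attenuation cancelled by the DAPI
ratio, EVL/dividing flags, plus outlines with known extension fractions
and random-walk clone tracks — so every stage is testable end to end with
no external data.

## Worked example

```r
library(explantr)

cfg  <- synthetic_nuclei_config("explant", n_nuclei = 500, seed = 1)
sim  <- generate_nuclei(cfg)
frame <- projection_frame(c(0, 0, 1))
proj <- project_and_measure(sim$nuclei, sim$refs, frame,
                            recenter_point = attr(sim, "recenter_point"))
res  <- quantify_sample(sim$nuclei, proj, sample_kind = "explant")
res
#> Nuclear signal quantification
#>   nuclei: 500 in, 197 considered, 113 positive (57.4%)
#>   bright nuclei: 34; classification: present
#>   background subtracted: 2.689
```

Of 500 simulated nuclei, 197 survive the exclusion flags and the
depth/distance windows (`res$drop_log` itemises every drop: 50 EVL, 20
dividing, 184 outside the 100 µm depth window, 14 beyond 150 µm, 35 with
non-positive background-subtracted signal). 113 of the 197 considered
nuclei (57.4%) exceed the 0.1 ratio threshold; the 34 bright nuclei are
well above the strongly-reduced boundary of 11, so the sample is
classified `present`.

```r
tr <- generate_clone_track(clone_sim_config(seed = 1))
dispersal_timecourse(tr)
#>   timepoint_min n_cells mean_pairwise_um mean_centroid_um
#> 1             0      20         21.29538         15.07046
#> 2            60      20         24.04189         17.23083
#> 3           120      20         25.67621         18.23119
```

Both dispersal proxies grow over the two simulated hours, as expected for
a random-walk clone.

A command-line wrapper for the common subcommands (simulate, quantify,
dispersal) is installed at `inst/scripts/explantr-cli.R`.

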