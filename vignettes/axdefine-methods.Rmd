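---
title: "Cleaning and quantifying fluorescently labeled axons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning and quantifying fluorescently labeled axons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axdefine)
```

## The problem

Quantifying sparsely labeled axonal fibers in fluorescence microscopy is
confounded by autofluorescent structures — lipofuscin granules,
hemosiderin, red blood cells, vessel walls — whose brightness can equal or
exceed that of the axons. A plain intensity threshold cannot separate
them, because the confound is not dimmer than the signal. Two independent
properties can: *morphology* (axons are thin and elongated; most artifacts
are compact or bulky) and *emission spectrum* (autofluorescence emits
broadly; a fluorophore label does not). This package implements a cleaning
pipeline that exploits both, followed by a background-calibrated area
quantifier.

## The cleaning model

An acquisition is a multi-channel z-stack in which, optionally, one
channel is an *autofluorescence (AF) channel*: it is excited at a label's
wavelength but collected in an emission band where that label does not
emit, so it images artifacts and not axons. Cleaning proceeds in three
stages; the first two operate on the z-stack, the last on the maximum
intensity projection (MIP):

1. **Large-particle removal** (per signal-channel z-slice). The slice is
   thresholded at $\mu + k\sigma$ of its own pixel population for
   $k \in \{1.5, 2, 2.5, 3\}$ in turn. At each iteration the binary mask
   is decomposed into 8-connected particles; any particle with
   $\text{area} \ge A_i$ *and* $\text{circularity} \ge C_i$ for **any** of
   up to five gates $(A_i, C_i)$ is zeroed. The default ladder —
   40/0.17, 25/0.32, 15/0.40, 10/0.70, 5/0.80 (area in $\mu m^2$) —
   encodes the rule that at lower circularity only increasingly large
   objects may be removed, which is what keeps thin fibers
   (circularity $\lesssim 0.1$) safe at every rung. Thresholds are
   recomputed from the *current* image each iteration, because each
   subtraction changes the intensity population; the increasing-$k$
   sequence therefore probes progressively brighter residual structure.
2. **AF subtraction** (per z-slice). The AF slice is binarized at
   $\mu + k_{AF}\sigma$ (default $k_{AF} = 1$), and the mask is subtracted
   from every signal channel of the same slice. Everything bright in the
   AF band is an artifact by construction. If intensely labeled fibers
   bleed faintly into the AF channel, raising `af_k` trades artifact
   removal for fiber safety; the stage can also be disabled entirely.
3. **Small-particle removal** (on the MIP). After projection, particles
   with area $\le 1\,\mu m^2$ and circularity in $[0.99, 1]$ at a
   $\mu + 1\sigma$ threshold are removed: residual single-pixel noise and
   fragments too small to be axons.

Removed pixels are set to 0 (binary AND-mask subtraction). No stage ever
increases a pixel, so cleaning is monotonically destructive and
idempotent in its effect on removed regions — both properties are tested.

**Why the z-stack and not the projection?** A 40 µm section is much
thicker than an axon. A fiber frequently passes above or below an
artifact that occupies only a few optical sections. Processing slice by
slice removes the artifact from the slices it occupies while leaving the
fiber's slices untouched; the subsequent projection then recovers the
full fiber. Processing a pre-projected image instead collapses fiber and
artifact onto the same pixels and loses the fiber there. The package's
canonical fixture, `overlap_scenario()`, encodes exactly this geometry
and the acceptance suite asserts both arms: ≥ 99 % fiber retention via
the z-stack route, 0 % retention inside the artifact footprint via the
projection route.

## Particle measurement conventions

These conventions are pinned because every criterion depends on them:

* **Connectivity**: 8-connected components (the common particle-analysis
  default in this field).
* **Thresholding**: population (not sample) standard deviation of the
  whole grid, and a *strictly greater* comparison. Strictness makes a
  constant image produce an empty mask, which the pipeline relies on: a
  blank z-slice (SD 0) is a harmless no-op at every stage rather than a
  statistics-corrupting degenerate case. Cropping blank slices with
  `crop_z()` is still recommended, and the batch front end warns about
  near-blank slices.
* **Area**: pixel count × physical pixel area; interior holes are not
  filled.
* **Perimeter**: the outer boundary is traced (Moore neighbourhood,
  clockwise, Jacob's stopping criterion) and steps are summed with weight
  1 for axis-parallel moves and $\sqrt 2$ for diagonal moves, scaled per
  axis by the pixel size, so anisotropic pixels are handled correctly.
* **Circularity**: $4\pi \cdot \text{area} / \text{perimeter}^2$, clipped
  at 1. Chain perimeters underestimate very short boundaries, so small
  compact particles can exceed 1 before clipping — the same behaviour as
  the common ImageJ convention, and deliberate: tiny specks must be
  removable by high-circularity gates. A single-pixel particle takes the
  unit-square perimeter and circularity 1 by convention. On a rasterized
  disk of radius 20 px this estimator yields circularity ≈ 0.91; the
  continuous-limit closed forms (square → $\pi/4$, 1×10 rectangle →
  ≈ 0.26) are exact by construction.

Labeling is implemented as vectorized neighbour-pair construction plus
graph components (igraph); the test suite checks it against an
independent breadth-first flood fill on 1000 random grids, and MIP and
pooled background statistics against explicit-loop oracles likewise.

## Quantification

Fiber density is reported as the area (µm²) above a threshold calibrated
on ten user-chosen 12 × 12 µm background regions containing no axons:
threshold $= \mu_{bg} + k\,\sigma_{bg}$ with default $k = 4$. The mean
and SD are pooled over the pixel multiset of all regions rather than
averaged per region — pooling is the better-conditioned estimator and
matches the natural reading of "mean and SD of those regions".
Overlapping regions are counted once (with a warning); regions are
specified in pixels (or µm) via sidecar CSV files for batch runs, since
the headless pipeline has no interactive selection. `propose_regions()`
offers an automatic proposal (the lowest-mean non-overlapping tiles),
clearly labeled as an extension — review it on images with large dark
non-tissue areas. Region sides convert to pixels by per-axis rounding
with a 1 px minimum. The 4-SD default is exposed as a parameter because
different labeling intensities can warrant different stringency.

## Settings recommendation

`preview_processing()` reruns the pipeline on a representative stack
while recording every removed particle with its measured area,
circularity, stage and threshold. The user marks mistakes
(`wrongly_removed_fiber` / `wrongly_kept_artifact` seed points), and
`recommend_settings()` revises the settings. The revision rule is this
package's own design (the original interactive tool promises
recommendations without publishing its heuristic), so it is isolated in
one module and documented as such:

* a marked *removed fiber* minimally tightens every gate it matched —
  whichever of the area floor or circularity floor needs the smaller
  relative increase is raised to 1 % above the particle's measurement;
* a marked *kept artifact* is re-measured at the least-stringent
  threshold; if morphology can capture it, the gate needing the smallest
  relative loosening is relaxed (1 % margin); otherwise, if the AF
  channel sees it above some cutoff $k > 0.5$, `af_k` is lowered to just
  below that cutoff (never below 0.5); otherwise it is reported as not
  separable by the available features.

The 1 % margin trades robustness against re-threshold jitter for minimal
drift from the user's intent. Tightening is sound by construction — a
protected particle can no longer match any gate — and the suite verifies
survival through a full re-run.

## Synthetic phantoms

`generate_phantom()` renders the scene classes the pipeline must
separate, with ground-truth masks: random-walk *fibers* (default width
1.4 px, intensity 120–180, spanning 1–3 adjacent z-slices, signal
channels only), elliptical *granules* (8–40 µm², intensity 160–230,
≤ 3 slices, rendered in signal channels and at 85 % intensity in the AF
channel — the lipofuscin-like bleed-through that makes AF subtraction
work), wide low-circularity *vessel* ribbons (also autofluorescent, hence
also rendered in the AF channel: their elongated shape defeats the
morphology gates, so their removal exercises the AF stage), and
integer-rounded, clipped Gaussian background
noise (mean 20, SD 4 at 8 bit). The default geometry is 0.83 µm/px,
matching a typical 20× confocal acquisition. All randomness flows from
one seed; a fixed seed reproduces the phantom bit for bit.

Placement: objects of the *same* class are re-drawn if their dilated
footprints would merge in the (y, x) projection, so labeling a class's
ground-truth projection recovers the requested object count. *Cross*-class
overlap is allowed by default — a fiber crossing a granule is precisely
the hard case the AF stage exists for. `discrimination_phantom()`
disables cross-class contact: it constructs the premise of the
morphological-discrimination check, in which every granule must *measure*
as compact (area ≥ 5 µm², circularity ≥ 0.8) and every fiber as elongated
(circularity ≤ 0.3); a granule merged with a crossing fiber measures as
neither class, which is a statement about the premise, not about the
pipeline.

What the phantoms deliberately do not model: the point-spread function,
depth attenuation, Poisson photon statistics, spectral unmixing physics,
and tissue texture. Passing tests on phantoms therefore demonstrate the
*logic* of the pipeline — stage composition, threshold statistics,
morphology gating, AF exactness — not its performance on any particular
tissue preparation, for which the settings-optimization loop exists.

## Problem sizes and numerical choices

The validation suite uses phantoms of 96–300 px per side with 2–6
z-slices and 1000-case oracle sweeps on grids up to 32 × 32 — sizes
chosen so the whole suite replays in well under a minute while still
exercising every code path at realistic object densities. Intensities are
integer throughout (8- or 16-bit); all thresholds are real-valued with a
strict comparison, so no tie-breaking is ever needed on integer data.
TIFF metadata: `tiff::writeTIFF` cannot emit resolution tags, so physical
pixel size, channel roles and page order travel in a plain-text YAML
sidecar next to each image; on reading, an explicit override takes
precedence over the sidecar, which takes precedence over TIFF resolution
tags (cm or inch units) found in files from other software. Acquisition
metadata beyond pixel size is not propagated to outputs.

## Known limitations

* The perimeter estimator biases circularity slightly downward for large
  smooth objects (disk ≈ 0.91, not 1.0); gates near that regime should be
  set with the package's own measurements (via `preview_processing()`),
  not nominal continuous values.
* AF subtraction is all-or-nothing per pixel; partial bleed-through of
  bright fibers into the AF channel costs fiber intensity unless `af_k`
  is raised.
* The recommendation rule is heuristic and local; it does not search the
  joint settings space.
* Batch region files are trusted as given; there is no automated check
  that a region is genuinely axon-free beyond its intensity statistics.
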