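---
title: "Quantification methods in gliaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods in gliaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaquant)
```

# Scope

`gliaquant` implements the quantification stages of a typical
immunofluorescence study of glial biology in an Alzheimer-model brain under
metabolic stress: microglial morphometry, plaque-associated glial
activation, hippocampal neurogenesis readouts, gene-signature screening, and
metabolic indices. Every stage runs on synthetic scenes with known ground
truth, generated by the package itself, so the whole pipeline is testable
end to end without animal data.

# Microglial form factor

Microglia shift between a compact "amoeboid" morphology and a highly
branched "ramified" surveillance morphology. The form factor quantifies this
as cell area divided by convex-hull area (a solidity measure): a compact
cell fills its hull (values near 1), while long thin processes expand the
hull far faster than the area (values well below 1). Cells are segmented
from the microglia channel at an inclusive 30--255 intensity window with no
flat-field correction, using 8-connected components so thin diagonal
processes stay attached to their soma.

**Hull convention.** Hulls are taken over the pixel-*corner* cloud (each
pixel contributes its four corners). This makes the hull the exact convex
hull of the pixel region as a solid: a single pixel has hull area 1, a
filled axis-aligned rectangle scores a form factor of exactly 1, and a 1×N
bar has a corner-to-corner Feret diameter of √(N²+1) (≈10.0499 for N = 10).
The cost of the convention is a small negative bias on curved convex
shapes: a rasterized disk of radius *r* pixels scores about 1 − 0.7/*r*
(0.965 at r = 20, 0.989 at r = 80), because the hull fills the staircase
notches of the rasterization. We prefer this exactness-plus-known-bias over
a pixel-center hull, which degenerates to zero area for single pixels and
thin bars.

Cells touching the image border are excluded by default since a truncated
hull biases the form factor; touching cells are not split (the generator
guarantees separation, and watershed splitting of real scenes is out of
scope). Group summaries use one-way ANOVA with Tukey's HSD at α = 0.05;
zero-variance inputs are flagged degenerate instead of tested.

# Plaque-associated glial activation

Plaques are segmented from the plaque channel (Thioflavin S or Amylo Glo)
at an inclusive 20--255 window. Each plaque gets a circular neighborhood of
diameter 8× its Feret diameter (the maximum caliper width of the hull),
i.e. radius 4×Feret around the plaque centroid. Pairs of plaques whose
neighborhood disks intersect are *both* excluded: the measured quantity
lives in the neighborhood, so we interpret "overlapping plaques" at the
neighborhood level (a mask-overlap mode is available). The flagging is
symmetric, idempotent and order-independent.

The glial halo of a non-excluded plaque is the integrated
background-corrected intensity inside its neighborhood disk: pixels with
intensity in 30--255 contribute `max(value − background_mean, 0)`, where
the background mean is taken over a reference region. By default that
region is the complement of all neighborhood disks eroded by 5 px; any
explicit region can be supplied. Disk membership uses pixel centers,
inclusive at the boundary; the rasterized disk area matches π(4F)² within
2% for the plaque sizes of interest.

Halo intensity is regressed on plaque area by ordinary least squares per
group, and slopes are compared against a reference group by the classical
interaction test: a pooled fit of `intensity ~ area × group`
(reference-coded) where each non-reference group's interaction coefficient
is its slope difference, tested by its t statistic. Following the
reference-versus-each reporting convention of such studies, no additional
multiplicity correction is applied to the slope contrasts (Tukey handles
the pairwise morphometry contrasts); a Bonferroni adjustment can be applied
by the caller if desired. Whether the published fluorescence units were
integrated or mean intensities is not stated anywhere we could rely on;
integrated background-corrected intensity is our declared convention, and
the regression stage is validated by simulation recovery rather than by any
printed R² value.

# Neurogenesis readouts

Inputs are vector annotations (an SGZ trace, mid- and outer-GCL reference
polylines, marker-positive soma positions, tagged dendrite paths), as
produced by manual tracing or by the generator; automated dendrite tracing
from pixels is a different research problem and out of scope. Linear
density is the count of somata within a band of the SGZ trace (default
20 µm, unstated in the source protocols) divided by trace arc length in mm.
Laminar quantification counts DCX⁺ somata (a), primary dendrites crossing
the mid-GCL line (b) and secondary dendrites crossing the outer-GCL line
(c); b/a is primary sprouting and c/b secondary branching. A path crossing
a line several times counts once — the declared rule for re-crossing
dendrites — and crossings are found by exact segment-intersection tests.
Ratios with zero denominators are reported as undefined (`NA`), never as 0.

# Signature screening and set intersection

Differential genes are filtered at a signed fold cutoff of ≥ 2 or ≤ −2,
inclusive at the boundary; downregulation is stored as a negative mirrored
fold (−2.69), not as a ratio below 1. Venn intersections are computed as
exact disjoint regions whose counts sum to the union. Perturbagen
connectivity scores (classes and compounds, in \[−100, 100\]) are screened
with *strict* thresholds ("exceeding 80.0", "above 90.0"). Gene symbols are
matched case-insensitively with whitespace stripped, and a packaged alias
table normalizes known typographical variants between running text and
tables (Carl3/Calr3, R1f/Rlf, Rio1/Riok1, Igbo-V7183/Igh-V7183, and
friends); the tables are taken as authoritative. The package ships verbatim
transcriptions of the perturbagen-class score table and the
commonly-up/downregulated gene tables as plain-text fixtures.

# Metabolic indices

HOMA-IR is fasting glucose (mM) × fasting insulin (U/mL) / 22.5, exactly as
printed, so (5.0, 4.5) scores 1.0; unit conversion is the caller's
responsibility. OGTT AUC is the trapezoidal integral of glucose over the
full sampled window (the endpoint convention is not printed; total AUC over
the window is our default, with an incremental-above-baseline option).

# The synthetic-scene generator

The generator is first-class, tested code: it produces every input the
pipeline consumes, with stored ground truth.

* **Microglia scenes** (default 9 cells on a 512 px canvas at 1 µm/px):
  soma disks of radius 8 µm — a realistic cultured-microglia soma — plus
  random-walk branches (default 4 per cell, 30 µm long, 2 µm wide) painted
  at intensity 200. Activation retracts branches by a fraction. Cells sit
  on a seeded, jittered grid whose pitch exceeds twice the maximal cell
  reach, so cells can never touch; requests that cannot fit raise an
  explicit infeasible-packing error.
* **Plaque scenes** (default 8 plaques on a 1024 px canvas): radial-falloff
  blobs (255 at center to the detection threshold at the rim, radius
  4–10 µm), placed so neighborhood disks stay disjoint. Each glial channel
  paints clustered blobs inside each neighborhood whose thresholded,
  background-corrected sum equals β₁·area + β₀ + N(0, σ) exactly up to one
  8-bit remainder pixel; the default law (β₁ = 633.8, β₀ = 276,179) mirrors
  a strong published area dependence of plaque-associated microgliosis, and
  σ is calibrated so the expected R² is 0.6, the regime such studies report.
  The background sits at a uniform 10, below the 30 threshold, so the
  reference region recovers the true background mean.
* **SGZ scenes**: a 2 mm trace (sinusoidal, rescaled to the exact arc
  length), somata placed arc-length-uniformly at the target density with
  perpendicular jitter inside the band, and dendrites constructed to cross
  their reference lines by known counts, so a/b/c are exact by
  construction. Default densities (8 DCX⁺ and 4 BrdU⁺ cells/mm) sit in the
  range typical of adult rodent dentate gyrus.
* **Signature tables**: genes assigned to designed Venn regions with folds
  drawn in \[2, 4\] (members) or (−2, 2) (non-members); score tables with
  counts above any threshold known from the draws.
* **Metabolic cohorts** (6 animals/group): normal-chow animals with fasting
  glucose ~5.5 mM and insulin such that HOMA-IR ≈ 1, versus metabolically
  stressed animals (~15 mM, elevated insulin) whose OGTT curve rises to a
  peak at 30 min and then decays at a group-specific rate — zero decay
  reproduces the no-return-to-baseline phenotype of high-fat-diet +
  streptozotocin models.

One integer seed drives a named pseudorandom stream per component, so
identical seeds give bit-identical scenes and adding components never
perturbs existing draws.

**What passing tests do and do not show.** The generator emulates geometry
and the halo intensity law, not photophysics: there is no point-spread
function, shot noise, uneven illumination, cell overlap, or tissue
autofluorescence. Recovery of generator truth therefore validates the
measurement code (segmentation, geometry, integration, statistics), not the
biological accuracy of thresholds on any particular microscope. Printed
in-vivo quantities (plaque counts per section, fluorescence intensities in
instrument units) are used only to parameterize simulations and check
directions of effect.

# Numerical and design choices

* Thresholds are inclusive intervals on 8-bit values; no shade correction.
* 8-connectivity everywhere; labels assigned in raster order of each
  component's first pixel, giving deterministic outputs.
* Minimum region sizes default to 30 px for cells and 20 px for plaques
  (unstated upstream; configurable).
* Feret diameter is the max pairwise distance over hull vertices; the test
  suite cross-checks it against a rotating-calipers implementation and an
  all-corner brute force on random masks.
* Simulation sizes are chosen for tight statistical behavior at desk scale:
  300 replicates for slope CI coverage (binomial SE ≈ 1.3%), 500 for the
  interaction-test type-I error (SE ≈ 1%), n = 60 plaques per regression
  arm. At R² = 0.6 and n = 60 the expected relative slope error is ~8% per
  fit, so the <5% mean-bias property is checked under moderate noise
  (σ = 0.25·β₁·SD(area), R² ≈ 0.94), while coverage and type-I error are
  checked at the R² ≈ 0.6 study regime.
* Degenerate inputs fail loudly: zero-variance regressions, empty
  background regions, zero-length traces, infeasible packings, and excluded
  plaques all raise errors rather than returning silent zeros.

# Known limitations

* No watershed separation of touching cells, no 3D geometry (confocal
  stacks are assumed maximum-projected upstream), no colocalization
  statistics.
* The connectivity-score and enrichment statistics themselves (CMap/CLUE,
  GSEA, pathway over-representation) are consumed as tabular outputs, never
  recomputed.
* The per-animal "15–20 plaques" sampling cap of typical protocols is not
  enforced; all non-excluded plaques are used unless the caller caps them.
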