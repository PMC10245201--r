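---
title: "Quantifying warning signals and mimicry convergence with warnsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying warning signals and mimicry convergence with warnsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warnsig)
```

## The problem

Aposematic (warningly coloured) prey are expected to be under positive
frequency-dependent selection: predators learn the locally common signal, so
rare variants pay a survival cost.  The same selection should (i) keep each
population's warning signal uniform and (ii) drive Müllerian mimicry —
convergence of signals between co-occurring defended species.  Peruvian
*Ranitomeya* poison frogs are a classic test system: three sympatric
species-level lineages form a geographic mosaic of ecotypes, mimetic in some
localities and not in others.

`warnsig` quantifies the warning signal of each frog from a standardized
dorsal photograph, fuses the measurements into a single phenotypic distance,
and derives the population-level statistics that the predation hypothesis
makes predictions about: within-population variability should correlate
*negatively* with mimicry similarity across localities.

## The measurement model

Each frog yields seven characteristics, three colours and four patterns:

| characteristic   | value                                        | distance |
|------------------|----------------------------------------------|----------|
| `colour.head`, `colour.back`, `colour.limb` | mean (hue, saturation) of non-black region pixels | Euclidean; hue on the circle |
| `pattern.head`   | binary G×G landmark-aligned raster            | Euclidean on flattened rasters (√Hamming) |
| `pattern.back`   | (left, right) transect transition counts      | Euclidean on the pair |
| `pattern.limb`   | hindlimb transect transition count            | absolute difference |
| `classif.pattern`| qualitative class (striped / spotted / lined / diffuse) | Dice: 0 same, 1 different |

Brightness is deliberately discarded: it reflects the illumination of the
photograph, not the frog, and avian predators discriminate colour across
varying brightness.

Each characteristic's pairwise matrix `mat` is min-max normalized,

$$NM = \frac{mat - \min}{\max - \min},$$

with min and max taken over the *full* matrix including the zero diagonal.
Consequence (documented, not hidden): whenever any off-diagonal entry is
positive the minimum is 0 and normalization reduces to division by the
maximum.  A constant matrix maps to all zeros.  The seven normalized
matrices fuse with identical weight:

$$D_{glob} = \sqrt{NM_{colour.head}^2 + NM_{colour.back}^2 + NM_{colour.limb}^2
 + NM_{pattern.head}^2 + NM_{pattern.back}^2 + NM_{pattern.limb}^2
 + NM_{classif}^2},$$

so every entry of `Matglob` lies in `[0, √7]`.  Because each `NM` is
scale-free, multiplying any characteristic's raw values by a positive
constant leaves `Matglob` unchanged — a property the test suite checks.

## Downstream statistics

* **Var** — within-population variability: the mean of `Matglob` over all
  unordered pairs of a population's individuals.
* **Im** — mimetic distance: the centroid distance between the focal
  population and a sympatric heterospecific population, divided by the mean
  centroid distance to *allopatric conspecific* populations.  Centroids are
  computed in the classical (Torgerson) multidimensional-scaling embedding
  of `Matglob`, retaining every component with a positive eigenvalue.  The
  fused matrix (with its 0/1 Dice component) is not guaranteed to be
  Euclidean-embeddable, so negative-eigenvalue components are dropped and
  their relative mass is reported as a diagnostic.  On an exactly
  Euclidean matrix this centroid distance equals the coordinate-space value
  to 1e-8, which the acceptance suite verifies against a planted 5-D oracle.
* **ms** — mimicry similarity: `1 / aggregate(Im)`.  The default aggregate
  is the *sum* over partners, with the *mean* available as an option.  With
  a single partner the two coincide (`ms = 1/Im`).  For a population with
  two partners a sum forces `ms ≤ 1` whenever one partner is non-mimetic,
  which makes multi-partner `ms` values hard to interpret; both modes are
  exposed and the choice is recorded in the run manifest rather than
  silently resolved.  `ms < 1` is classified non-mimetic; the boundary
  `ms = 1` counts as mimetic ("below 1" is the stated rule).
* **Var–ms correlation** — Pearson `r` with `df = n − 2`, two-sided p
  (one-sided also reported); each margin is screened with a Shapiro–Wilk
  test first, and non-normality warns rather than blocks.
* **Morphospace** — classical MDS (k = 2 by default), per-population
  frequency surfaces on a common 50×50 grid over the 5%-padded bounding box
  with 10 equally spaced frequency levels, and an *outlier fraction*: the
  share of a population's individuals strictly closer to another
  conspecific population's centroid than to their own (leave-self-out, ties
  are not outliers).  The underlying field notion ("individuals more
  similar to another locality's signal") is not operationally defined in
  the literature; the nearest-centroid rule is our formalization and is
  labelled as such in outputs.
* **Characteristic anatomy** — per-population mean pairwise normalized
  distance per characteristic; two labelled readings of the
  cross-population total (sum of mean pairwise distances, and sum of
  variances of pairwise distances); Kruskal–Wallis across the six
  quantitative characteristics (df = 5) followed by all 15 pairwise
  Wilcoxon rank-sum tests with Bonferroni multiplication capped at 1.  The
  groups share individuals, so the distances are *not* independent; the
  package replicates the field procedure and says so in the output
  metadata, and a paired signed-rank mode is available.

## Image phenotyping: parameters that matter

* **Blackness threshold** (default `0.2`, on hexcone brightness in
  `[0, 1]`): a pixel is a non-black pattern element when its brightness
  exceeds it.  The field workflow used manual magic-wand selections; a
  fixed threshold is the reproducible replacement.  Synthetic frogs render
  pattern at brightness 0.9, so the default has wide margins even under a
  0.5× colour cast.
* **Colour correction**: a 3×4 affine transform in linear RGB (3×3 matrix +
  offset), least-squares fitted from ≥ 4 reference patches (observed mean →
  true RGB), replacing proprietary colour-checker software.  Fewer than 4
  patches or an affinely degenerate patch set is an error.  Per-patch RMS
  residuals are attached to the corrected image.
* **Hue averaging** (`circular` default / `arithmetic`): red-orange hues
  straddle 0°/360°, so the circular mean is correct; the arithmetic mode
  exists only for literal replication of a "mean HSB" computation and is
  wrong across the wrap.  The same flag pair exists for distances
  (`circular`: `Δh' = min(|Δh|, 360 − |Δh|)/180`, combined as
  `√(Δh'² + ΔS²)`; `linear`: hue degrees as plain numbers).
* **Transect layout**: the two dorsal transects run neck → groin, offset
  ±15% of the shoulder width from the spine axis; the limb transect runs
  hip → knee (forelimbs are never measured).  The anatomy is from the field
  protocol; the coordinates are ours.  Transition counting samples pixels
  with Bresenham's algorithm and counts black/non-black label changes, so a
  clean b-band dorsum scores exactly 2b.
* **Head-pattern alignment**: a least-squares affine warp from the 10-point
  landmark template (10 landmarks ≫ the 3 an affine needs), sampling the
  head onto a G×G grid (default G = 64).  Affine handles the similarity
  transforms that camera pose introduces exactly; we did not implement the
  optional thin-plate-spline refinement — no pre-installed dependency
  provides one and no invariant in scope requires non-affine warps.
  Collinear landmark configurations (in either image or template) are an
  alignment error.

Pixel coordinates are 0-based (x right, y down) at pixel centres; regions
come from mask rasters (0 background, 1 head, 2 dorsum, 3 hindlimb) rather
than manual recolouring.

## The synthetic world

`generate_phenotypes()` draws, per individual: hue from a wrapped normal on
the colour circle; saturation and head-pattern coverage from clamped
normals; band counts as `max(0, round(Normal))` — integers, matching
transect-count semantics.  `render_frog()` turns a record into an image:
black body, dorsum crossed by exactly the record's band count (so each
dorsal transect counts exactly twice the bands), hindlimb bars likewise, a
head pattern whose style follows the qualitative class and whose pixel
coverage equals the record's coverage, six reference patches, and a global
linear colour cast.  Determinism: one seed drives the whole study; an
identical spec reproduces byte-identical tables and images.

Design choices worth spelling out:

* **Convergence is advergence.**  Each population's `convergence ∈ [0, 1]`
  pulls its generative means along the shortest hue arc towards the *base*
  means of its designated sympatric attractor (the first other species
  listed at its locality); the attractor itself does not move.  A mutual
  pull towards partner base means would *swap* means at full convergence
  rather than equalize them, and a symmetric midpoint pull would make the
  partner centroid distance proportional to `|1 − 2c|` — non-monotone in
  `c`.  One-sided advergence (a mimic converging on its model) keeps the
  convergence dial monotone and is the standard reading of mimicry pairs.
* **One band count per frog.**  Both dorsal transects report the same
  underlying band count; the rendered bands span the full dorsum width, so
  left and right counts agree by construction.  Treating the two transects
  as independent draws would contradict the renderer's exact-count
  contract.
* **Head pattern is deterministic given the record.**  The head field is a
  fixed class-specific score landscape thresholded at the record's
  coverage.  Two same-class frogs therefore differ on the head raster by
  exactly the symmetric difference of nested superlevel sets — head area ×
  coverage difference — so the raster distance (√Hamming) equals
  `√(area·|Δcoverage|)`.  The table-only analysis route uses the scalar
  analogue `√|Δcoverage|`, and after min-max normalization the two routes
  coincide; the pipeline test checks this two-path consistency.
  Positional jitter remains where it is harmless (band placement), and
  never changes a transition count.
* **Default generator values.**  Saturation ≈ 0.85 ± 0.02, hue sd of a few
  degrees for tight ecotypes, band means 2–5: these are the magnitudes a
  field photograph of a *Ranitomeya* ecotype suggests (vivid, highly
  saturated signals; a handful of dorsal bands or reticulation rows).
  `predation_study()` encodes the stated study structure — 3 species, 9
  localities, 15 sympatric population points — with a per-locality
  predation strength `s ∈ [0.05, 0.95]` that simultaneously shrinks all
  within-population sds and raises the convergence of mimics onto the local
  model.  This is the mechanism under test, stated once and not tuned.

What the generator does **not** emulate: photographic noise beyond a global
linear cast (no vignetting, no per-pixel noise, no specular highlights),
landmark placement error, body-outline variation between individuals,
reaction–diffusion pattern individuality (same-class, same-coverage heads
are identical by design), and UV/avian-vision colour channels.  A green
round-trip test therefore establishes that the *pipeline* is correct, not
that real photographs would behave this well; the published field numbers
(e.g. a Var–ms correlation of −0.62) depend on the deposited photographs
and are out of reach at desk scale.

## Numerical choices

* Eigenvalues below `1e-9 × max|eigenvalue|` are treated as zero in the MDS
  embedding; the non-metric variant (`MASS::isoMDS`) uses tolerance 1e-6
  and at most 500 iterations from the classical start.
* MDS axis signs follow a fixed convention (first nonzero loading
  positive), making embeddings reproducible across runs.
* Wilcoxon tests use the normal approximation (`exact = FALSE`): the
  distance groups are large and heavily tied.
* A fully tied Kruskal–Wallis input degenerates to `H = 0, p = 1` with a
  warning instead of an error.
* Ranking ties share the minimum rank with stable alphabetical order.
* Missing characteristic values are an error, never imputed.

## Known limitations

* Within-population pairwise distances share individuals; the
  Kruskal–Wallis / Wilcoxon stage inherits that non-independence from the
  field procedure it replicates.
* The multi-partner `ms` aggregation is genuinely ambiguous (sum vs mean);
  both are implemented, neither is declared "the" value.
* `Var` on normalized matrices is study-relative: adding or removing
  populations changes each characteristic's normalization maximum and
  hence every Var.  Comparisons are meaningful within one study, not
  across studies.
* The renderer is a test harness, not a frog: use the image route to
  validate the measurement chain, and the table route for statistical
  experiments at scale.
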