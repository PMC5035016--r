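---
title: "Automated scoring of scanned RFFT protocols: models and methods"
author: "rfftscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated scoring of scanned RFFT protocols: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfftscan)
```

## The scoring problem

The Ruff Figural Fluency Test (RFFT) measures nonverbal fluency: in each of
five one-minute parts the respondent sees a sheet of 35 identical five-dot
patterns and draws as many *unique designs* as possible by connecting dots.
A design repeated within a part is a *perseverative error*. Human scoring is
slow and rater-dependent, which motivates automated scoring of color scans
of the protocol sheets.

The combinatorial backbone is simple: a five-dot pattern admits
$\binom{5}{2} = 10$ distinct straight connections, so the set of drawable
designs is the set of non-empty connection subsets, $2^{10} - 1 = 1023$.
`rfftscan` encodes a design as a 10-bit integer (the *design ID*): bit $k$
is set iff the connection with canonical index $k$ is present, where the
canonical order is lexicographic over the 0-based dot pairs. Design
equality is strictly mask equality; rotations and reflections of a
connection set are different designs.

## Board geometry

A `BoardLayout` describes a page at a given resolution: a 7 x 5 grid of
cell boxes, a centered *dot square* inside each cell onto which normalized
dot coordinates are mapped, the printed dot radius, and per-part dot
patterns with their distractors (diamonds in part 2, short lines in
part 3). Everything loads from a YAML file
(`inst/extdata/layouts/default_rfft.yaml`) so a licensed stimulus layout
can be swapped in; the shipped default is an *approximation*:

* parts 1–3 use a regular pentagon (circumradius 0.45 of the dot square);
* parts 4–5 use the pentagon rotated 180 degrees.

The true parts 4–5 arrangement is only described as a variation of
part 1's pattern, and the licensed artwork is not reproducible here. The
rotated pentagon was chosen deliberately so that **no three dots are
collinear** in any part: with a collinear triple, a long connection is
visually indistinguishable from its two halves and the design space
collapses below 1023, contradicting the ten-connections/1023-designs
model that holds for every part. (A quincunx — four corners plus center —
was considered and rejected for exactly this reason.)

All geometry is stated at 300 dpi, the scan resolution of the original
protocols, and scales linearly with `dpi/300`.

## The five-task recognition algorithm

For each cell the recognizer receives the cell's red-ink mask and the five
registered dot centers, and runs:

1. **Active dots** — a dot is active iff at least `minActivationPixels`
   (default 3) red pixels lie within the activation radius (default
   dot radius + 4 px at 300 dpi) of its center.
2. **Candidate connections** — all pairs of active dots.
3. **Pixel assignment** — each red pixel is designated to the nearest
   candidate segment within a corridor (half-width dot radius + 3 px);
   ties go to the shorter segment, then the lower canonical index, so
   assignment is deterministic.
4. **Line compatibility** — a candidate is accepted iff the projections of
   its pixels onto the segment cover at least 75% of its length *and* the
   largest projection gap (including end gaps) is at most 20% of the
   length. Coverage is computed on ~1 px bins, which makes acceptance
   monotone under added corridor pixels.
5. **False-positive rejection** — collinear subsumption: an accepted long
   candidate $i\!-\!k$ passing within the activation radius of an active
   interior dot $j$, with $i\!-\!j$ and $j\!-\!k$ both accepted, is removed
   unless at least `minIndependentPixels` of its pixels lie outside both
   short candidates' corridors. The concrete rule is this package's
   definition; the original software's exact criteria are not public.

The surviving *true connections* are encoded as the cell's design ID.

**Violations.** Strokes that cross *through* the dots rather than stopping
at them breach the test instructions and are counted separately: a drawn
stroke is a violation if at least `minViolationPixels` of its pixels
(its own or unassigned ones, within the corridor of its infinite line)
extend beyond a dot center by more than the overshoot threshold (12 px at
300 dpi, about 1 mm). Restricting the evidence to own/unassigned pixels
prevents ink of an adjacent stroke sharing the dot from masquerading as
overshoot. Violating strokes are excluded from the true connections by
default; `countViolationsAsDesigns = TRUE` emulates the more liberal
human reading. A cell with ink but no true connections and no violations
is *unscorable*: it enters neither the unique nor the perseveration tally
and is only logged — the scoring rules define no category for such ink.

Thresholds were chosen once from the geometry of the rendered strokes
(dot radius ~8.4 px, stroke width 5 px, plausible hand noise) and all
live in one `RecognitionConfig`; pixel defaults scale with `dpi/300`.

## Scan ingestion

*Red segmentation* keeps pixels whose HSV color falls in a window around
red (hue within ±20°, saturation ≥ 0.35, value ≥ 0.25); black print fails
the value floor and paper fails the saturation floor. The thresholds are
configuration, not dogma — the original description assumes red ink but
states no windows.

*Registration* detects printed dots as dark connected components filtered
by area (0.45–1.9 x the nominal dot area) and moment elongation (≤ 2.2,
which drops the line distractors; diamonds fail the area window), matches
them to the layout's expected dot positions by nearest neighbor, and fits
a similarity transform (translation, scale, small rotation — flatbed
scans of flat sheets need no shear) by least squares, with one robust
re-fit that drops matches whose residual exceeds 3 px (dots partially
overdrawn by respondent ink shift their centroids). Cropping maps every
red pixel through the inverse transform into layout coordinates, so the
partition of pixels among cells is exact and pixels outside the grid are
counted and dropped.

## The synthetic renderer as ground truth

No clinical scans can ship with the package, so validation rests on a
renderer that draws the printed board (black dots, part-2 diamonds,
part-3 line segments) and scripted respondent strokes in red, then the
pipeline must recover the script. The hand-drawing noise model perturbs
each stroke: Gaussian perpendicular endpoint jitter (SD 1 px), a quadratic
bow (uniform up to 2 px), endpoint shortfall (1 px), per-pixel RGB channel
noise on the ink (SD 0.02), and a violation mode that extends the stroke
30 px (~2.5 mm) past both dot centers. Identical seeds give bit-identical
renders; `randomScript()` draws new designs without replacement within a
part so that scripted repeats are exactly the ground-truth perseverations.

What the renderer does *not* emulate: paper texture, pencil or blue ink,
strongly rotated or skewed scans, designs anchored away from dots, and
real hand-noise distributions (the defaults are plausible, not fitted to
cohort data). Passing synthetic tests therefore demonstrates correctness
of the algorithmic chain under the stated noise model, not performance on
clinical scans.

## Agreement statistics

The package implements the agreement analyses used to compare two
assessments of the same protocols:

* **ICC(A,1)** — two-way, absolute-agreement, single-measures intraclass
  correlation (McGraw & Wong), from the two-way ANOVA mean squares, with
  the standard F-based confidence interval and p-value. Named explicitly
  so users can cross-check against reference implementations.
* **Lin's CCC** — $2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ with
  biased (1/n) moments and the Fisher-z confidence interval of Lin (1989).
* **Bland–Altman** — differences $d = x - y$ (the convention is recorded
  in the output; $x$ is the computerized or first assessment), their mean
  and sample SD ($n-1$ denominator), and limits of agreement
  mean ± 1.96 SD. With the published summaries (−1.42, SD 2.78) and
  (+0.56, SD 2.36) this reproduces the published limits (−6.87, +4.03)
  and (−4.07, +5.19) to two decimals, which fixes the multiplier at
  exactly 1.96 and the SD at the sample version.
* **Reconciliation** — a third rater is required iff the first two differ
  by more than two points in any part or more than four in total; with a
  third rater, the two raters with the smallest absolute *total*
  difference are averaged per measure. "Most concordant" on the total and
  the tie order (1,2) > (1,3) > (2,3) are this package's choices; the
  procedure's source does not define the metric.

## Problem sizes and numerical choices

The validation suite uses sizes chosen to exercise the claims fully:

* the noise-free round trip is exhaustive — all 1023 designs at 300 dpi;
* the simulation study scores 100 protocols (17,500 cells, 500 pages) at
  moderate noise, rendered and ingested at 150 dpi with all geometry and
  thresholds scaled by the `dpi/300` rule — a deliberate choice of scale
  for a desk-size study, with per-cell behavior identical up to pixel
  quantization;
* 18 filled cells per part with a 10% perseveration rate mirror the
  cohort's typical performance (mean ~81 unique designs, median ~9
  perseverative errors per protocol), and a 2% violation rate exercises
  the violation path without dominating the scores;
* ICC/CCC estimates are checked against independent brute-force
  sums-of-squares/direct-formula oracles to 1e-10, and ICC parameter
  recovery on simulated two-way data (n = 5000) conditions on the
  realized rater effects, whose spread dominates Monte-Carlo error when
  raters are few.

Degenerate inputs are defined away rather than guessed at: zero total
variance is an error for ICC ("undefined-statistic"), zero variance in
both inputs likewise for CCC, |CCC| = 1 yields a degenerate interval, and
an empty red mask always yields design 0 regardless of configuration.

## Known limitations

* The default layout is a stand-in; scoring real scans requires a layout
  file measured from the licensed sheets.
* Cohort-level agreement values (e.g., ICC ≈ 0.994 between computerized
  and human assessment) require the original 1,761 protocols and are out
  of reach of synthetic validation; the package validates the machinery,
  not those point estimates.
* Single upright page per part; no OCR, no automatic part identification,
  no de-skewing beyond the small-rotation similarity fit.
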