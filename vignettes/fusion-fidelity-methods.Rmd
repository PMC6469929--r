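---
title: "Quantifying fusion fidelity in epithelial sheet closure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fusion fidelity in epithelial sheet closure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

During Drosophila dorsal closure two lateral epidermal sheets advance over
the amnioserosa and fuse at the dorsal midline, restoring a continuous,
segmented epidermis. Fusion must match the two flanks both geometrically
(arc lengths, fusing-front widths) and in cell number (the leading-edge
"DME" cells), segment compartment by segment compartment, so that segment
boundaries end up in register. fusefid analyses this process starting from
*tracked measurements* — the long tables a tracking session produces — not
from images. Everything downstream of segmentation/tracking is in scope:
disparity descriptors, equalization detection, interface-geometry
classification, rearrangement typing, and group statistics.

All analyses run on a **retrospective time axis**: 0 is the completion of
closure and every earlier frame is negative, so embryos of different
absolute duration align at their endpoint. Per-segment fusion times `t_F`
anchor compartment-level landmarks such as `t_-100` (100 min before that
pair fuses). Units are fixed throughout: micrometres, minutes, degrees.

## Disparity descriptors

The central descriptor is the normalized difference between a
contralateral pair of measurements,

$$\mathrm{norm\_diff}(u, l) = \frac{u - l}{(u + l)/2},$$

applied frame-wise to arc lengths (`arc_length`), fusing-front widths
(`width`) and DME cell counts (`dme_arc`, `dme_compartment`). The sign
convention is upper minus lower. The value is 0 exactly at equality,
antisymmetric, scale-free, and bounded by $\pm 2$ (the boundary is reached
only when one cell count is zero). Frames at which either member of the
pair is missing are skipped, never interpolated: peripheral compartments
are simply invisible in a dorsal-up view before their `visible_from` time,
and a skipped frame is more honest than an invented one.

Two sampling grids coexist, mirroring how such data are collected: lengths
and widths every frame (1 min), manual cell counts every 5 min. Series
that combine both live on the 5-min grid. Manual tracings are averaged
over six repeats and the fractional mean is kept — rounding a mean count
of 20.5 to an integer before differencing would discard exactly the
one-cell signal the analysis is after. Whole-arc count series start at
−100 min (counts cannot be collected earlier, when the leading edge is not
distinctly visible), whereas length series run from the earliest
analyzable frame.

**Equalization time** is defined operationally, because a plotted arrow on
a disparity trace is not an algorithm: it is the earliest time $t^*$ from
which $|v(t)|$ stays within a band $\varepsilon$ for the rest of the
series, with at least `hold` consecutive frames in the terminal run.
Transient re-divergence therefore pushes detection later; a series that
never settles returns undefined, which is a valid outcome. Defaults:
$\varepsilon = 0$ for integer-valued count series, $0.05$ for length and
width tracings (which carry tracing noise), `hold = 2`. Both knobs are
exposed, because the tolerance of published "time of equalization" arrows
to brief re-divergence is not stated anywhere; bracketing interpretations
is the honest option.

**Variance of ΔDME** across partner pairs uses the population variance
(divide by $N$) within each embryo, then the unweighted mean across
embryos — exactly as the formula is printed, with no silent switch to
$N-1$. The conventional pair sets are three contralateral and four
ipsilateral pairs from segments A2–A4 per embryo, but any $N \ge 1$ is
accepted.

Other descriptors: the **constriction index** $W/N$ (µm per cell) of a
fusing front at fusion; **normalized intensity** $I/I_{DV}$, which
references the fluorescence of a fused/fusing interface set to the
D/V-oriented interfaces of the same cells, cancelling acquisition scale;
the **alignment index** $\theta = |90° - \alpha|$ of a contralateral
boundary pair, where $\alpha$ is the acute angle of the joining line to
the A/P axis (0° = perfect register); and the DME cell **aspect ratio**
(D/V length over A/P length) with the fraction of cells at or above a
cutoff of 6.

## Interface geometry and interlocking

Fused interfaces are classified from their 2-D polylines (x = A/P axis,
y across the midline; angles measured against x, always reported acute).
Eligibility first: at least 1 µm long, connecting two D/V interfaces,
within segments T2–A6. Eligible interfaces are partitioned into

* **curved** — sinuosity (polyline length over endpoint chord) above a
  threshold, default 1.05;
* **angular** — chord angle in \[20°, 90°\];
* **straight** — chord angle in \[0°, 20°).

Two genuinely open choices are made explicit. First, published bin
definitions overlap at exactly 20°; we assign the boundary to *angular*
(closed lower bound) so the partition is well defined, and expose
`angle_split`. Second, "curved/squiggly" is a by-eye category; sinuosity
is our operationalization, the threshold is configurable, and a manual
`curved_flag` on a record overrides it. The chord (not a fitted line) is
used for the angle of curved interfaces as well.

**Interlocking** — the Y-shaped tricellular configuration that obliterates
the midline seam after fusion — is operationalized as: angular label and
both endpoint vertex degrees equal to 3. A compartment (one side of the
midline) is **interlocking defective** when at least 70% of its cells lack
interlocked interfaces. Compartments from Lb and A7, closure-stage
compartments within 10 cells of a canthus, and the central-most
compartment of a post-closure embryo are excluded as not assessable. The
call is monotone: giving any cell an interlocked interface can never turn
a non-defective compartment defective.

## Rearrangement typing

Cell additions to the leading edge come from mixer cells (crossing the
compartment boundary) or posterior intercalating cells (joining from the
row below). Additions of one stripe pair within the same 5-min count frame
are merged into one episode; the counts at the last frame before and the
first frame after the episode bracket it. The rule table — type 1 (no
disparity, no additions), type 2 (disparity unchanged, additions on both
sides), type 3 (disparity reduced, addition on the lower-count side) — is
applied in that order, with an explicit **other** bin for everything else
(disparity-increasing additions, additions on the higher-count side,
persistent disparity without additions). Disparity here means the
*magnitude* of the count difference; the typing section of the source
conventions reports it unsigned. Width disparity around an episode is
evaluated at the nearest sampled frames ~10 min before, at, and ~10 min
after completion; slots beyond the track boundary are flagged missing.

## What the synthetic generator emulates — and what it does not

`simulate_embryos()` is a phenomenological generator at the level of the
*measurements*: it produces the same tables a tracking session would, with
ground truth for every downstream classifier. It is not a vertex or force
model of the tissue.

The defaults are the study conditions, fixed once:

* **Chronology.** Closure spans −190 to 0 min; Lb/A7 fuse near −130,
  zippering onset is −100, central segments fuse in succession, A3 last at
  0 (all `t_F` on the 5-min grid). Tension-deficient mode delays fusion by
  20 min.
* **Arc lengths.** A shared contraction profile (350 → 8 µm) with a
  normalized disparity of magnitude 0.2 that decays linearly at 1/150 per
  minute, timed so the *expected* |disparity| crosses the 0.05 detection
  band exactly at −100 min. Noise is multiplicative Gaussian with 2% CV
  per tracing, averaged over six replicate tracings (stored values are the
  rounded means; replicates can be stored too).
* **Counts.** Whole-arc counts are a baseline (~110 cells) plus cumulative
  scheduled additions; the count disparity settles to zero *exactly* at
  −50 min via a final scheduled addition, so arc length equalizes before
  cell number, 50 minutes apart. One consequence of modelling counts as
  baseline-plus-additions is that the simulated whole-arc count does not
  fall as zippering shortens the arc, as a between-canthi count would in
  a real embryo; the conservation contract (counts change only at logged
  addition events, by exactly their increment) was judged more valuable
  for testing than that piece of realism.
* **Stripe pairs.** Initial and at-fusion count disparities are sampled by
  a comonotone coupling, so *both* configured marginals hold exactly:
  at fusion 46.2% of control central stripe pairs differ by one cell and
  none by two; the bazooka-deficient mode shifts 41.6% of pairs to a
  two-cell gap. The gap between initial and final disparity is closed by
  scripted episodes (type 3 additions on the lower side, type 2 paired
  additions, occasional disparity-increasing "other" additions), each of
  which also transiently relieves the pair's width disparity (×0.3 for
  5 min). Stripes carry roughly half as many DME cells as interstripes.
  Interstripe pairs keep persistent disparities; interstripe widths
  equalize strongly (×0.28 by fusion) while stripe widths do so weakly
  (×0.6) — and not at all in the tension-deficient mode.
* **Interfaces.** Each simulated interface appears as a pre-fusion record,
  an en-face record at fusion, and a post-fusion record at its interlock
  completion time. Kinetic times are truncated normal with means from the
  study conditions (bazooka recruitment 11.2 min control / 20.4 min
  bazooka-deficient; interlock completion 15.9 / 24.6 min; actin clearance
  10.9 min control, persisting ≥ 20 min without bazooka). Only means ±
  errors are reported for such kinetics in the literature, not
  distributions; we default to truncated normals with SD 5 min (interlock)
  and expose the choice. Post-fusion geometry classes are drawn per mode,
  and class-conditional angle distributions are Beta laws rescaled to the
  class's angle range with *exact* configured means — so the configured
  population mean angle (39.7° control, 32.3° bazooka-deficient, 18°
  tension-deficient) is recovered by plain sample averages without
  truncation bias. Angular interfaces get degree-3 vertices in control
  (hence interlock); the tension-deficient mode leaves degree-4 vertices
  and straight/curved geometry.
* **Snapshots and intensities.** Post-closure snapshots hold 10 cells per
  compartment side with a deterministic count of cells lacking interlocked
  interfaces (5–30% in control, 75–95% in the perturbation modes, so
  ground-truth defect status is unambiguous). Intensity records follow a
  stage × marker ratio table (actin/myosin/vinculin enriched before and at
  fusion, cleared after; bazooka reciprocal, rising to a peak at
  interlocking; a small E-cadherin dip), normalized to D/V references.

Determinism is a contract: identical (seed, config) yields byte-identical
serialized datasets and reports. Serialization uses
shortest-round-tripping decimal strings, so write→read is the exact
identity on doubles.

What passing tests on simulated data do **not** show: robustness to
segmentation/tracking errors, to non-Gaussian tracing noise, to frame
drops, to miscounted cells, or to biological covariance between
descriptors (e.g. correlated width and count dynamics beyond the scripted
relief). Recovery rates of 100% on simulator output are statements about
internal consistency of definitions, not about performance on real
embryos.

## Statistics

Group comparisons use the two-sided Mann–Whitney U (Wilcoxon rank-sum)
test — the test that the conventional phrase "Mann-Whitney unpaired
t-test" denotes — with exact enumeration for tie-free samples up to 20 per
group and the tie-corrected normal approximation beyond, and the two-sided
F test for variance ratios. Summaries default to median ± interquartile
range (the cluster-plot convention) with mean ± SD on request. No
multiple-testing correction is applied by default, matching
per-comparison reporting; apply `p.adjust` downstream if a family of
comparisons is made.

The end-to-end pipeline's headline comparison contrasts the whole-arc
|Norm.ΔDME| across embryos at the earliest count frame against the
completion frame; in control simulations with 16 embryos this is flagged
significant at p < 0.01, and in tension-deficient simulations — where the
disparities are constant in time — the early and late samples coincide
and the p-value is 1.

## Numerical choices and degenerate inputs

* Measured values are generated at 4-decimal precision (0.1 nm, far below
  tracing accuracy); TSVs round-trip exactly.
* `norm_diff` refuses negative inputs and the 0/0 case; count pairs with
  one zero are valid and sit on the ±2 boundary.
* The 20° class boundary belongs to *angular*; the 70% defect boundary is
  inclusive (exactly 70% lacking is defective); the aspect-ratio cutoff is
  inclusive (≥ 6).
* Empty tables are written header-only and read back empty; an empty
  dataset aborts the pipeline before any output is written, and a stage
  failure removes partial outputs.
* Problem sizes in the test-suite and acceptance script (tens to a few
  hundred simulated embryos per check) were chosen so each statistical
  recovery has comfortable margins — e.g. 600 stripe pairs put the
  at-fusion percentage within ±2 points (1 SD) of its configured value.

## Known limitations

* The simulator's arc-count conservation (no losses to zippering) is a
  deliberate departure from the between-canthi counting convention, noted
  above.
* `t_F` is stored per segment: the stripe and interstripe of one segment
  fuse together in the model, though the data model would accept
  per-compartment times with minor extension.
* Seam straightness after fusion is a qualitative judgement in the
  literature and is not implemented.
* Laser-ablation recoil measurements and anything upstream of tracked
  tables (segmentation, intensity extraction from images) are out of
  scope.
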