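---
title: "Orientation-dependent transparency rendering of tractograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation-dependent transparency rendering of tractograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractfade)
```

## The problem

Whole-brain fiber tractography reconstructs hundreds of thousands of
streamlines — polylines in millimeter world coordinates — from diffusion MRI.
Rendered conventionally, the superficial pathways occlude everything beneath
them: a 3D tractogram viewed from any side is mostly a wall of the streamlines
that happen to run toward the camera, and the deep architecture (crossing
regions, deep bundles, a tumor boundary) is invisible. `tractfade` implements
*orientation-dependent transparency*: the opacity of each streamline (or each
streamline segment) is made a function of how well its orientation aligns with
a user-chosen **opacity axis** `t`. Pathways running along `t` can be faded
out (decluttering the view) or, symmetrically, be the only thing kept visible
(isolating a bundle with known orientation, e.g. an antero-posterior
fasciculus).

## Streamline orientation: local and global

A streamline is a point sequence $\gamma_1, \dots, \gamma_N$. The **local**
orientation at point $i$ is the normalized difference of its neighbors —
central differences at interior points, one-sided differences at the two ends
(`local_orientations()`). Orientations are *axial*: $n$ and $-n$ are
equivalent, so everything downstream uses $|n \cdot t|$.

Two **global** single-axis summaries are provided (`global_orientation()`):

* **endpoints** — the normalized chord $\gamma_N - \gamma_1$. Cheap and
  meaningful ("what does this pathway connect"), but dominated by where the
  endpoints happen to land, and undefined for closed loops (the package
  returns an explicit undefined-axis marker rather than an arbitrary vector).
* **scatter** — the first eigenvector $s_1$ of the scatter matrix
  $S = \frac{1}{N}\sum_i n_i n_i^\top$ of the local orientations. This is the
  maximum-likelihood mean axis of a bipolar Watson distribution fitted to the
  segment axes, i.e. the direction *most of the streamline actually runs in*.

The two disagree exactly where it matters: for U-shaped bundles (callosal
projections, arcuate-like arcs spanning more than 180°) the chord runs along
the short connecting direction while the scatter axis runs along the limbs;
the test suite checks that the disagreement exceeds 45° on arcs of 200°–330°.

The sorted eigenvalues $\beta_1 \ge \beta_2 \ge \beta_3$ of $S$ (they sum to
1) give the **linear coefficient**

$$c_l = \frac{\beta_1 - \beta_2}{\beta_1 + \beta_2 + \beta_3} \in [0, 1],$$

which is 1 exactly for a straight streamline and 0 when no single direction
dominates. Two closed-form anchors used throughout the tests, obtained by
integrating the tangent dyadics analytically: a quarter-circle arc has
$c_l = 2/\pi \approx 0.637$ (in-plane eigenvalues $1/2 \pm 1/\pi$) and a
semicircle has $c_l = 0$ ($\beta_1 = \beta_2 = 1/2$). Discretized arcs
converge to these values at roughly $O(1/N)$, so tests that assert the limits
to $10^{-3}$ sample 2000–5000 points.

### Numerical conventions

Eigenvectors are defined up to sign; `scatter_summary()` fixes the sign so the
largest-magnitude component is positive (first such component on ties), which
makes every reported axis, and therefore every test, deterministic. When
$\beta_1 = \beta_2$ (e.g. two orthogonal axes with equal weight) the reported
axis is whichever LAPACK returns first under that sign rule — documented as a
tie-break, not a meaningful direction. Coincident consecutive points would
make a local orientation `0/0`; they are rejected at construction, and the
file readers deduplicate them (with a reported count) instead of failing.

## Opacity functions

With $x = |n \cdot t| \in [0,1]$, the two single-parameter power functions are

$$\alpha_\text{decreasing}(x) = (1 - x)^c, \qquad
  \alpha_\text{increasing}(x) = x^c, \qquad c > 0,$$

implemented in `power_decreasing()` / `power_increasing()`. The exponent $c$
controls steepness and, implicitly, the cut-off where opacity approaches 0;
the default `c = 3` is a moderate setting, and `c = 7` fades noticeably more
(the suite asserts $\alpha_{c=7} < \alpha_{c=3}$ pointwise on the open
interval). The two functions are reflections of each other:
$\alpha_\text{dec}(x) = \alpha_\text{inc}(1-x)$, checked on a $10^4$-point
grid.

`linear_theta()` offers a clamped linear ramp in the angle
$\theta = \arccos|n\cdot t| \in [0, \pi/2]$:
$\alpha = a\theta + b$ clamped to $[0,1]$ (so $\alpha = 0$ below
$\theta = -b/a$ and $\alpha = 1$ above $\theta = (1-b)/a$). Slope and
intercept tune steepness and cut-off independently, which the power family
cannot. Defaults `a = 2/pi`, `b = 0` ramp linearly from transparent at
$\theta = 0$ to opaque at $\theta = \pi/2$. The slope must be positive — the
ramp is an *increasing* function of the angle; a negative slope would
silently invert the clamp branches and is rejected.

Dot products are validated to lie in $[0, 1]$ within $10^{-9}$ and then
clipped; larger excursions indicate non-unit axes upstream and raise an error
rather than being hidden.

## The option matrix and the dispersion gate

`assign_opacity()` combines three orthogonal choices, bundled in an
`opacity_config()`:

* **scale** — `local` (one $\alpha$ per point, from $n_i$) or
  `global_endpoints` / `global_scatter` (one $\alpha$ per streamline,
  broadcast to all its points). Global rendering preserves the continuous
  appearance of a pathway; local rendering can fade just the segments that
  turn toward the axis.
* **axis mode** — `t` fixed in space (inspect a known bundle from any
  viewpoint) or coupled to the camera's viewing axis `v` (fade exactly what
  obscures the current view; the flagship decluttering mode).
* **function** — one of the three above.

On perfectly straight streamlines local and global scales agree exactly — an
invariant in the tests.

A global axis is a fiction for strongly dispersed pathways (fornix-like
curves, U-fibers). The optional threshold `T_cl` gates the opacity function:
any streamline with $c_l <$ `T_cl` is rendered fully opaque so it stays
visible in every view. The gate always uses the scatter-matrix $c_l$, in
*all* scales including `global_endpoints` — an endpoint-based dispersion
measure does not exist, and a single definition keeps the semantics
independent of the scale switch. The gate is off by default; `T_cl = 0.29`
is the reference setting exercised in the acceptance tests (it cleanly
separates semicircles, $c_l \approx 0$, from straight lines, $c_l = 1$).
Streamlines whose global axis is undefined (closed loops under the endpoints
method) are likewise rendered opaque, with a report.

`dot_histogram()` tabulates $|n \cdot t|$ (locally or globally) so a user can
inspect the alignment distribution before choosing a function; for uniformly
random axes the distribution is uniform on $[0,1]$ (the Archimedes projection
property), which the suite verifies with a $\chi^2$ test at $n = 10^5$.

## Watson distribution

The bipolar Watson distribution underpins both the interpretation of the
scatter axis and the phantom generator's angular jitter. With respect to the
uniform surface measure,

$$p(\pm n;\, \mu, \kappa)
  = \frac{e^{\kappa (\mu^\top n)^2}}{4\pi\, M(\tfrac12, \tfrac32, \kappa)},
  \qquad \kappa \ge 0 .$$

The classical form of the density omits the uniform-measure constant; the
$1/(4\pi)$ is included here so the density integrates to 1, which the tests
confirm by product-grid quadrature ($200 \times 400$ nodes, error $<10^{-3}$
at $\kappa \in \{0, 5, 20\}$). `kummer_m()` sums the confluent
hypergeometric series directly to a relative tolerance of $10^{-12}$; the
closed form $M(\tfrac12,\tfrac32,\kappa) = \tfrac{\sqrt\pi}{2}\,
\mathrm{erfi}(\sqrt\kappa)/\sqrt\kappa$ serves as an independent oracle in
the tests (agreement to $10^{-10}$ for $\kappa$ up to 50). The girdle regime
$\kappa < 0$ is not supported — nothing in the package needs it.

`sample_watson()` uses rejection sampling from the uniform sphere with
envelope $e^\kappa$: transparent to audit, exact, and fast enough for the
concentrations used here (the acceptance rate, $M e^{-\kappa}$, is about 1%
at $\kappa = 50$ and is reported as an attribute). `estimate_mean_axis()` is
the ML estimator — the first eigenvector of the sample scatter matrix — and
recovers $\mu$ to well under 3° at $\kappa = 50$, $n = 1000$ across 20
seeded replicates.

## Synthetic phantoms

`make_phantom()` generates the geometric regimes against which the method's
behavior is provable: `straight` bundles (corticospinal-like; $c_l = 1$
exactly), planar `arc` bundles (90° reproduces the $2/\pi$ anchor, 180° the
$c_l = 0$ anchor; >180° arcs reproduce the U-fiber endpoint/scatter
discrepancy), `helix` bundles (curved but with a well-defined axis), and
`crossing` pairs of straight bundles at a set angle (the selective-display
scenario). Defaults — 20 streamlines, 100 points, 80 mm length, 30 mm arc
radius, 10 mm bundle spread — are in the realistic range for major human
bundles at typical tractography step sizes.

Per-streamline axis jitter is Watson-distributed with concentration
`jitter_kappa`; the default is `Inf` (no jitter) so the closed-form anchors
hold exactly, and tests that need realistic dispersion set $\kappa$ of 20–50
(a few degrees of spread) explicitly. Every phantom is a pure function of its
arguments including the seed, and ground truth (axes, bundle membership) is
attached as an attribute and written as a JSON sidecar by the CLI.

What the phantoms deliberately do *not* emulate: tractography step-length
noise along the streamline, premature terminations, fanning within a bundle,
partial-volume kissing configurations, or anatomically realistic geometry.
Passing tests demonstrate the orientation statistics, the opacity semantics
and the compositing are correct on controlled geometry — not that any
clinical rendering is diagnostic.

## Compression

Depth-sorting cost is linear in the number of segments, so tractograms are
compressed by removing points in nearly linear stretches
(`compress_streamline()`, default tolerance 0.01 mm). The algorithm is a
greedy forward scan: from the last kept point, the next kept point is pushed
as far ahead as possible while every spanned point stays within the tolerance
(perpendicular distance) of the candidate segment. It is deterministic,
single-pass, keeps both endpoints, and guarantees — verified property, 100
random noisy phantoms — that no original point ends up farther than the
tolerance from the compressed polyline. With tolerance 0 only exactly
collinear interior points are removed. Scalar channels are subset to the kept
points by `compress_tractogram()`.

## Rendering

`render_scene()` reproduces, in software, what an interactive GL viewer does
per frame:

1. assign opacities (coupling `t` to the camera's viewing axis in `view`
   mode);
2. project points (orthographic by default — the axis-aligned anatomical
   views this tool targets are orthographic in character; a perspective mode
   exists);
3. build one segment per consecutive point pair — segment $\alpha$ is the
   mean of its endpoint alphas, segment color the directional encoding
   (RGB $= |n|$) of its chord;
4. sort *all* segments of the tractogram (not per streamline) back-to-front
   by mean distance from the eye, with a stable sort so equal depths keep
   input order;
5. composite with the standard "over" operator
   $C \leftarrow \alpha C_\text{seg} + (1-\alpha) C$ as 1-pixel analytic
   lines, no antialiasing.

"Over" in back-to-front order is the standard painter's-algorithm blend; no
other blend mode is offered. The no-antialiasing rasterization makes renders
byte-reproducible, which the CLI test asserts on PNG files. Because the
directional colors are anchored to the world axes, rotating scene and camera
together leaves geometry and opacity untouched but permutes color channels
accordingly — the rotation-invariance test asserts exactly that.

## Problem sizes and runtime

Everything in the test and acceptance suites is sized to run in seconds on
one CPU: phantoms of 5–50 streamlines with 20–2000 points, rasters of
60–100 px, $10^4$–$10^5$ Monte-Carlo draws, 20 replicates for recovery
statistics. These sizes are where the analytic anchors already hold to the
asserted tolerances; nothing about the implementation caps the input size,
and the compression step exists precisely to make larger tractograms cheap
to sort.

## Known limitations

* The renderer is a verification-oriented software rasterizer: no
  antialiasing, lighting, tubes, or interactivity.
* Global depth sorting by segment midpoint distance is the classic painter's
  approximation; intersecting segments at nearly equal depth can blend in
  either order.
* TRK/TCK support covers the common single-file layouts (Float32 data, up to
  10 TRK scalar channels); anatomical underlays and voxel-space processing
  are out of scope.
* The endpoint orientation of almost-closed loops (chord shorter than 1 nm)
  is treated as undefined rather than noisy.
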