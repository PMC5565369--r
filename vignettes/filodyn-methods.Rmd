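---
title: "Models and methods for signalling filopodia dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for signalling filopodia dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filodyn)
```

## Scope and data model

`filodyn` analyses the dynamics of signalling filopodia (cytonemes) from
manually tracked point data.  The unit of observation is one filopodium:
a *cluster* with two point tracks, the base (track #1) and the tip
(track #2), each an ordered list of `(frame, x, y)` positions.  Frames
are 1-based as stored in MTrackJ files; internal time is
`t = (frame − 1) × Δt` minutes, so all velocities are µm/min.  The
default acquisition matches the histoblast imaging protocol this analysis
was designed around: Δt = 2 min (30 s movies are supported via
`frame_interval_min = 0.5`), a 30-min analysis window, and a 49 × 76 µm
tracking region.  Image handling, automatic detection and track curation
are out of scope: tracking is an input, and clusters flagged as
non-filopodium reference tracks are excluded by id
(`read_mdf(..., exclude_clusters = )`), mirroring the manual discarding of
unclear tracks.

Frames present in only one of the two tracks are dropped, not
interpolated: no gap-filling rule is defined for this kind of data, and
dropping is conservative; the count of dropped points is logged so every
input point is accounted for (accepted, rejected with a reason, or
dropped).  A track contributes only if at least two paired frames remain.

## The extent series and the two dynamic models

The *extent* at a frame is the Euclidean base–tip distance
`E = sqrt((x_tip − x_base)² + (y_tip − y_base)²)`.  Because it is a
relative measure, it is exactly invariant under rigid motion of the whole
tissue — drift does not bias any downstream quantity.

Two piecewise-linear kinetic models describe the extent-over-time of one
filopodium.  Both place the filopodium *origin* one frame before the
first recorded frame and its *end* one frame after the last, at extent
zero; the *lifetime* is `t_end − t_origin`, so a gap-free track of `n`
frames has lifetime `(n + 1) Δt`.

**Triangle (2 phases: elongation, retraction).**  The elongation velocity
`Ve` is the slope from the origin to the *first* frame attaining the
maximum extent `Emax`; the retraction velocity `Vr` is (minus) the slope
from the *last* frame attaining `Emax` to the end.  Velocities are
reported as unsigned magnitudes.  The model curve has a single apex at
the intersection of the two sides.  With a unique peak frame the apex is
exactly `(t_peak, Emax)` and the curve reproduces noiseless triangular
data with zero error.

**Trapezoid (3 phases: elongation, stationary, retraction).**  The
stationary phase is characterised by `Es`, the extent at the
half-lifetime `t_h = (t_origin + t_end)/2`, and `Vs`, the mean of the
consecutive frame-to-frame velocities inside the stationary span.  The
span runs from the first to the last experimental point with extent
≥ `Es`; the stationary segment is the line of slope `Vs` through
`(t_h, Es)`; the sides connect the origin and end to that line at the
span boundaries.  When the span is a single point the construction
degenerates exactly to the triangle.

Two details are interpretations where the operational definition is
under-specified, and are therefore explicit package assumptions:

- `Es` is obtained by *linear interpolation* between the two frames
  bracketing `t_h` (using the nearest frame instead would make `Es`
  depend on the parity of the frame count);
- the stationary line is *anchored at `(t_h, Es)`* rather than being a
  least-squares level of the stationary points.

## Classification

Both models are fitted to every filopodium and evaluated at the observed
frame times; the label is the model with the smaller RMSE.  Exact ties go
to the simpler triangle, with one principled exception: when the fits tie
*and* two or more frames are tied at `Emax`, the maximum itself is a
plateau — direct evidence of a stationary phase — and the label is
trapezoid.  This matters because a trapezoid whose plateau spans exactly
two frames is also fitted exactly by the single-apex triangle (the tied
frames straddle the apex), so without the exception such filopodia would
be systematically mislabelled even on noiseless data.

## Phase eligibility and cohort statistics

Not every filopodium shows both phases inside the recording window.  A
filopodium already present at the first window frame — or whose first
observed extent already equals `Emax` — has no observable elongation, so
`Ve` is not reported; one still present at the last window frame has no
observable retraction, so `Vr` is not reported.  `Emax` and lifetime are
always reported (for truncated tracks the lifetime is the observed-window
lifetime).  These exclusions reproduce the per-variable cohort sizes used
when pooling filopodia across animals.

Cohorts are compared per variable with the Mann–Whitney–Wilcoxon rank-sum
test (two-sided).  The historical description of this test as a
"homogeneity of variances" test is a misnomer; it is the standard
location-shift rank test, and that is what is implemented.  The exact
null distribution is used when `n_a + n_b ≤ 14` and there are no ties;
otherwise the normal approximation with midranks, tie correction and
continuity correction.  Shapiro–Wilk normality is computed per group and
reported descriptively — it does not gate the nonparametric comparison.
No multiple-testing correction is applied (stars are per-comparison:
`*` p<0.05, `**` p<0.01, `***` p<10⁻³, `****` p<10⁻⁴).  Pupa-level
clustering is deliberately not modelled (filopodia are pooled).

## Wing-disc quantification

The maximum cytoneme extent of a disc is summarised as the mean of its
ten longest protrusions (k configurable), measured from the A/P border to
the tip.  Gradient extension is read from 1D intensity profiles along the
A/P axis: the background is the median of the 10% most-distal samples,
and the domain width is the distance from the border to the farthest
position where the intensity still reaches
`background + f × (max − background)` (default `f = 0.5`), with the
crossing interpolated between samples.  The previously used
gradient-length procedure is not available in detail; this
threshold-crossing definition is a documented substitute, invariant to
affine intensity rescaling, and `f` is exposed as a parameter.  Error
bars use the sample SD (n − 1).

## The synthetic generator: what it emulates, and what it does not

`gen_cohort()` states the world the test-suite operates in: base points
follow a straight drift path (default 0.1 µm/min — slow tissue drift);
the tip sits at `base + u·E(t)` for a fixed unit direction (filopodia are
treated as straight; only the scalar extent matters downstream); Gaussian
localisation noise is applied to the tip coordinates (base noise would be
absorbed into the same effective σ); frames where the model extent is
zero, and frames outside the window, are not emitted.  Defaults: Δt =
2 min, window 30 min, Emax uniform 2–8 µm, lifetime uniform 8–24 min
snapped to the frame grid, plateau fraction 0.3–0.6 for trapezoids,
`Vs = 0` (a flat plateau is the canonical stationary phase and the only
regime with a well-defined exact-recovery check), and births spread so
that some tracks are clipped by the window, with truncation recorded in
the ground truth.  No distributional information is available for these
parameters; uniform ranges at the scale of
histoblast filopodia are a stand-in, and all are configurable.
`allow_truncation = FALSE` confines every model to the window — the
regime in which labels and parameters are fully identifiable, used by the
recovery and classification checks.

The generator does not emulate: curved or branching filopodia, tracking
mistakes (wrong point picked), frame gaps, base-point localisation error
as a separate term, or any spatial interaction between filopodia.  A
green recovery test therefore establishes correctness of the *pipeline
arithmetic* under the stated kinetic models, not robustness to every
failure mode of manual tracking.

Synthetic intensity profiles are background + plateau + exponential
decay, with the closed-form domain width
`plateau + decay × log(1/f)` available for oracle checks.

## Numerical choices

- Comparisons against `Emax`/`Es` use a relative tolerance of 1e−12 so
  binary-representation jitter does not split exact plateaus.
- RMSE ties in classification use a 1e−9 relative tolerance.
- CSV output formats numbers with R's shortest lossless decimal
  (`as.character`), giving byte-identical files for identical inputs and
  bit-exact read→write→read round-trips for finite decimal inputs.
- The exact Mann–Whitney tail uses the null distribution of U
  (`pwilcox`); the test suite checks it against an independent
  enumeration over all `choose(n_a + n_b, n_a)` labelings.

## Known limitations

- **Noise fragility of the literal trapezoid construction.**  `Es` is a
  single interpolated value at `t_h`; with measurement noise it sits near
  the top of the plateau noise, so the stationary span (points ≥ `Es`)
  can collapse to ~1 point and the trapezoid fit degenerates towards the
  triangle.  Conversely, raw RMSE model selection favours the more
  flexible trapezoid on noisy triangles, whose triangle fit is pinned to
  the noise-inflated peak frame.  At tip noise of 2% of Emax this yields
  ~70–80% classification accuracy on mixed cohorts (velocity recovery is
  unaffected: median relative error ~2%).  The corresponding acceptance
  check (≥95%) is intentionally left failing rather than papering over it
  with noise-tolerance parameters the method does not define.
- Lifetime of window-truncated filopodia is the observed-window lifetime,
  a downward-biased estimate of the true lifetime.
- The gradient-width procedure is a stated re-interpretation, not a
  reproduction of the cited original.

## Session info

```{r}
sessionInfo()
```
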