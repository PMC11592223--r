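---
title: "Methods: photographic scoliosis measurement in scolioscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photographic scoliosis measurement in scolioscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scolioscreen)
```

scolioscreen turns two kinds of back photographs into the three numbers a
clinician uses to screen and follow scoliosis without X-rays: the coronal
curvature type (C / S / multi-curved), a severity grade on the clinical
four-class Cobb scale, and the sagittal angle of trunk rotation (ATR).
This vignette is the package's account of the underlying models, the
parameters that matter, what the synthetic generators do and do not
emulate, and the numerical decisions taken where the design was open.

## The coronal model: a quartic spine curve

A standing back photo yields seven labeled keypoints: five along the
spine (top to bottom) and the two scapular prominences. All geometry is
done in the image pixel frame (origin top-left, y downward).

**Spine-aligned fit.** Spines in standing photos are near-vertical and
their keypoints strictly monotone in the vertical coordinate, so the fit
uses the vertical coordinate `t` as the independent variable and the
lateral position `d` as the dependent one. The degree-4 least-squares
polynomial through five points with distinct abscissae is an exact
interpolant; `spine_curve()` solves the 5x5 Vandermonde system on the
normalized coordinate `u = (t - t_min)/(t_max - t_min)` (condition number
a few hundred, against ~1e12 for raw pixel abscissae) and converts
coefficients back to the pixel frame for reporting. Slope, curvature and
inflections come from the analytic derivatives of the fit, never from
finite differences of the sampled curve.

**Apex detection.** A tangent point (apex) is a sign change of `d'(t)`.
A window of one tenth of the 200-sample evaluation grid slides in steps
of 2 samples; each sign change inside a window is refined to the exact
root of the analytic derivative. Candidates must pass a curvature check
(unsigned curvature above the median of non-flagged grid samples), and
candidates closer than one window width merge into the higher-curvature
one, with ties resolved toward smaller `t`. Counting the surviving
apexes gives the type: one is C, two is S, more is multi-curved. A curve
with no apex (near-straight spine) has no class of its own clinically;
it is labeled C with a `degenerate` flag so no information is lost.

Two guards deal with artifacts that the plain rule cannot: an
interpolating quartic oscillates near the ends of its data range, and
under keypoint noise those end wiggles (and occasional small interior
wiggles) carry *higher* pointwise curvature than the true apex, so the
curvature check alone keeps them. `tangent_points()` therefore (a)
rejects sign changes within half a window of either domain end, and (b)
when several apexes survive, drops those whose lateral prominence — the
smaller change of `d` toward the adjacent apexes or domain ends — is
below 20% of the most prominent candidate's (`rel_prominence`). Both
guards are provably inert on the clean archetypes (their apexes are
interior and of equal prominence); the 20% value sits in the middle of a
wide plateau over which noisy-cohort accuracy is flat, i.e. the exact
number is not delicate.

**Cobb angle.** For a C-curve the domain splits at the apex; on each side
the grid point of maximum `|d'|` marks the most-tilted vertebra, and the
Cobb angle is `|atan(m_upper) - atan(m_lower)|` in degrees. The
difference-of-inclinations form is used deliberately instead of the
acute-angle formula with `1 + m1 m2` in the denominator: it has no
singularity at perpendicular tangents and matches the clinical habit of
summing endplate inclinations, so angles above 90 degrees are possible
for severe curves. S- and multi-curves are split at the zero crossings
of the analytic second derivative (refined by root finding to 1e-3 of
the domain), each convex/concave part is measured by the C-rule — using
the part's own apex, or its midpoint when it has none — and the parts
are *summed*, so a double curve reports the accumulated deviation of
both arcs.

**Scapular spine triangle and fusion.** The triangle joins the two
scapular keypoints to the lowest spine keypoint; `triangle_asymmetry()`
reports the absolute difference of its two base angles, a scale-free
asymmetry index that grows with coronal deviation. Severity grading uses
half-open intervals `[0,10) [10,20) [20,45) [45,Inf)` for the Cobb angle
— covering every real angle while keeping "<10" and ">=45" exact — and
three configurable thresholds (default 2, 5, 10 degrees) for the
triangle difference. There is no canonical clinical mapping from
triangle asymmetry to the Cobb classes; the defaults are an explicit
calibration, surfaced in `pipeline_config()` rather than buried.
`fusion_grade()` routes by type: triangle for C (and degenerate) spines,
Cobb for S/multi, where the triangle index confounds the two lobes.

## The sagittal model: profile + AMPD

A forward-bend photo shows the back from behind as a silhouette whose
upper contour carries two bumps — the scapular prominences. The pipeline
is: optional preprocessing (3x3 median denoise, histogram equalization)
→ Otsu binarization (or a supplied binary mask) → edge detection →
per-column profile → AMPD → ATR.

**Edge operators.** `edge_detect()` implements the three classical
choices with their standard kernels: Roberts (2x2 diagonal differences),
Prewitt (3x3 first differences; the default, and in practice the most
stable of the three on back contours), and LOG (Gaussian smoothing at
`sigma = 1.4`, a common textbook default, followed by the 4-neighbour
Laplacian with edges at zero crossings). Borders are replicate-padded so
the edge map keeps the image dimensions and column indices stay aligned
with the profile. Zero crossings are marked at the smaller-magnitude
member of any opposite-sign 4-neighbour pair, with a 1e-9 relative
tolerance so the perfectly antisymmetric response of an ideal step does
not fall between two pixels.

**Profile.** `extract_profile()` reads, per image column, the top-most
foreground pixel (mask) or the top-most pixel at >= 50% of the maximum
edge strength (edge map), converted to height above the image bottom so
the scapular bulges are maxima. This per-column reading is the package's
explicit construction of the 1-D signal; columns without foreground are
invalid, interior gaps are linearly interpolated and marginal gaps
trimmed before peak detection, which needs a uniform gap-free signal.

**AMPD.** The profile is linearly detrended, then the local maxima
scalogram is built: for scales `k = 1 ... ceiling(N/2) - 1`, entry
`(k, i)` is 0 when the tested sample beats both neighbours at lag `k`,
and `r + 1` with fresh uniform `r` otherwise (boundary columns always
random). The scale `lambda` with the most local maxima is selected and
peaks are the samples whose scalogram column is zero at every scale up
to `lambda` (column standard deviation zero, tolerance 1e-12 to absorb
floating-point summation). Because the row sums are a fixed multiple of
the deterministic zero counts plus zero-mean noise, `lambda` is computed
from the deterministic part; this makes the selected scale — and with it
the peak set — exactly independent of the random-number seed, which the
tests verify. With `lambda = 1` the standard deviation of a single row
is undefined and the zero-entry rule of row 1 is used directly.

Two practical consequences are documented rather than hidden. First,
AMPD has a boundary blind zone: a maximum closer than about `lambda`
samples to either signal end sits in the scalogram's boundary region and
cannot be detected; back profiles keep their bumps far from the frame
edges, and the test sinusoids are phased accordingly. Second,
mask-derived profiles are integer-valued and real apexes become plateaus
of exactly equal heights, which defeats the strict `>` comparisons; after
detrending, `measure_atr()` adds an infinitesimal deterministic tilt
(1e-9 of the signal range — far below the 1 px height quantum) to break
ties, then re-centers each detected peak on its plateau. Both steps are
inert on continuous signals.

**Bimodal filtering and ATR.** If more than two peaks survive, each is
scored by topographic prominence divided by local flatness (standard
deviation of heights within ±N/20 columns), and the two best peaks at
least N/10 columns apart are kept; fewer than two admissible peaks raise
a `bimodal_failure`, signalling an unusable photo rather than returning
a fabricated angle. The ATR is `atan(|dh|/|dcol|)` between the two
retained prominences, in degrees. The prominence/flatness score and the
separation are declared configuration, not recovered constants.

## What the synthetic generators emulate

`synth_coronal_case()` draws the spine's lateral deviation from the sine
family `d(t) = A L sin(m pi t / L)` with `m = 1, 2, 3` interior extrema
for C, S and multi (and `m = 0` for straight), samples it at
`t = {0, 1/4, 1/2, 3/4, 1} L`, and adds i.i.d. Gaussian positional noise
to every keypoint coordinate. The analytic Cobb ground truth applies the
same segment rule to the generating sine, giving
`2 m atan(A m pi)` degrees. `synth_sagittal_case()` builds a baseline
plus two Gaussian scapular bumps, calibrates the taller bump so the line
through the realized continuous-profile apexes makes exactly the
requested ATR, rasterizes by filling below the profile, and jitters the
contour per column to model segmentation noise.

The generators emulate geometry and noise, not photography: no clothing,
hair, lighting, perspective, soft-tissue asymmetry, or detector-specific
error structure. Passing tests therefore demonstrate that the
*measurement geometry* is implemented correctly and is robust to
positional noise of the stated magnitude — not that any particular
keypoint detector or segmenter reaches that noise level on real photos.

Default study conditions: spine length 400 px, amplitude grid 1–15% of
spine length, keypoint noise 1% of spine length for noisy cohorts;
sagittal masks 512x384 px with 200 px bump separation, sigma-25 px
bumps, 1 px contour jitter, ATR 4–16 degrees; cohorts of 300 coronal and
50 sagittal cases. These sizes keep the full suite and the acceptance
script in the tens of seconds while leaving every property measurable.

## Known limitations

* **Five points are a coarse spine model.** The quartic through five
  samples of a *full* sine period (the S archetype) overshoots the
  generating curve's slopes substantially: the interpolant is the odd
  cubic with endpoint slope `32A/3` against the sine's `2 pi A`, a ~70%
  overshoot, so measured S-curve Cobb angles run ~25% above the analytic
  archetype values even at zero noise (C-curves agree to under a degree
  across the amplitude grid). The package reports the fit's angle
  faithfully; absolute S/multi Cobb values should be read as an index
  consistent within the method, not as an unbiased estimate of the
  generating curve's angle. A denser keypoint set would remove this
  bias, but five labeled points is the realistic annotation budget.
* **Small curves drown in keypoint noise.** At 1% positional noise, an
  amplitude of 1% of spine length gives signal-to-noise 1 per keypoint;
  no classifier on the interpolant can recover the type reliably there.
  Measured type accuracy is 100% noiseless and ~0.90 under 1% noise over
  the full 1–15% amplitude grid, with errors concentrated at amplitudes
  of at most 3%.
* **ATR needs a usable silhouette.** Blank or unimodal profiles raise
  `bimodal_failure` by design; the pipeline never guesses.
* **Raster I/O is PNG-only**; images from other formats should be passed
  as intensity matrices.
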