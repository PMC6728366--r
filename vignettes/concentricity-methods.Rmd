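---
title: "Quantifying hair-cell orientation and concentricity in neuromasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hair-cell orientation and concentricity in neuromasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromast)
library(dplyr)
```

## The biological question

Zebrafish neuromasts are rosette-shaped sensory organs in which central
hair cells sit surrounded by support cells. Each hair cell carries a single
kinocilium at one pole of its apical surface; the kinocilium's position
defines the cell's planar polarity. In wild-type animals the polarity axes
line up with a body axis (anterior–posterior for primI-derived organs,
dorso-ventral for primII-derived ones). Two mutant phenotypes look
superficially similar — "disordered" hair cells — but are geometrically
distinct:

* **random misorientation**: polarity axes uniformly distributed, the
  signature of broken core planar cell polarity (PCP) signaling;
* **concentric misorientation**: polarity axes aligned with the *tangent*
  of the organ outline, a circular arrangement associated with loss of
  Wnt/Wnt11-class signaling.

Telling these apart requires a statistic that is sensitive to tangential
organization but blind to overall rotation of the organ. This package
implements that statistic — the **concentricity test** — together with the
surrounding toolkit: axial circular statistics, division-angle geometry,
cortical intensity polarity profiling, and support-cell shape analysis, all
driven by a seeded synthetic generator so every stage can be verified
without raw microscopy data.

## The concentricity statistic

Given annotated cells (centers $(x_i, y_i)$ and axial polarity angles
$\phi_i \in (-90, 90]$ degrees):

1. **Ellipse fit.** An ellipse is fitted to the cell centers by principal
   component analysis: the center is the centroid, the rotation is the
   first principal axis, and the semi-axes are $\sqrt{2}$ times the
   standard deviations along the principal axes. For points sampled
   uniformly in the ellipse parameter this is exact
   ($\operatorname{var}(a\cos t) = a^2/2$), which is why the package uses
   the population (divide-by-$n$) covariance.
2. **Projection.** Each cell is projected to the nearest point on the
   ellipse boundary. The projection minimizes Euclidean distance over the
   boundary parameter with a 720-point coarse grid, bounded local
   refinement, and a final Newton polish — the grid stage guards the
   well-known instability of pure Newton iteration near the ellipse's
   evolute, and the polish brings the answer to machine precision (the
   documented guarantee is $10^{-6} a$).
3. **Tangent deviation.** The signed axial difference between the boundary
   tangent at the projected point and the cell's polarity axis,
   anticlockwise positive, on $(-90, 90]$. Deviations are frame-free:
   rotating or translating the whole field leaves them unchanged.
4. **Uniformity test.** Deviations are binned into 12 equal axial bins and
   tested against uniformity with the chi-square goodness-of-fit statistic
   ($df = 11$); the field is labelled *Concentric* when $p < 0.01$.
5. **Von Mises description.** When the distribution is non-uniform, an
   axial von Mises fit ($\mu$, $\kappa$) describes the preferred deviation
   and its spread. Axial data are doubled before fitting so $\kappa$
   retains its standard meaning; $\mu$ is half the doubled-scale mean
   direction. $\kappa$ is capped at 1000 and flagged when the mean
   resultant length approaches 1.

A concentric field gives deviations piled near 0 and a small $p$; a
randomly oriented field gives uniform deviations; a body-axis-aligned field
also rejects uniformity (its deviations track the tangent angle around the
ellipse), which is why the label is a statement about *non-uniformity of
tangent deviations*, not a complete phenotype classification. An optional
stricter criterion (`strict_mu = TRUE`) additionally requires $|\mu| <
30^\circ$ so that strongly radial fields are not called concentric; it is
off by default because the default mirrors the significance-only labelling
used in practice.

### Choices we had to fix

* **Which uniformity test.** The binned chi-square on the 12-bin histogram
  was chosen (over continuous alternatives such as Rayleigh or Kuiper)
  because the analysis is defined on the binned probability histogram and
  the support-cell analysis uses the same one-way chi-square; the two
  stages share one code path.
* **Which ellipse.** By default the ellipse is fitted to the scored cells'
  own centers; `concentricity_test(..., ellipse = )` accepts a reference
  ellipse (e.g. fitted to all cells, or the generating geometry in
  simulations).
* **Tie conventions.** All half-open ranges close on the anticlockwise
  side: $-90$ wraps to $+90$; a $90^\circ$ axial difference is $+90$; a
  directional angle of exactly $45^\circ$ belongs to the "up" quadrant.
  These are arbitrary but deterministic and documented.
* **Coordinate frame.** Internally all math is y-up with anticlockwise
  angles positive. Image-derived tables (y down) are negated on ingestion
  (`read_cells(frame = "image_y_down")`, the CLI default), so screen
  anticlockwise remains positive.

## Orientation, pairs, and divisions

Kinocilium annotations arrive as line segments drawn from the pole
opposite the kinocilium toward it; `orientation_from_line()` converts them
to directional angles on $(-180, 180]$ and their axial wraps. Axis
preference is tested two ways: an exact binomial test of whether the
right+left quadrant count differs from half (A–P vs D–V preference), and
Fisher's exact test comparing the 2×2 axis table of two conditions.

Sister hair cells arise from one progenitor with kinocilia pointing toward
each other. `pair_opposition()` operationalizes "correct orientation" as
each cell's direction lying within a tolerance (default $90^\circ$, i.e.
positive inner product) of the unit vector toward its sister — published
percentages are based on visual judgment, so the numeric tolerance is this
package's construction and is a parameter.

Division geometry: the division angle is the smallest angle between the
daughter–daughter vector and the vector from the organ center to the
division midpoint, folded to $[0, 90]$, in 2D or 3D. Conditions are
compared with Welch's two-sample t-test (the unequal-variance default is a
deliberate choice where only "t-test" is specified).

## Cortical intensity profiles

Polarity of a cortical marker (e.g. a GFP-tagged Vangl2) around the
cuticular plate is quantified from an angular intensity profile: mean
intensity over a 4-pixel band normal to the contour, parameterized by angle
about the contour centroid, resampled to a 1° grid. Profiles are aligned so
the maximum sits at 0°, wrapped to $(-179, 180]$, averaged pointwise with
SEM, and optionally normalized to a maximum of 1.

Peak width comes from a nonlinear least-squares fit of
$I(\theta) = b + A e^{-\theta^2 / 2\sigma^2}$ (Levenberg–Marquardt,
initialized from the maximum, half-maximum width and minimum). Parameter
errors are Monte Carlo: 100 refits of synthetic data formed by adding
Gaussian noise at the residual standard deviation to the fitted curve, with
the per-parameter SD over refits reported. The noise model for the refits
is the package's choice (the alternative — resampling residuals — is a
one-line change and gave indistinguishable error bars in our checks). The
coverage experiment in the acceptance script fits profiles generated with
the peak already at 0°: aligning to the *noisy* maximum first selects an
upward-fluctuating grid point, which biases the amplitude by about a
quarter of a standard error and would confound a measurement of the Monte
Carlo method itself. A wrapped-Gaussian variant is not needed at the peak
widths of interest ($\sigma \le 60^\circ$); beyond that the plain Gaussian
underestimates tail mass.

Polarity ratios average the three grid values nearest the 0°, 90° and 180°
anchors (the anchor's bin and its two neighbors) and propagate errors to
first order: $\sigma_r / r = \sqrt{(\sigma_a/a)^2 + (\sigma_b/b)^2}$.

## Support-cell shapes

Support-cell coordination is measured from segmented label images (the
segmentation itself is out of scope; any segmenter producing integer
labels works). Each region is fitted with the ellipse of matching second
central moments — axis lengths $4\sqrt{\lambda_{1,2}}$ of the central
moment matrix, so a rendered ellipse recovers its own axes — and its
orientation is folded to the unsigned $[0, 90]$ range against the
horizontal. Regions smaller than 5 pixels or with axis ratio below 1.05
(no meaningful major axis) are excluded and reported as such. The
orientation histogram (default 9 bins of 10°) is tested with the same
one-way chi-square against uniformity.

## The synthetic generator

The generator produces data with the statistical structure the analyses
assume, not photorealistic microscopy:

* **Fields**: 15–40 cells (default 30, a typical mature organ) placed
  uniformly in ellipse parameter on a boundary band (default
  `radial_jitter = 0.15` of the boundary radius — neuromast hair cells
  form a rosette, not a filled disk, and the band matches the
  fitted-ellipse assumption of the concentricity measure). Orientation
  models: `uniform` on $(-90, 90]$, `axial_bimodal` along a body axis, and
  `concentric` (local tangent plus axial von Mises noise). The default
  noise concentration `kappa = 4` gives a clearly-but-not-perfectly
  concentric field: about 0.97 power at $n = 30$, comfortably above
  chance but far from degenerate. Von Mises noise is sampled with the
  Best–Fisher rejection algorithm on doubled angles; `kappa` at or above
  the 1000 cap (or `Inf`) is the exact noiseless limit.
* **Pairs**: sister cells on a random axis, the first always pointing at
  the second (± Gaussian noise), the second opposing with probability
  `opposition_prob`, otherwise uniform — under the default criterion a
  non-opposed pair is still scored "opposed" half the time by chance, and
  tests account for that compound rate.
* **Label images**: filled ellipses at the cell positions with the cell's
  axial angle as major-axis orientation, drawn in the same y-up pixel
  convention the measurement uses, with retried jittered placement on
  overlap.
* **Profiles**: Gaussian angular peak on a constant baseline with additive
  i.i.d. Gaussian noise (matching the Monte Carlo error scheme).
* **Divisions**: daughter pairs at controlled angles off the local radius
  (`radial`, `tangential`, or `uniform` on $[0, 90]$).

Every generator takes a seed; one global seed expands into per-component
substreams so adding one generator call does not shift the draws of
another. What the generator does **not** emulate: optics (PSF, shot noise,
bleaching), segmentation errors, 3D structure, cell-cell contact geometry,
or developmental dynamics. Passing tests therefore demonstrate the
*estimators and tests* are correct and calibrated under their stated
assumptions — not that those assumptions hold in any particular imaging
dataset.

## Numerical choices and degenerate inputs

* Chi-square p-values come from the regularized upper incomplete gamma
  (`pchisq`); expected counts below 1 attach a validity warning rather
  than blocking the test.
* $\kappa = A_1^{-1}(\bar R)$ uses the Best–Fisher series start plus
  Newton refinement on the exponentially scaled Bessel ratio; it
  round-trips $A_1$ to $10^{-6}$ over $\kappa \in [0.1, 50]$.
* A point exactly at the ellipse center has no unique nearest boundary
  point; the major-axis vertex is returned with a `degenerate` flag.
* Near-circular fitted ellipses ($a/b < 1.05$) flag their rotation as
  ill-conditioned; tangent deviations remain well-defined.
* Duplicate coordinates in the nearest-neighbor analysis resolve to the
  lowest cell id; degenerate (zero-variance) t-tests return flagged
  results instead of errors.
* Fields with fewer than 5 cells are analysed but flagged `low_n`; both
  per-organ and pooled testing are possible by concatenating deviation
  columns before `bin_axial()`.

## Problem sizes used in verification

The test suite and the acceptance script verify, among other properties:
projection against a $10^6$-point brute-force scan on 1000 random
ellipse/point pairs; type-I error and power of the concentricity label
over 200 seeded 30-cell fields each; von Mises recovery at $n = 1000$;
exact-test agreement with enumeration for all axis tables with samples up
to 20; Monte Carlo error-bar coverage over 200 independent noisy profiles
(120-point grids); and label-image orientation round-trips at 1° RMS.
These sizes give binomial Monte Carlo bands tight enough to detect
miscalibration of a 1% test while keeping a full run in a couple of
minutes on one core.

## Known limitations

* The concentricity label conflates "non-uniform tangent deviations" with
  "concentric"; use `strict_mu` or inspect $\mu$ when radial organization
  is plausible.
* The PCA ellipse fit assumes roughly uniform-in-parameter sampling of a
  convex outline; strongly clustered cells bias the fitted axes (an
  algebraic direct least-squares conic fit would behave differently; the
  PCA fit is the method implemented here because it is the one the
  analysis pipeline defines).
* The Gaussian peak model is unwrapped; peaks wider than about 60° spill
  around the circle and bias $\sigma$ downward.
* Profile extraction approximates the contour normal by the radial
  direction from the centroid — exact for circles, slightly oblique for
  eccentric contours.
```{r session}
sessionInfo()
```
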