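---
title: "Spatial normalization of RPPA slides: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial normalization of RPPA slides: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rppanorm)
```

## The problem

A reverse-phase protein array (RPPA) slide carries thousands of printed
lysate spots probed with a single antibody; the scanned signal intensity of
each spot is the measurement. Because different regions of a slide are not
exposed identically to the detection reagents, identical samples printed in
different places yield systematically different intensities. This spatial
heterogeneity inflates the variance of replicates and can push otherwise
usable slides past quality cutoffs.

The key observation is that the standard slide design already contains a
survey of the bias: positive-control spots — technical replicates from one
batch of mixed-cell lysate — are printed at regular intervals across the
whole slide. In the absence of spatial effects, all positive controls of a
given dilution should read the same; their observed variation maps the bias.

## Measurement model

Let $I(x,y)$ be the measured intensity at slide position $(x,y)$ and
$I'(x,y)$ the true (bias-free) intensity. We model the spatial effect as a
multiplicative correction factor $CF(x,y)$:

$$I(x,y) = CF(x,y)\, I'(x,y), \qquad
  CF(x,y) = \frac{PCI^{*}(x,y)}{\langle PCI\rangle},$$

where $PCI^{*}(x,y)$ is the (pseudo-)positive-control intensity at $(x,y)$
and $\langle PCI\rangle$, the mean positive-control intensity over the
slide, serves as the reference. $CF > 1$ marks regions biased high, $CF <
1$ regions biased low, and correction is division:
$I'(x,y) = I(x,y)/CF(x,y)$.

Positive controls are only measured at their own positions, so $PCI^{*}$ at
sample positions is obtained by interpolation. Each of the 96
positive-control dilution sets contributes one *anchor*: by default the
set's median-intensity spot, the dilution most likely to fall in the linear
range of the assay (`select_anchors()`, policy `"median"`; a deterministic
`"fixed"` policy taking a chosen dilution step of every set is also
provided). For a query point between four anchors, the surface is the
standard bilinear blend — linear in each coordinate, exact at the anchors
and bounded by them. An alternative tensor-product cubic spline surface
(`method = "spline"`) is available; in practice it behaves very similarly,
and the simpler bilinear form is the default.

### Edge handling

In the default layout the control row sits at the bottom of each subgrid,
so roughly one subgrid-height band of the slide (and the columns flanking
the outermost control sets) lies outside the anchor rectangle — about
1/12th of the slide area. Spots there take the correction factor of the
nearest covered grid position (Euclidean distance in spot-index space, ties
broken toward smaller row then column). Interpolation is performed in spot
index space rather than physical millimetres: on a uniform print grid the
two are affinely equivalent, so bilinear results are identical.

### Numerical safeguards

* **Anchor lattice assembly.** Anchors are keyed by subgrid row and by the
  left-to-right order of control sets within the row, giving a regular
  12 × 8 lattice on the default layout. Each lattice line's coordinate is
  the mean position of its anchors, so the ±2-spot jitter of median-spot
  positions cannot break rectangularity.
* **Median of even-sized sets.** After removing invalid spots a set may
  hold an even number of values; the lower-median spot is used, so the
  anchor is always a real spot with a real position.
* **CF clamping.** Correction factors are clamped into `clamp_bounds`
  (default `(0.1, 10)`). Near-zero pseudo-PCI in a dead slide region would
  otherwise explode corrected intensities; clamp events are counted and
  reported.
* **Spline end conditions.** The spline surface uses the classic cubic
  spline with Forsythe–Malcolm–Moler end conditions (exact on cubic
  polynomials, which the test suite exploits as an oracle); lattices with
  fewer than 4 rows or columns fall back to bilinear with a warning.

## Quality metrics

`cv_percent()` is $100\,\sigma/\mu$ with the sample ($n-1$) standard
deviation — replicate counts are small, where the unbiased form matters.
`slide_cv()` resolves a replicate grouping map (sample → group, crossed
with dilution step so replicates are compared at matching dilution),
reports per-group %CV and their unweighted mean, and flags the slide
against a cutoff (default 15%, the conventional acceptance threshold).
`pearson()` measures agreement of duplicate slides spot-by-spot;
`z_prime()` (Zhang's $1 - 3(\sigma_p+\sigma_n)/|\mu_p-\mu_n|$) and
`welch_t()` quantify the separation of positive controls from buffer
spots. All are descriptive; no p-values are attached.

One caveat the package makes measurable
(`dilution_series_correlation()`): a correlation pooled across all
dilutions of a series is inflated by the intensity range the dilutions
span, so pooled $\rho$ between duplicate slides exceeds every
within-dilution $\rho$. Within-dilution agreement is the honest measure.

`control_dilution_cv()` supports the main validation device: the
normalizer consumes one spot per control set, so the *remaining* control
dilutions are held-out technical replicates, untouched by the fit, whose
%CV before vs after correction measures bias removal without circularity.

## The synthetic-slide simulator

Real slides offer no ground truth, so every claim above is validated on
simulated slides (`simulate_slide()`, `simulate_replicate_study()`,
`simulate_duplicate_pair()`) where truth is stored exactly:

$$\text{measured} = \text{truth} \times \text{bias}(x,y) \times
  e^{\varepsilon},\qquad \varepsilon\sim N(0,\sigma_{\log}).$$

Noise is multiplicative (lognormal) because RPPA signal generation is
proportional — the colorimetric signal scales with bound antibody — and
because multiplicative bias composes cleanly with the CF model. Bias
fields are normalized to unit mean over the slide so the simulated
$\langle PCI\rangle$ is an unbiased reference; they are applied to buffer
spots too, so Z′ comparisons see realistic negatives. Defaults were chosen
once as representative of a well-behaved slide: positive-control top
intensity 10000 units, sample tops lognormal (meanlog $\log 8000$, sdlog
0.5 — roughly two orders of magnitude of sample spread), buffer background
200 units, 5% measurement noise ($\sigma_{\log} = 0.05$), bias amplitude
±30%, and the default 132 × 44 layout with five serial half-dilutions.

Field kinds: `constant`, `linear_gradient`, `radial_gaussian`,
`low_freq_sinusoid` (one cycle per slide by default; phases drawn per
slide unless pinned), and `cellwise_bilinear`. The last one draws node
values on the slide's nominal anchor lattice and interpolates them
bilinearly — it lies exactly in the span of the bilinear normalizer, so
with zero noise correction must recover truth to machine precision; this
is the backbone of the exact-recovery tests. For that cancellation to be
exact the cellwise field is normalized to unit mean over its *nodes*
(the other, analytic fields are normalized over the whole slide; for the
cellwise field the slide mean is then close to, but not exactly, 1).

In `simulate_replicate_study()`, biological replicates of a condition
share a lognormal condition mean and scatter with a chosen CV
($\sigma_{\log,\mathrm{rep}} = \sqrt{\log(1+cv^2)}$); replicate sets are
printed in successive blocks so the replicates of one condition sit in
distant slide regions, as in real replicate designs — spatial bias then
acts between replicate positions, which is precisely what the correction
is supposed to remove.

### What the simulator does not model

Antibody cross-reactivity, signal saturation and dynamic-range ceilings,
spot morphology and segmentation error, carry-over between pins, and
slide-to-slide scale differences are all absent. Passing tests therefore
demonstrate that the estimator removes *smooth multiplicative spatial
bias* under realistic noise — not that it cures every pathology of real
slides. Sharp, discontinuous artefacts (scratches, dust) violate the
smoothness assumption and are better handled by spot flagging (the
`valid` flag is carried through the whole pipeline for this purpose).

## Validation summary

The test suite and `scripts/acceptance.R` recompute, at the problem sizes
named here, on one CPU in a few seconds:

* layout arithmetic of the default design (5808 spots, 48 subgrids of 121,
  1056 samples, 96 control sets / 480 spots, 48 buffer spots; anchors are
  under 2% of spots);
* the identity property (uniform controls ⇒ CF ≡ 1 to 1e-12) and scale
  invariance of CF;
* equivalence of the surface with a naive four-corner oracle on a
  3 × 3-anchor toy slide, and of edge handling with a brute-force
  nearest-point search on 50 seeded exterior queries;
* exact recovery of a cell-wise bilinear bias at zero noise (≤ 1e-9
  relative; held-out control %CV collapses to 0);
* stochastic improvement under a ±30% sinusoid bias with 5% noise:
  held-out control %CV falls after correction in ≥ 95 of 100 seeded
  slides, and duplicate-pair ρ and Z′ are non-decreasing in ≥ 90% of 50
  seeded pairs;
* definitional oracles for %CV, ρ, Z′ and Welch t to 1e-12, and the
  pooled-vs-per-dilution ρ inflation on simulated duplicate pairs.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 11, bias = bias_field("low_freq_sinusoid", 0.3))
study <- simulate_replicate_study(cfg, n_bio_replicates = 3,
                                  replicate_cv = 0.10)
norm <- normalize_slide(study$slide)

before <- slide_cv(study$slide, study$grouping)
after <- slide_cv(study$slide, study$grouping, values = norm$corrected)
c(before = before$mean_cv, after = after$mean_cv)
```

On this slide the raw mean biological %CV sits well above the simulated
10% dispersion because the bias field separates replicate positions;
after correction it returns to roughly the simulated dispersion plus the
5% measurement noise. The README shows the printed numbers.

## Known limitations

* The correction is within-slide only; between-slide scaling and loading
  normalization are out of scope, as is concentration estimation from
  dilution series (corrected tables are written so that standard
  dose-response fitting tools can consume them downstream).
* Bias varying faster than the anchor spacing (11 spots between control
  rows in the default design) is aliased, not corrected.
* Whether the original normalization practice anchored the median value
  at the median spot's own position or at a fixed per-set position is a
  design freedom; both are supported (`anchor_policy = "median"` /
  `"fixed"`), the median-spot position being the default.
* Model-based alternatives (row/column fixed effects, surface regression
  with shrinkage) are deliberately not implemented; the interpolation
  approach makes no assumption about sample-to-sample relationships.
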