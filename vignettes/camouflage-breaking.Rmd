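---
title: "Quantifying camouflage and how colour vision breaks it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying camouflage and how colour vision breaks it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camobreak)
```

## The problem

Cryptic prey are hard to find because their luminance and pattern resemble
the background against which they sit. Whether an observer with reduced
colour vision — a red-green dichromat — is better or worse at breaking that
camouflage is a long-standing question: dichromats lack the red-green
opponent channel, but the achromatic luminance channel thought to drive
pattern and spatial processing is untouched. `camobreak` implements a
complete analysis chain for visual-search experiments on this question:
photograph-level camouflage metrics, dichromat image rendering, cleaning of
search-game event logs, and BIC-simplified linear mixed models of log
capture time, together with synthetic generators that make the whole chain
testable end to end.

## Images, luminance and the dichromat rendering

All metrics operate on the luminance channel, defined as the average of the
red and green pixel values, `L = (R + G) / 2`. Pixel values are floating
point in `[0, 1]`; files are assumed to be linearized upstream (e.g.
white-balanced against a grey standard), and no gamma handling is applied.
The simulated dichromat rendering replaces R and G by their average and
leaves B untouched, producing a blue-yellow image. Because luminance is
itself `(R + G) / 2`, the rendering preserves the luminance channel exactly
(bit for bit in double precision), so every camouflage metric is identical
in the two viewing conditions — by design, since viewing condition must
manipulate colour information only.

Coordinates are 0-based with the pixel-centre convention (x rightward, y
downward). Target polygons are rasterized by the even-odd rule with
half-open containment, so an axis-aligned `k x k` box covers exactly `k^2`
pixel centres.

## Measurement regions

For each photograph, three regions are measured: the target polygon, a
"doughnut" annulus whose distance from the target edge lies in
`(15, 500]` px, and the whole background (everything farther than 15 px from
the target). The 15 px spacer keeps out-of-focus pixels straddling the
target edge out of both backgrounds. Distance from the target edge is exact
Euclidean distance to the nearest target pixel; "radius" suggests the
Euclidean metric, and the exact distance transform makes the masks testable
against brute-force evaluation. Annuli running off-frame are clipped at the
image bounds without compensation, as real near-edge targets would be.

## Camouflage metrics

**Granularity (pattern) analysis.** The luminance image is decomposed into
band-pass spatial-scale bands starting at 2 px and incrementing at
multiples of sqrt(2), capped at the size of the smallest target in a game:
15 bands to 256 px for the adult-target game, 13 bands to 128 px for the
egg game (a relative tolerance of 1e-6 at the cap keeps the nominal cap in
the schedule despite floating-point powers). The filter bank uses
hard-edged (ideal) annular masks in the Fourier amplitude domain with
boundaries at the geometric midpoints between scheduled sizes, so the bands
tile the spectrum exactly; this choice makes the filter analytically
predictable (a pure grating excites exactly one band) and is kept behind a
single function so a soft-edged bank could be swapped in for sensitivity
checks. Band *energy* is the population standard deviation of the filtered
image over the region's pixels, with non-region pixels filled with the
region mean before the transform so mask edges inject no spurious energy.
**Pattern difference** between target and background is the sum of absolute
band-energy differences.

**Luminance distribution difference** is the total-variation distance
between the target's and the background's luminance histograms on 100
fixed-width bins spanning `[0, 1]`: half the sum of absolute differences of
the two unit-mass histograms, hence bounded in `[0, 1]` with 0 for
identical and 1 for disjoint distributions. The fixed global bin range
keeps values comparable across photographs. Note the statistic is not
dilution-invariant: appending the same pixels to both patches shrinks it by
the ratio of old to new patch size, a direct consequence of the
total-variation definition.

**Patch contrast** is the population SD of luminance divided by its mean
(coefficient of variation), computed for target, annulus and whole
background. Population (not sample) SD is used throughout, in both contrast
and band energy.

## Synthetic scenes

No photograph deposit accompanies the original experiments, so the package
generates scenes with known ground truth. The background is isotropic
Gaussian noise with a `1/f^beta` *power* spectrum (`beta = 2` by default, a
standard natural-image surrogate; the exponent convention is power, not
amplitude), shaped by a log-Gaussian spectral weight of one octave width
centred on a dominant scale (16 px by default). The dominant scale matters:
a pure power law is scale-free, so multiplying a target texture's scale
would be statistically undetectable; the spectral bump is what gives
"pattern scale" meaning. The elliptical target carries independent
background-like texture with its dominant scale multiplied by
`target_pattern_scale_shift` and its luminance shifted by
`target_lum_offset`, alpha-blended over a 2 px feather at the ellipse edge.
Chromatic content is added symmetrically to R and G (and independently to
B), so per-pixel luminance equals the generated luminance plane exactly and
the dichromat transform changes the image visibly without touching any
metric. Scenes are bit-identical given the same spec.

`scene_pool()` builds a small photograph set whose luminance offsets,
pattern-scale shifts, target sizes, background luminances and contrasts all
vary (with coprime cycle lengths, so even two dozen scenes span the
covariate space). For these scene sizes the measurement radii are scaled
down (8 px spacer, a quarter of the image side for the outer radius) so the
"near" annulus remains a genuinely local surround; the full-size 15/500 px
protocol values remain the defaults of `build_regions()`.

What the generator does *not* emulate: real vegetation structure,
shadows and depth-of-field, specular highlights, display nonlinearity, and
observer-side chromatic adaptation. Passing tests therefore demonstrate
that the pipeline measures and recovers what it is defined to measure, not
that any particular field photograph set behaves this way.

## Simulated game sessions

Sessions follow the citizen-science protocol: 20 slides per session, the
target placed uniformly within the central 60% of the image (which
determines the edge distance, measured from the placed target centre to
the nearest image edge — the reference point is a package choice, as the
protocol does not define one), a 30-second limit per slide, and all clicks
recorded. The generative model is the statistical model run forward: latent
log capture time = linear predictor (viewing condition, log pattern
difference, luminance distribution difference, target area, background
luminance, slide number, first-slide flag, log edge distance, and the
viewing-condition interactions) + session random intercept + photograph
random intercept + Normal(0, `sd_resid`). Latent times above 30 s become
timeout records with no capture time, exactly the records the exclusion
rules must drop. Incorrect clicks are Poisson with spatially uniform
positions — the raw logs give no model for them, and only the ">2 incorrect
clicks" rule consumes them downstream. Timeout-heavy settings are reachable
by raising the intercept, which the censoring tests use.

Default coefficients encode the qualitative structure of the adult-target
experiment: a dichromat penalty of the order of a 15% slowdown, positive
viewing x pattern-difference and viewing x luminance-difference
interactions, negative viewing x area and viewing x background-luminance
interactions, a learning slope of -0.03 per slide, and session/photograph
random-intercept SDs of 0.25/0.15 with residual SD 0.5 on the log scale.
The published relative-risk effect sizes (about 23-36% in the highest
decile contrasts) set the order of magnitude; the latent coefficients
themselves were never published, so these values are the package's own
calibration and are not claimed to equal the originals.

All randomness flows from one master seed with per-session substreams
derived by counter, so studies are reproducible and the event stream does
not depend on session evaluation order.

## Cleaning rules and the analysis table

`filter_events()` applies the two exclusion rules — more than 2 incorrect
clicks on a slide ("scatter-gun" clicking), and timeouts (indistinguishable
from distraction, hence excluded rather than treated as censored; a
survival-analysis variant is deliberately out of scope) — and reports
counts per reason plus malformed rows, so retained + excluded always equals
input. `derive_covariates()` joins retained captures with photograph
metrics and applies the transforms: natural log of capture time, edge
distance and pattern difference. A pattern difference of zero has no
logarithm; the pipeline stops with an error rather than imputing an offset,
because any offset choice would silently change the covariate scale. The
first slide is flagged as categorically different (trial naivety),
separately from the participant-level played-before flag.

`choose_background_scope()` fits the same maximal model on the
near-annulus table and the whole-background table and keeps the scope with
the lower BIC, with exact ties resolving to "near".

## Model fitting and BIC simplification

Models are fitted with `lme4::lmer` behind `fit_lmm()`, which owns the
spec-to-formula construction, rank-deficiency checking (aliased columns are
named in the error), the BIC computed explicitly as
`-2 logLik + k log(n)`, and per-term Wald F statistics. Denominator
degrees of freedom use a conservative lower-bound convention: `n` minus the
number of fixed-effect parameters minus the number of random-effect
grouping factors. This is a stated convention, not a claim of equivalence
to any particular df approximation. Treatment coding uses trichromat and
the youngest age bracket as references. A constant response (every
variance component zero) is returned as an analytic degenerate fit rather
than tripping the solver.

`simplify_model()` runs the three-phase BIC procedure: backward
elimination of fixed effects under ML with the full allowed random
structure (interactions and the quadratic slide term drop before the main
effects they contain, preserving marginality); forward selection of random
intercepts under REML — ML for fixed-effect comparisons and REML for
random-structure comparisons is standard practice, and the forward phase
starts from the session intercept, which is mandatory because sessions are
the repeated-measures unit a final fit must respect; then a second backward
pass over the fixed effects under ML with the chosen random structure.
Candidate fits that fail or do not converge count as "not an improvement"
and are logged in the trace; fits with a variance component estimated at
zero are accepted and simply lose the BIC comparison. BIC ties (difference
below 1e-6) resolve toward the smaller model. Every evaluated candidate is
recorded in the selection trace with the BIC before and after and an
accepted flag, so the final spec can be replayed.

## Recovery harness and problem sizes

`recovery_study()` simulates replicate studies in which exactly one
viewing interaction is active (viewing x log pattern difference, with
target contrast carrying the null interaction), runs the full
filter-derive-simplify chain per replicate, and reports retention of the
true term, drop of the null term, and whether the estimate falls within 3
standard errors of truth. The active coefficient (0.3) is set well above
its sampling error at the default study size of 250 sessions x 20 slides =
5,000 slides, mirroring the very large samples behind the original
interaction estimates. `sign_recovery_study()` checks the qualitative
pattern instead: with the default generative signs (+, +, -, -) for the
four viewing interactions, the fitted signs should match in at least 90%
of replicates.

The packaged test suite and the acceptance script run these at 16-24
replicates of 250 sessions on a 24-scene pool of 160 px images with a
48 px granularity cap — sizes chosen so a full run completes comfortably on
a single CPU while keeping every estimate far from its decision boundary.
Larger studies only sharpen the same conclusions (the consistency test
verifies the error shrinks as sessions grow).

## Known limitations

* The original toolbox's exact band-pass filter shape is not published;
  the ideal annular bank is a documented substitution behind a swappable
  interface, and absolute pattern-difference values will differ from other
  filter choices even though orderings are stable.
* Whether the upstream pattern-difference definition normalizes by total
  energy is unspecified; the unnormalized sum is implemented.
* The luminance-histogram statistic is one of several "overlap" measures;
  total variation was chosen for its `[0, 1]` bounds and exact
  testability.
* Edge distance uses the target centroid; protocols measuring from the
  target boundary would shift that covariate by roughly the target radius.
* The simulators invert the analysis model; they do not model saccade-level
  search behaviour, fatigue, or display differences beyond what the session
  random intercept absorbs.
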