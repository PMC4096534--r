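---
title: "Measuring colony growth kinetics on high-density arrays"
author: "ColonyKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring colony growth kinetics on high-density arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ColonyKinetics)
```

# The measurement problem

Genome-wide phenotype screens grow thousands of microbial colonies on
high-density arrayed agar plates (384 or 1536 positions) and ask which
strains grow abnormally. The standard readout — colony area at one fixed
incubation time — discards the kinetics of growth and is badly confounded
by the *neighbor effect*: colonies surrounded by eight neighbors compete
for nutrients and grow visibly less than colonies at the plate border with
five. ColonyKinetics implements a time-lapse alternative: plates are
scanned with transmitted light every 30 minutes over 20 hours, each colony
is quantified as *integrated pixel absorbance*, the resulting series is
fitted to a Gompertz model, and the fitted curve is summarized into three
growth characters plus the conventional endpoint:

* **LTG** (lag time of growth): where the tangent at the curve's
  inflection crosses zero, $(\ln(1/b) + 1)/\ln c$;
* **MGR** (maximum growth rate): the slope at the inflection,
  $-a \ln c / e$;
* **SPG** (saturation point of growth): the asymptote $a$;
* **CONV**: colony area at the 20 h scan (the conventional method's
  value).

The model is $G(t) = a\,e^{-b c^t}$ with $a > 0$, $b > 0$, $0 < c < 1$.
The two closed forms above are what the package reports; both are verified
in the test suite against independent geometric constructions (a
finite-difference maximum-slope search and an explicit tangent-intercept
construction).

## Whole-colony mass and center mass (mass*)

For a colony region $R$ with surrounding-agar mean intensity $I_{agar}$,

$$m = \sum_{i \in R} \max\left(0, -\log_{10} \frac{I_i}{I_{agar}}\right).$$

Because colonies grow fastest at their periphery — exactly the part that
approaches the neighbors — the package also integrates the same absorbance
over a fixed disc of 17 pixels (about 1 mm) at the colony center,
**mass\***. Peripheral growth is excluded, so mass\* is far less sensitive
to crowding. The 17-pixel default is the empirical colony diameter at the
onset of detectable crowding differences (about 2.5 h of incubation); for
other media, organisms or scanner resolutions it should be re-estimated,
and both the disc diameter and the CONV reference time are plain
parameters.

# Image analysis

Each scan passes through:

1. **Lighting correction** — a quadratic polynomial surface is fitted to
   non-colony pixels (colonies masked by an Otsu threshold) and divided
   out, normalized to mean 1. The synthetic generator's vignette is
   quadratic by construction, so on simulated data the correction is exact
   up to noise; on real scanners a low-order surface is an approximation.
2. **Otsu binarization and grid detection** — connected colony components
   are labeled, their centroids are fitted per axis to an affine lattice,
   and all `nRows x nCols` centers are predicted from the fit. Missing
   colonies are therefore filled in from the lattice; if fewer than half
   the expected components are found, or the centroids do not sit on a
   regular lattice (axis-fit residual above a quarter pitch), detection
   fails loudly rather than guessing.
3. **Region extraction** — each position owns a pitch-by-pitch cell
   window. Background statistics come from the window's outer 15% border
   band after excluding colony-like pixels (below the band median minus
   4 robust SDs). A pixel belongs to the colony when its intensity falls
   below `agarMean - 10 * agarSd`, one-sided, because transmitted-light
   colonies are darker than agar. The background SD carries a relative
   floor of `1e-9 * agarMean` so that strictly noiseless synthetic images
   do not threshold their own floating-point jitter.
4. **Quantification** — mass as above; negative per-pixel absorbances are
   clipped to zero so that noise cannot cancel true mass; zero intensities
   are floored at the smallest positive double and logged via a warning.
   The mass\* disc is centered on the absorbance-weighted centroid
   (lattice center for empty regions) and a pixel is inside the disc when
   its center is within `diameter/2` (inclusive) of the colony center —
   at an integer center the widest disc row spans exactly 17 pixels.

The exact Otsu threshold is computed over the observed intensity levels
(no histogram binning), which makes it translation-equivariant and lets
the tests compare it against an exhaustive search. For megapixel scans the
*internal* masking threshold is computed from a deterministic 50k-pixel
subsample; the exported `otsuThreshold()` is always exact.

# Growth analysis

Raw series are preprocessed exactly as the measurement method prescribes:
values are floored at 1 (the lower quantification limit), divided by the
series minimum, and the first 25 valid points whose normalized value
strictly exceeds 1 enter the regression. Fewer than five qualifying points
is reported as "insufficient growth" rather than fitted. Whether points
exactly equal to 1 after normalization count as growth is genuinely
ambiguous; the package requires a strict excess, which also makes the
selection idempotent on its own output.

The fit is Levenberg–Marquardt least squares with analytic gradients,
parameterized as $(\log a, \log b, \mathrm{logit}\, c)$ so every converged
fit satisfies the parameter constraints by construction, keeping the
spirit of an unconstrained `nls` call. Starting values: $a_0$ is 1.05
times the maximum; $b_0, c_0$ come from the linearization
$\log(-\log(y/a_0)) = \log b + t \log c$. Convergence uses relative
tolerances of $10^{-12}$ with at most 200 iterations; constant or
too-short series return `converged = FALSE` instead of raising, matching
the observation that regression fails only for absent or extremely poor
growth.

# Normalization

Growth-value tables are normalized per metric, multiplicatively, and with
medians throughout (robust to defective-mutant outliers), in this fixed
order:

1. *plate–plate*: each plate is rescaled so its median equals the grand
   median of plate medians;
2. *row/column*: each value is divided by its row median relative to the
   plate median, medians are recomputed, then the same per column;
3. *spatial*: each value is divided by its 7x7 local median relative to
   the plate median.

The neighbor-effect and batch normalization steps of the conventional
recipe are deliberately absent — the center-mass metric replaces the
former, and flat-file desk runs have no batch structure. Each step is
scale-equivariant; the window of 7 (about the colony-block scale) is a
configuration entry. Lag times are time-like rather than scale-like, so a
multiplicative treatment of LTG is a modeling choice; it is used uniformly
because all growth values here are positive and ratio-compared, and it
keeps the three steps identical across metrics. Local-median smoothing
leaves edge and corner cells slightly over- or under-corrected (the
window is clipped there); on production-size grids this residual is well
under the 2% the pipeline targets.

# Correcting the rate dependence of lag and yield

Measured lag and yield depend on the growth rate itself. Two classical
relationships model this: population lag at high inoculum,
$\lambda(\mu) = \ln(1 + \mu\tau)/\mu$ (with $\tau$ the mean individual
lag; the $\mu \to 0$ limit is $\tau$, computed by series expansion), and
the maintenance-energy yield model
$Y(\mu) = \mu / (\mu/Y_G + m)$. Both are fitted to the (MGR, LTG) and
(MGR, SPG) clouds by **least trimmed squares**, because screens contain
many genuine outliers — the very mutants being screened for. The fitted
expectation is then *subtracted*, so corrected values are excess lag in
hours and excess yield in growth units.

The nonlinear LTS is implemented as concentration steps (fit on a subset,
re-select the $h$ best residuals, repeat) from the full-data start plus 50
random elemental starts, deterministic given a seed. The objective — the
sum of the $h$ smallest squared residuals — is checked in the tests
against exhaustive enumeration over all size-$h$ subsets at $n = 12$. The
default trim fraction is 0.75, which protects against just under 25%
contamination; evaluations that inject 30% gross outliers run the fit at
trim 0.5 (the maximal-breakdown setting), since $h \le n_{clean}$ is a
mathematical requirement for breakdown, not a tuning choice. No additive
offset is fitted in either model: the pure one- and two-parameter forms
are used, so the correction cannot absorb genuine strain effects into an
intercept.

# Screening

Strains are selected by the **rank product**: within each replicate,
strains are ranked (ties averaged; missing replicates skipped with the
per-strain replicate count adjusted), and the statistic is the geometric
mean of rank ratios. Significance comes from permutations that reassign
each replicate's observed rank values among its present strains — this
preserves missingness and tie structure exactly. `p` is the
plus-one-corrected pooled tail fraction; the FDR estimate is the
*percentage of false positives* (expected null statistics at or below the
observed one, divided by the strain's rank position), the estimator native
to the rank-product method. Selection requires both `p < 0.01` and
`pfp < 0.01` by default, one-sided in the defect direction (low MGR, high
corrected LTG, low corrected SPG), and the three selections are
intersected into the kinetic defect groups. Reproducibility metrics are
the one-way-ANOVA ICC (with an F-distribution confidence interval, mean
group size for unbalanced designs) and the percent coefficient of
variation.

# The synthetic-data generator

Every quantitative claim the package makes is tested against simulations
with known truth, so the generator is first-class code:

* **Kinetics**: per-colony Gompertz parameters; defaults $a = 600$
  (absorbance-pixel units, 5% lognormal colony scatter), $b = 5.6$,
  $c = 0.65$, giving lag ~1.7 h, inflection ~4 h and saturation well
  before 20 h — colonies pinned from a dense overnight culture.
* **Optics**: a colony is a radially decreasing quadratic absorbance cap
  whose height grows with its radius (mass scales as radius cubed —
  colonies thicken as they widen). The cap is chosen for its closed-form
  integral, and each rendered dome is rescaled so its discrete pixel sum
  equals the recorded true mass exactly. With the default geometry a
  colony reaches the 17-px onset diameter at ~2.1 h holding ~10% of its
  final mass, so most growth is exposed to crowding, as observed. Images
  are agar background times a quadratic vignette, times $10^{-A}$, plus
  truncated Gaussian noise; intensities are arbitrary linear units in
  [0, 1] (scanner bit depth is not modeled) and all randomness derives
  from one seed via fixed substreams, so stacks are bit-reproducible and
  rendering a subset of scans reproduces the full stack's frames.
* **Neighbor effect**: phenomenological and discrete — once a colony
  exceeds the onset diameter, each per-scan growth increment is divided by
  $1 + s \sum_{\text{neighbors}} m$ over neighbors within 1.6 pitches
  (the 8-cell neighborhood). $s = 0$ reproduces independent growth
  exactly. The study strength $s = 10^{-3}$ was set so the simulated
  crowded-vs-uncrowded gap in final mass is plainly visible (~15%), the
  magnitude class reported for real dense arrays.
* **Screen tables**: strain baselines follow the lag and yield models (so
  LTG and SPG are genuinely MGR-dependent), with multiplicative strain
  defects, plate/row/column/smooth-spatial biases, and 5% replicate
  noise. For FDR calibration against truth labels the baseline
  strain-to-strain variation is set to zero, because otherwise the
  slowest baseline strains are *reproducibly* slow and the screen rightly
  flags them — a property of real collections, not an error.

What the generator does **not** emulate: colony morphology changes (domes
are always radially symmetric caps, so morphology mutants are invisible
here), reflected-light imaging, nutrient-diffusion physics or quorum
signaling (the neighbor model is phenomenological), scanner-light growth
effects, and batch structure across runs. Passing tests therefore show the
*computational chain* is correct and that the center-mass metric defeats
the modeled crowding mechanism; they cannot show that real colonies obey
the dome or suppression models.

# Study sizes

The simulation studies are sized for a desk machine: neighbor-effect
evaluations use 12x16 arrays at the production pixel pitch (40 px), one
wild-type plate plus four shuffled-array plates, each scanned 41 times;
grid detection is exercised on a full 1536-position plate; screen
calibration uses 1000 strains with 7 replicates and 1000 permutations;
parameter-recovery studies use 100 noise seeds. Genome-wide screens of a
real knockout collection (tens of thousands of colonies over multiple
scanners) are out of scope for these runs, and the headline counts of such
screens are not reproduced here.

# Limitations

* The dome and suppression models are convenient idealizations; the
  crowding comparisons are qualitative reproductions, not calibrated
  predictions.
* Multiplicative normalization of LTG is a pragmatic uniform choice (see
  above).
* The pfp estimator is one member of the FDR family; with very few
  replicates it is conservative near the top ranks.
* Morphology-aberrant colonies are measured as if they were domes; such
  strains need a separate morphology readout.

# A minimal end-to-end run

```{r pipeline, eval = FALSE}
cfg <- list(nRows = 8L, nCols = 8L, nReplicates = 3L, nPerm = 500L,
            effects = list(slowMGR = list(fraction = 0.1, factor = 0.8)),
            seed = 11L)
manifest <- runPipeline(cfg, "runs/demo")
screen <- readGrowthTable("runs/demo/screen.tsv")
head(screen[order(screen$p), ])
```

The run directory contains one TSV per stage (layout, truth, observations,
phenotypes, normalized, corrected, screen), the resolved configuration,
and a JSON manifest with the stage file lists and the configuration hash;
re-running with the same configuration reproduces every table
byte-for-byte.
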