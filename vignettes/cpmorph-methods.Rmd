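---
title: "Methods: skeleton-based morphometrics and allometric regression in cpmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skeleton-based morphometrics and allometric regression in cpmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmorph)
```

`cpmorph` quantifies the 3D morphology of insect olfactory receptor neurons
segmented from volume electron microscopy. This vignette documents the
methods in enough detail to judge them: the coordinate conventions, the
axial-profiling and peak-calling procedures, the hierarchical regression and
its sampler, the numerical choices made where the field's descriptions leave
freedom, and what the synthetic validation geometry does and does not show
about real data.

## Skeletons and projection

A skeleton is an ordered polyline in micrometres, usually read from SWC
(`read_swc`); pixel coordinates are scaled per axis at load time (for
serial block-face EM a typical scale is 5 nm in x/y and a 40 nm z-step).
Branched skeletons keep their full node table, but all arc-length
operations use a single unbranched *profiling path*: the longest
root-to-leaf chain by arc length. Axons and dendrite center-lines in this
domain are essentially unbranched, so the choice only discards incidental
skeletonisation spurs.

Orthogonal projection (`project_point`) clamps the foot of the
perpendicular to each segment and takes the global minimum; exact ties
resolve to the lowest segment index so results are order-stable. Basal
extrapolation — needed when a soma lies below the cuticle base — extends
the *first* segment backward along its own direction, and only backward;
the distal end is never extrapolated. On the extrapolated ray, positions
are signed arc lengths along the ray, so a normalised position of −1 is one
full path length behind the start. For curved center-lines this "arc length
along the ray" convention is one of two defensible readings (the other
being chord length to the base); it is the one the package uses and
reports.

## Axial cross-sectional-area profiles

A segmented structure enters as the set of its value-1 voxels with an
anisotropic voxel size. Voxels are treated as their *centers* (half-index
convention); volume is exactly `count × voxel volume`. Every voxel center
is projected to a normalised position t ∈ [0, 1] along the skeleton,
positions are histogrammed into half-open bins of width 0.001 (t = 1 joins
the last bin), the x axis is rescaled by the physical length L, and the
curve is rescaled so its rectangle-rule integral equals the structure
volume. The bin value is then the local cross-sectional area in µm²: for a
cylinder of radius r the interior bins recover πr², and the integral
identity `Σ area × bin_µm = volume` holds to machine precision by
construction (it is asserted at 10⁻⁶ relative in the tests).

Smoothing uses a discrete Gaussian kernel truncated at 4σ with *reflective*
boundary padding. Reflection makes the convolution mass-conserving: mass
that would leak past an end is folded back, so the volume identity survives
smoothing (asserted at 10⁻³ relative; in practice the error is at rounding
level). The smoothing σ is **not** dictated by the field's published
descriptions; the package default is σ = 5 bins (0.5% of the normalised
length, i.e. 0.25 µm on a 50 µm axon). That choice suppresses single-bin
voxelisation noise while leaving 1 µm-scale varicosities essentially
unattenuated; it is exposed as a parameter and recorded in output metadata,
as is the boundary mode.

One numerical caveat worth knowing: on perfectly grid-aligned synthetic
cylinders the 0.001 histogram can alias against the voxel pitch (slices
landing in every k-th bin), producing a low-frequency ripple in the raw
curve. Real segmented material, and any smoothed curve at the default σ,
does not show this at meaningful amplitude; the package's analytic tests
choose bin widths commensurate with the voxel pitch so that assertions are
sharp rather than loose.

## Varicosities, connectors, occupancy

Varicosities are local maxima of the smoothed curve whose topographic
prominence (height above the higher of the two flanking minima, bases found
by the standard extend-until-higher rule) reaches 30% of the curve's
reference maximum. "Maximum excluding outliers" is made precise as the
99.5th percentile of the smoothed curve — robust to isolated spikes and
equal to the true maximum on smooth curves; both the fraction and the
quantile are parameters. Varicosity length is the full width of the peak at
half height. The package's default convention is width at
`peak − prominence/2` (half *relative* height, matching the prominence
machinery); an absolute half-maximum variant is available via
`height = "half_max"`. Crossings are linearly interpolated between bins,
and widths are searched within the peak's prominence bases.

Connectors are the exact complement of the varicosity intervals in
[0, L], including the two terminal stretches, each summarised by its mean
smoothed area. Treating terminal stretches as connectors keeps the tiling
identity — varicosity plus connector intervals partition the axon with
zero overlap — which downstream summaries rely on and tests assert
exactly.

Mitochondrial occupancy divides the smoothed mitochondrial curve
elementwise by the smoothed axonal curve on the same bin grid; bins where
the axon area is below a floor (10⁻⁶ µm² by default) report 0 and are
flagged rather than producing unstable ratios. For mitochondria
geometrically nested inside the axon the ratio cannot meaningfully exceed
1; discretisation allows a few percent of slack, and the tests bound it at
1.05. Mitochondrion instances are assigned to compartments by projecting
each instance's center of mass and testing membership in the varicosity
FWHM intervals. Center-of-mass membership (rather than an overlap
fraction) and the FWHM interval (rather than a wider basin) are the
package's choices where the field's descriptions are silent; both are
deliberate, and the center-of-mass rule is the one the tests validate
against brute-force membership.

## Soma depth and cuticle encapsulation

The cuticle proportion C of a soma is the normalised position of its
center of mass projected onto the cuticle center-line (0 = base, 1 = tip).
If the nearest location is the base endpoint itself, the projection is
repeated with basal extrapolation, giving C < 0. Depth below the base is
then **D = −C × L** with L the cuticle length; D > 0 classifies the soma as
below the base, D = 0 at the base, and D < 0 above it — the last typically
indicating a laterally placed soma, which is why above-base somata keep
their un-extrapolated projection rather than being forced onto the axis.

Encapsulation projects the cuticle base point onto the outer-dendrite
skeleton and reads off the normalised position with 0 at the dendrite tip
and 1 at the ciliary constriction: the fraction of sensory dendrite length
enclosed by the cuticle. Because nothing in an SWC file marks which end of
a dendrite skeleton is the tip, the orientation is *required metadata*
(`dendrite_orientation`), never guessed; omitting it is an error. For an
on-axis base point the encapsulated fraction and the fraction of dendrite
below the base sum exactly to 1, a property the tests exercise.

## The hierarchical allometric regression

The model relates y = log₁₀ inner-dendrite volume to x = log₁₀
outer-dendrite surface area across four groups g (species × neuron type):

- y_i ~ Normal(α_g(i) + β_g(i) x_i, σ_obs), σ_obs ~ half-Cauchy(0, 15)
- α_g = α_overall + σ_intercept z_g, α_overall ~ Normal(0, 20),
  σ_intercept ~ half-Cauchy(0, 10), z_g ~ Normal(0, 1)
- β_g = β_overall + δ_s(g) + γ_g, β_overall ~ Normal(1.5, 10),
  δ_s ~ Normal(0, σ_δ), σ_δ ~ half-Cauchy(0, 50)
- γ_g ~ Normal(0, σ_γ), σ_γ ~ half-Cauchy(0, 10)
- constraint β_g ≥ 0 for every group.

All Normal scale arguments are standard deviations. The prior on the
overall slope is centred at 3/2 because volume scales with the cube and
surface area with the square of linear size. The γ_g hyperprior is the
package's own completion of the hierarchy (the within-species deviation
needs a scale; a half-Cauchy(0, 10) mirrors the treatment of δ_s and is
weakly informative at the scale of plausible slopes). The nonnegativity
constraint is read as applying to the *assembled group slopes* and is
enforced by rejection — states with any β_g < 0 get zero posterior
density; a variant that truncates only β_overall is available
(`constraint = "overall"`). The reduced model omits δ_s entirely.

### Sampler

Posteriors are drawn by a componentwise adaptive random-walk
Metropolis-within-Gibbs sampler written in C++ (Rcpp). Scale parameters are
sampled on the log scale with the Jacobian included; group intercepts use
the noncentered parameterisation by default (a centered variant exists and
is checked for agreement in the tests). Step sizes adapt per coordinate
toward 0.44 acceptance in batches of 50 during warm-up with diminishing
adaptation, then freeze.

Plain componentwise walks mix notoriously slowly along the two structural
pathologies of such hierarchies: likelihood-invariant translations (e.g.
raising α_overall while lowering every z_g) and scale funnels (σ and its
deviations). The sampler therefore adds structured *interweaving moves*,
each a deterministic map x′ = T(x, ε) with symmetric ε accepted with the
posterior ratio times the map's Jacobian: translations trading α_overall
against z_g, β_overall against γ_g, β_overall against δ_s, and δ_s against
its species' γ_g; and joint scale moves multiplying the deviations while
shifting the corresponding log-scale (Jacobian e^(−kε)). These cost one
posterior evaluation each and remove the slow directions.

MCMC defaults follow the conventional four chains with a 1,000-draw warm-up
and 2,000 retained draws per chain. Because a random-walk sampler has a
longer autocorrelation time per iteration than a gradient-based one, each
retained draw corresponds to `thin = 5` raw iterations (and warm-up is
scaled the same way); with the interweaving moves this yields split-R̂
typically at or below ~1.02 on the package's simulation benchmarks. The fit
*reports* split-R̂ for every raw parameter plus per-coordinate acceptance
rates, and warns — never silently — when any split-R̂ exceeds 1.01.
Divergence counts, a Hamiltonian-sampler diagnostic, have no analogue here;
acceptance rates and R̂ fill that role. Chain seeds derive
deterministically from the user seed, so fits are reproducible.

Convergence checking against an independent implementation is part of the
test suite: the same hierarchy (without the slope constraint, on data whose
slopes keep the constraint inactive) is fitted with JAGS and the posterior
means compared.

### Model comparison

The pointwise log-likelihood matrix is stored with every fit, and
leave-one-out expected log predictive density is computed by Pareto-smoothed
importance sampling: per observation, the largest importance ratios (the
smaller of 20% of draws and 3√draws) are replaced by quantiles of a
generalised Pareto distribution fitted to their tail with the Zhang–Stephens
profile posterior-mean estimator (shape regularised toward 0.5 at small
tail sizes), truncated at the raw maximum. The Pareto shape k is reported
per observation; values above ~0.7 flag unreliable smoothing, exactly the
regime where the package's brute-force leave-one-out oracle (refit n times)
is used in tests to bound the error. `loo_compare_fits` reports
elpd_full − elpd_reduced with a standard error from the pointwise
differences; comparing a fit with itself gives exactly zero.

On small hierarchical datasets every left-out observation is influential
and PSIS is expected to be rough (large k); the test suite therefore
validates PSIS against brute-force refits on a single-group n = 8 dataset,
where importance sampling operates in its intended regime, and validates
model *selection* (full vs reduced) across 20 replicate simulations with a
strong species gap.

## Statistical comparisons

Within-sensillum comparisons gate on normality: Shapiro–Wilk on the
*paired differences* (the quantity the t test assumes normal — the gated
vector is a documented choice) at α = 0.05 selects the paired t test, else
the Wilcoxon signed-rank test. Zero differences use the Pratt convention —
zeros participate in ranking |d| and their ranks are then discarded — with
a tie-corrected normal approximation; zero-free small samples use the exact
signed-rank distribution. An all-zero difference vector is reported as
degenerate with p = 1 rather than an error. Across-type comparisons use
Kruskal–Wallis with tie correction; two-sample comparisons use the
two-sided Mann–Whitney U (exact for small tie-free samples). Morphometric
ratio summaries divide each sensillum's measurements by its reference
neuron (column "C" by default) before averaging, and round to one decimal
only in the display string. No multiple-testing correction is applied, by
design.

## Synthetic geometry: what it emulates, and what it does not

`make_axon` builds a straight axon whose radius is a thin baseline plus
Gaussian bumps, r(s) = r₀ + Σ aᵢ exp(−(s−cᵢ)²/2σᵢ²), voxelised as a solid
of revolution by the voxel-center-in-solid test. Defaults emulate the scale
of the real material: a 50 µm axon bearing ten varicosities spaced 5 µm
apart (density 0.2 per µm), connector radius 0.15 µm, varicosity peak
radius 0.65 µm, and an isotropic 40 nm voxel pitch matching a typical SBEM
z-step while keeping volumes desk-sized (~2 × 10⁵ voxels). The analytic
truth (∫πr² ds by quadrature, bump centers, radius-profile FWHM intervals)
rides along; bump layouts that merge (closer than ~2.5σ) are flagged.
`make_mitochondria` nests coaxial capsules at a stated fraction of the
local axon radius, so occupancy has the closed-form value fraction² inside
capsules. `make_sensillum` builds straight cuticle and dendrite
center-lines with exact C, D and encapsulation truth, and
`simulate_allometry` forward-samples the regression's own generative model.

What passing these tests shows: the projection, binning, rescaling,
smoothing, peak-calling, ratio and regression machinery is numerically
correct and recovers known truth through the *entire* pipeline. What it
does not show: robustness to properties only real material has — curved
and kinked axons, skeletonisation error, segmentation noise at the
membrane, lamellar (sheet-like) dendrite geometry, anisotropic voxel
artefacts of section alignment, non-Gaussian varicosity shapes, or
mitochondria that wander off-axis. Results on real volumes inherit those
caveats, and the smoothing σ and prominence threshold may need re-tuning
for noisier profiles.

## Test problem sizes

The suite fixes its own scales: voxelised structures of roughly 10⁵–10⁶
voxels (spheres at 20 nm pitch, axons at 10–40 nm), 1,000-bin profiles,
200–1,000-point projection oracles against a path resampled at 10⁻⁴ of its
length, 50-replicate interval-coverage simulations at n = 20 per group,
20-replicate model-recovery simulations at n = 25 per group (two chains,
1,000 retained draws each), and 500-replicate null-calibration runs for
the rank tests. These sizes make every check sharp at conventional
tolerances while the whole suite stays in the minutes range on one core.

## Known limitations

- Skeletons are inputs; the package does not skeletonise rasters, and
  profiling quality inherits skeleton quality.
- The profiling path is a single chain; structures that genuinely branch
  are profiled along their longest chain only.
- Surface areas are not estimated from rasters (voxel-count volumetry
  only); mesh-based area extraction is out of scope.
- PSIS-LOO is unreliable when most Pareto k exceed ~0.7 (tiny hierarchical
  datasets); use the reported diagnostics, or brute-force refits, there.
- The Metropolis sampler trades per-iteration efficiency for having no
  gradient requirement; for much larger datasets a Hamiltonian backend
  would be preferable.
- The Normal(1.5, 10) slope prior is effectively truncated by the β_g ≥ 0
  constraint; with data this weakly informative prior is dominated, but in
  the no-data limit the implied prior mean of a constrained slope sits
  slightly above its unconstrained centre. This is inherent to the stated
  constraint and documented rather than "corrected".
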