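# cpmorph

Morphometric analysis of insect olfactory receptor neurons (ORNs) segmented
from volume electron microscopy, built around the capitate-peg (cp)
sensillum of the mosquito maxillary palp — the sensillum housing the
CO₂-sensing cpA neuron and its odor-sensing cpB/cpC neighbours.

Volume-EM studies of these neurons reduce segmented 3D structures to a small
set of quantitative descriptors: axial cross-sectional-area profiles of
axons ("pearls-on-a-string" varicosities and the thin connectors between
them), mitochondrial occupancy along the axon, the depth of each soma below
the sensillum cuticle base, the proportion of the sensory outer dendrite
encapsulated by the cuticle, and an allometric scaling law relating
inner-dendrite volume to outer-dendrite surface area across species and
neuron types. `cpmorph` implements that entire quantitative pipeline as
reusable, tested R functions, together with synthetic-geometry generators
that carry exact analytic ground truth — so every stage can be validated
end-to-end without downloading a multi-gigabyte EM volume.

## What the package computes

**Skeleton geometry** (`read_swc`, `path_length`, `project_point`):
SWC center-line skeletons in µm, Pythagorean arc length, orthogonal
projection of points onto the path with optional backward (basal)
extrapolation of the first segment.

**Axial profiling** (`project_cloud`, `area_profile`, `smooth_profile`):
a binarised structure (MRC or multi-page TIFF mask, or an in-memory
`voxel_cloud`) becomes a cross-sectional-area curve A(s) along its skeleton:
every voxel center is projected to a normalised position t ∈ [0, 1], the
positions are histogrammed (bin width 0.001), the x axis is rescaled by the
physical length L and the y axis so that ∫A(s)ds equals the structure volume
(voxel count × voxel volume), then the curve is smoothed with a 1D Gaussian
(σ = 5 bins by default, reflective boundaries — the integral is preserved).

**Varicosity calling** (`detect_varicosities`, `define_connectors`,
`varicosity_density`, `occupancy`, `assign_mitochondria`): local maxima of
the smoothed curve with topographic prominence ≥ 30% of the
outlier-excluded curve maximum (99.5th percentile) are varicosities;
varicosity length is the full width at half maximum (at
peak − prominence/2, linearly interpolated). Complement intervals are
connectors, tiling [0, L] exactly. Mitochondrial occupancy is the
elementwise ratio of the smoothed mitochondrial to axonal curves;
mitochondrion instances are assigned to varicosities or connectors by their
projected center of mass.

**Position metrics** (`cuticle_proportion`, `soma_depth`,
`encapsulated_proportion`): the soma center of mass is projected onto the
cuticle center-line to give the cuticle proportion C (0 = base, 1 = tip,
negative on the extrapolated basal segment); depth below the base is
**D = −C × L**. The cuticle base projected onto the outer-dendrite skeleton
gives the encapsulated fraction (0 at the dendrite tip, 1 at the ciliary
constriction).

**Allometric regression** (`allometry_fit` and methods,
`species_slope_difference`, `loo_elpd`, `loo_compare_fits`): a hierarchical
Bayesian regression of y = log₁₀ inner-dendrite volume on x = log₁₀
outer-dendrite surface area over the four species × neuron-type groups,

y_i ~ N(α_g(i) + β_g(i) x_i, σ_obs),  α_g = α_overall + σ_intercept z_g,
β_g = β_overall + δ_s(g) + γ_g,  β_g ≥ 0,

with weakly informative priors (β_overall centred at 3/2, the
volume-to-surface scaling exponent; half-Cauchy scales) and a noncentered
intercept parameterisation. A reduced variant omits the species slope
deviation δ_s; the two models are compared by PSIS-LOO expected log
predictive density. Sampling uses a componentwise adaptive
Metropolis-within-Gibbs sampler (compiled via Rcpp) with structured
interweaving moves for the hierarchical directions; split-R̂, acceptance
rates and Pareto-k diagnostics are reported.

**Group statistics** (`paired_compare`, `rank_group_compare`,
`two_sample_rank`, `ratio_summary`): Shapiro–Wilk-gated choice between the
paired t test and the Wilcoxon signed-rank test (Pratt zero handling),
Kruskal–Wallis across neuron types, the Mann–Whitney rank-sum test, and
within-sensillum morphometric ratios relative to the smallest neuron
("5.0:1.2:1"-style summaries).

**Synthetic data** (`make_axon`, `make_mitochondria`, `make_sensillum`,
`simulate_allometry`, `make_sphere`): pearls-on-a-string axons (Gaussian
radial bumps over a thin baseline, voxelised as solids of revolution),
coaxial capsule mitochondria, sensillum geometry bundles, and allometry
datasets forward-sampled from the generative model — each with
machine-readable analytic truth attached.

## Worked example

A 50 µm synthetic axon with ten varicosities spaced 5 µm apart
(peak radius 0.5 µm over a 0.15 µm baseline), voxelised at 40 nm:

```r
library(cpmorph)

ax <- make_axon()                    # defaults match the geometry above
pf <- profile_structure(ax$cloud, ax$skeleton)
calls <- detect_varicosities(pf)
head(as.data.frame(calls)[, c("center_um", "fwhm_um", "prominence_um2")], 3)
#>   center_um   fwhm_um prominence_um2
#> 1     2.525 0.9657619      0.9904817
#> 2     7.525 0.9701868      0.9862389
#> 3    12.525 0.9701027      0.9861238
varicosity_density(calls, path_length(ax$skeleton))
#> [1] 0.2
```

All ten varicosities are recovered at their true centers (2.5, 7.5, … µm,
to within one 0.05 µm bin), giving the expected density of 0.2 per µm.
Coaxial mitochondria at 0.837 × the local axon radius produce a peak
occupancy of 0.837² ≈ 0.70:

```r
mt <- make_mitochondria(ax$truth, occupancy_radius_frac = 0.837)
occ <- occupancy(profile_structure(merge_clouds(mt$clouds), ax$skeleton), pf)
round(max(occ$occupancy), 2)
#> [1] 0.7
```

Position metrics from the bundled example geometry (a 12.98 µm cuticle with
the soma center of mass on the extrapolated basal axis):

```r
geom <- read_sensillum_json(system.file("extdata", "example_sensillum.json",
                                        package = "cpmorph"))
position_metrics(geom)
#>         C     D_um classification encapsulated_proportion
#> 1 -0.4607 5.979886     below_base                    0.82
```

The soma sits 5.98 µm below the cuticle base and 82% of the outer dendrite
is encapsulated. Fitting the allometric model to a simulated dataset with a
true species slope gap of 0.6:

```r
df <- simulate_allometry(n_per_group = 20, seed = 1, delta = c(0, 0.6))
fit <- allometry_fit(df, seed = 1)
fit
#> Hierarchical allometric regression (full model)
#>   80 observations, 4 groups; 4 chains x 2000 draws
#>   posterior mean group slopes:
#>     beta[Aedes.CO2] = 1.425
#>     beta[Aedes.odor] = 1.518
#>     beta[Drosophila.CO2] = 2.082
#>     beta[Drosophila.odor] = 2.028
#>   max split-Rhat 1.018; mean acceptance 0.44
d <- species_slope_difference(fit)
sprintf("%.2f [%.2f, %.2f], Pr(>0) = %.2f",
        d$mean, d$interval[1], d$interval[2], d$prob_positive)
#> [1] "0.58 [0.51, 0.66], Pr(>0) = 1.00"
loo_compare_fits(fit, allometry_fit(df, model = "reduced", seed = 1))
#> elpd (full) 48.65 | elpd (reduced) 48.88 | diff -0.22 (se 0.60)
```

The species slope gap is recovered (0.58 against a truth of 0.6). Note that
on a single dataset of this size the LOO difference between the full and
reduced models is small relative to its standard error — the reduced model
can absorb much of a species gap through its group-level slope deviations —
so model preference is only resolved reliably across replicates or with
stronger gaps.

A thin command-line wrapper (`inst/cli/cpmorph`) exposes the same pipeline
as subcommands (`simulate`, `profile`, `varicosity`, `occupancy`,
`position`, `allometry-fit`, `allometry-compare`, `stats`); every run
writes a `manifest.json` recording all effective parameters, and identical
invocations produce byte-identical outputs.

## Vignette

`vignettes/cpmorph-methods.Rmd` describes the model and the numerical
choices (binning, smoothing, peak conventions, sampler design, PSIS-LOO),
what the synthetic generators do and do not emulate, and the package's
known limitations.
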