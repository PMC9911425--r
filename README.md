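# dynshape

Spatiotemporal statistical shape modeling (SSM) of dynamic anatomies in R.

Many clinical questions are about how anatomical *shape changes over time* —
an organ moving through its cycle, or a structure evolving across
longitudinal visits. Correspondence-based SSM represents each surface in a
cohort by M landmark particles ("point distribution model", PDM) whose
indices mean the same anatomical location on every shape. Classic
entropy-based particle optimization assumes every shape is an independent
sample, which is wrong for N subjects × T time points: it ignores
within-subject correlation and washes out trajectories.

`dynshape` optimizes particles with the entropy objective

> Q = α·H(Z) − Σₙₜ H(Xₙₜ)

(shape-space compactness vs. per-shape uniform spread, particles constrained
to surfaces), and models the time dependency inside the optimization by
**regularized principal-component polynomial regression**: PCA of the
shape-space samples z = Uq + μ, a degree-(T−1) polynomial h(t) fit to the
scores with an elastic-net penalty

> Σₖ ‖qₖ − h(tₖ)‖² + r₁ Σₚ‖βₚ‖₁ + r₂ Σₚ‖βₚ‖₂²,

(r₁, r₂ chosen by subject-stratified 5-fold cross validation), and particle
updates driven by the residuals from g(t) = U·h(t) + μ. This captures
non-linear dynamics, encodes spatial regularity through the population
modes, and tolerates missing time points. Three baselines are included for
comparison: cross-sectional, disentangled (per-time and per-subject
entropies), and per-coordinate linear regression.

The package also ships the synthetic dynamic-ellipsoid benchmark (subject
x-diameter ~ Normal(0.6, 0.4/3), shared sinusoidal y-diameter
0.6 + 0.4·sin(2πt/T), z fixed at 1) and the evaluation protocol: PCA modes
of variation, subject-wise sinusoidal regression (SSE, pooled R²), a
repeated-measures ANOVA-type time-dependency test, and mesh descriptors
(volume, surface area, sphericity).

## Worked example

```r
library(dynshape)

# 1. a small dynamic cohort: 10 subjects x 8 time points of ellipsoids
cohort <- generate_cohort(ellipsoid_cohort_spec(n_subjects = 10, rng_seed = 5))

# 2. optimize 32 corresponding particles per shape with the
#    pc-polynomial method (coarse-to-fine init, then alternating fits)
cfg <- optimizer_config(target_particles = 32, iterations = 600, rng_seed = 7)
res <- optimize_spatiotemporal(cohort, method = "pc_polynomial", config = cfg)

# 3. does the PDM capture the known sinusoidal dynamics?
gof <- sine_goodness_of_fit(res$system)
round(gof$r2, 4)
#> [1] 0.9863

# 4. population structure: two generative factors -> two dominant modes
Z <- as_shape_matrix(res$system)
vf <- sapply(pca_modes(Z)$modes, `[[`, "variance_fraction")
round(sum(vf[1:2]), 4)
#> [1] 0.9987

# 5. statistically significant time dependency (and none after shuffling)
time_dependency_test(res$system, n_coords = 50, rng_seed = 3)$p_value
#> [1] 2.41e-09
time_dependency_test(shuffle_times(res$system, 3), n_coords = 50,
                     rng_seed = 3)$p_value
#> [1] 0.14
```

(Per-iteration objective values are kept in the optimization trace,
`res$trace`. The full 128-particle benchmark configuration reaches
R² ≈ 0.995–0.999.)

Interpretation: R² ≈ 1 means each particle coordinate's trajectory over a
subject's sequence is explained by a single sinusoid — the PDM kept
correspondence *through time*, not just across subjects. The two leading
PCA modes carrying ~100% of variance match the two generative factors of
the benchmark (subject x-diameter, temporal y-diameter). The
repeated-measures test rejects "no difference in mean particle positions
across time" for the fitted PDM but not for a time-shuffled control.

A command-line pipeline wraps the same steps:

```sh
Rscript -e 'quit(status = dynshape::cli_main())' generate-ellipsoids --seed 7 --out cohort/
Rscript -e 'quit(status = dynshape::cli_main())' optimize \
    --manifest cohort/manifest.csv --method pc-polynomial --out pdm/
Rscript -e 'quit(status = dynshape::cli_main())' evaluate \
    --manifest cohort/manifest.csv --particles-dir pdm/particles --out eval/
```

Mesh-backed cohorts are read from a manifest CSV pointing at ASCII PLY/VTK
triangle meshes (pre-aligned; no Procrustes step is applied).

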