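# homokappa

Meta-analytic homotopic connectivity (MHC) from coordinate-based
neuroimaging data, with the comparison machinery to hold it against
resting-state voxel-mirrored homotopic connectivity (VMHC).

## The problem

Homotopic connectivity — the functional coupling between mirror regions of
the two hemispheres — is usually measured from resting-state fMRI as the
Fisher-z-transformed Pearson correlation between each voxel's time series
and its mirror voxel's (VMHC). `homokappa` estimates the same construct
from a *corpus of published activation foci* instead: it asks how often
mirror-region pairs co-activate across experiments, which captures
homotopic coupling under task rather than rest. It is aimed at
coordinate-based meta-analysts who want a homotopic-connectivity map out
of a foci database, and at anyone comparing task co-activation structure
with resting-state connectivity.

## The estimator

1. **Modeled activation.** Around every focus of an experiment an
   isotropic 3-D Gaussian kernel is placed,
   `g(d) = V_vox · exp(-d²/2σ²) / ((2π)^{3/2} σ³)` with
   `σ = FWHM/√(8 ln 2)`, truncated at 5σ; foci combine by probabilistic
   union `MA = 1 − Π(1 − g)`. Contributions crossing the midline are
   attenuated inside a 24-mm midline band (offset adjustment).
2. **Activation matrix.** Experiment × region entries are 1 when ≥ 20 %
   (configurable; 0 % means "any voxel") of the region's voxels carry
   positive modeled activation.
3. **Patel's κ** per homotopic pair, from the joint state probabilities
   θ₁..θ₄ = P(both), P(left only), P(right only), P(neither):

   ```
   κ = (θ₁ − E) / [ D·(max(θ₁) − E) + (1 − D)·(E − min(θ₁)) ]
   E = (θ₁+θ₂)(θ₁+θ₃)      max(θ₁) = min(θ₁+θ₂, θ₁+θ₃)
   D = 1{θ₁ ≥ E}            min(θ₁) = max(0, 2θ₁+θ₂+θ₃−1)
   ```

   κ ∈ [−1, 1]: 1 = maximal attainable co-activation, 0 = independence.
   Significance is the Dirichlet(counts + 1) posterior probability that
   κ > e, by seeded Monte Carlo.
4. **Comparison arm.** `vmhc()` computes the mirrored-correlation core on
   preprocessed 4-D data; `compare_maps()` yields the global map
   correlation, a leave-one-voxel-out contribution map (VCC, exact
   sufficient-statistic downdating), and the z-standardised difference
   map (MHC − VMHC).

Everything downstream of raw data is seeded and reproducible, and every
stage has a synthetic generator with known ground truth
(`gen_synthetic_atlas()`, `gen_coactivation_experiments()`,
`gen_rest_timeseries()`).

## Worked example

Simulate a 4-pair symmetric atlas and 1000 experiments whose pairs range
from strong co-activation to active avoidance, then run the full
estimator:

```r
library(homokappa)

grid  <- symmetric_grid(c(16, 16, 28), 4)          # 4-mm mirror-closed grid
atlas <- gen_synthetic_atlas(grid, n_pairs = 4, radius = 6, spacing = 36)
theta <- rbind(c(0.45, 0.05, 0.05, 0.45),          # true kappa  0.800
               c(0.30, 0.10, 0.10, 0.50),          #             0.583
               c(0.16, 0.24, 0.24, 0.36),          #             0 (independence)
               c(0.05, 0.30, 0.30, 0.35))          #            -0.592
foci <- gen_coactivation_experiments(
  atlas, coactivation_spec(theta, 1000, seed = 7))

fit <- mhc(foci, atlas, kernel = kernel_spec(8), seed = 7)
tidy(fit)[, c("pair_id", "left_name", "kappa",
              "posterior_prob_exceeds", "significant")]
#> # A tibble: 4 × 5
#>   pair_id left_name   kappa posterior_prob_exceeds significant
#>     <int> <chr>       <dbl>                  <dbl> <lgl>
#> 1       1 L1         0.807                  1      TRUE
#> 2       2 L2         0.606                  1      TRUE
#> 3       3 L3        -0.0794                 0.0522 FALSE
#> 4       4 L4        -0.619                  0      FALSE
```

The estimates track the generating κ (0.800, 0.583, 0, −0.592): the two
genuinely co-activating pairs are recovered and declared significant
(posterior probability 1 that κ > 0), the independent pair sits near 0,
and the avoidance pair is strongly negative. Comparing against a VMHC map
computed from simulated rest data with matching planted structure:

```r
rho <- array(0, grid$dims)
for (p in 1:4)
  rho[atlas$labels %in% c(p, 4 + p)] <- c(0.6, 0.45, 0.2, 0.05)[p]
ser <- gen_rest_timeseries(grid, rest_spec(225, rho = rho, seed = 7))
cmp <- compare_maps(mhc_map(fit), vmhc(ser), mask = atlas$labels > 0)
glance(cmp)
#> # A tibble: 1 × 2
#>   r_global n_voxels
#>      <dbl>    <int>
#> 1    0.940      112
```

The two maps correlate at r = 0.94 over the 112 in-atlas voxels;
`cmp$vcc` and `cmp$difference` localise which voxels drive convergence
and which technique dominates where. `autoplot()` methods render the
kappa table, voxel maps and the VCC-vs-difference scatter.

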