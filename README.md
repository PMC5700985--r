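# sofiquant

Quantitative molecular density mapping and cluster analysis for
super-resolution optical fluctuation imaging (SOFI).

Membrane proteins form nanoscale clusters that ordinary TIRF microscopy
cannot resolve and that threshold-based cluster analyses quantify only as
well as their hand-picked parameters allow. `sofiquant` turns a raw TIRF
image sequence of stochastically blinking fluorophores into a
super-resolved map of molecular density and quantifies high-density
regions (HDRs) across the *whole* range of density thresholds, with the
operating threshold chosen automatically from the behavior of a random
molecule distribution — no user-tuned cutoff. A full stochastic simulator
of blinking fluorophores (Markov on/off photokinetics, Gaussian PSF,
Poisson photoelectrons, EMCCD gain and read noise) with known ground truth
validates the pipeline.

## The method in brief

For pixel traces $X_i(t)$, zero-time-lag cross-cumulants of orders
$n = 2,3,4$ are computed block-wise (500-frame blocks, averaged) on an
$n$-fold finer virtual grid: distinct camera pixels whose centroid falls
on a grid node are combined and corrected by the Gaussian distance factor
$\exp(-\sum_i |r_i - c|^2/2\sigma^2)$. With a 105 nm camera pitch the
4th-order density map has a 26.25 nm pitch (52.5 nm Nyquist limit).

A population of emitters with brightness $\varepsilon$ and on-time ratio
$\rho$ satisfies $g_n = N \mu_n \varepsilon^n \kappa_n(\rho)$, so the
ratios $K_1 = \mu_2 g_3 / (\mu_3 g_2)$ and $K_2 = \mu_2 g_4 / (\mu_4 g_2)$
invert in closed form,

$$\varepsilon = \sqrt{3K_1^2 - 2K_2},\qquad
\rho = \frac{3K_1^2 - K_1\sqrt{3K_1^2 - 2K_2} - 2K_2}{2(3K_1^2 - 2K_2)},
\qquad
N(r) = \frac{g_2(r)/\mu_2}{\varepsilon^2 \rho(1-\rho)},$$

giving molecular density per pixel area. Background is masked with the
linearized (brightness-linear) 2nd-order bSOFI image. HDRs are the
8-connected components above a relative density threshold; the sweep
records count, area, equivalent diameter ($2\sqrt{A/\pi}$) and occupied
ROI fraction per threshold, and the automatic threshold is the point
where a Gaussian fitted to a random distribution's region-count curve
falls below one region, $t^\ast = m + s\sqrt{2\ln A}$.

## Worked example

```r
library(sofiquant)

# a 5000-frame TIRF sequence of 10 ground-truth HDRs (180 nm,
# 3000 molecules/um^2, contrast 100) on a 3 x 3 um field
sim <- simulate_scenario(diameter_nm = 180, hdr_density_per_um2 = 3000,
                         contrast = 100, seed = 1)
sim$gt
#> <sofi_ground_truth> 1020 molecules, 10 HDRs on 3 x 3 um, background 30 /um^2

res <- analyze_sequence(sim$seq, psf_sigma_nm = 130)
res
#> <sofi_analysis> grid pitch 26.25 nm (Nyquist 52.5 nm), delta_avg 0.003728 /px
#>   selected threshold 39 x delta_avg: 1 HDR(s), relative area 6.96e-05
```

`analyze_sequence()` chains drift correction (optional), cumulants,
density inversion, masking and the threshold sweep; the printout shows the
26.25 nm grid and the 52.5 nm Nyquist limit that follow from the 105 nm
camera pitch. For strongly clustered samples the threshold should be
calibrated on a matched random control, which is what the validation
protocol does:

```r
hdr_recovery_experiment(seeds = 1:3)
#>   seed threshold n_regions n_true control_n_at_threshold
#> 1    1       5.1        11     10                      6
#> 2    2       6.1         9     10                      4
#> 3    3       5.5        10     10                      8
```

Per replicate: the control-calibrated threshold (in multiples of the mean
density), the number of HDRs segmented in the clustered sample at that
threshold, the ground-truth count, and the random-control count at the
same threshold. The clustered samples recover the ten planted HDRs to
within one region; the control column shows how many random clumps survive
at the same threshold.

Command-line entry points (thin wrappers over the same functions) live in
`inst/cli/`:

```sh
Rscript inst/cli/sofi-simulate.R --out sims/ --diameter-nm 180 --density 3000 --contrast 100 --seed 1
Rscript inst/cli/sofi-analyze.R  --stack sims/run001_stack.tif --config config.yaml --out results/ --no-drift
```

`sofi-analyze` writes `sweep.csv`, `regions.csv`, `summary.json`,
`density_map.tif`, `bsofi.tif` and a run manifest.

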