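# ssfseSim

Simulation and reconstruction toolkit for **compressed-sensing accelerated
single-shot fast spin-echo (SSFSE) MRI**, aimed at people studying or
teaching accelerated T2-weighted abdominal acquisition: it reproduces, at
desk scale, the full chain from protocol arithmetic through k-space
simulation to iterative reconstruction and the reader-study statistics such
protocols are evaluated by.

Single-shot FSE collects every phase-encode line of a slice in one echo
train, trading motion robustness for T2 decay along the train (blurring,
signal loss). Accelerating the train with variable-density undersampling and
recovering the image by sparsity-regularized inversion shortens the train,
the repetition time and the breath-hold. The reconstruction at the core of
the package solves

    I_hat = argmin_I  1/2 || A I - D ||_2^2  +  lambda || W I ||_1

with `D` the acquired multi-coil k-space, `W` an orthonormal multilevel Haar
wavelet transform, and `A` the system operator (coil-sensitivity maps
estimated from a 24-line calibration scan, unitary Fourier transform,
phase-encode masking), minimized by proximal-gradient iteration (ISTA, or
FISTA with function-value restart). Alongside it sit the conventional
baselines — homodyne partial-Fourier synthesis (6/8 coverage) and the
coil-combined zero-filled adjoint on uniform (parallel-imaging geometry)
masks — plus quantitative image metrics (NRMSE, PSNR, SSIM, organ-boundary
sharpness) and the five-point ordinal rating workflow (descriptive
statistics, insufficiency rates, exact/approximate Wilcoxon signed-rank
tests with Bonferroni adjustment).

## Worked example

Protocol arithmetic and the sampling pattern of the accelerated protocol:

```r
library(ssfseSim)

pr <- protocolPreset("skyra_ssfse_cs")
pr
#> ProtocolParams [ssfse_cs]: matrix 384 x 253, R = 3, PF = 1, ACS = 24
#>   TR/TE = 500/99 ms, esp = 3 ms, FA = 118 deg, 32 slices (inc 4)
echoTrainLength(pr)
#> [1] 84
buildVDMask(253L, 84L, seed = 1)
#> SamplingMask [variable_density]: 84 of 253 lines (R_eff = 3.01), 24 ACS
```

The echo-train length is the single-shot budget `floor(253 / 3) = 84`; the
variable-density mask spends 24 of those 84 lines on a fully sampled center
block and reaches an effective acceleration of 3.0.

A complete seeded experiment — one phantom, four acquisition arms (full,
partial-Fourier, uniform, variable-density plus calibration scan), each
reconstructed with its matched method and scored against ground truth:

```r
res <- runExperiment(defaultRunConfig(seed = 1, outputDir = "run1"))
res$metrics[, c("method", "nrmse", "psnr_db", "ssim")]
#>                method nrmse psnr_db  ssim
#> 1        full_adjoint 0.183    28.9 0.490
#> 2         pf_homodyne 0.165    29.8 0.485
#> 3      pf_zero_filled 0.226    27.1 0.444
#> 4 uniform_zero_filled 0.494    20.3 0.370
#> 5      vd_zero_filled 0.224    27.2 0.791
#> 6               vd_cs 0.156    30.3 0.850
```

Reading the table: the CS arm (`vd_cs`) recovers the 3-fold undersampled
data better than the zero-filled adjoint of the same data (`vd_zero_filled`,
NRMSE 0.156 vs 0.224) and better than either conventional baseline; homodyne
beats plain zero-filling of the same partial-Fourier data (0.165 vs 0.226);
uniform undersampling without kernel interpolation aliases badly (0.494);
and even the fully sampled arm carries T2-decay blur (0.183) because its
128-echo train decays along the way. Images, masks, the solver's objective
trace and this metrics table are written under `run1/`.

The ratings workflow on synthetic consensus scores (101 cases, latent
quality 3.5 / 3.4 / 4.4 for conventional SSFSE / multishot TSE / CS-SSFSE,
reader noise 0.7):

```r
rt <- simulateRatings(101, c(ssfse_conv = 3.5, mtse = 3.4, ssfse_cs = 4.4),
                      readerSd = 0.7, seed = 7)
compareSequences(rt, "overall")
#>                  pair statistic n_effective  p_value p_bonferroni significant
#> 1     ssfse_conv-mtse      2442          68 6.05e-01     1.00e+00       FALSE
#> 2 ssfse_conv-ssfse_cs       860          74 1.10e-07     3.30e-07        TRUE
#> 3       mtse-ssfse_cs       510          66 7.59e-10     2.28e-09        TRUE
```

A one-category latent advantage is detected decisively in both CS
comparisons at the 0.025 threshold, while the near-equal conventional pair
is not.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/ssfsesim.R protocol --preset skyra_ssfse_cs
Rscript inst/cli/ssfsesim.R demo --seed 1 --out run1
Rscript inst/cli/ssfsesim.R ratings --csv scores.csv --criterion overall
```

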