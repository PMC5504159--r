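# nusrelax

Joint non-uniform sampling and one-step Fourier–Laplace reconstruction
of protein NMR relaxation experiments.

## The problem

Measuring <sup>15</sup>N longitudinal relaxation rates (R<sub>1</sub>)
of a protein backbone normally means recording a full series of 2D
HSQC spectra — one per relaxation delay — and fitting an exponential to
every peak's intensity across the series.  That costs hours of
spectrometer time, and classical NUS of the indirect dimension alone
cannot reduce it much, because each 2D plane still needs 50–70 samples
to be recoverable.

`nusrelax` implements the joint alternative: the two-dimensional space
of (t<sub>1</sub>, t<sub>relax</sub>) is undersampled *as a whole*
(e.g. 256 of 10240 cells, 2.5%), and the data are inverted in one step
through the combined dictionary **P** = **F** ⊗ **L** — inverse
Fourier synthesis in t<sub>1</sub> times an exponential Laplace kernel
in t<sub>relax</sub> — by solving the sparse recovery problem

```
min_Q  || P Q − q ||₂²  +  τ || Q ||₁
```

with FISTA and complex soft thresholding, independently for every
direct-dimension column.  The reconstruction is a pseudo-3D spectrum
whose third axis is the decay rate: each peak's R is read off as the
center of a Gaussian fitted along the rate axis — no exponential curve
fitting.  The package also provides the conventional fully-sampled
baseline (FT + mono-exponential fits) and cross-method correlation
reports, plus a synthetic protein-like data generator used throughout
the tests.

Intended users: NMR spectroscopists and methods developers who want to
prototype, validate or teach joint-NUS relaxometry without spectrometer
data.

## Worked example

```r
library(nusrelax)

## a small end-to-end scenario: 4 peaks, 2 per direct column,
## 96 of 2560 joint cells sampled (3.75%)
sc <- scenario(name = "mini",
               geometry = acquisition_geometry(n_t1 = 32, sw_indirect = 800,
                                               trelax_min = 0.01, trelax_max = 0.8,
                                               trelax_mesh = 0.01,
                                               n_f1_recon = 64, n_r_recon = 64,
                                               r_min = 0.5, r_max = 5),
               n_peaks = 4, snr = 100, seed = 5, n_schedule = 96,
               config = solver_config(tau = 0.002, n_iter = 3000))
rep <- run_scenario(sc)
print(rep)
#> Scenario 'mini': 4 peaks, SNR 100, 96-point schedule, seed 5
#>   noise sigma (median amplitude / SNR): 0.01762
#>   joint vs truth r^2:      0.99813
#>   joint vs baseline r^2:   0.99992
#>   peaks within one rate bin (0.07143 1/s) of truth: 2 / 4
```

The run takes a few seconds.  `rep$rates_joint` holds the per-peak
Gaussian read-off estimates,
`rep$rates_baseline` the mono-exponential fits of the fully sampled
series, and the two r² lines above are their squared Pearson
correlations against the simulated truth and against each other — the
figure of merit for the method.  "Within one rate bin" counts peaks
whose read-off rate lands within one rate-grid spacing of the
simulated truth.

The reference protein-scale conditions (128-point t<sub>1</sub> grid,
3000 Hz, delays 0.01–0.8 s on a 0.01 s mesh, 256-point joint schedule,
rate band 0.5–5 s⁻¹) are packaged as `reference_scenario()`.

A thin command-line driver is installed as `exec/nusrelax` with
subcommands `simulate`, `schedule`, `reconstruct`, `baseline`, `sweep`
and `compare`, all driven by a flat key–value scenario file
(`write_scenario()` / `read_scenario()`).

## Package layout

- `R/geometry.R`, `R/peaks.R`, `R/simulate.R` — domain types and the
  synthetic generator
- `R/schedule.R` — joint NUS schedules (generation, nested
  subsampling, nuslist-style files)
- `R/operator.R` — the sampled Fourier–Laplace operator (separable and
  FFT-based actions, dense assembly for verification)
- `R/solver.R` — FISTA with complex soft thresholding, restart and
  continuation
- `R/pipeline.R` — cube reconstruction, conventional baseline,
  sampling-level sweep
- `R/analysis.R` — Gaussian rate read-off, mono-exponential fitting,
  rate correlation
- `R/scenario.R` — scenario container, reference scenario, end-to-end
  runner
- `vignettes/joint-ft-ilt.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations)
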