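# drsfit

Diffuse reflectance spectroscopy (DRS) modelling and inversion for optical
breach detection during pedicle-screw placement.

During spinal-fusion surgery, a probe advancing through a vertebra must not
breach the cortical shell. A fiber-optic K-wire with two optical fibers
(1.042 mm apart) measures broadband diffuse reflectance (450–1600 nm) of the
tissue ahead of the tip. Because marrow-rich cancellous bone is fatty while
cortical bone is almost fat-free, the **fat fraction**

```
FF [%] = Fat / (Fat + Water) × 100
```

drops sharply as the probe approaches the cortical wall — an intraoperative
breach-warning signal. `drsfit` implements the full analysis chain:

* **Forward model** — linear chromophore mixing (HbO2, Hb, fat, water) plus
  power-law reduced scattering `µs'(λ) = a (λ/800)^(−b)`, propagated through
  the steady-state diffusion-approximation dipole solution
  `R(ρ)` at the fiber separation (extrapolated boundary, `A ≈ 3.25` for
  tissue refractive index 1.4).
* **Inverse fit** — bounded Levenberg–Marquardt least squares with analytic
  Jacobians and multistart; recovers hemoglobin concentrations (g/l), fat
  and water volume fractions and the scattering parameters, and derives
  **blood content** (% of 150 g/l whole blood) and **fat fraction** with
  delta-method 95% confidence intervals from the residual-variance
  covariance `σ² (JᵀJ)⁻¹`.
* **Synthetic experiment generator** — ground-truthed in-silico replicas of
  vertebral insertions (cancellous / pre-cortical / cortical / breach
  zones), three probe-handling conditions (low pressure, high pressure,
  retracted with blood-pool mixing), and the 70-minute post-sacrifice
  perfusion decay.
* **Breach pipeline** — zone labelling from probe depth, per-zone
  median/min/max summaries, fat-fraction drop detection with retraction
  disambiguation, and 1200 nm spectral normalization.
* **Statistics** — Jarque–Bera normality, exact/approximate Wilcoxon
  rank-sum, OLS R², and confidence-interval range summaries (α = 0.01).

The packaged chromophore absorption tables are synthetic parametric
reconstructions of the canonical literature band shapes (see
`inst/extdata/chromophores/provenance.yaml`); simulation and inversion share
them, so recovery results demonstrate the internal consistency of the
chain. Real instrument data would substitute measured calibration curves.

## Worked example

```r
library(drsfit)

chrom <- load_chromophores()
inst  <- instrument_config()        # 1.042 mm fibers, 1 nm grids, 1% noise
model <- zone_model()

# simulate one noisy measurement of cancellous bone and invert it
truth <- zone_median_composition("cancellous", model)
spec  <- add_instrument_noise(forward_reflectance(truth, inst, chrom),
                              inst, seed = 7)
fit   <- fit_spectrum(spec, inst, chrom)
fit
#> <drs_fit> converged (11 iterations, relative residuals)
#>   blood content 28.9% (ci95 0.01), fat fraction 25.7% (ci95 1.81)
#>   fat 20.4%, water 58.9%, mu_s'(800) 15.88 cm^-1, slope 1.00
#>   residual norm 0.333 on 1151 points
```

The generating truth was blood 28.9%, fat fraction 26.4%, `µs'(800)`
15.9 cm⁻¹: the fit recovers all three, and the fat-fraction 95% half-width
(±1.8 pp) sits in the low single-digit range expected at 1% instrument
noise.

A full in-silico experiment — simulate six insertions, fit all 270 spectra,
summarize zones, run the condition contrasts and extract breach calls:

```r
report <- run_pipeline(run_config(seed = 1))
report
#> <drs_report>
#>   270 measurements, 6 insertions, seed 1
#>   zone medians (fat fraction %):
#>     cancellous   21.6 [  4.4,  48.0] (n=90)
#>     pcz           4.1 [  0.0,  17.0] (n=60)
#>     cortical      0.0 [  0.0,   7.1] (n=60)
#>     breach       10.2 [  1.9,  14.7] (n=60)
#>   fat-fraction CI half-width range: [1.17, 6.92] pp
```

(Pooled zone medians sit below the low-pressure configuration because the
retracted condition dilutes fat fraction; conditioning on low pressure
recovers the configured 26.4 / 5.3 / 0 / 11.2% medians.) A thin CLI wrapper
over the same functions lives in `inst/cli/drsfit.R`
(`simulate` / `fit` / `run` subcommands).

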