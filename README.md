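# scrlti

Forward and inverse modelling of the mapping from sudomotor nerve (SN)
activity to skin conductance responses (SCR) under linear time-invariant
(LTI) assumptions — for psychophysiologists and methodologists who build
or validate model-based electrodermal analyses.

Model-based SCR analysis treats the peripheral effector system (nerve
terminals, transmitter diffusion, sweat glands) as an LTI system, fully
described by one impulse response — the skin conductance response function
(SCRF). `scrlti` implements that model and an end-to-end testing
framework around it:

* **SN bursts** as Gaussians
  `u(t) = A/(sqrt(2*pi)*sigma) * exp(-(t-mu)^2/(2*sigma^2)) + c`,
  with area `A`, latency `mu`, dispersion `sigma` (~0.3 s) and baseline
  `c`.
* **The SCRF** as a third-order linear ODE,
  `x''' + theta1*x'' + theta2*x' + theta3*x + g*u(t - theta4) = 0`,
  simulated by a fast fixed-step RK4 (C++), with a convolution pathway
  (`scrf_predict()`) that agrees with the ODE solution to better than
  1e-3 relative L2.
* **Estimation**: Nelder–Mead burst fits, bounded multi-start profiled
  least squares for the SCRF (optionally through an observation model of
  the recording chain), slope-only or affine gain regression, explained
  variance, variance partitioning across canonical / subject-level /
  epoch-level response functions, reference-SCRF comparison and
  gain-trend regression.
* **Preprocessing**: causal Butterworth band-pass, equiripple FIR nerve
  band-pass, z-scoring, rectified leaky integration, decimation,
  piecewise detrending, epoch extraction, minimum correction, averaging,
  clipping detection.
* **A synthetic-data generator** that emulates an intraneural *recording*
  experiment (sparse sensory events, nerve + conductance channels, with
  non-sudomotor interference) and an intraneural *stimulation* experiment
  (constant-rate epochs recorded through an AC-coupled derivative device),
  including a gain-depletion nonlinearity that breaks time invariance
  above ~0.6 Hz stimulation.

## Worked example

Generate a stimulation-style dataset — two subjects, each with one
~0.1 Hz and one ~1.5 Hz constant-rate epoch of 12 stimulations, gain
depletion enabled — then fit the response function per epoch and compare
it with the generating impulse response:

```r
library(scrlti)

cfg <- synth_config("exp2",
                    rates_by_subject = list(s01 = c(0.1, 1.5),
                                            s02 = c(0.1, 1.5)),
                    events_per_epoch = 12, seed = 42)
ds <- generate_dataset(cfg)
ds
#> <scr_dataset> style=exp2 subjects=2 events=48 seed=42

ref <- scrf_impulse_response(canonical_params()$theta$low_rate, duration = 30)
report <- run_exp2_pipeline(ds, pipeline_config(n_starts = 3),
                            reference_ir = ref)
report
#> <scr_report> kind=exp2
#>   low: EV per-epoch 97.6%, per-subject 97.6%, pooled 97.5%
#> <gain_trend> slope=0.1217 (SE 0.0266), t(21)=4.58, p=0.000162

report$reference_comparison[, c("epoch_id", "class", "rate_hz", "r2")]
#>   epoch_id class    rate_hz        r2
#> 1  s01_e01   low 0.09986639 0.9968915
#> 2  s01_e02  high 1.51160577 0.1560805
#> 3  s02_e01   low 0.10015820 0.9942958
#> 4  s02_e02  high 1.51468521 0.2389073
```

Reading the output: at ~0.1 Hz stimulation the per-epoch LTI fits explain
97.6% of signal variance (the analytic ceiling for the configured 5%
measurement noise is 99.75%) and the fitted response functions share >99%
of their variance with the generating one. At ~1.5 Hz the depletion
nonlinearity is engaged: the fits still track the data, but the estimated
response functions no longer resemble the true one (shared variance 16%
and 24%) — a violation of time invariance, visible exactly as a
rate-dependent change of the estimated SCRF. The positive gain trend over
stimulation repetition reflects the sign convention: fitted gains are
negative (a positive input drives the ODE negative), so physically
*declining* response gains under depletion appear as an increasing trend.
The 10 Hz epochs of the full design are excluded as beyond physiological
burst rates.

The full-size study analyses live in `analysis/` and write their tables
to `results/`:

```sh
Rscript analysis/01_simulate.R        # both datasets + manifest
Rscript analysis/02_exp1_analysis.R   # recording-experiment pipeline
Rscript analysis/03_exp2_analysis.R   # stimulation-experiment pipeline
Rscript analysis/04_lti_checks.R      # forward-model verification
```

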