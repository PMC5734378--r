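# circavis

Circadian analysis of *Drosophila* visual responsiveness and locomotor
behaviour, with a matched synthetic-data generator.

Fly vision is not constant across the day: the gain of the eye's response
to light carries a circadian signature that can be read out
electrophysiologically.  `circavis` implements the full measurement chain
needed to quantify that signature, for electrophysiologists and
chronobiologists who want a tested, reproducible reference implementation:

* **Flash ERG feature extraction** — receptor potential, off-transient,
  peak-to-peak amplitude, latency — from voltage traces with known
  stimulus timing.
* **Two-frequency SSVEP decomposition.**  With a stimulus that sums 12 Hz
  and 15 Hz square-wave contrast modulations, the nonlinear visual cascade
  responds at harmonics and intermodulation frequencies that index
  successive anatomical stages: 1F1 (12 Hz, photoreceptors), 2F1 (24 Hz,
  lamina), 2F1+2F2 (54 Hz, medulla).  Amplitudes are read at exact DFT bins
  with flanking-bin noise floors.
* **Period estimation with the period as a free parameter.**  Responses
  over circadian time are fit with
  `SS(t) = C + α sin(2πt/Ω) + β cos(2πt/Ω)`; for each candidate period Ω
  on a grid (0.4–1.6 days) the linear coefficients are solved exactly, the
  residual-vs-Ω profile exposes the well-fitting periods, and the best one
  is refined by nonlinear least squares with Jacobian-based standard
  errors.
* **Locomotor rhythmicity** — Trikinetics-style 2-min count streams,
  30-min daily profiles, per-fly Lomb-Scargle periodograms over a 16–32 h
  band, rhythmic/arrhythmic calls and cohort summaries.
* **A synthetic-data generator** for all of the above (nonlinear SSVEP
  cascade, fERG templates, circadian series, Poisson activity streams)
  with seeded, bit-reproducible ground truth, so every analysis stage is
  validated against known answers.

## Worked example

The default experiment contrasts a control-like genotype whose visual gain
cycles with a 14.6 h period against a clock-mutant-like genotype with a
unimodal 25.2 h rhythm, then asks whether the pipeline recovers that
contrast from simulated recordings alone:

```r
library(circavis)
report <- run_experiment(experiment_config(seed = 11))
report
#> Synthetic circadian-vision experiment report
#>   fitted periods (h) per genotype x SSVEP component:
#>  genotype component period_h se_period_h
#>       st1   1F2-1F1 14.69000   0.2181136
#>       st1       1F1 14.52537   0.1218584
#>       st1       2F1 14.61759   0.1986572
#>       st1   1F1+1F2 14.69064   0.2177017
#>       st1   2F1+2F2 14.70965   0.2645930
#>    ClkJrk   1F2-1F1 25.01495   0.9675027
#>    ClkJrk       1F1 25.58098   0.6882208
#>    ClkJrk       2F1 24.84122   0.8576542
#>    ClkJrk   1F1+1F2 25.01510   0.9659479
#>    ClkJrk   2F1+2F2 24.91096   1.1429212
#>   locomotor rhythmicity:
#>  genotype  n fraction_rhythmic mean_period_h true_fraction lights_off_step
#>       st1 32           0.68750          24.4         0.690       0.5049740
#>    ClkJrk 32           0.15625          25.2         0.166       0.5760822
```

Reading the output: every SSVEP component of the control-like cohort fits
a period near 14.6 h (a twice-daily rhythm), while every component of the
mutant-like cohort fits near 25.2 h — the genotypes separate cleanly, with
standard errors of a fraction of an hour.  The locomotor block recovers
the seeded rhythmic fractions (69% vs 16.6%), the free-running periods of
the rhythmic flies, and the mutant's post-lights-off activity step.

Individual stages are plain functions on plain objects:

```r
tr  <- generate_ssvep_trace(flicker_stimulus(c1 = 0.5, c2 = 0.5),
                            cascade_params(noise_sd_mv = 0.2), seed = 1)
extract_components(amplitude_spectrum(tr))
#>   component frequency_hz amplitude_mv noise_floor_mv
#> 1       1F1           12   6.37237894    0.006053440
#> 2       2F1           24   0.45390115    0.007280119
#> 3   1F2-1F1            3   2.33103578    0.006215432
#> 4   1F1+1F2           27   2.23302013    0.009875344
#> 5   2F1+2F2           54   0.02399397    0.004895309
```

Component amplitudes sit one to three orders of magnitude above their
noise floors at exact stimulus bins — the property that makes the
steady-state approach robust to broadband noise.

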