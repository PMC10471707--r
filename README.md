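# retinafunc

Functional characterisation of retinal ganglion cells (RGCs) from
high-density multielectrode-array (MEA) recordings under full-field
chromatic stimulation.

Large-scale MEA surveys of the retina — for example of the bird retina,
whose output is dominated by combined OnOff channels rather than the
segregated On/Off channels of mammals — characterise every sorted cell by a
battery of four stimuli and a set of standard indices. This package
implements that analysis end to end, for anyone who needs to reproduce,
audit or reuse it:

* **Stimuli**: white contrast steps (WS; 100–10% contrast, 2 s On / 2 s Off),
  single-LED colour steps (CS; 630, 560, 505, 480, 420, 360 nm), an
  exponential chirp (1→30 Hz over 30 s), and binary chromatic noise
  (R, G, C, B at 20 Hz, M-sequence).
* **Electrical images**: spike-triggered voltage averages on the 64 × 64
  array (10 pre- + 40 post-spike frames), channel selection by the signal
  score `max(STA) × |min(STA)| × diff(STA)`, shortest-path axon tracing on a
  geometric proximity graph, and conduction velocity
  `S_axon = D_short / (Fmin_max × 1/f_s) / 1000` (m/s), plus the
  exponential-asymptote fit of detection probability against spike count.
* **Indices**: polarity `PI = (A_On − A_Off)/(A_On + A_Off)`, transience
  `TI = (A_Tr − A_Sus)/(A_Tr + A_Sus)` (transient window 80–160 ms,
  sustained 240–2000 ms), spectral dominance `SD`, spectral tuning `ST`
  against log-transformed visual-pigment nomograms, latency (time to half
  peak), high-frequency index
  `HFI = (P_high − P_low)/(P_high + P_low)` from the chirp power spectrum.
* **Spectral kernels**: per-LED linear filters over the 1 s pre-spike window
  by spike-triggered averaging, z-normalised against a pre-spike baseline;
  amplitude, spectral centroid, and time-resolved colour opponency with the
  colour-opponency index (COI).
* **Phase locking**: per-frequency-bin vector strength with significance
  against a count-matched Poisson bootstrap null.
* **Quality control**: signal-to-noise quality index
  `QI = Var_t[⟨C⟩_r] / ⟨Var_t[C]⟩_r`, SPIKE-synchronization / ISI-distance
  based step quality, Hartigan dip test of waveform unimodality, spike-cloud
  circularity, On/Off × waveform-subcluster independence, Spearman bias
  audits.
* **Clustering**: block-wise PCA (≥ 50% variance per block) and a Gaussian
  mixture model over four covariance structures selected by BIC, with
  correlation-based cluster merging and a minimum-size retention filter.
* **Synthetic ground truth**: a linear–nonlinear–Poisson simulator and a
  synthetic electrical-footprint generator, so every estimator has a
  parameter-recovery test with known answers.

See the methods vignette (`vignettes/methods.Rmd`) for the model
assumptions, parameter defaults and numerical choices.

## Worked example

Simulate a fast Off-transient cell, measure its step-response indices, and
recover a synthetic axon's conduction velocity from its electrical image:

```r
library(retinafunc)

ws <- build_white_steps()                      # 10 contrasts, 2 s On / 2 s Off
cell <- gt_cell("example", baseline_rate = 1, gain = 120,
                on_weight = 0.1, off_weight = 0.9,
                filter_kind = "biphasic", tau_s = 0.012,
                spectral_weights = c(1, 0.8, 0.6, 0.4, 0.15, 0.02))
sp <- simulate_lnp(list(cell), ws, n_repeats = 5, seed = 1)

amp <- response_amplitudes(sp$time_s, ws, n_repeats = 5)
on100  <- amp[amp$kind == "WS_on"  & amp$parameter == 1, ]
off100 <- amp[amp$kind == "WS_off" & amp$parameter == 1, ]
pi_v <- polarity_index(on100$a_mean, off100$a_mean)
ti_v <- compound_ti(transience_index(on100$a_tr, on100$a_sus),
                    transience_index(off100$a_tr, off100$a_sus), pi_v)
sprintf("PI = %.2f, compound TI = %.2f", pi_v, ti_v)
#> "PI = -0.66, compound TI = 0.83"

ax <- synthetic_axon(c(10, 10), matrix(c(10, 45), ncol = 2),
                     velocity_m_s = 1.5)
ei <- compute_ei(simulate_footprint(ax, n_spikes = 1, noise_sd = 0))
tr <- trace_axon(ei, compute_esignal(ei))
sprintf("axon detected: %s, D = %.2f mm, velocity = %.2f m/s",
        tr$detected, tr$d_short_mm, conduction_velocity(tr))
#> "axon detected: TRUE, D = 1.43 mm, velocity = 1.43 m/s"
```

The negative PI and positive TI read off the cell as Off-dominated and
transient, matching the parameters it was built with; the traced velocity
recovers the planted 1.5 m/s within a few percent (the discretisation of
the transit time to whole frames bounds the attainable precision).

For a full run — quality filtering, indices, kernels, opponency, clustering
and the report — generate a labelled fixture dataset and hand it to the
pipeline:

```r
fx  <- generate_fixture_dataset(fixture_config(), seed = 42)
run <- run_pipeline(fx, pipeline_config(k = 5, seed = 1, min_members = 4))
run$report$group_percentages
```

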