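# glucodrnn

Blood-glucose forecasting for type-1 diabetes with dilated recurrent
neural networks, in R.

People with type-1 diabetes manage their glucose with a continuous glucose
monitor (CGM) sampling every 5 minutes. A reliable 30-minute-ahead glucose
forecast enables predictive alarms and insulin suspension before
hypoglycaemia. This package implements that forecasting pipeline end to
end for researchers in physiological time-series modelling:

* **`cgm_sim`** — a synthetic-cohort generator (Bergman-style minimal
  model with gut and subcutaneous-insulin compartments, RK4 at 1-min
  steps; 3 meals/day with 10% size CV and 20-min timing SD, 1–5
  boluses/day, AR(1) sensor noise) plus clinical-style defect injectors
  (dropped intervals, spikes, frozen sensor), so the whole pipeline is
  testable without licensed data.
* **preprocessing** — gap detection, first-order interpolation (training),
  25-min median filtering, causal least-squares extrapolation (testing),
  time-of-day indexing, and the transfer-learning corpus builder.
* **windowing** — sliding 12-step windows of the four channels
  `[G, I, M, T]` labelled with the glucose change ΔBG over a 6-slot
  (30-min) horizon; channel standardization; chronological 90/10 splits;
  seeded mini-batches.
* **the forecaster** — a 3-layer dilated vanilla-RNN (dilations 1, 2, 4;
  32 hidden nodes/layer), where layer *l* recurs from its own state
  *d<sub>l</sub>* steps back:

  h<sub>t</sub><sup>l</sup> = tanh(W<sub>rec</sub> h<sup>l</sup><sub>t−d<sub>l</sub></sub> + W<sub>in</sub> h<sup>l−1</sup><sub>t</sub> + b<sup>l</sup>),  ŷ<sub>T</sub> = W<sub>FC</sub> h<sup>L</sup><sub>T</sub> + b<sub>FC</sub> + x<sub>T</sub>,

  trained by analytic backpropagation through time with RMSprop
  (lr 0.001, decay 0.9, batch 512), gradient clipping and early stopping,
  with optional two-phase transfer learning across subjects.
* **baselines** — ARX(3) lagged least squares, a three-layer fully
  connected network (NNPG), and RBF-kernel SVR (C = 100, γ = 0.01).
* **evaluation** — RMSE (mg/dL), MARD (%), cross-correlation time lag
  (minutes, sub-slot resolution via parabolic peak interpolation), and
  paired t-tests between methods.

See the methods vignette (`vignettes/glucose-forecasting-methods.Rmd`)
for the models, parameter choices and limitations.

## Worked example

```r
library(glucodrnn)

# simulate a 35-day subject (30 train days + 5 test days)
scenario <- sim_scenario(n_days = 35, seed = 42)
subj <- simulate_subject(scenario)
subj
#> subject_series 'sim01': 10080 slots (35.0 days), 10080 valid (100.0%)
#>   glucose [mg/dL]: median 113, range [60, 230]
#>   events: 93 boluses (570.0 U total), 105 meals (6281 g total)

# train the dilated RNN and benchmark it against ARX(3)
cfg <- train_config(max_epochs = 60, patience = 8, seed = 1)
metrics <- benchmark_subject(subj, train_days = 30, test_days = 5,
                             methods = c("drnn", "arx"), config = cfg)
metrics
#>   method subject     rmse     mard  time_lag
#> 1   drnn   sim01 8.198022 4.510670 11.455908
#> 2    arx   sim01 9.895297 6.083054  9.687583
```

The table reads: on the held-out 5 days, the dilated RNN forecasts
30 minutes ahead with an RMSE of 8.2 mg/dL and a mean absolute relative
difference of 4.5%, beating the ARX baseline trained on the identical
windows on both error statistics; on this single subject at the short
60-epoch demo budget its cross-correlation lag (11.5 min) is slightly
behind ARX (9.7 min) — the cohort experiments in
`scripts/acceptance.R`, run at the full training budget, give the
dilated RNN the smaller lag as well. (Numbers above are the output of
this exact script; they are deterministic given the seeds.)

The command-line interface wraps the same functions:

```sh
Rscript inst/cli/glucodrnn simulate --days 35 --subjects 5 --seed 1 --out cohort/
Rscript inst/cli/glucodrnn train --in cohort/sim01.csv --out model.json --epochs 60
Rscript inst/cli/glucodrnn benchmark --config inst/config/pipeline-example.yaml
```

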