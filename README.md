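# stresseeg

Individualized, quantitative stress assessment from frontal EEG.

## What this package is for

Most EEG "stress detection" work classifies two or three coarse levels. This
package instead treats stress as a continuous quantity: during a stress–relax
session — a 6-minute arithmetic stressor with social pressure (MIST),
a 5-minute virtual-reality relaxation, and a final eyes-closed rest — a
participant answers eight one-question surveys ("What is your level of stress
on a scale from 1 to 5?", the self-perceived stress level, SPSL) while four
frontal channels (Fp1, Fp2, F5, F6) are recorded at 256 Hz. A regression
model is then fitted *per participant* to predict the SPSL from spectral EEG
features.

The pipeline:

1. **Preprocess** each phase recording: 48–52 Hz notch, 2–48 Hz 4th-order
   zero-phase Butterworth bandpass, resampling to the nominal phase length,
   2-s epoching (180 + 150 + 30 = 360 epochs per session), zeroing of epochs
   exceeding 75 μV, per-epoch detrending and standardization.
2. **Extract features** per epoch: channel-averaged band powers
   P<sub>Delta</sub> (1–4 Hz), P<sub>Theta</sub> (4–8), P<sub>Alpha</sub>
   (8–13), P<sub>Beta</sub> (13–25), P<sub>Gamma</sub> (25–45) from
   Tukey-windowed periodograms, plus two stress indices,

   RG = P<sub>Gamma</sub> / (P<sub>Alpha</sub> + P<sub>Theta</sub>),
   AA = P<sub>Alpha</sub>(F6) − P<sub>Alpha</sub>(F5),

   smoothed with a 30-s moving average → a 360 × 7 feature matrix.
3. **Labels**: the 8 survey answers are interpolated (linear / pchip /
   spline / nearest) onto the 360-epoch timeline. The 8 surveyed epochs form
   the test set; the 352 interpolated epochs form the training set.
4. **Models**: ridge regression (with polynomial feature expansion), random
   forest, a small multi-layer perceptron and support vector regression,
   each tuned by exhaustive grid search with 5-fold cross-validation on the
   training rows only, seeded for reproducibility.
5. **Evaluate** on the 8 true answers with the mean squared percentage error

   MSPE = [ mean (y<sub>test</sub> − y<sub>pred</sub>)² / mean y<sub>test</sub> ] · 100

   and R² (squared Pearson correlation), aggregated over a cohort as
   mean ± SEM per regressor × interpolation cell.

Because the original human recordings are not publicly deposited, the
package ships a protocol-faithful **synthetic session generator**
(`simulate_session()`): band-limited EEG noise whose band powers are coupled
to a ground-truth stress trajectory, 50 Hz mains contamination, >75 μV
artifact bursts and survey reporting noise. Every stage of the pipeline is
tested against it; see the methods vignette
(`vignettes/stress-regression-pipeline.Rmd`) for what it does and does not
emulate.

## Worked example

One synthetic participant, random forest on linearly interpolated labels:

```r
library(stresseeg)
sched  <- build_default_schedule()
sess   <- simulate_session(sched, synth_config(seed = 42))
epochs <- preprocess_session(sess$recordings, sched)
fm     <- extract_features(epochs)
fm
#> Feature matrix: 360 epochs x 7 features (mist_test, relax, rest2)

knots <- map_surveys_to_epochs(sched)
trace <- interpolate_spsl(survey_series(sess$truth$surveys), knots,
                          n = 360, method = "linear")
fit <- grid_search_fit("random_forest", fm$values, trace$values,
                       make_split(trace))
fit
#> stress_fit [random_forest]: best CV MSE 0.1781 with num_trees=100,
#>   max_features=5, max_depth=7

res <- evaluate_predictions(sess$truth$surveys$spsl, fit$predictions)
round(res[, c("mspe", "r2")], 3)
#>    mspe   r2
#> 1 1.762 0.98

round(rbind(truth = sess$truth$surveys$spsl,
            predicted = fit$predictions), 2)
#>           [,1] [,2] [,3] [,4] [,5] [,6] [,7] [,8]
#> truth        2    3 4.00 5.00 4.00 3.00 2.00 1.00
#> predicted    2    3 4.06 4.95 3.94 3.09 2.05 1.63
```

The MSPE of 1.76 says the mean squared prediction error is 1.76% of the mean
reported stress level; R² = 0.98 says the predictions track the rise through
the stress test and the decay through relaxation almost perfectly. (These
are synthetic-data numbers: the generator's feature–stress coupling is
cleaner than human EEG, so scores are better than one should expect on real
recordings.)

A full cohort with the study's default settings (23 participants, 4
regressors × 4 interpolation methods):

```r
out <- run_cohort(run_config(seed = 0))
out$report      # mean ± SEM of MSPE and R² per cell, best cell, per-survey errors
```

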