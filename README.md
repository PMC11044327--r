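# eitsbt

Breath-by-breath electrical impedance tomography (EIT) analysis around a
spontaneous breathing trial (SBT).

## What it is for

During weaning from mechanical ventilation, a patient performs an SBT
(typically a T-piece trial: positive pressure removed, later restored).
Thoracic EIT monitors the lung throughout, producing a stream of
reconstructed pixel impedance maps (~50 Hz). This package turns those raw
frame sequences — together with a lung-contour mask, a 1 Hz ventilator log
and the SBT phase timestamps — into clean per-breath and per-epoch trend
tables of the standard EIT weaning parameters:

- **EELI** — end-expiratory lung impedance, surrogate for end-expiratory
  lung volume;
- **ΔZ** — tidal impedance swing, surrogate for tidal volume;
- **RR, VT, MV, RSBI** — respiratory rate, calibrated tidal volume
  (`VT = c·ΔZ` from a pre-SBT point calibration against the ventilator),
  minute ventilation, rapid shallow breathing index `RR/VT[L]`;
- **GI** — global inhomogeneity index,
  `GI = Σ_{x,y∈lung} |DI_xy − median(DI_lung)| / Σ_{x,y∈lung} DI_xy`,
  0 for perfectly homogeneous ventilation;
- **CoV** — impedance-weighted center of ventilation (% of lung extent,
  ventral→dorsal and left→right);
- **NSS / DSS / FLS** — nondependent and dependent silent spaces (lung
  pixels with tidal change < 10% of the maximum, split at the CoV line)
  and functional lung space (`FLS = 100% − silent space`);
- regional ventilation fractions (left/right, ventral/dorsal).

Preprocessing removes spike and step artifacts and the cardiac-frequency
component, segments breaths from the global lung signal, and automatically
selects stable tidal-breathing periods. Parameters are averaged over the
pre-SBT baseline, five equal SBT epochs and the post-SBT phase, with EELI
and ΔZ expressed as percent change from baseline — the tables a downstream
mixed-model analysis consumes. A synthetic scenario generator with complete
ground truth (breath boundaries, true EELI/ΔZ tracks, amplitude maps, true
GI, injected artifacts) backs every stage with parameter-recovery tests.

## Worked example

Generate the reference synthetic SBT session (2 min baseline, 5 min
T-piece trial, 2 min after reconnection; RR 15→25/min, EELI −20% during the
trial with incomplete recovery, ΔZ −15% with full recovery, cardiac
oscillation at 90/min, spikes on 1% of frames) and run the full pipeline:

```r
library(eitsbt)

sc  <- generate_scenario(scenario_config(seed = 1))
ses <- run_session(sc$seq, sc$mask, sc$vent, sc$ann, patient_id = "demo")
ses
#> <eit_session> demo (outcome: unknown)
#>   183 stable breaths in 3 periods; c = 3.999 ml/AU
#>   epoch EELI % change: 0.0, -17.8, -20.1, -20.1, -20.1, -20.1, -10.6

dplyr::select(ses$epochs, epoch, n_breaths, eeli_mean, dz_mean, rr_mean,
              rsbi_mean, gi_mean, pct_change_eeli)
#> # A tibble: 7 x 8
#>   epoch n_breaths eeli_mean dz_mean rr_mean rsbi_mean gi_mean pct_change_eeli
#>   <fct>     <int>     <dbl>   <dbl>   <dbl>     <dbl>   <dbl>           <dbl>
#> 1 pre          30     1000.    99.5    15.3      38.6   0.537             0
#> 2 sbt_1        25      822.    86.1    25.0      72.6   0.761           -17.8
#> 3 sbt_2        25      799.    86.3    25.0      72.4   0.728           -20.1
#> 4 sbt_3        25      799.    86.4    25.0      72.3   0.712           -20.1
#> 5 sbt_4        25      799.    86.4    25.0      72.3   0.723           -20.1
#> 6 sbt_5        25      799.    87.1    24.6      70.9   0.740           -20.1
#> 7 post         28      894.   100.     15.0      37.4   0.526           -10.6
```

Reading the table: at trial start EELI drops by 20% (derecruitment after
losing positive pressure) and only recovers to −10% after reconnection,
while the tidal swing drops ~15% and restores fully — the signature
dissociation between end-expiratory volume and tidal volume. The rate
nearly doubles, so the RSBI roughly doubles too, and the ventilation
distribution becomes more inhomogeneous (GI 0.54 → ~0.73) while the trial
runs. The recovered calibration factor (3.999 ml/AU, 30 points) matches the
generator's true 4 ml/AU to 0.03%.

Everything is a tibble: `tidy(ses)` gives the long per-epoch table,
`glance(ses)` a one-row session summary, `cohort_table(list(ses, ...))` the
long cohort table for external statistics, and
`autoplot(ses$epochs)`, `plot_global_signal()`, `plot_tidal_image()` the
standard figures.

File-based sessions work through `run_pipeline()` with a YAML or list
config pointing at a session container or at frame-csv/mask/vent/annotation
files; `inst/cli/eitsbt.R` wraps `generate`, `run` and `cohort` for shell
use.

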