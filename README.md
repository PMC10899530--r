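# ktrq

Quantitative analysis of ERK pathway signaling from kinase translocation
reporter (KTR) live-cell imaging, and metastatic-burden quantification from
fluorescent histology — with synthetic-data generators that carry exact
ground truth, so every stage of the pipeline can be validated at desk scale.

## Who this is for

Labs using ERK translocation reporters (ERKTR) read out single-cell ERK
activity as the ratio of cytoplasmic to nuclear reporter fluorescence: when
ERK phosphorylates the reporter it exits the nucleus, so the ratio rises
with pathway activity. A typical experiment images an H2B nuclear channel
and the ERKTR channel every 6 minutes through a 4 h baseline, growth-factor
addition, a 15 h response window, and a terminal MEK-inhibitor (MEKi)
treatment that drives ERK activity to its floor. Parallel histology
workflows measure metastatic burden on DAPI/vimentin/marker-stained lung
sections. `ktrq` implements both analysis chains end to end:

- **`synth`** — generators for single-cell trace ensembles, two-channel
  time-lapse movies, and three-channel tissue sections, each returning the
  exact ground truth used by the validation tests
  (`simulate_trace_ensemble()`, `simulate_timelapse()`,
  `simulate_tissue_section()`).
- **live-cell** — nuclear segmentation (Otsu + watershed), cytoplasmic
  ring construction, greedy nearest-neighbor tracking, and activity-trace
  extraction (`segment_nuclei()`, `make_cyto_rings()`, `link_tracks()`,
  `extract_activity_traces()`, `ktr_extract()`).
- **responder analysis** — MEKi-floor normalization, per-cell paired
  t-test responder calls at P < 0.005 with maximum amplitude (1 h window)
  and 12 h AUC features, responder fractions with Wilson CIs, Hill
  dose-response fits, and transient / waning / sustained class assignment
  (`normalize_traces()`, `call_responders()`, `responder_fraction()`,
  `fit_dose_response()`, `classify_response_class()`).
- **tissue** — DAPI tissue and vimentin tumor segmentation, tumor counts,
  metastatic burden (tumor area / lung area x 100), 90th-percentile marker
  intensity inside the tumor mask, fixed-cell compartment signals, and
  Bland-Altman method agreement (`segment_tissue()`, `segment_tumor()`,
  `metastatic_burden()`, `marker_p90()`, `bland_altman()`).
- **reporting** — fold changes, organoid percent survival,
  Benjamini-Hochberg FDR adjustment, group mean ± SEM summaries, and a
  config-driven `run_pipeline()`.

All tabular results are tibbles; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## The core quantities

For each cell with background-corrected compartment means, ERK activity is

    activity(t) = (cytoplasmic mean - background) / (nuclear mean - background)

normalized per cell by its mean over the MEKi floor window. A cell is a
responder when a two-sided paired t-test on order-matched 1 h pre/post
treatment windows gives p < 0.005 with an increased post-treatment mean.
Responders are further characterized by the maximum baseline-subtracted
amplitude within 1 h and the trapezoidal AUC over 12 h. On tissue,

    burden (%) = 100 * tumor area / lung area

with tumors as 8-connected vimentin-positive components above a minimum
area inside the DAPI tissue mask.

## Worked example

```r
library(ktrq)

sched <- acquisition_schedule()          # 6-min frames, 4 h + 15 h + MEKi
params <- sim_params(response_class = 3, dose = 30,
                     responder_pmax = 0.8, responder_ec50 = 10,
                     n_cells = 1000)
sim   <- simulate_trace_ensemble(params, sched, seed = 1)
norm  <- normalize_traces(sim$traces, sched)
calls <- call_responders(norm, sched)
responder_fraction(calls)
#> # A tibble: 1 × 5
#>       n n_responders fraction ci_low ci_high
#>   <int>        <int>    <dbl>  <dbl>   <dbl>
#> 1  1000          608    0.608  0.577   0.638
```

The generator's dose-response model gives a true responder probability of
0.8 / (1 + 10/30) = 0.60 at 30 ng/mL; the pipeline recovers 0.608 with a
Wilson interval that covers the truth. Classifying the responding cells'
normalized traces:

```r
resp <- norm[norm$cell_id %in% calls$cell_id[calls$is_responder], ]
classify_response_class(resp, sched)
#> # A tibble: 1 × 5
#>   response_class persistence duration_index peak_response n_cells
#>            <int>       <dbl>          <dbl>         <dbl>   <int>
#> 1              3       0.985          0.968          2.51     608
```

Persistence near 1 marks the sustained (class 3) response the ensemble was
generated with. The same pattern applies to imaging and histology: render
a movie or section with `simulate_timelapse()` / `simulate_tissue_section()`,
run `ktr_extract()` or `segment_tissue()` + `segment_tumor()` +
`metastatic_burden()`, and compare against the returned ground truth.

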