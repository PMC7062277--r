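# huntmove

Tools for quantifying how GPS-collared large herbivores respond to
**drive hunts** — the common European hunting technique in which
beaters and dogs sweep a delimited area towards a line of stationary
shooters. Wildlife managers increasingly use the *non-lethal* side of
hunting (fear, displacement, delayed returns) to steer ungulates away
from sensitive areas; doing that well requires quantitative answers to
two questions: **what does an animal do while it is being hunted**,
and **how long does it stay away afterwards**?

`huntmove` implements the full analysis chain for collar data around
drive hunts:

* **Hunting events and the immediate response.** A hunting event is a
  monitored individual inside the hunted-area polygon at the start of a
  drive. Its immediate response is classified as *fleeing* (at least
  one fix strictly beyond the shooting line, identified with the
  polygon boundary, during the drive) or *staying*. Per event the
  package computes maximum 2-min step speed (km/h), sinuosity
  (mean cosine of turning angles: 1 = straight, 0 = Brownian,
  negative = back-tracking), the cumulative distance during the drive
  (DistI, m) and up to the first dawn (DistD, m), and net-displacement
  profiles over the five days around the hunt.
* **Site familiarity.** The annual home range is estimated as a fixed-
  kernel utilization distribution (UD) from 12-hourly relocations and
  split into ten nested isopleth bands, iso(0–10) … iso(90–95). The
  familiarity of a hunted area *j* for animal *i* is the weighted
  overlap

  `Fam_ij = Σ_b w_b · area(band_b ∩ area_j) / area(area_j)`

  with weights descending 1.0, 0.9, …, 0.2, 0.15 from the core band to
  the outermost; area outside the 95% isopleth contributes 0.
* **Return times.** For each event, a censored post-hunt return time
  (first fix outside → first fix back inside, censored at 144 h) and a
  reversed-time undisturbed control (the absence spell immediately
  before the hunt) are built and compared with Kaplan–Meier curves;
  a 72-h dichotomy feeds a logistic GLMM.
* **Response models.** A linear mixed model of
  `log(Dist) ~ Bush + Fam + Dogs + Beat + Shot` with an individual
  random intercept, and a logistic mixed model of the short-return
  indicator on hunt occurrence × familiarity; both report estimates
  with 95% and 75% intervals.
* **Synthetic herd generator.** Because collar data of this kind are
  rarely shareable, the package ships a generator producing GPS
  trajectories, hunted areas and hunt logs with known ground truth
  (behaviour labels, exit times, return lags), emulating the field
  design: dual fix schedule (2-min fixes 08:00–20:00 on hunt days,
  hourly otherwise), 82%/86% fix success, 5.8 m GPS error, ~101 ha
  hunted areas, 0.68 flee probability, and post-hunt/control return
  medians of 34 h / 17 h with 38%/12% non-return mass.

## Worked example

Simulate 120 independent hunting events with ground truth, run
detection, classification, movement metrics and the survival stage:

```r
library(huntmove)
set.seed(42)
sim <- simulate_events(120, with_returns = "both")
cfg <- analysis_config()
events <- detect_events(sim$trajectories, sim$hunts, sim$areas, cfg)
events <- build_event_table(events, sim$trajectories, sim$areas, cfg)
table(events$classification)
#> fleeing staying
#>      64      36

aggregate(cbind(speed_max_kmh, sinuosity, dist_immediate)
          ~ classification, events, median)
#>   classification speed_max_kmh sinuosity dist_immediate
#> 1        fleeing         16.50     0.724           3862
#> 2        staying          6.85    -0.267           1020
```

Fleeing animals move fast and straight and cover nearly four times the
distance of staying animals during the drive hour; the pooled-variance
comparison makes that formal:

```r
cmp <- compare_group_distances(events, "immediate")
sprintf("t = %.2f, df = %d, p = %.3g", cmp$statistic, cmp$df, cmp$p_value)
#> "t = -36.84, df = 98, p = 3.23e-59"
```

Return times show the delayed side of the response — after a hunt the
animals stay away roughly twice as long as they would anyway:

```r
rec <- build_return_table(events, sim$trajectories, sim$areas, cfg)
km_median(km_estimate(rec, "post_hunt"))   # hours
#> 36.97
km_median(km_estimate(rec, "control"))
#> 16
```

(120 events is a small sample; at a few hundred events the medians
settle at the configured 34 h and 17 h.)

For file-based work, `simulate_population()` writes `relocations.csv`,
`hunts.csv` and `areas.geojson`, `read_relocations()` / `read_hunts()`
read them back, and `run_pipeline()` chains every stage — including
per-individual UDs and the familiarity covariate, the two mixed-model
fits and a JSON run manifest. A thin command-line wrapper lives in
`inst/exec/huntmove-pipeline.R`.

See the methods vignette (`vignettes/drive-hunt-analysis.Rmd`) for the
models, their assumptions, and the design choices behind the generator.

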