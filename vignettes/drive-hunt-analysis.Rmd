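---
title: "Quantifying immediate and delayed responses of ungulates to drive hunts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immediate and delayed responses of ungulates to drive hunts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huntmove)
```

## The problem

A drive hunt confronts every animal inside a delimited area with an
acute, spatially bounded threat: beaters and dogs sweep the area
towards a line of shooters. Collar data collected around such hunts
let us ask two linked questions. During the drive, does the animal
cross the shooting line and flee, or does it stay and hide? And
afterwards, how far does it move and how long does it avoid the place?
`huntmove` implements this analysis as a reusable chain: data model
and readers, step-level movement metrics, a kernel-based
site-familiarity index, event detection and classification, censored
return-time survival analysis, and two mixed-effects response models.
Because collar datasets of this kind are rarely deposited, the package
also contains a first-class synthetic generator with ground truth, so
that every stage can be validated end to end.

## Data model and conventions

All coordinates are Euclidean metres in a projected CRS; geographic
input is rejected rather than silently reprojected, because every
metric in the chain (speeds, step lengths, polygon areas) assumes
planar metres. Timestamps are stored in UTC; civil clock times — dawn
at 08:00, day as 08:00–18:00 — are evaluated in a configurable study
time zone (default `Europe/Paris`). Fixes flagged invalid are kept for
fix-success reporting but excluded from all metrics.

The expected collar schedule is dual: one fix every 2 minutes from
08:00 to 20:00 on hunt days, one per hour otherwise during the hunting
season (and sparser outside it). `regime_report()` audits a
trajectory against this schedule, because fix success (82% in the
2-min regime, 86% hourly, in the emulated design) bounds what any
downstream metric can see.

## Movement metrics

Steps join consecutive valid fixes. A step whose duration reaches
`gap_tolerance_factor` (default 2) times the nominal interval spans at
least one missing fix: it still contributes length to cumulative
distances, but is excluded from speeds, and turning angles are not
computed across it — a composite 4-minute step would bias the angle
distribution towards straightness.

* **Sinuosity** is the mean cosine of turning angles: exactly 1 for a
  straight path, about 0 for Brownian-like motion, negative for
  back-and-forth movement typical of an animal dodging beaters inside
  cover.
* **Maximum speed** uses each step's actual duration, not the nominal
  interval, so irregular fix spacing does not corrupt it.
* **DistI** (immediate distance) sums the 2-min step lengths between
  drive start and end. **DistD** (delayed distance) sums hourly steps
  from the drive to the first 08:00 dawn; the trajectory is resampled
  onto the hourly grid first, so the dense 2-min fixes during the
  drive contribute hourly steps, not 2-min steps. Two window
  conventions exist for DistD in the field — from hunt start or hunt
  end; both are supported (`delayed_from`), with hunt start the
  default so that the immediate and delayed responses nest.
* **Net displacement** from the encounter point (the animal's position
  at hunt start) is evaluated at the valid fix nearest a requested
  time, within half the nominal interval; `displacement_profile()`
  summarizes it over half-day day/night periods across the five days
  centred on the hunt, separately for fleeing and staying animals.

## Site familiarity

The annual utilization distribution (UD) is a bivariate Gaussian
kernel density of 12-hourly relocations (one fix per 12-h bin, nearest
the bin centre), computed with `MASS::kde2d` on a grid padded three
bandwidths beyond the data and renormalized to mass 1. The default
bandwidth is the ad hoc bivariate reference rule
$h = \bar\sigma\, n^{-1/6}$ used throughout the home-range literature;
a fixed bandwidth in metres can be supplied instead. The default grid
cell is 10 m (configurable); for a typical ~550 ha range this resolves
isopleth bands to well under 1% of their mass.

The L% isopleth set is the minimal-area set of grid cells containing
L/100 of the UD mass (cells ranked by density). Ten nested bands
iso(0–10), iso(10–20), …, iso(90–95) carry weights 1.0, 0.9, …, 0.2,
0.15. Only the first, second and last weights are anchored by the index's
reported form; the intermediate ones follow the only pattern
consistent with all three — a linear descent — and the weight vector
is exposed as an argument so other choices remain possible. The
familiarity of a hunted area is

$$\mathrm{Fam} = \sum_b w_b \,
  \frac{\mathrm{area}(\mathrm{band}_b \cap \mathrm{area})}
       {\mathrm{area}(\mathrm{area})},$$

so 1 means the whole area sits in the core band and 0 means it lies
outside the 95% home range entirely.

Two numerical choices matter here. First, bands are kept as unions of
grid cells rather than polygonized contours; band–polygon overlaps are
computed *cell-exactly* by Sutherland–Hodgman clipping of the hunted
polygon against each boundary cell (interior cells of a convex polygon
take the fast path). The polygonized and raster routes agree within
grid tolerance, and the cellwise route makes the index exactly
consistent with the band definition. Second, the package carries its
own planar-geometry primitives (shoelace area, boundary-aware
point-in-polygon, signed distance, rectangle clipping): they are a few
dozen lines, exactly testable, and keep the dependency footprint to
base R. A point on the polygon boundary counts as *inside* throughout
— an animal standing on the shooting line has not crossed it.

## Hunting events, classification, and responses

Event membership is decided at hunt start: the valid fix nearest the
start (within half the 2-min interval) must lie inside the hunted
polygon. Anchoring at the start matches the encounter-point definition
used for net displacement; animals entering mid-drive are not events
(the alternative any-time rule would create events with no encounter
anchor).

Classification is a pure function of geometry: *fleeing* iff any valid
fix in the hunt window lies strictly outside the polygon — a single
excursion suffices, even if the animal re-enters, because the risk is
crossing the line, not the final position. A configurable buffer
(default 0; typically the 5.8 m GPS error) can be added so that
boundary-hugging noise does not flip labels. Windows holding fewer
than two valid fixes, or less than half the expected fixes (collar
failure, animal killed), are left unclassified rather than guessed.

## Return times

For each event two censored durations are built:

* **Post-hunt:** the clock starts at the first valid fix outside the
  polygon at/after hunt start (for stayers, their delayed exit) and
  stops at the first valid fix back inside; no return within 144 h
  (6 days, chosen to avoid overlap with the next weekly hunt) gives a
  censored record.
* **Control:** on a reversed time scale from hunt start, the entry fix
  of the presence spell containing the hunt is located, then the exit
  fix — the last inside fix before the preceding absence spell; the
  duration is their gap. If the animal was continuously present over
  the horizon, or the exit lies beyond it, the record is censored at
  144 h. Using one horizon for both conditions keeps the two curves
  comparable; both are configurable.

Kaplan–Meier curves come from `survival::survfit` (product-limit with
a Greenwood/log 95% band). "Return" means the first valid fix inside —
single-fix re-entries count; a minimum-dwell rule would need a
parameter with no established value, so the simplest rule is kept. The
72-h dichotomy codes uncensored durations below 72 h as 0 and
durations (censored or not) of at least 72 h as 1; a record censored
before 72 h is unresolvable and dropped from the dichotomy. Exactly
72 h codes as 1 — the boundary is measure-zero in practice.

## Response models

The distance response is modelled as

$$\log(\mathrm{Dist}_i) = \mu + \alpha\,\mathrm{Bush}_i +
\beta\,\mathrm{Fam}_i + \gamma\,\mathrm{Dogs}_i +
\delta\,\mathrm{Beat}_i + \rho\,\mathrm{Shot}_i + u_{a(i)} +
\varepsilon_i,$$

with a Gaussian random intercept per individual (animals are exposed
to several hunts), fitted by REML via `lme4::lmer`; the short-return
indicator is a Bernoulli GLMM on hunt occurrence, familiarity and
their interaction, fitted by Laplace approximation via `lme4::glmer`.
The inferential surface is the point estimate with 95% and 75%
intervals (Wald, from the fixed-effect standard errors). A Bayesian
backend with weakly informative priors would report the same surface;
the backend used is recorded in each fit object and in the run
manifest, so results are interpretable either way. Covariates enter on
their natural scales (proportions, per-hectare densities, counts);
standardization is available behind a flag and changes only the
intercept's meaning.

Degenerate inputs are handled explicitly: a constant covariate raises
a degenerate-design error naming it; one individual degrades to a
fixed-intercept regression with a warning and `sigma_u = 0`; a
constant binary response is reported as separation, and near-separated
fits (escaping estimates or exploding standard errors) carry a
`separation` flag instead of being silently returned. The flee/stay
distance comparison is the pooled-variance two-sample t statistic
(df = n1 + n2 − 2).

## The synthetic herd generator

The generator emulates the monitoring design the analysis assumes:
14 individuals, annual ranges drawn truncated-normal with mean
561.1 ha and SD 282.5 ha, 23 weekly hunt days of 4–6 one-hour drives,
hunted areas truncated-normal with mean 101 ha and SD 30 ha on
[47, 201] ha (a uniform draw on the range would have mean 124 ha and
contradict the stated mean), flee probability 0.68, effort covariates
drawn uniformly over their field-reported ranges (a modelling convenience —
the field distributions are unknown), GPS noise as per-axis Gaussian
with sd chosen so the *median radial* error is 5.8 m, and fix dropout
at 18%/14% per regime.

Behaviour branches are kinematic caricatures calibrated to the
field-reported summaries: the flee branch is a fast (log-normal around
16 km/h per 2-min step), near-straight flight that crosses the
boundary and keeps going, yielding a median maximum speed near
18 km/h; the stay branch is slow, strongly reversing movement
(heading increments of π plus noise with sd 1.57 rad, giving a mean
turning-cosine near −0.29) with occasional flushes, confined at least
20 m inside the boundary so that GPS noise cannot carry a fix across
the line. After the drive both branches drift away so that
first-dawn net displacement lands near 2158 m and the cumulative
hourly distance near the field-reported per-branch values.

Return behaviour is generated at the level of area-presence spells,
not left emergent from the walk, so the survival stage has exact
ground truth. Lags are a two-branch mixture: a non-return branch with
probability 0.38 (post-hunt) or 0.12 (control), and a log-normal
returner branch whose meanlog is solved so that the *overall* median
equals the configured 34 h or 17 h — the quantity the Kaplan–Meier
stage recovers. The returner log-sd (0.2 post, 0.35 control) is kept
deliberately tight: it makes median recovery at a few hundred events
a sharp test, and it reproduces the strongly bimodal split between
returns within days and non-returns that motivates the 72-h
dichotomy. Sub-hour lags are floored at one hour, the resolution of
the hourly schedule. Spell endpoints are aligned to the hourly fix
grid so the observed exit-to-entry gap equals the drawn lag up to
schedule rounding.

Two generator routes exist. `simulate_events()` produces independent
events, each in its own landscape tile and on its own day — the route
for controlled validation (classifier recovery, survival-stage round
trips), with both post-hunt and control spells constructed exactly.
`simulate_population()` is the integration route: home-range-attracted
Ornstein–Uhlenbeck walks (attraction time scale 6 h; stationary sd
calibrated so the 95% Gaussian range equals the drawn home-range area)
sampled on the full dual schedule, hunts placed over the herd, and
behaviour responses spliced into the walks. Post-hunt absence spells
are imposed on the walk (the walk is resampled outside the polygon
until exit + lag, a return fix is planted, and the path then relaxes
back to the base walk over ~12 h); individuals inside an active spell
are not re-exposed, since a second splice would corrupt the first. The
*control* spells of this route are emergent from the walk and shorter
than the field values — undisturbed area-crossing statistics of an OU
walk are not those of real deer — so controlled survival validation
uses the event route. All randomness flows through R's global RNG:
`set.seed()` before a generator call makes its output byte-identical.

What the generator does **not** emulate, and what passing tests
therefore cannot show about field data: habitat selection and terrain
(movement is isotropic), fence effects at the study-area boundary,
behavioural heterogeneity between individuals beyond the random
intercept, habituation across repeated hunts, and any dependence of
the flee decision on the covariates (branches are drawn independently
of Bush, Fam and effort, so the response models' null behaviour is the
generator's truth — parameter *recovery* is validated by simulating
directly from the model equations instead).

## Problem sizes and numerical choices

The shipped tests run the definitional checks on small constructed
fixtures, classifier-recovery and proportion round trips on a few
hundred simulated events, survival round trips on ~240 records per
condition, and interval-coverage studies with 100 replicates of 200
events across 20 individuals — sizes at which each check's sampling
error is comfortably inside its tolerance while the whole suite stays
in the minutes range. Isopleth probes for the boundary-value checks
are placed by `band_probe_polygon()`, which verifies that the probe
square lies wholly inside the target band before it is used, making
the expected index value exact by construction.

Ties in the UD density ranking are broken by grid order; mass
conservation is enforced to 1e−6 after normalization; the KM median is
the smallest time with survival at or below 0.5 (the standard step
convention, `NA` when the curve never reaches it).

## Known limitations

* Wald intervals on the GLMM scale are first-order; with very few
  individuals or near-separated responses they are approximate, which
  is why separation is flagged rather than absorbed.
* The familiarity index inherits grid resolution: bands are unions of
  cells, so Fam of areas much smaller than a few cells is quantized.
  Shrink `ud_cell_m` for small areas.
* `simulate_population()` controls post-hunt spells exactly but not
  control spells (see above), and splices behaviour responses into the
  walk with a relaxation that briefly distorts the home range after
  each event.
* Dawn and dusk are fixed clock times (08:00/18:00 local), not solar
  ephemeris — matching the monitoring design, not astronomy.
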