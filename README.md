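# griffonRanges

Home ranges, key zones and daily occupancy of GPS-tracked Griffon
Vultures (*Gyps fulvus*).

Griffon Vultures are obligate scavengers that search vast areas for
ephemeral carcasses, yet on the Balkan Peninsula the tracked population
concentrates in a handful of shared "vulture key zones" around breeding
colonies and managed feeding sites. Knowing where those zones are — and
how much of a bird's time they absorb — is what lets conservation
managers target anti-poisoning, power-line and habitat work where it
matters. `griffonRanges` packages the full analysis chain from raw
GPS/GSM fix streams to zone-level conservation summaries, for vulture
telemetry and for comparable wide-ranging soaring birds.

## What the package computes

1. **Cleaning** of per-bird fix streams: duplicate-timestamp removal, a
   sequential speed filter (default 120 km/h), exclusion of the first 50
   days after release (re-acclimatisation), restriction to a study
   region, and projection to a local equal-area system.
2. **Temporal partitioning**: the diurnal analysis window
   \[06:00, 18:00) at fixed UTC+2, solstice/equinox seasons, a 45-day
   season-completeness filter and a 50-tracked-day minimum per bird.
3. **Utilization distributions** from the dynamic Brownian bridge
   movement model (dBBMM). Between consecutive fixes the bird follows a
   Brownian bridge whose position at time fraction *α* of a segment of
   duration *T* is Gaussian with mean the linear interpolation of the
   endpoints and per-axis variance

   *T α(1−α) σ²ₘ + (1−α)² δ² + α² δ²*,

   where *δ* is the GPS error SD (≤ 20 m for these transmitters) and the
   motion variance *σ²ₘ* (m²/s) is re-estimated along the track with a
   sliding-window behavioural-change procedure (window 31 fixes, margin
   11, BIC comparison of one- vs two-variance models).
4. **Isopleths**: the 95% contour of the UD is the home range, the 50%
   contour the core area; areas are reported in km².
5. **Vulture key zones**: overlapping home ranges are dissolved into
   candidate areas; areas that some bird connects by same-day movement
   on more than 5% of its tracked days are merged into one zone.
6. **Daily occupancy**: each bird-day is `inside` (> 95% of its diurnal
   fixes in the zone network), `outside` (none), or `partial`; nocturnal
   fixes yield roost sites by single-linkage clustering of nightly
   median positions.
7. **Cohort statistics**: per-group summaries and one-way ANOVA with
   Fisher's LSD post-hoc comparisons.

A seeded synthetic generator (`simulateTracks()`) emulates the structure
of the field data — 10-minute fixes in a 05:00–20:00 duty cycle,
attraction-centre residence, occasional long commutes, nights at the
roost, sub-20-m GPS noise — together with the ground truth needed to
score every stage, so the whole pipeline is testable offline.

## Worked example

Cohort statistics recomputed from the bundled published per-bird
tracking table (48 Balkan Griffon Vultures, 2016–2021):

```r
library(griffonRanges)
birds <- griffonBirds()
rangeStats(birds$homerange95_km2, birds$capture_group)
#>                group  n     mean    median       sd     min      max degenerate
#> 1       reintroduced 20 1104.974  297.9035 1772.468  69.608 5320.030      FALSE
#> 2        wild_caught 22 1642.164 1652.2125 1202.903  23.197 4176.175      FALSE
#> 3 wild_rehabilitated  6 1745.208 1819.9310 1271.082 137.276 3163.986      FALSE

rangeAnova(birds$homerange95_km2, birds$capture_group)
#> One-way ANOVA: F(2, 45) = 0.848, p = 0.435
```

The capture groups do not differ significantly in home-range size — the
released birds behave like the wild ones. The full pipeline on a
synthetic three-colony study:

```r
cfg <- pipelineConfig(simulation = simConfig(nBirds = 3, days = 45, seed = 21),
                      minTrackingDays = 40, cellSize = 600, seed = 21)
res <- runPipeline(cfg, quiet = TRUE)
res$zones
#> VultureZoneSet: 3 zone(s)
#>   Z1: 536.04 km^2, 2 bird(s)
#>   Z2: 519.48 km^2, 3 bird(s)
#>   Z3: 361.8 km^2, 2 bird(s)
res$occupancy
#>   category days percent
#> 1   inside  115   85.19
#> 2  partial   20   14.81
#> 3  outside    0    0.00
```

The three simulated attraction centres are recovered as three zones; the
birds spend 85% of their days entirely inside the zone network (the
`partial` days are commutes between colonies). `res$roosts` locates the
night roosts, `res$zoneTable` mirrors a per-zone report of member birds
with 50%/95% areas, and with `outDir` set the run writes CSV, GeoJSON
and ESRI-ASCII rasters. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

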