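# foragecam

Camera-trap foraging analysis for individually marked butterflies.

Motion-triggered cameras pointed at flower stations turn butterfly foraging
into an event stream: every triggered video is one visit by one marked
individual to one station at one time. `foragecam` takes the annotation
tables produced by video review and answers the questions behavioural
ecologists ask of such records:

* **When do they forage?** Kernel-density activity curves per species or
  sex, and the coefficient of temporal overlap
  `Δ(f, g) = ∫ min(f(t), g(t)) dt` between groups (1 = identical
  schedules, 0 = disjoint).
* **How is feeding structured?** Segmentation of each individual's visit
  stream into *feeding bouts* — maximal runs of visits to the same station
  with inter-visit gaps ≤ 20 min (configurable) — with bout duration,
  visits per bout, intra-bout intervals, bouts per camera-hour, and the
  trend of duration over successive bouts.
* **Do they forage at random?** Per-individual Pearson chi-squared tests of
  station counts against the uniform null (probability 1/K per station;
  0.2 with five stations, 0.25 with four), with asymptotic or Monte-Carlo
  p-values, `X² = Σ (obs − exp)² / exp`.
* **Do they trapline?** Recurrence-quantification determinism (DET) of each
  individual's station sequence: after collapsing within-bout repeats, the
  fraction of recurrent points that lie on diagonal lines of length ≥ 3 —
  i.e. the share of recurrences explained by repeated sub-sequences of
  flowers. DET = 1 for a perfectly repeated route, 0 when no sequence ever
  recurs.

Because real insectary datasets are expensive, the package ships an
agent-based simulator (`simulate_dataset()`) that emulates the experiment —
morning-peaked activity with a sex shift, bout-structured revisitation,
site fidelity / trapline / uniform station choice, imperfect detection —
and returns the ground truth (true bout memberships, preference vectors,
strategy labels) so every analysis stage can be validated against known
answers.

## Worked example

Simulate a trial-like experiment (five stations, four species, 15 days,
08:00–16:00 recording) and run the analyses:

```r
library(foragecam)

cfg <- sim_config(seed = 99)       # defaults emulate a two-species-genus trial
sim <- simulate_dataset(cfg)
sim
#> <forage_sim> 12307 generated visits, 9069 detected (mode: fidelity)

d <- filter_min_visits(sim$dataset)   # drop individuals with < 2 visits

mean_activity_time(d, by = "sex")
#>    group    n mean_min   se_min mean_time
#> 1 female 4255 683.2148 1.314284     11:23
#> 2   male 4814 710.8338 1.313091     11:51
```

Females forage about half an hour earlier than males (the simulator's
configured sex shift is 30 min). Temporal overlap between species is high —
all species share one activity model here:

```r
round(unclass(overlap_matrix(d))[, ], 2)
#>              D. iulia H. erato H. melpomene H. sara
#> D. iulia         1.00     0.94         0.93    0.92
#> H. erato         0.94     1.00         0.95    0.92
#> H. melpomene     0.93     0.95         1.00    0.96
#> H. sara          0.92     0.92         0.96    1.00

b <- segment_bouts(d, gap_threshold = 20)
bout_statistics(b, camera_hours = 120)
#>          group n_bouts mean_duration mean_visits mean_interval bouts_per_hour
#> 1     D. iulia     277      25.79061    5.429603      5.822331       2.308333
#> 2     H. erato     513      24.21485    5.087719      5.923804       4.275000
#> 3 H. melpomene     578      23.03899    4.809689      6.047472       4.816667
#> 4      H. sara     432      23.14988    5.034722      5.737665       3.600000
```

Feeding is grouped into bouts of ~5 visits lasting ~25 min with ~6-min
intra-bout intervals. Under strong site fidelity every individual rejects
the uniform-foraging null:

```r
tests <- randomness_tests(d)           # X² against p = 1/5 per station
randomness_summary(tests)
#>          group n_tested n_random prop_random percent_random
#> 1     D. iulia        8        0           0              0
#> 2     H. erato       14        0           0              0
#> 3 H. melpomene       14        0           0              0
#> 4      H. sara       11        0           0              0
```

`run_pipeline(pipeline_config(sim = cfg, seed = 1, out_dir = "out"))`
executes all stages in order, writes one TSV per stage plus a markdown
report, and is byte-reproducible under a fixed seed. A command-line
front-end over the same functions is installed at
`system.file("cli", "foragecam.R", package = "foragecam")`.

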