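# sawatch

Hierarchical monitoring of canine separation-anxiety (SA) behavior from
wearable accelerometers.

Separation anxiety is the most common canine psychiatric disorder. It is
triggered by the owner's absence and shows up as *symptomatic complex
behaviors*: excessive destructive behavior, excessive exploratory behavior
and excessive vocalization. Direct observation defeats the purpose (the
symptoms only occur when nobody is watching), so `sawatch` monitors a
home-alone dog from two synchronized 50 Hz tri-axial accelerometers — one on
the neck (head postures) and one on the back (body postures) — and raises a
three-level behavioral assessment for veterinary behavior researchers and
engineers building animal-borne monitoring systems.

## The model

**Level 1 — postures (1 s).** Raw six-column sensor logs (sensor ID, frame
number, timestamp, x/y/z acceleration) are cut into tumbling one-second
windows of 50 samples, min–max normalized per recording, per sensor and per
axis, and classified by two parallel stacked recurrent networks (two LSTM
layers of 64 units each, softmax output), one for head postures
{Up, Down, Bark} and one for body postures {Walk, Lie, Sit, Stand, Dig,
Jump}. Each classified window is a posture event *P = E(id, s, p, t)*.
Training uses categorical cross-entropy with Adam (β₁ = 0.9, β₂ = 0.999,
learning rate 0.0025), batch size 25, 50 epochs and seeded 5-fold
cross-validation; SVM, naive Bayes and decision-tree baselines on 12
windowed statistical features (per-axis min, max, mean, sd) are included
for comparison.

**Level 2 — atomic behaviors (2 s).** A complex-event-processing (CEP)
engine slides a 2-s observation window in 1-s steps over the posture
stream and applies pattern rules, emitting atomic behavior events
*A = E(id, ab, ts, te)* with *ts < te*:

* *repeat* rules (C1): an unbroken run of at least two identical postures —
  Walking ← Walk, Lying ← Lie, Sitting ← Sit, Standing ← Stand,
  Digging ← Dig, Escaping ← Jump, Barking ← Bark;
* a *follow* rule (C2): Sniffing ← body (Walk ∨ Stand) → head Down.

Matched posture events are consumed per output class, so four seconds of
Walk yield exactly two Walking events.

**Level 3 — symptomatic complex behaviors (15 s).** For each tumbling 15-s
observation window, an aggregation rule per complex behavior
(Destructive ← {Escaping, Digging}, Exploratory ← {Walking, Sniffing},
Vocalization ← {Barking}) computes the *coverage fraction* f ∈ [0, 1] — the
share of the window covered by the union of the related atomic-behavior
intervals. A Mamdani fuzzy system with input sets {Seldom, Consistent,
Most} over f, output sets {Normal, Abnormal} over a diagnosis index on
[0, 3], min-implication, max aggregation and center-of-gravity
defuzzification

&nbsp;&nbsp;&nbsp;&nbsp;index = ∫ x·μ(x) dx / ∫ μ(x) dx

turns f into a crisp index, thresholded per behavior (vocalization > 1.0,
destructive and exploratory > 1.5) into the symptom state of the emitted
event *C = E(id, cb, d, ts, te)*.

Evaluation uses per-class precision = TP/(TP+FP), recall = TP/(TP+FN),
F1 = 2PR/(P+R) and their unweighted macro average, with interval matching
(>50% overlap of a truth event) at Levels 2–3.

Because no public dog recordings exist, the package ships a seeded
synthetic-scenario generator: per-posture 50 Hz signal templates
(orientation baseline + oscillation + Gaussian noise) and scripted behavior
timelines that expand into both sensor streams plus ground truth at all
three levels.

## Worked example

Simulate an SA episode, run the behavior hierarchy on its posture stream,
and score the result:

```r
library(sawatch)
library(dplyr)

scenario <- script_to_streams(scenario_preset("sa_episode", seed = 7))
filter(as_tibble(scenario$truth$l3), d == "Abnormal")
#> # A tibble: 7 × 5
#>   subject_id behavior     d           ts    te
#>   <chr>      <chr>        <chr>    <dbl> <dbl>
#> 1 dog1       Exploratory  Abnormal    15    30
#> 2 dog1       Exploratory  Abnormal    30    45
#> 3 dog1       Vocalization Abnormal    45    60
#> 4 dog1       Destructive  Abnormal    75    90
#> 5 dog1       Destructive  Abnormal    90   105
#> 6 dog1       Exploratory  Abnormal   120   135
#> 7 dog1       Destructive  Abnormal   135   150
```

The 150-s scripted scenario contains seven symptomatic 15-s windows; the
remaining windows are Normal. Rerunning the hierarchy on the Level-1 stream
reproduces the truth exactly:

```r
res <- run_hierarchy(scenario$truth$l1, t_end = scenario$duration)
render_metrics_table(evaluate_events(scenario$truth$l3, res$l3, 3))
#> Category                       Num. Precision   Recall F1-Score
#> Destructive/Abnormal              3    1.000    1.000    1.000
#> Destructive/Normal                7    1.000    1.000    1.000
#> Exploratory/Abnormal              3    1.000    1.000    1.000
#> Exploratory/Normal                7    1.000    1.000    1.000
#> Vocalization/Abnormal             1    1.000    1.000    1.000
#> Vocalization/Normal               9    1.000    1.000    1.000
#> Average                                1.000    1.000    1.000
```

The fuzzy diagnosis is inspectable at every step. A behavior covering 30%
of an observation window fuzzifies to half Seldom, half Consistent, and its
defuzzified index lands between the two decision thresholds:

```r
fuzzify(0.3)
#> # A tibble: 3 × 3
#>       f set        degree
#>   <dbl> <chr>       <dbl>
#> 1   0.3 Seldom        0.5
#> 2   0.3 Consistent    0.5
#> 3   0.3 Most          0

diagnose(c(0.1, 0.3, 0.8), "Vocalization")
#> # A tibble: 3 × 4
#>   behavior         f index d
#>   <chr>        <dbl> <dbl> <chr>
#> 1 Vocalization   0.1 0.542 Normal
#> 2 Vocalization   0.3 1.51  Abnormal
#> 3 Vocalization   0.8 2.22  Abnormal
```

An index of 0.542 is the centroid of the pure-Normal output set: a behavior
seen 10% of the time is unremarkable, while 30% already exceeds the
vocalization threshold of 1.0.

To put the classifier in the loop, train on synthetic windows and classify
the raw streams before the hierarchy:

```r
ts <- synthetic_training_set("body", windows_per_class = 100, seed = 11)
model <- build_model(classifier_config("body"))
model <- train_posture_model(model, ts$x, ts$labels, training_config(seed = 11))
tidy(model)      # per-fold precision/recall/F1
events <- classify_stream(scenario$body, model, stats = ts$stats)
```

A command-line wrapper with `simulate`, `train`, `classify`, `detect`,
`diagnose` and `evaluate` subcommands is available at
`inst/cli/sawatch.R` (see `cli_main()`).

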