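---
title: "Detecting state-dependent social sequences in grouped mice: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting state-dependent social sequences in grouped mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialseq)
```

## The problem

When two male and two female mice share an arena for several hours, the
males fight. A male that has just been chased or fled (the *aggressed*
state) behaves differently from the male that chased him (the *aggressor*
state): aggressed males tend to approach a female quickly and briefly, and
the aggressor then often engages the *same* female — a "bait-and-switch"
that is followed by markedly fewer fights. `socialseq` implements the full
chain of analyses needed to quantify this phenomenon from tracked poses:
interaction detection, triggered-sequence extraction, circular statistics,
permutation controls, and decoding — together with a simulator that plants
the effect with known parameters so every stage can be validated.

## Data model

A recording is a `recording_bundle`: an arena (default 76.2 × 76.2 cm at
30 frames/s), a table of mice (two of each sex), a dense pose table (one
fitted ellipse per mouse per frame: centroid, orientation, semi-axes, nose
position, all in cm), and a table of labeled behavior events (chase, flee,
walk, investigate, fight) with half-open `[start, end)` 0-based frame
intervals. Chases and flights carry discernible roles: the chasing (or
fled-from) male is the aggressor, the chased (or fleeing) male the
aggressed. Coordinates have their origin at the lower-left arena corner.

## Interaction detection

Each pose is dressed with a *social ellipse*: the body ellipse with the
semi-major axis lengthened 3 cm at each end (front and back), minor axis
and center unchanged. Two mice interact socially in a frame when their
closed social ellipses intersect, and a bout is a maximal run of at least
6 consecutive overlap frames (0.2 s at 30 fps); no gap-merging is applied.
Overlap is decided by a separating-axis test on 64-gon polygonal
approximations, with two exact center-distance bounds short-circuiting the
clearly-separated (distance above the summed semi-majors) and
clearly-touching (below the summed semi-minors) cases. The 64-gon was
preferred over the algebraic quartic-discriminant test for robustness and
auditability; the test suite checks it against a brute-force
10^4-point boundary-membership oracle on 1,000 random pairs, excluding
only configurations within 0.01 cm of tangency (none arise at the tested
seed). A centroid-distance detector (separation ≤ 6 cm, one body length)
is available behind `method = "centroid"` for sensitivity analyses, since
the two published descriptions (ellipse overlap in the methods, "within
3 cm" in the results) are not identical; the ellipse construction is
treated as canonical.

## Triggered sequences

For each aggressive trigger, the sequence extractor takes the earliest
male–female bout starting at or after the trigger's onset and before the
next trigger's onset, so every bout is attributed to at most one trigger.
Latency is the bout start minus the trigger *end* (in seconds) and may be
negative when socialization begins while the chase is still running; the
attribution window deliberately has no absolute latency cap. Partner state
is *aggressed* or *aggressor* according to which male met the female;
walks and investigations serve as nonaggressive triggers with
walker/non-walker and investigator/investigated labels, subsampled to
match the aggressive sample size (`control_triggers`).

Three-step sequences extend a triggered sequence with the next bout by
*either* male before the next trigger. When the two bouts involve
different males they are typed by who went first and whether the second
bout involves the same female: type 1 = aggressed then aggressor with the
same female (the bait-and-switch), type 2 = aggressor then aggressed, same
female; types 3 and 4 are the other-female versions. Repeat bouts by the
same male are excluded from typing and counted. Fights are attributed to
a sequence when they start after the second bout and before the next
trigger (a fixed horizon is available via `horizon_s`).

## Circular statistics and the initiator

The angle between a male's heading (center → nose) and the direction to a
female (center → female center) is the two-argument arctangent of the
cross-product magnitude and dot product, always in `[0, π]`. Orientation
differences are wrapped to `(-π, π]`. The circular median minimizes the
mean arc-length distance over the sample (ties to the smallest angle);
circular variance is one minus the mean resultant length. Two circular
distributions are compared with Watson's two-sample U² on the pooled
empirical distribution functions (tie-weighted), with significance from
random label permutations — `p = (1 + #{U² ≥ observed}) / (1 + B)` — so
every sample size is handled uniformly; the statistic is exactly invariant
under a joint rotation of both samples.

Bout initiators follow two rules in order: if exactly one partner's
instantaneous speed at bout onset is below 0.023 cm/s (the published
stationarity threshold — implausibly slow at ≈0.0008 cm/frame, so kept
configurable), the moving partner initiated; otherwise the animal whose
*front* half-ellipse (nose side of the minor axis) first overlaps the
partner's social ellipse initiated, with a *mutual* label when the two
front overlaps begin within 6 frames of each other and both animals head
toward each other (angle < π/2). Both-stationary and
no-front-overlap cases are *undetermined*: the published rules do not
cover them. Zone latencies use five 6 cm circles — the arena center and
the four midpoints between the center and the wall midpoints; the paper
names the zones but not their coordinates, so these are package defaults
and configurable.

## Resampling and decoding

The *difference index* is
`(n_aggressor_partner − n_aggressed_partner) / total`; negative values
mean aggressed males dominate post-aggression interactions. Two
permutation suites guard it: (1) drawing 50 sequences per recording
without replacement, 1,000 times, and testing the index distribution
against zero (`z = mean/sd`); (2) flipping each trigger's role assignment
with probability ½ (order and durations kept), recomputing the index
1,000 times, and comparing the observed index to that null. A
recording-level flip variant is available.

Behavioral state is decoded from latency and duration with an axis-aligned
decision tree (`rpart`, minsplit 2, minbucket 1, no complexity penalty —
hyperparameters are unstated in the source material, so the most
permissive impurity-based tree is used and recorded in the configuration)
over 1,000 random 75/25 train/test splits; accuracy distributions are
compared to 50% chance with a one-sided `z = (mean − chance)/sd`. The
paper never prints that formula; using the distribution's sd (not sd/√n)
reproduces the order of the printed z magnitudes, and the alternative is a
one-line change. Controls: *size-matched* subsamples the majority class to
the minority size each iteration; *time-randomized* redraws the trigger
start times uniformly (durations kept) and re-extracts the sequences each
iteration, destroying the temporal linkage. Multiclass targets (hour of
occurrence, chance 20%; sequence type from inter-individual distances,
chance 25%) use a linear-kernel support-vector machine with the native
one-vs-one ensemble.

Phase-normalized distance profiles split each typed sequence into four
phases (aggression, gap, first interaction, 5 s post-interaction), and
linearly interpolate each instance's dyad-distance series onto a grid as
long as the longest instance of that phase, preserving endpoints;
zero-length gaps (non-positive latency) are skipped in aggregation. Point
read-outs are taken at interaction start + 1 s and 1/2/3 s after the end.

## The simulator

`synthetic_config()`/`generate_recording()` produce recordings with
planted ground truth. Baseline locomotion is an Ornstein–Uhlenbeck speed
process (stationary mean 6 cm/s, sd 2 cm/s, relaxation 1 s, clipped at
zero) with heading diffusion (1.5 rad²/s) and triangle-wave folding at the
walls; headings point along the direction of travel and the nose sits one
semi-major axis ahead of the centroid. No quantitative movement model is
published for these data, so the OU baseline is a stand-in chosen for its
stationarity and tunability — it is not claimed to match real murine
kinematics, and passing tests validate the *pipeline*, not realism.

Scripted kernels override the baseline: chases steer the aggressor behind
the running aggressed male (gap below two body lengths throughout), flees
freeze the aggressor while the aggressed sprints away, fights co-locate
both males at high speed, investigations bring the males into contact at
low speed. After each aggressive bout, each male independently approaches
a uniformly chosen female with his state's probability
(`p_approach_aggressed`/`p_approach_aggressor`), after a state-specific
log-normal latency, holding contact (2 cm center offset, inside mutual
ellipse reach for any orientation) for a state-specific duration. A
follow-up interaction by the other male targets the same female with
probability `p_follow_same_female` (aggressed-first case) or
`p_follow_same_female_alt` (aggressor-first), and a fight follows a
completed three-step sequence with a type-dependent probability.

Defaults are calibrated once to the printed effect sizes: approach
probabilities 0.47/0.45 with latency medians 1.2 s/4 s (log-sd 0.8)
jointly give ≈62% aggressed-partner sequences and a difference index near
−0.25; interaction-duration medians 1.5 s/3 s give the shorter aggressed
interactions; the two same-female probabilities 0.85/0.55 reproduce type
shares near 53/21/9/17%. Aggressive bouts sit on a renewal grid (default
40/h) whose pitch exceeds the worst-case span of a full triggered block,
so blocks never overlap and — because each block consumes a fixed number
of random draws — effect-mode and null-mode runs at the same seed share
the same aggressive-event schedule. `null_mode = TRUE` equalizes every
state-dependent parameter at its mean.

In the default *noise-free* mode, males and females keep to disjoint home
regions joined by approach corridors, and the target female pauses during
an approach episode until the male has retreated out of ellipse reach.
This guarantees the planted episodes are the only male–female contacts —
a property the exact-recovery tests require — at the cost of realism:
males then never encounter females by chance, walks are not strictly
solitary, and planted latencies are all positive (negative latencies,
which the extractor supports, are exercised by constructed fixtures
instead). With `noise_free = FALSE` all mice roam the whole arena and
incidental contacts occur; the zone-latency analyses use this mode.
Ground-truth interaction intervals are realized by evaluating the same
ellipse-overlap geometry on the generated poses within the episode
window, so planted frames are exactly what any correct detector sees; the
geometry itself is validated independently against the brute-force oracle.
Schedule-level generation (`poses = FALSE`) skips trajectory synthesis and
treats the scheduled episodes as the interaction table — two orders of
magnitude faster, used for the statistical replicate studies.

## Numerical and design notes

- Frames are 0-based, intervals half-open; durations are `(end − start)/fps`.
- The speed at frame 0 is backfilled from frame 1 rather than left `NA`.
- Exploration grids tile the bounding box from the origin; partial edge
  bins count in the denominator for rectangles, center-inside bins for
  circles. Bin areas 9/36/81 cm² are the published sizes.
- The aggression score follows the published formula
  `(count_male2 − count_male1)/total` with a 1-df chi-square
  goodness-of-fit test against equal counts; it is antisymmetric under
  swapping the male order and undefined (flagged) without aggressive events.
- Post-hoc event refinement applies the published per-label thresholds
  verbatim and strictly (`>`/`<`); "trajectories overlapping by at least
  20%" is read as the fraction of chase frames in which the chaser passes
  within 2 cm of the chased male's bout path, and classifier scores are
  opaque inputs, never recomputed. Some printed thresholds (the
  investigate speed band, the 0.04 cm distance) have implausible units;
  they are applied as printed and every threshold is configurable.
- Wilcoxon signed-rank on identical paired samples returns W = 0, p = 1
  (the test statistic degenerates); Kruskal–Wallis post hoc pairs use
  Dunn's rank z-tests with Šidák family-wise correction, and a Bonferroni
  α utility covers the zone comparisons.
- Watson-U² permutation counts use a 10⁻¹² slack when comparing permuted
  statistics to the observed one so ties from identical samples count
  conservatively.

## Problem sizes used by the tests

The suite validates geometry on 1,000 random ellipse pairs against a
10⁴-point oracle; exact planted recovery on five 30-minute noise-free
recordings; effect recovery on an 11-recording, 5-hour schedule-level
cohort with approach probabilities 0.8/0.2 (all 1,000 subsample indices
negative, shuffle p < 0.001) and null calibration over 100 replicate
cohorts (≤ 8% rejections at α = 0.05); decoder behavior on a 3-recording
cohort (observed above chance, time-randomized within 2 sd of chance);
three-step typing on hand-built streams plus ≥ 500 planted sequences at
`p_follow_same_female = 0.53`; and decoder type-I error over 200
schedule-level null replicates. These sizes are the package's own choice
of a desk-scale validation; the published cohort (11 five-hour recordings
with poses) is reproducible with the same functions given more compute.

## Known limitations

- The simulator's noise-free geometry is deliberately artificial (home
  regions, paused females); statistical conclusions about *real* data
  require the deposited recordings, which are outside this package.
- Negative-latency sequences and same-sex interaction bouts are supported
  by the analysis but not planted by the generator.
- The initiator rules mirror the published description; cases the
  description does not cover are labeled `undetermined` rather than
  guessed.
- Zone centers and several refinement-rule units are unstated in the
  source material; the defaults here are documented choices, all
  configurable.
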