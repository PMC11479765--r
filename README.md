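# socialseq

Trajectory-based analysis of social behavior sequences in mixed-sex groups
of mice.

When two male and two female mice interact freely, male–male aggression
creates two transient behavioral states: the **aggressor** (the chasing or
fled-from male) and the **aggressed** (the chased or fleeing male).
`socialseq` quantifies how those states shape what happens next — in
particular the *bait-and-switch* sequence in which the aggressed male
briefly engages a female immediately after an aggressive encounter and the
aggressor then engages the **same** female, a pattern associated with far
fewer subsequent fights. The package is for behavioral neuroscientists and
computational ethologists working with multi-animal pose tracking
(ellipse fits at ~30 frames/s) and classifier-labeled behavior events.

## What it computes

- **Social interactions.** Each pose ellipse is extended 3 cm front and
  back into a *social ellipse*; a male–female interaction (SI) is a maximal
  run of ≥ 6 frames (0.2 s) in which the two social ellipses overlap
  (64-gon separating-axis test, validated against a dense membership
  oracle).
- **Aggression-triggered sequences.** For each aggressive trigger, the
  first SI before the next trigger, with latency
  `(SI start − trigger end)/fps` (negative allowed) and duration; partner
  state per trigger roles. Walks and investigations give size-matched
  nonaggressive controls.
- **Three-step taxonomy.** The next SI by the other male types the
  sequence: type 1 (aggressed→aggressor, same female; the bait-and-switch),
  2 (aggressor→aggressed, same female), 3 and 4 (other female), plus
  fight attribution after the second SI and phase-normalized dyad-distance
  profiles across aggression/gap/SI/post phases.
- **State dependence.** The difference index
  `(n_aggressor − n_aggressed)/(n_aggressor + n_aggressed)` with a
  50-per-recording subsampling distribution and an identity-shuffle
  permutation null; decision-tree decoding of partner state from latency
  and duration over 1,000 random 75/25 splits with one-sided
  `z = (mean − 50)/sd`, under observed, size-matched, and time-randomized
  conditions; multiclass (one-vs-one linear SVM) decoding of hour and
  sequence type.
- **Kinematics.** Heading-to-female angles `atan2(|v1 × v2|, v1·v2)`,
  circular median/variance, Watson's two-sample U² with permutation
  p-values, SI initiator assignment (stationarity at 0.023 cm/s, then
  front-half-ellipse-first-overlap), and zone latencies.
- **Synthetic arena recordings.** An Ornstein–Uhlenbeck random-walk
  simulator with scripted behavior kernels plants ground-truth events,
  interaction episodes and sequence types with tunable effect sizes and a
  null mode, so the whole pipeline is testable without video data.

## Worked example

```r
library(socialseq)

cfg <- synthetic_config(duration_s = 1200, rate_aggressive_per_h = 55)
rec <- generate_recording(cfg, seed = 42)     # 20 min, 4 mice, 30 fps
b   <- rec$bundle

si   <- detect_interactions(b)                # social-ellipse bouts
trig <- b$events[b$events$label %in% c("chase", "flee"), ]
sq   <- extract_triggered_sequences(trig, si, fps = 30)
ts   <- classify_three_step(sq, si, trig)

cat(sprintf("%d aggressive bouts, %d male-female bouts, %d triggered sequences\n",
            nrow(trig), nrow(si), nrow(sq)))
cat(sprintf("aggressed-partner share: %.0f%%; median latency %.2f s\n",
            100 * mean(sq$partner_state == "aggressed"), median(sq$latency_s)))
table(ts$sequence_type)
difference_index(sq)
```

prints

```
17 aggressive bouts, 20 male-female bouts, 10 triggered sequences
aggressed-partner share: 70%; median latency 2.08 s

1 2 4
7 1 2
[1] -0.4
```

Seventeen aggressive bouts yielded ten triggered sequences; seven of ten
typed sequences are bait-and-switch (type 1), the aggressed male met the
female first in 70% of them, and the difference index of −0.4 points the
same way (negative = aggressed majority). On this noise-free recording the
detector recovers exactly the planted episodes, so these numbers reflect
the generator's planted effect.

The `analysis/` directory holds the full workflow as numbered drivers —
`01_simulate.R` (cohorts), `02_detect.R` (detection, initiators,
exploration, refinement), `03_sequences.R` (triggered sequences and
controls), `04_state_dependence.R` (index permutations and decoders),
`05_three_step.R` (typing, profiles, fight association) — each writing
its tables under `results/`.

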