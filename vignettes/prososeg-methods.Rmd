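---
title: "Detecting prosodic phrase boundaries from forced-alignment timings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting prosodic phrase boundaries from forced-alignment timings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous conversation is produced in short prosodic phrases — intonation
units — of roughly one second and three to four words, delimited by a
battery of acoustic cues: the speaker slows down on the unit's last word
(pre-boundary lengthening), accelerates into the next unit, often pauses,
and resets the pitch that declined across the unit. Segmenting speech into
these units is easy for the human ear and stubbornly hard to automate;
most published detectors need acoustic feature stacks, syntactic models, or
supervised training.

`prososeg` implements a deliberately minimal, training-free alternative:
given only the word and phone timings a forced aligner already produces, it
places boundaries at word onsets flagged by *discontinuities in speech rate*
(DSRs) or by *silent pauses*. Everything else in the package exists to
validate that choice: boundary-agreement scoring against a manual
segmentation, pitch-declination and reset statistics over the resulting
phrases, positional duration and word-frequency profiles, and a seeded
generator of synthetic conversations with known ground truth so the whole
pipeline is testable without any corpus download.

## The detector

**Local speech rate.** For every word onset $t_0$ in a turn, the rate is

$$ r = \frac{1}{\langle d_{\text{phone}} \rangle}, $$

the inverse of the mean duration of the phones whose midpoints fall in the
window $[t_0, t_0 + W)$, with $W = 300$ ms by default — about one word.
Only phones enter the average, so silence inside the window is excluded by
construction. Anchoring windows at word onsets encodes the method's one
structural assumption: a phrase boundary cannot occur inside a word. Words
whose window captures no phone (out-of-dictionary tokens without phone
timings, followed by silence) get an *undefined* rate; consecutive
differences are then taken between nearest defined neighbours rather than
silently zeroed.

**Two-pass thresholding.** Within a turn, the differences
$d_i = r_i - r_{i-1}$ are compared against $\theta_1 \cdot \max_i d_i^{+}$
with $\theta_1 = 0.88$; every strictly exceeding difference marks a
boundary at that word's onset (pass 1). Because the threshold is relative,
the argmax itself always exceeds 88% of itself, so any turn with a positive
difference yields at least one DSR. Stretches between consecutive
boundaries (turn edges acting as virtual boundaries) that last more than
3 s *and* hold more than 10 words are re-thresholded once at
$\theta_2 = 0.70$ of the stretch's own largest positive difference
(pass 2); there is no further recursion.

**Pauses and merging.** Every inter-word gap strictly longer than
$\Delta_{\min} = 300$ ms marks a boundary at the following word onset.
When the same word is flagged by both cues, the boundary is attributed to
speech rate. Phrases run from a boundary to the last word before the next
one, ending at that word's *end*, so trailing silence belongs to no phrase.
Turns with fewer than `min_turn_words = 2` words are returned as a single
phrase flagged `excluded` — backchannels are not segmented.

### Numerical choices

* Differences are signed: only accelerations (positive $d_i$) can be DSRs.
  The slow-down into a final word is the *precursor* of the jump, not the
  jump itself. For the alternative reading, `signed_diffs = FALSE`
  thresholds absolute differences.
* All threshold comparisons are strict (`>`), including the word-count and
  duration gates of pass 2 and the pause rule; ties at the maximum
  difference are all flagged (each exceeds 88% of the shared maximum).
* Phone-in-window membership is decided by the phone midpoint, which is
  robust to the aligner's 10 ms rounding at word edges; the same midpoint
  rule attaches phones to words when reading TextGrids.
* Stretch duration in pass 2 is measured first word onset to last word end,
  excluding trailing silence.
* The detector is fully deterministic: repeated runs on the same input are
  byte-identical, which the test suite asserts on serialized JSON.

## Evaluation protocol

The evaluation universe is one binary slot per onset of words $2..n$ of
each multi-word turn; the slot before a turn's first word is trivially a
boundary and is excluded, which also removes every slot following a speaker
change. Reference phrase-start times are matched to slots within a
tolerance (default 50 ms, five times the aligner resolution) by greedy
nearest-first matching, each slot and each reference boundary used at most
once and distance ties resolved toward the earlier reference boundary.
Phrase starts matching no slot — turn starts, or positions the detector
cannot express — lie outside the universe, which keeps
$TP + FP + FN + TN$ equal to the number of scored slots exactly.

By default only *multi-unit* turns (turns where the reference itself holds
at least two units) are scored, the protocol under which the method was
designed; single-unit turns inevitably receive one spurious relative-maximum
boundary and were excluded from the method's published evaluation. Pass
`multi_unit_only = FALSE` for the plain multi-word-turn universe.

From the confusion counts the package derives precision, recall, F-score,
accuracy, and Cohen's kappa on the binary slot labels. Chi-square tests of
independence (Yates-corrected for 2×2) expose their expected-count tables;
the genre and finality contrasts are built on them. Recall by finality
labels each internal boundary with the finality of the unit it terminates;
units followed by speaker change carry no internal boundary and drop out by
construction.

## Pitch statistics

Pitch never participates in detection; it is the independent check that
detected phrases behave like intonation units. Supplied pitch tracks are
post-processed per speaker stream: snapping to the stream's native sample
grid, a 5-sample running median (spike removal; the filter length is a
package choice), linear interpolation across unvoiced gaps whose flanking
voiced samples are closer than 25 ms, and a 25 ms Hamming-window moving
average whose weights are renormalized over available samples, so constant
contours pass through unchanged and longer gaps stay missing.

Each phrase's contour is resampled at 40 equally spaced points of
normalized time (linear interpolation, edge values held) and divided by its
own mean, so every accepted contour has mean exactly 1 — dividing by the
phrase mean rather than a speaker-level statistic keeps the phrase the unit
of analysis; per-speaker normalization can be layered on top by the caller.
Phrases with fewer than 4 voiced samples or more than 50% unvoiced samples
are rejected rather than imputed.

The summary statistics follow the declination/reset logic: the mean
normalized contour per file, the across-phrase standard deviation per file,
window means at $t \in [0.15, 0.25]$ (just after the reset peak) versus
$t \in [0.85, 0.95]$, variability at $t \in [0.9, 1]$ versus the first
half, and paired one-sided t-tests across files. When the per-file
differences are identically zero (flat contours) the t statistic is
undefined and the package reports $p = 1$ rather than erroring. The
`random_phrase_spans()` negative control chops each speaker stream into
exponentially distributed spans; averaging contours over such arbitrary
spans flattens the mean curve, and the test suite asserts the random-span
begin-end contrast stays below a third of the true-segmentation effect.

## Lexical and duration statistics

Durations by position from the phrase end are computed per audio file and
aggregated across files (mean ± s.e.m.), over phrases of 2-20 words.
Phrase length and duration histograms use 0.25 s duration bins; the
exponential tail is fitted by least squares of log counts against bin
midpoints from 1.0 s outward, *weighted by the counts* — the log of a
Poisson count has variance roughly $1/N$, and unweighted fitting lets
stray single-count far-tail bins flatten the slope materially. The fitted
time constant is the negative inverse slope. Degenerate tails (fewer than
three occupied bins, no decay, or fewer than 100 phrases) are flagged, not
fitted.

Word labels are case-folded and stripped of annotation marks for the
positional frequency tables (original labels are preserved in the
alignment); `<unk>` tokens always count toward position totals and appear
in the ranked lists by default (`include_unk = FALSE` hides them). Group
error bars come from splitting the corpus files into `n_groups` (default 3)
and treating each group as one measurement; a word absent from a group
contributes probability zero to that group's moment.

## The synthetic-conversation generator

The generator is a pure function of `(config, seed)` and encodes the study
conditions the package is validated under:

* **Phrase lengths** are `1 + Geometric`, mean 4.1 words. This single
  choice reproduces two further observed features: about 24% single-word
  units (close to the ~20% share reported for conversational English), and
  an exponential tail of phrase durations with time constant
  $-\,0.201\,/\,\ln(1 - 1/4.1) \approx 0.72$ s, in the 0.68-0.73 s range
  measured on real conversation.
* **Word durations** are lognormal with mean 201 ms (sd 7 ms) for middle
  words and 356 ms (sd 28 ms) for final words — the narrow distributions
  measured on manually segmented units. First words of multi-word phrases
  are 15% shorter. Single-word units are built final-like: long, slow, and
  carrying *no* initial acceleration, so their left boundary is invisible
  to the rate cue — a deliberate, realistic hard case.
* **Phones** tile each word exactly: the count is the word duration over a
  target phone duration (74 ms middle, 118 ms final, first-word targets
  shortened 15%), clamped to 2-6, with near-even random splits. Deriving
  the count from the duration is what lets the word-level and phone-level
  targets hold simultaneously; integer quantization leaves the realized
  middle-phone mean near 67-72 ms while the closing-phone 118 ms target is
  matched. Final lengthening therefore lives in *slower phones*, which is
  what the rate window sees; the `finality_effect` multiplier (default 1 —
  off) scales both the final word and its phone target for units high in
  the prosodic hierarchy.
* **Pauses**: a silent pause of $0.35 + \mathrm{Exp}(0.25)$ s follows 75%
  of internal boundaries — the unit definition used by human transcribers
  lists the pause as a typical boundary cue, and with a quarter of
  boundaries opening single-word units this rate sets the detectability
  ceiling consistent with the package's design goal of near-complete
  recovery on clean input. Within phrases, 8% of word junctions carry a
  brief hesitation gap of $0.03 + \mathrm{Exp}(0.06)$ s; these almost never
  exceed 300 ms, which is exactly why 300 ms is the optimal pause threshold
  in the sweep.
* **Pitch**: per-speaker baselines are uniform on 120-220 Hz; each phrase
  rises from the previous unit's end level to a peak at normalized time 0.2
  and declines linearly so that the value at $t = 0.9$ is $1 -$
  `decline_frac` (default 0.15) of the peak, with 2% multiplicative sample
  noise at 10 ms spacing.
* **Lexicon**: a 50-word function-word-heavy lexicon with a phrase-initial
  bias; "and" opens exactly 10% of phrases.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real recordings: emphasis-driven slow-downs
unrelated to boundaries (the main noise source in real speech), isorhythmic
stretches, disfluencies and truncated words, overlapping speech, boundary
tones and the elevated pitch variability at unit ends, octave errors and
unvoiced stretches in pitch tracks, and annotator disagreement in the
reference. Real-corpus agreement for this family of methods is therefore
substantially lower (F around 0.6-0.7) than the ~0.92 the clean synthetic
corpus permits.

## Problem sizes

The default corpus is 12 files × 40 turns (≈1,400 phrases, ≈5,900 words),
which the package's tests and the acceptance script use for detection,
sweep, pitch, and lexical statistics; parameter-recovery checks that need
tighter standard errors scale up (10⁴ phrases for the final-word mean,
5,000 draws for the tail fit, 1,000 random turns for the brute-force
equivalence check). These sizes were chosen so each analysis has the
precision its assertion needs.

## Known limitations

* The relative (88%-of-max) threshold guarantees a boundary in every turn
  it touches: genuinely single-unit multi-word turns receive one spurious
  boundary. The published protocol excluded such turns; the evaluator's
  `multi_unit_only` default mirrors that.
* Long isorhythmic units that satisfy the pass-2 gates are over-segmented,
  since pass 2 also thresholds relative to the stretch's own maximum.
* Boundaries into single-word units carry no rate discontinuity; without a
  pause they are undetectable by design.
* The pause rule depends on the aligner's silence timing; hesitation
  silences above 300 ms become false boundaries.
* Kappa is computed on word-onset slots; agreement figures computed on
  boundary events rather than slots are not comparable.
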