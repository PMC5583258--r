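---
title: "Classifying mother-infant vocal exchanges around nest reunions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying mother-infant vocal exchanges around nest reunions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalexchange)
```

## The analysis problem

In infant-parking mammals the mother repeatedly leaves her nest-bound
infants to forage and returns to them, producing many natural
separation/reunion episodes per night. The question this package
operationalizes is whether the vocal behaviour around those episodes has
greeting structure: calling that is concentrated at reunions rather than
leave-takings, reciprocal (both partners call within the same short
window), predictable in sequence, and initiated by the returning mother.

The package works entirely on *annotated* data: a table of call events
(onset/offset in seconds, caller role, call type) and a table of nest
stays (entry/exit per individual). Audio or video processing — call
detection, call-type identification, occupancy scoring — is out of scope;
those annotations are the input, exactly as a human observer would
produce them from spectrograms and video.

## Observation intervals

Two kinds of one-minute windows are anchored to the mother's movements:

* **Reunion**: `[entry − 10 s, entry + 50 s)`. The window reaches 10 s
  before the entry because mothers typically sit in front of the nest
  and call inward before they are fully inside; on the window-relative
  time axis the entry therefore sits at t = 10 s.
* **Leave-taking**: `[exit − 60 s, exit)`.

Eligibility filters keep only informative windows: the mother must have
been absent at least 180 s before a reunion (so the separation was long
enough to make a reunion an event) and present at least 120 s before a
leave-taking (so there was a joint period to leave from), and at least
one infant must overlap the window. All windows under the default
configuration are exactly 60 s, and a reunion window can never overlap a
leave-taking window (the 120 s presence floor exceeds the 50 s
post-entry span).

Several conventions here are genuinely open choices, fixed once and
tested as such:

* Windows are **half-open** `[start, end)` and a call belongs to a
  window iff its *onset* lies inside. This prevents double counting
  between adjacent windows and makes membership independent of call
  duration.
* Both eligibility thresholds are **inclusive** (an absence of exactly
  180 s qualifies), reading "at least" literally.
* The absence before the first recorded entry is measured **from the
  session start** — conservative, since the true prior absence is
  unknown and can only be longer.
* Whether the infant must be present for the whole window or any part
  of it is unknowable from published descriptions; the package requires
  **any positive overlap**, the strictest condition computable from the
  stay table.
* If the mother exits again within 50 s of entering, the reunion window
  is kept at full length: it is defined by the entry alone.
* Times are held at **millisecond resolution**. Annotation tools work
  comfortably above this, and 25 fps video cannot resolve below 40 ms,
  so nothing real is lost; ms is also the resolution at which two first
  onsets count as a tie.

## Exchange classification

Within a window, caller roles are ordered by onset and consecutive
same-role calls are collapsed into *bouts*; the collapsed sequence
alternates by construction. On it:

| pattern | definition | example |
|---|---|---|
| reciprocal | both roles called | M,M,I → MI |
| sequential | alternating exchange of ≥ 3 bouts | M-I-M |
| antiphonal | alternating exchange of ≥ 4 bouts | M-I-M-I |

Antiphonal is deliberately a subtype of sequential (every 4-bout
alternation contains a 3-bout one); both percentages are reported
side by side. Whether published sequence counts were computed on raw
calls or collapsed bouts is not stated anywhere we could check;
bout-collapsing was chosen because it makes patterns like M,M,I,M
unambiguous, and the classifier is verified against an exhaustive
enumeration of all 126 role strings up to length six.

The *initiator* is the role of the earliest call in a reciprocal window.
Identical first onsets (at ms resolution) are ties and are excluded from
the denominator of the mother-initiated percentage — an initiator
question presupposes distinct onsets. Families with no reciprocal
reunion windows get missing values, never zeros, in the
initiator/sequence/timing fields.

Per family and condition the summary layer reports the percentage of
windows with mother calls, infant calls and both; the sequential and
antiphonal percentages are computed over reciprocal reunion windows by
default (`sequential_denominator = "all"` switches to all reunion
windows — the published phrasing is ambiguous, so the choice is
explicit and configurable).

## Group statistics

Per-family percentages are compared between conditions with a paired
Wilcoxon signed-rank test implemented in the package: zero differences
dropped, mid-ranks for tied magnitudes, statistic `T` = smaller signed
rank sum. The asymptotic two-sided p-value is the normal approximation
*without* continuity correction,

$$p = 2\,\Phi\!\left(\frac{T - n(n+1)/4}{\sigma}\right),\qquad
\sigma^2 = \frac{n(n+1)(2n+1)}{24} - \sum_t \frac{t^3 - t}{48},$$

the convention under which `T = 0, N = 11` gives `p = 0.003` and
`T = 5, N = 11` gives `p = 0.013`. The exact p-value is computed from
the full distribution of the positive-rank sum over all $2^n$ sign
assignments, evaluated by convolution over the observed (possibly tied)
ranks, with doubled ranks so mid-ranks stay on an integer lattice:
$p = P(|W - n(n+1)/4| \ge |W_{obs} - n(n+1)/4|)$. The two agree closely
but not to two decimals at $n = 15$: omitting the continuity correction
leaves a half-lattice error of order $0.4/\sigma \approx 0.028$, which
the test suite bounds analytically rather than pretending it away.

Quartiles use R's default linear-interpolation convention (type 7),
configurable because quartile conventions differ across statistics
packages; quartile agreement with other software is therefore not a
validation surface. The initiator percentage is tested against the 50 %
chance level with the one-sample form of the same machinery (which is,
by construction, the paired test applied to `x − 50`).

The binomial GLMM stage (`outcome ~ condition + (1|family) +
(1|litter size)`) is a deliberate delegation to `lme4`: mixed-model
fitting is standard machinery, not this package's contribution. Litter
size has at most three levels, statistically marginal for a random
intercept, so non-convergence is a realistic outcome; it is reported as
a missing p-value with the optimizer's diagnostics attached, never
silently replaced. The stage is off by default and all headline
conclusions rest on the nonparametric tests.

## The synthetic-data generator

`simulation_config()` encodes the study design the package targets:
**11 families**, litter sizes drawn 1:7:3 over {1, 2, 3}, **24 h
sessions**. Infants stay in the nest for the whole session (the modelled
infants are ~10 days old and nest-bound). The mother alternates
exponential out-of-nest and in-nest bouts, by default with means
**600 s out / 360 s in** — about ten-minute foraging trips, which give
recordings a few dozen eligible windows per condition per night and keep
roughly three quarters of entries above the 180 s absence floor (real
bout distributions are unpublished; the exponential is a modelling
choice, and the eligibility fraction is asserted in the tests).

Calling is context dependent, with defaults chosen once to sit in the
regime the analysis assumes — high, mother-led reunion calling and
near-zero leave-taking calling:

* at each entry the mother calls with probability **0.85**, emitting
  `1 + Poisson(1)` trills at offsets uniform on **[−10, +20] s** around
  the entry (the approach phase);
* each trill is answered with probability **0.4** after a
  gamma(shape 2, mean **12 s**) latency;
* spontaneous infant calls arrive as a Poisson process at **0.002/s**
  (~7/h);
* a mother call precedes an exit with probability **0.05**.

Under these defaults a reunion window is reciprocal with probability
just above one half and mother calls precede infant calls by roughly
10–15 s, the qualitative pattern the analysis is designed to detect.
Responses are generated wherever their latency lands, even outside any
window: the generator and the analyzer stay decoupled, and windowing is
solely the analyzer's decision. Per-family RNG streams come from child
seeds `(seed + i·100003) mod (2³¹−1)`, so family `i`'s data do not
depend on how many families are simulated.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: acoustic structure (no waveforms, no
call-type confusion), infant identity (responses are not attributed to
littermates), non-exponential bout structure and diel rhythm, behavioural
states in which mothers linger at the entrance, and any dependence of
response probability on call order or timing beyond the fixed latency
distribution. One visible consequence: simulated initiator percentages
run near 90–100 % mother-first, higher than a real colony where infants
sometimes call spontaneously just before the mother, so initiator-level
statistics on synthetic data say little about real initiator rates.

## Validation strategy and problem sizes

Each layer is checked against an independent oracle: interval extraction
against a brute-force predicate scan over every entry/exit on 500
randomized sessions; classification against exhaustive enumeration of
all role strings up to length six; the exact signed-rank p against
explicit enumeration of all `2ⁿ` sign vectors; the asymptotic p against
the standard library implementation with continuity correction off; and
the full pipeline against a direct Monte-Carlo of the generative rules —
at 320,000 s per session (≥ 200 eligible reunions per family) the mean
per-family reciprocal percentage must land within five points of the
Monte-Carlo expectation. These sizes keep the complete suite under a
minute on one core while leaving each check statistically sharp.

## Known limitations

* Percentages are unweighted within family; families with few windows
  contribute noisier percentages, which the rank tests tolerate but do
  not model. The GLMM stage exists precisely to weight by window count.
* The exchange classifier ignores call *types* — any mother call counts,
  any infant call counts. Type-specific analyses (e.g. trills only)
  require pre-filtering the event table.
* With multiple infants pooled into one role, "reciprocal" means
  mother-plus-any-infant; true dyadic turn-taking per littermate is not
  recoverable from these inputs.
* Published initiator test values could not be reproduced from their
  reported statistic under any standard one-sample signed-rank
  convention we tried, so the one-sample machinery is validated against
  enumeration and closed forms instead of against that printed value.
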