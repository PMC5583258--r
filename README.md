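# vocalexchange

Analysis of mother-infant vocal turn-taking around nest reunions and
separations, built for infant-parking species such as the gray mouse lemur
(*Microcebus murinus*): while the mother forages, the infants stay at the
sleeping site, so every recording night contains many natural
leave-takings and reunions. The package asks whether the calling around
those events has the structure of a vocal greeting — reciprocal, mother-led
exchanges concentrated at reunions — and provides everything needed to test
that on annotated nest-box recordings or on synthetic data with known
ground truth.

## What it computes

Inputs are two plain tables: **call events** (one row per annotated
vocalization: onset, offset, caller role, call type) and **nest stays**
(entry/exit times of each individual). From these the pipeline derives:

1. **Observation intervals (OIs)** — 60 s analysis windows.
   *Reunion*: from 10 s before a mother's nest entry to 50 s after it
   (covering her approach phase), provided she was absent ≥ 3 min.
   *Leave-taking*: the 60 s before a nest exit, provided she was inside
   ≥ 2 min. Both require at least one infant in the nest. Windows are
   half-open `[start, end)`; calls belong to a window by onset.
2. **Exchange classification per OI** — with M/I the caller roles and
   consecutive same-role calls collapsed into bouts:
   *reciprocal* (≥ 1 mother **and** ≥ 1 infant call),
   *sequential* (alternating exchange of ≥ 3 bouts, e.g. M-I-M),
   *antiphonal* (≥ 4 bouts, e.g. M-I-M-I),
   *initiator* (role of the earliest call; tie if onsets coincide at ms
   resolution), and first/last call time per role.
3. **Per-family summaries** — for each family × condition the percentage
   of OIs with mother calls, infant calls, and reciprocal calling; over
   reciprocal reunion OIs the initiator, sequential and antiphonal
   percentages and mean call-timing landmarks.
4. **Group statistics** — paired Wilcoxon signed-rank tests between
   conditions on the per-family percentages, a one-sample signed-rank
   test of the initiator percentage against the 50 % chance level, and
   medians with interquartile ranges. The signed-rank machinery reports
   `T` (the smaller signed rank sum), uses mid-ranks for ties, drops zero
   differences, and offers the asymptotic two-sided p
   `p = 2Φ((T − n(n+1)/4)/σ)`, `σ² = n(n+1)(2n+1)/24 − Σ(t³−t)/48`,
   without continuity correction, or the exact p from the full `2ⁿ`
   sign-assignment distribution. An optional binomial GLMM
   (`outcome ~ condition + (1|family) + (1|litter size)`, via `lme4`)
   cross-checks the paired tests.
5. **Synthetic studies** — a point-process generator with alternating
   exponential absence/presence bouts, entry-triggered mother trill
   bursts, latency-distributed infant responses and Poisson baseline
   infant calling, emitting the same canonical CSVs plus per-entry ground
   truth for parameter-recovery tests.

## Worked example

```r
library(vocalexchange)

study <- simulate_study(simulation_config(seed = 1))   # 11 families, 24 h each
res   <- analyze_sessions(study$sessions)
res
#> <vx_analysis> 1463 OIs (741 reunion, 722 leave-taking), 11 families
#>   mother_calling         T =   0.00  N = 11  p = 0.00335
#>   infant_calling         T =   0.00  N = 11  p = 0.00335
#>   reciprocal_calling     T =   0.00  N = 11  p = 0.00335
#>   initiator_vs_chance    T =   0.00  N = 11  p = 0.00333
#>   timing_first_call      T =   0.00  N = 11  p = 0.00335

head(subset(res$summaries, condition == "reunion"), 4)[,
  c("family_id", "n_ois", "pct_mother", "pct_infant", "pct_reciprocal")]
#>   family_id n_ois pct_mother pct_infant pct_reciprocal
#> 2       F01    69      82.61      47.83          43.48
#> 4       F02    77      77.92      48.05          48.05
#> 6       F03    71      91.55      73.24          71.83
#> 8       F04    73      78.08      43.84          39.73
```

Every family calls more — and only here reciprocally — around reunions:
the median per-family reciprocal percentage is 52.5 % in the Reunion
condition versus 0 % at Leave-taking, and with all eleven paired
differences on one side the signed-rank statistic is `T = 0` with
asymptotic `p = 0.0033`. Mothers vocalize first (first-call landmark
around 10 s into the window, i.e. at the nest entry) and infants answer
some 10–15 s later.

Real annotated data enter through `read_call_events()` (canonical CSV or
an Audacity label track) and `read_nest_stays()`, then
`analyze_files(events, stays, ...)` writes the OI table, per-OI
classifications, family summaries and a JSON statistics report. A thin
command-line wrapper with `simulate` / `analyze` / `run` subcommands is
installed at `inst/cli/vocalexchange.R`.

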