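# One reusable session: mother out [0,100)+[... ,400), in [400,660], infant
# parked the whole time.
worked_session <- function(first_exit = 100, entry = 400, exit = 660,
                           duration = 1000) {
  stays <- nest_stays(
    session_id = rep("S1", 3), individual_id = c("mom", "mom", "inf1"),
    role = c("mother", "mother", "infant"),
    entry = c(0, entry, 0), exit = c(first_exit, exit, NA)
  )
  session("S1", "F1", 1, duration, call_events(), stays)
}

test_that("a qualifying entry yields the 60 s reunion window around it", {
  s <- worked_session()  # absence 400 - 100 = 300 >= 180
  ois <- extract_reunion_ois(s)
  expect_equal(nrow(ois), 1)
  expect_equal(ois$start, 390)
  expect_equal(ois$end, 450)
  expect_equal(ois$anchor_time, 400)
  expect_equal(ois$condition, "reunion")
})

test_that("entries after a short absence are ineligible", {
  s <- worked_session(first_exit = 250)  # absence 150 < 180
  expect_equal(nrow(extract_reunion_ois(s)), 0)
})

test_that("an interval requires an infant overlapping the window", {
  stays <- nest_stays(
    session_id = rep("S1", 3), individual_id = c("mom", "mom", "inf1"),
    role = c("mother", "mother", "infant"),
    entry = c(0, 400, 500), exit = c(100, 660, NA)  # infant arrives at 500
  )
  s <- session("S1", "F1", 1, 1000, call_events(), stays)
  expect_equal(nrow(extract_reunion_ois(s)), 0)   # window [390, 450)
  expect_equal(nrow(extract_leavetaking_ois(s)), 1)  # window [600, 660)
})

test_that("a qualifying exit yields the 60 s leave-taking window before it", {
  s <- worked_session()  # presence 660 - 400 = 260 >= 120
  ois <- extract_leavetaking_ois(s)
  expect_equal(nrow(ois), 1)
  expect_equal(ois$start, 600)
  expect_equal(ois$end, 660)
  expect_equal(ois$anchor_time, 660)
})

test_that("presence/absence thresholds are inclusive; short bouts drop out", {
  exactly <- worked_session(entry = 400, exit = 520)   # presence exactly 120
  expect_equal(nrow(extract_leavetaking_ois(exactly)), 1)
  expect_equal(extract_leavetaking_ois(exactly)$start, 460)
  short <- worked_session(entry = 400, exit = 490)     # presence 90 < 120
  expect_equal(nrow(extract_leavetaking_ois(short)), 0)
  edge_abs <- worked_session(first_exit = 220)         # absence exactly 180
  expect_equal(nrow(extract_reunion_ois(edge_abs)), 1)
})

test_that("windows that would precede the recording are dropped with a warning", {
  stays <- nest_stays(
    session_id = rep("S1", 2), individual_id = c("mom", "inf1"),
    role = c("mother", "infant"), entry = c(185, 0), exit = c(NA, NA)
  )
  s <- session("S1", "F1", 1, 1000, call_events(), stays)
  # absence 185 >= 180 qualifies but start would be 175 >= 0: kept
  expect_equal(nrow(extract_reunion_ois(s)), 1)
  stays2 <- nest_stays("S1", "mom", "mother", entry = 5, exit = NA)
  s2 <- session("S1", "F1", 1, 1000, call_events(),
                rbind(stays2, nest_stays("S1", "inf1", "infant", 0, NA)))
  expect_equal(nrow(suppressWarnings(extract_reunion_ois(s2))), 0)
})

test_that("call membership is half-open on onsets only", {
  oi <- data.frame(session_id = "S1", family_id = "F1", condition = "reunion",
                   start = 390, end = 450, anchor_time = 400)
  calls <- call_events(
    session_id = rep("S1", 4),
    onset = c(390.0, 449.999, 450.0, 389.9),
    offset = c(391, 450.5, 451, 391),
    role = rep("mother", 4), call_type = rep("trill", 4)
  )
  got <- assign_calls_to_oi(oi, calls)
  expect_equal(got$onset, c(390.0, 449.999))
  expect_equal(got$rel_onset, c(0, 59.999))
})

test_that("every extracted interval is 60 s and reunion/leave-taking windows of one stay never overlap", {
  for (seed in 1:40) {
    s <- random_session(seed)
    ois <- suppressWarnings(extract_ois(s))
    if (!nrow(ois)) next
    expect_equal(ois$end - ois$start, rep(60, nrow(ois)))
    re <- ois[ois$condition == "reunion", ]
    lv <- ois[ois$condition == "leave_taking", ]
    # under default thresholds (min_presence 120 > pre_entry + post_entry)
    # no reunion window can overlap any leave-taking window
    if (nrow(re) && nrow(lv)) {
      for (i in seq_len(nrow(re))) {
        expect_true(all(lv$start >= re$end[i] - 1e-9 |
                          lv$end <= re$start[i] + 1e-9))
      }
    }
  }
})

test_that("extractor agrees with the brute-force predicate scan on random sessions", {
  for (seed in 101:160) {
    s <- random_session(seed)
    got <- suppressWarnings(extract_ois(s))
    want <- oracle_extract_ois(s)
    got <- got[order(got$start, got$condition), , drop = FALSE]
    rownames(got) <- NULL
    expect_equal(got, want, info = paste("seed", seed))
  }
})
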