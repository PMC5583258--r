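test_that("the worked exchange patterns classify as expected", {
  mimi <- with(oi_from_roles("MIMI"), classify_oi(oi, calls))
  expect_true(mimi$reciprocal && mimi$sequential && mimi$antiphonal)
  expect_equal(mimi$initiator, "mother")
  expect_equal(mimi$role_sequence, "MIMI")

  imi <- with(oi_from_roles("IMI"), classify_oi(oi, calls))
  expect_true(imi$reciprocal && imi$sequential)
  expect_false(imi$antiphonal)
  expect_equal(imi$initiator, "infant")

  m <- with(oi_from_roles("M"), classify_oi(oi, calls))
  expect_true(m$mother_called)
  expect_false(m$infant_called || m$reciprocal || m$sequential)
  expect_equal(m$initiator, "none")

  # two mother calls then one infant collapse to M,I: reciprocal but not
  # an alternating exchange of three bouts
  mmi <- with(oi_from_roles("MMI"), classify_oi(oi, calls))
  expect_true(mmi$reciprocal)
  expect_false(mmi$sequential)
  expect_equal(mmi$role_sequence, "MI")
  expect_equal(mmi$initiator, "mother")

  silent <- with(oi_from_roles("M"), classify_oi(oi, calls[0, ]))
  expect_equal(silent$n_calls, 0)
  expect_false(silent$mother_called || silent$infant_called)
  expect_equal(silent$role_sequence, "")
})

test_that("classification matches exhaustive enumeration on every role string up to length six", {
  strings <- all_role_strings(6L)
  expect_length(strings, 126)
  for (rs in strings) {
    got <- with(oi_from_roles(rs), classify_oi(oi, calls))
    want <- oracle_classify_roles(rs)
    expect_equal(got$reciprocal, want$reciprocal, info = rs)
    expect_equal(got$sequential, want$sequential, info = rs)
    expect_equal(got$antiphonal, want$antiphonal, info = rs)
    expect_equal(got$initiator, want$initiator, info = rs)
    expect_equal(got$role_sequence, want$collapsed, info = rs)
  }
})

test_that("simultaneous first onsets of both roles give an initiator tie", {
  oi <- oi_from_roles("MI")$oi
  calls <- call_events(
    session_id = c("S1", "S1"), onset = c(5, 5), offset = c(5.5, 6),
    role = c("mother", "infant"), call_type = c("trill", "stream")
  )
  got <- classify_oi(oi, calls)
  expect_true(got$reciprocal)
  expect_equal(got$initiator, "tie")
  # a millisecond apart is enough to break the tie
  calls2 <- call_events(
    session_id = c("S1", "S1"), onset = c(5, 5.001), offset = c(5.5, 6),
    role = c("infant", "mother"), call_type = c("stream", "trill")
  )
  expect_equal(classify_oi(oi, calls2)$initiator, "infant")
})

test_that("first/last call times are reported on the interval-relative axis", {
  oi <- data.frame(session_id = "S1", family_id = "F1", condition = "reunion",
                   start = 390, end = 450, anchor_time = 400)
  calls <- call_events(
    session_id = rep("S1", 4),
    onset = c(395, 403, 415, 437), offset = c(395.5, 404, 417, 439),
    role = c("mother", "mother", "infant", "infant"),
    call_type = c("trill", "trill", "stream", "stream")
  )
  got <- classify_oi(oi, calls)
  expect_equal(got$first_mother, 5)
  expect_equal(got$last_mother, 13)
  expect_equal(got$first_infant, 25)
  expect_equal(got$last_infant, 47)
  only_m <- classify_oi(oi, calls[calls$role == "mother", ])
  expect_true(is.na(only_m$first_infant) && is.na(only_m$last_infant))
})

test_that("adding a call never turns a reciprocal interval non-reciprocal", {
  withr::with_seed(11, {
    for (rep in 1:60) {
      n <- sample(2:6, 1)
      rs <- paste(sample(c("M", "I"), n, replace = TRUE), collapse = "")
      fix <- oi_from_roles(rs)
      before <- classify_oi(fix$oi, fix$calls)
      extra_t <- runif(1, 0, 59)
      extra <- call_events("S1", fix$oi$start + extra_t,
                           fix$oi$start + extra_t + 0.1,
                           sample(c("mother", "infant"), 1), "other")
      after <- classify_oi(fix$oi, rbind(fix$calls, extra))
      if (before$reciprocal) expect_true(after$reciprocal)
      expect_gte(after$n_calls, before$n_calls)
    }
  })
})

# a classification table built by hand: 4 reunion OIs per the worked
# summary example (mother-only, two reciprocal, silent) plus leave-taking
make_cls <- function(fam = "F1") {
  pats <- list(
    list(roles = "M", cond = "reunion"),
    list(roles = "MI", cond = "reunion"),
    list(roles = "IM", cond = "reunion"),
    list(roles = "", cond = "reunion"),
    list(roles = "", cond = "leave_taking"),
    list(roles = "I", cond = "leave_taking")
  )
  rows <- lapply(pats, function(p) {
    fix <- oi_from_roles(if (nzchar(p$roles)) p$roles else "M")
    calls <- if (nzchar(p$roles)) fix$calls else fix$calls[0, ]
    fix$oi$condition <- p$cond
    fix$oi$family_id <- fam
    classify_oi(fix$oi, calls)
  })
  do.call(rbind, rows)
}

test_that("family summaries compute the documented percentages", {
  cls <- make_cls()
  s <- summarize_families(cls)
  re <- s[s$condition == "reunion", ]
  expect_equal(re$n_ois, 4)
  expect_equal(re$pct_mother, 75)
  expect_equal(re$pct_infant, 50)
  expect_equal(re$pct_reciprocal, 50)
  # of the two reciprocal OIs one is mother-first
  expect_equal(re$pct_mother_initiated, 50)
  lv <- s[s$condition == "leave_taking", ]
  expect_equal(lv$pct_mother, 0)
  expect_equal(lv$pct_infant, 50)
  expect_equal(lv$pct_reciprocal, 0)
  expect_true(is.na(lv$pct_mother_initiated))
  expect_true(all(s$pct_reciprocal <= pmin(s$pct_mother, s$pct_infant)))
})

test_that("initiator ties are excluded from the initiator denominator", {
  oi <- oi_from_roles("MI")$oi
  tie_calls <- call_events(c("S1", "S1"), c(5, 5), c(5.5, 6),
                           c("mother", "infant"), c("trill", "stream"))
  cls <- rbind(
    classify_oi(oi, tie_calls),
    with(oi_from_roles("MI"), classify_oi(oi, calls)),
    with(oi_from_roles("MI"), classify_oi(oi, calls)),
    with(oi_from_roles("IM"), classify_oi(oi, calls))
  )
  s <- summarize_families(cls)
  # 4 reciprocal, 1 tie -> 2 mother-first of 3 non-tie
  expect_equal(s$pct_mother_initiated, 100 * 2 / 3)
})

test_that("families with no reciprocal reunion get missing, not zero, exchange fields", {
  fix <- oi_from_roles("M")
  cls <- classify_oi(fix$oi, fix$calls)
  s <- summarize_families(cls)
  expect_true(is.na(s$pct_sequential))
  expect_true(is.na(s$pct_mother_initiated))
  expect_true(is.na(s$mean_first_infant))
  expect_equal(s$pct_mother, 100)
})

test_that("sequential/antiphonal denominators are configurable", {
  cls <- rbind(
    with(oi_from_roles("MIM"), classify_oi(oi, calls)),   # sequential
    with(oi_from_roles("MI"), classify_oi(oi, calls)),    # reciprocal only
    with(oi_from_roles("M"), classify_oi(oi, calls))      # not reciprocal
  )
  over_rec <- summarize_families(cls, sequential_denominator = "reciprocal")
  over_all <- summarize_families(cls, sequential_denominator = "all")
  expect_equal(over_rec$pct_sequential, 50)
  expect_equal(over_all$pct_sequential, 100 / 3)
})
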