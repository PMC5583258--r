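#' Classify the vocal-exchange pattern of one observation interval
#'
#' Implements the exchange definitions used throughout the package:
#' * **reciprocal** — the interval contains at least one mother call and at
#'   least one infant call;
#' * **role sequence** — the chronological caller roles with consecutive
#'   same-role calls collapsed into a single bout (so `M,M,I` collapses to
#'   `M,I`); by construction the collapsed sequence alternates;
#' * **sequential** — an alternating exchange of at least three role bouts
#'   (mother-infant-mother or infant-mother-infant);
#' * **antiphonal** — an alternating exchange of at least four role bouts
#'   (a strict subtype of sequential);
#' * **initiator** — the role of the earliest call of a reciprocal
#'   interval; if the two roles' first onsets coincide at millisecond
#'   resolution the initiator is `"tie"`; non-reciprocal intervals have
#'   initiator `"none"`.
#'
#' First/last call times per role are reported relative to the interval
#' start (`rel_onset` axis).
#'
#' @param oi a single-row observation interval.
#' @param calls the session's call events sorted by onset (the function
#'   windows them with [assign_calls_to_oi()]); alternatively a table that
#'   already carries `rel_onset` for exactly the member calls.
#' @return a one-row data.frame with the interval's identifiers plus
#'   `n_calls`, `mother_called`, `infant_called`, `reciprocal`,
#'   `initiator`, `sequential`, `antiphonal`, `role_sequence` (string such
#'   as `"MIMI"`), and `first_mother`, `last_mother`, `first_infant`,
#'   `last_infant` in seconds from interval start (`NA` when the role is
#'   silent).
#' @export
classify_oi <- function(oi, calls) {
  if (!"rel_onset" %in% names(calls)) {
    calls <- assign_calls_to_oi(oi, calls)
  }
  calls <- calls[order(calls$rel_onset), , drop = FALSE]
  roles <- calls$role
  t_rel <- round(calls$rel_onset, 3)  # millisecond resolution

  mother_called <- any(roles == "mother")
  infant_called <- any(roles == "infant")
  reciprocal <- mother_called && infant_called

  bouts <- rle(roles)$values
  role_sequence <- paste(ifelse(bouts == "mother", "M", "I"), collapse = "")
  # the collapsed sequence alternates by construction, so its length is the
  # length of the longest alternating run
  sequential <- reciprocal && length(bouts) >= 3L
  antiphonal <- reciprocal && length(bouts) >= 4L

  first_time <- function(role) if (any(roles == role)) min(t_rel[roles == role]) else NA_real_
  last_time <- function(role) if (any(roles == role)) max(t_rel[roles == role]) else NA_real_
  fm <- first_time("mother"); fi <- first_time("infant")

  initiator <- if (!reciprocal) {
    "none"
  } else if (fm == fi) {
    "tie"
  } else if (fm < fi) "mother" else "infant"

  data.frame(
    session_id = oi$session_id, family_id = oi$family_id,
    condition = oi$condition, start = oi$start, end = oi$end,
    anchor_time = oi$anchor_time,
    n_calls = nrow(calls),
    mother_called = mother_called, infant_called = infant_called,
    reciprocal = reciprocal, initiator = initiator,
    sequential = sequential, antiphonal = antiphonal,
    role_sequence = role_sequence,
    first_mother = fm, last_mother = last_time("mother"),
    first_infant = fi, last_infant = last_time("infant"),
    stringsAsFactors = FALSE
  )
}

#' Classify every observation interval of a session or study
#'
#' @param ois interval table from [extract_ois()] (possibly several
#'   sessions row-bound).
#' @param calls call-event table covering the same sessions.
#' @return one classification row per interval (see [classify_oi()]).
#' @export
classify_ois <- function(ois, calls) {
  if (!nrow(ois)) {
    return(classify_oi(oi_template(), calls[0, , drop = FALSE])[0, , drop = FALSE])
  }
  calls <- calls[order(calls$onset), , drop = FALSE]
  rows <- lapply(seq_len(nrow(ois)), function(i) {
    oi <- ois[i, , drop = FALSE]
    classify_oi(oi, calls[calls$session_id == oi$session_id, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

oi_template <- function() {
  data.frame(session_id = "x", family_id = "x", condition = "reunion",
             start = 0, end = 60, anchor_time = 10, stringsAsFactors = FALSE)
}

#' Per-family, per-condition exchange summaries
#'
#' For each family and condition the percentage of intervals containing at
#' least one mother call (`pct_mother`), at least one infant call
#' (`pct_infant`) and both (`pct_reciprocal`). Over the family's
#' *reciprocal Reunion* intervals it additionally reports:
#' `pct_mother_initiated` (share of non-tie reciprocal intervals where the
#' mother called first; ties are excluded from the denominator),
#' `pct_sequential` and `pct_antiphonal` (denominator configurable, see
#' below), and the mean first/last call time per role in seconds from the
#' interval start. Families without a reciprocal Reunion interval carry
#' `NA` — not zero — in these fields.
#'
#' @param classifications classification table from [classify_ois()].
#' @param sequential_denominator `"reciprocal"` (default) computes the
#'   sequential/antiphonal percentages over reciprocal Reunion intervals;
#'   `"all"` uses every Reunion interval.
#' @return one row per family x condition present in the input:
#'   `family_id`, `condition`, `n_ois`, the percentages and (on reunion
#'   rows) initiator/sequence/timing summaries.
#' @export
summarize_families <- function(classifications,
                               sequential_denominator = c("reciprocal", "all")) {
  sequential_denominator <- match.arg(sequential_denominator)
  cl <- classifications
  groups <- unique(cl[, c("family_id", "condition")])
  groups <- groups[order(groups$family_id, groups$condition), , drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    fam <- groups$family_id[i]
    cond <- groups$condition[i]
    g <- cl[cl$family_id == fam & cl$condition == cond, , drop = FALSE]
    n <- nrow(g)
    out <- data.frame(
      family_id = fam, condition = cond, n_ois = n,
      pct_mother = 100 * mean(g$mother_called),
      pct_infant = 100 * mean(g$infant_called),
      pct_reciprocal = 100 * mean(g$reciprocal),
      n_reciprocal = sum(g$reciprocal),
      pct_mother_initiated = NA_real_,
      pct_sequential = NA_real_, pct_antiphonal = NA_real_,
      mean_first_mother = NA_real_, mean_last_mother = NA_real_,
      mean_first_infant = NA_real_, mean_last_infant = NA_real_,
      stringsAsFactors = FALSE
    )
    if (cond == "reunion" && any(g$reciprocal)) {
      rec <- g[g$reciprocal, , drop = FALSE]
      nontie <- rec[rec$initiator != "tie", , drop = FALSE]
      if (nrow(nontie)) {
        out$pct_mother_initiated <- 100 * mean(nontie$initiator == "mother")
      }
      denom <- if (sequential_denominator == "reciprocal") rec else g
      out$pct_sequential <- 100 * sum(rec$sequential) / nrow(denom)
      out$pct_antiphonal <- 100 * sum(rec$antiphonal) / nrow(denom)
      out$mean_first_mother <- mean(rec$first_mother)
      out$mean_last_mother <- mean(rec$last_mother)
      out$mean_first_infant <- mean(rec$first_infant)
      out$mean_last_infant <- mean(rec$last_infant)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname summarize_families
#' @param family_id restrict the summary to one family.
#' @export
summarize_family <- function(classifications, family_id,
                             sequential_denominator = c("reciprocal", "all")) {
  keep <- classifications$family_id == family_id
  if (!any(keep)) stop("no classified intervals for family ", family_id,
                       call. = FALSE)
  summarize_families(classifications[keep, , drop = FALSE],
                     sequential_denominator)
}
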