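#' Observation-interval extraction parameters
#'
#' The analysis windows are anchored to the mother's nest entries and exits.
#' A Reunion interval starts `pre_entry` seconds before an entry and ends
#' `post_entry` seconds after it (10 + 50 = 60 s by default, so the window
#' covers the approach phase during which mothers call in front of the nest
#' before entering). A Leave-taking interval is the `pre_exit` seconds
#' before an exit. An entry only qualifies if the mother was out of the
#' nest for at least `min_absence` seconds beforehand; an exit only
#' qualifies if she was inside for at least `min_presence` seconds. Both
#' thresholds are inclusive.
#'
#' @param pre_entry,post_entry seconds before/after a nest entry spanned by
#'   a Reunion interval (defaults 10 and 50).
#' @param pre_exit seconds before a nest exit spanned by a Leave-taking
#'   interval (default 60).
#' @param min_absence minimum prior out-of-nest time for an entry to
#'   qualify (default 180 s).
#' @param min_presence minimum prior in-nest time for an exit to qualify
#'   (default 120 s).
#' @return an object of class `vx_extraction_config`.
#' @export
extraction_config <- function(pre_entry = 10, post_entry = 50, pre_exit = 60,
                              min_absence = 180, min_presence = 120) {
  vals <- c(pre_entry = pre_entry, post_entry = post_entry,
            pre_exit = pre_exit, min_absence = min_absence,
            min_presence = min_presence)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all extraction parameters must be strictly positive", call. = FALSE)
  }
  structure(as.list(vals), class = "vx_extraction_config")
}

# Mother stays of a session as a matrix of (entry, exit) with open-ended
# exits clipped to the session duration.
mother_bouts <- function(session) {
  m <- session$stays[session$stays$role == "mother", , drop = FALSE]
  m <- m[order(m$entry), , drop = FALSE]
  exit <- ifelse(is.na(m$exit), session$duration, pmin(m$exit, session$duration))
  list(entry = m$entry, exit = exit, open = is.na(m$exit))
}

# TRUE if some infant stay overlaps [start, end) for a positive duration.
infant_present <- function(session, start, end) {
  s <- session$stays[session$stays$role == "infant", , drop = FALSE]
  if (!nrow(s)) return(FALSE)
  exit <- ifelse(is.na(s$exit), session$duration, s$exit)
  any(s$entry < end & exit > start)
}

oi_row <- function(session, condition, start, end, anchor) {
  data.frame(session_id = session$session_id, family_id = session$family_id,
             condition = condition, start = start, end = end,
             anchor_time = anchor, stringsAsFactors = FALSE)
}

empty_ois <- function() {
  data.frame(session_id = character(), family_id = character(),
             condition = character(), start = numeric(), end = numeric(),
             anchor_time = numeric(), stringsAsFactors = FALSE)
}

#' Extract Reunion observation intervals
#'
#' One interval per qualifying mother nest entry. An entry qualifies when
#' (a) the mother's preceding absence was at least `cfg$min_absence`
#' seconds — the absence before her first recorded entry is measured from
#' the session start — and (b) at least one infant's stay overlaps the
#' window for a positive duration. The interval spans
#' `[entry - pre_entry, entry + post_entry)`, half-open. A window that
#' would start before the recording is dropped with a warning.
#'
#' @param session a [session()] object.
#' @param cfg an [extraction_config()].
#' @return a data.frame with one row per interval: `session_id`,
#'   `family_id`, `condition`, `start`, `end`, `anchor_time` (the entry).
#' @export
extract_reunion_ois <- function(session, cfg = extraction_config()) {
  mb <- mother_bouts(session)
  out <- empty_ois()
  prev_exit <- 0
  for (i in seq_along(mb$entry)) {
    entry <- mb$entry[i]
    absence <- entry - prev_exit
    prev_exit <- mb$exit[i]
    if (absence < cfg$min_absence) next
    start <- entry - cfg$pre_entry
    end <- entry + cfg$post_entry
    if (start < 0) {
      warning(sprintf("reunion window at entry %.3f precedes recording start; dropped",
                      entry), call. = FALSE)
      next
    }
    if (!infant_present(session, start, end)) next
    out <- rbind(out, oi_row(session, "reunion", start, end, entry))
  }
  rownames(out) <- NULL
  out
}

#' Extract Leave-taking observation intervals
#'
#' One interval per qualifying mother nest exit: the mother's in-nest bout
#' must have lasted at least `cfg$min_presence` seconds (inclusive) and at
#' least one infant must overlap the window. The interval spans
#' `[exit - pre_exit, exit)`, half-open. Bouts still open at the end of
#' the recording have no exit and yield no interval.
#'
#' @inheritParams extract_reunion_ois
#' @return a data.frame as in [extract_reunion_ois()], `anchor_time` the exit.
#' @export
extract_leavetaking_ois <- function(session, cfg = extraction_config()) {
  mb <- mother_bouts(session)
  out <- empty_ois()
  for (i in seq_along(mb$entry)) {
    if (mb$open[i]) next
    exit <- mb$exit[i]
    presence <- exit - mb$entry[i]
    if (presence < cfg$min_presence) next
    start <- exit - cfg$pre_exit
    if (start < 0) {
      warning(sprintf("leave-taking window at exit %.3f precedes recording start; dropped",
                      exit), call. = FALSE)
      next
    }
    if (!infant_present(session, start, exit)) next
    out <- rbind(out, oi_row(session, "leave_taking", start, exit, exit))
  }
  rownames(out) <- NULL
  out
}

#' Extract all observation intervals of a session
#'
#' @inheritParams extract_reunion_ois
#' @return the Reunion and Leave-taking intervals of [extract_reunion_ois()]
#'   and [extract_leavetaking_ois()], row-bound and sorted by start time.
#' @export
extract_ois <- function(session, cfg = extraction_config()) {
  out <- rbind(extract_reunion_ois(session, cfg),
               extract_leavetaking_ois(session, cfg))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign call events to an observation interval
#'
#' Membership is decided by onset alone: a call belongs to the interval iff
#' its onset lies in the half-open window `[start, end)`. The returned
#' events carry `rel_onset = onset - start`, the call time on the
#' interval-relative axis used for all timing analyses (under the default
#' configuration the nest entry sits at t = 10 s of a Reunion interval).
#'
#' @param oi a single-row interval as returned by the extractors (or any
#'   list with `start` and `end`).
#' @param calls call-event table sorted by onset.
#' @return the member events with an added `rel_onset` column.
#' @export
assign_calls_to_oi <- function(oi, calls) {
  keep <- calls$onset >= oi$start & calls$onset < oi$end
  out <- calls[keep, , drop = FALSE]
  out$rel_onset <- out$onset - oi$start
  rownames(out) <- NULL
  out
}
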