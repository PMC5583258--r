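#' Simulation parameters for a synthetic nest-recording study
#'
#' The generator emulates a captive mother-infant recording study: a fixed
#' number of family groups, litters of one to three nest-bound infants
#' that stay in the nest box for the whole recording, and a mother who
#' alternates out-of-nest (foraging) and in-nest bouts with exponentially
#' distributed durations. Calling is context dependent: at each nest entry
#' the mother produces a burst of trill calls around the entry (covering
#' the approach phase just before she is fully inside), each trill is
#' answered by an infant vocal stream with some probability after a
#' positive latency, spontaneous infant calls arrive as a homogeneous
#' Poisson process, and calling before a nest exit is rare.
#'
#' Defaults mirror the study design the package targets: 11 families with
#' litter sizes distributed 1:7:3 over sizes 1/2/3, 24-hour sessions, high
#' reunion calling and near-zero leave-taking calling, mother-first
#' timing. Bout means (10 min out, 6 min in) are chosen so that typical
#' recordings yield a few dozen eligible windows per condition and most
#' nest entries follow an absence longer than the 3-minute eligibility
#' threshold.
#'
#' @param n_families number of family groups (default 11).
#' @param litter_size_probs probabilities of litter sizes 1, 2, 3
#'   (default `c(1, 7, 3) / 11`).
#' @param session_duration recording length in seconds (default 86400).
#' @param mean_absence,mean_presence means of the exponential out-of-nest /
#'   in-nest bout durations, seconds (defaults 600 and 360).
#' @param p_mother_call_reunion probability the mother calls at a nest
#'   entry (default 0.85).
#' @param p_mother_call_leave probability of a mother call in the minute
#'   before a nest exit (default 0.05).
#' @param mother_call_count_mean mean number of trills per calling entry;
#'   counts are `1 + Poisson(mean - 1)` (default 2).
#' @param mother_call_offset_range trill onsets are uniform on this range
#'   relative to the entry time, seconds (default `c(-10, 20)`).
#' @param p_infant_response probability that a trill elicits an infant
#'   vocal stream (default 0.4).
#' @param response_latency_shape,response_latency_mean gamma shape and
#'   mean (seconds) of the positive infant response latency (defaults 2
#'   and 12).
#' @param infant_baseline_rate rate (calls/second) of spontaneous infant
#'   calls (default 0.002, about 7 per hour).
#' @param seed master RNG seed; per-family child seeds are derived from it
#'   deterministically (see [simulate_study()]).
#' @return an object of class `vx_simulation_config`.
#' @export
simulation_config <- function(n_families = 11,
                              litter_size_probs = c(1, 7, 3) / 11,
                              session_duration = 86400,
                              mean_absence = 600,
                              mean_presence = 360,
                              p_mother_call_reunion = 0.85,
                              p_mother_call_leave = 0.05,
                              mother_call_count_mean = 2,
                              mother_call_offset_range = c(-10, 20),
                              p_infant_response = 0.4,
                              response_latency_shape = 2,
                              response_latency_mean = 12,
                              infant_baseline_rate = 0.002,
                              seed = 1L) {
  probs <- c(0, 0, 0)
  probs[seq_along(litter_size_probs)] <- litter_size_probs
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-6) {
    stop("litter_size_probs must be non-negative and sum to 1", call. = FALSE)
  }
  cfg <- list(
    n_families = as.integer(n_families),
    litter_size_probs = probs,
    session_duration = session_duration,
    mean_absence = mean_absence,
    mean_presence = mean_presence,
    p_mother_call_reunion = p_mother_call_reunion,
    p_mother_call_leave = p_mother_call_leave,
    mother_call_count_mean = mother_call_count_mean,
    mother_call_offset_range = mother_call_offset_range,
    p_infant_response = p_infant_response,
    response_latency_shape = response_latency_shape,
    response_latency_mean = response_latency_mean,
    infant_baseline_rate = infant_baseline_rate,
    seed = as.integer(seed)
  )
  pr <- c(cfg$p_mother_call_reunion, cfg$p_mother_call_leave,
          cfg$p_infant_response)
  if (any(pr < 0 | pr > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  pos <- c(cfg$session_duration, cfg$mean_absence, cfg$mean_presence,
           cfg$response_latency_shape, cfg$response_latency_mean)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("durations, bout means and latency parameters must be positive",
         call. = FALSE)
  }
  if (cfg$mother_call_count_mean < 1) {
    stop("mother_call_count_mean must be at least 1", call. = FALSE)
  }
  if (cfg$infant_baseline_rate < 0) {
    stop("infant_baseline_rate must be non-negative", call. = FALSE)
  }
  if (cfg$n_families < 1L) stop("need at least one family", call. = FALSE)
  structure(cfg, class = "vx_simulation_config")
}

# Deterministic child seed for family i: reproducible per-family streams
# that do not depend on how many families are simulated. Kept within the
# 32-bit integer range.
derive_child_seed <- function(master, i) {
  as.integer((as.numeric(master) + i * 100003) %% 2147483647)
}

#' Simulate one family's recording session
#'
#' The mother starts outside the nest (so the session opens with a
#' separation) and alternates exponential out/in bouts until the recording
#' ends; a bout still running at the end is emitted as open-ended. Infants
#' occupy the nest for the whole session. Event generation follows the
#' config (see [simulation_config()]); events whose onset would fall
#' outside the recording are dropped and offsets are clipped at the
#' session end. Responses are generated regardless of whether they land
#' inside an analysis window — windowing is the analyzer's job, not the
#' generator's.
#'
#' @param family_id family identifier (also used to derive the session id).
#' @param cfg a [simulation_config()].
#' @param seed integer seed for this session's RNG stream.
#' @return a list with `session` (a [session()] object) and `truth`, a
#'   data.frame of per-entry latent labels: entry/exit times, preceding
#'   absence, bout presence, whether the mother called, number of trills,
#'   whether any infant response was generated.
#' @export
simulate_session <- function(family_id, cfg = simulation_config(),
                             seed = cfg$seed) {
  withr::with_seed(seed, simulate_session_impl(family_id, cfg))
}

simulate_session_impl <- function(family_id, cfg) {
  dur <- cfg$session_duration
  session_id <- paste0("sess-", family_id)
  litter <- sample(1:3, 1, prob = cfg$litter_size_probs)

  # alternating absence/presence bouts, session starts with the mother out
  entries <- numeric(0); exits <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::rexp(1, 1 / cfg$mean_absence)  # absence ends, mother enters
    if (t >= dur) break
    entry <- t
    t <- t + stats::rexp(1, 1 / cfg$mean_presence) # presence ends, mother exits
    entries <- c(entries, entry)
    exits <- c(exits, if (t >= dur) NA_real_ else t)
    if (is.na(exits[length(exits)])) break
  }

  onset <- numeric(0); role <- character(0); type <- character(0)
  dur_call <- numeric(0)
  n_entries <- length(entries)
  mother_called <- logical(n_entries)
  n_trills <- integer(n_entries)
  infant_responded <- logical(n_entries)
  n_responses <- integer(n_entries)
  leave_called <- logical(n_entries)

  off_lo <- cfg$mother_call_offset_range[1]
  off_hi <- cfg$mother_call_offset_range[2]
  lat_scale <- cfg$response_latency_mean / cfg$response_latency_shape

  for (i in seq_len(n_entries)) {
    if (stats::runif(1) < cfg$p_mother_call_reunion) {
      mother_called[i] <- TRUE
      k <- 1L + stats::rpois(1, cfg$mother_call_count_mean - 1)
      n_trills[i] <- k
      offs <- sort(stats::runif(k, off_lo, off_hi))
      t_trill <- entries[i] + offs
      onset <- c(onset, t_trill)
      role <- c(role, rep("mother", k))
      type <- c(type, rep("trill", k))
      dur_call <- c(dur_call, stats::runif(k, 0.4, 1.0))
      resp <- stats::runif(k) < cfg$p_infant_response
      if (any(resp)) {
        infant_responded[i] <- TRUE
        n_responses[i] <- sum(resp)
        lat <- stats::rgamma(sum(resp), shape = cfg$response_latency_shape,
                             scale = lat_scale)
        t_resp <- t_trill[resp] + lat
        onset <- c(onset, t_resp)
        role <- c(role, rep("infant", sum(resp)))
        type <- c(type, rep("stream", sum(resp)))
        dur_call <- c(dur_call, stats::runif(sum(resp), 1.0, 3.0))
      }
    }
    if (!is.na(exits[i]) && stats::runif(1) < cfg$p_mother_call_leave) {
      leave_called[i] <- TRUE
      t_lv <- exits[i] + stats::runif(1, -60, 0)
      onset <- c(onset, t_lv)
      role <- c(role, "mother")
      type <- c(type, "trill")
      dur_call <- c(dur_call, stats::runif(1, 0.4, 1.0))
    }
  }
  n_base <- stats::rpois(1, cfg$infant_baseline_rate * dur)
  if (n_base > 0) {
    onset <- c(onset, stats::runif(n_base, 0, dur))
    role <- c(role, rep("infant", n_base))
    type <- c(type, rep("stream", n_base))
    dur_call <- c(dur_call, stats::runif(n_base, 1.0, 3.0))
  }

  keep <- onset >= 0 & onset <= dur
  onset <- onset[keep]; role <- role[keep]; type <- type[keep]
  offset <- pmin(onset + dur_call[keep], dur)
  calls <- call_events(session_id = rep(session_id, length(onset)),
                       onset = onset, offset = offset, role = role,
                       call_type = type,
                       individual_id = ifelse(role == "mother",
                                              paste0(family_id, "-mom"),
                                              NA_character_))

  stays <- nest_stays(
    session_id = rep(session_id, n_entries + litter),
    individual_id = c(rep(paste0(family_id, "-mom"), n_entries),
                      paste0(family_id, "-inf", seq_len(litter))),
    role = c(rep("mother", n_entries), rep("infant", litter)),
    entry = c(entries, rep(0, litter)),
    exit = c(exits, rep(NA_real_, litter))
  )

  prev_exit <- if (n_entries) c(0, exits[-n_entries]) else numeric(0)
  truth <- data.frame(
    family_id = rep(family_id, n_entries),
    session_id = rep(session_id, n_entries),
    litter_size = rep(litter, n_entries),
    entry = round(entries, 3),
    exit = round(exits, 3),
    absence = round(entries - prev_exit, 3),
    presence = round(ifelse(is.na(exits), NA, exits - entries), 3),
    mother_called = mother_called, n_trills = n_trills,
    infant_responded = infant_responded, n_responses = n_responses,
    leave_called = leave_called,
    stringsAsFactors = FALSE
  )

  list(
    session = session(session_id, family_id, litter, dur, calls, stays),
    truth = truth
  )
}

#' Simulate a whole study
#'
#' Runs [simulate_session()] once per family with child seeds derived
#' deterministically from the master seed
#' (`(seed + i * 100003) mod (2^31 - 1)` for family `i`), so each family's
#' event stream is reproducible and independent of the number of families
#' simulated.
#'
#' @param cfg a [simulation_config()].
#' @return an object of class `vx_study`: a list with `sessions` (list of
#'   [session()] objects), `truth` (row-bound per-entry ground truth) and
#'   `config`.
#' @export
simulate_study <- function(cfg = simulation_config()) {
  fams <- sprintf("F%02d", seq_len(cfg$n_families))
  sims <- lapply(seq_along(fams), function(i) {
    simulate_session(fams[i], cfg, seed = derive_child_seed(cfg$seed, i))
  })
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  rownames(truth) <- NULL
  structure(list(sessions = lapply(sims, `[[`, "session"),
                 truth = truth, config = cfg),
            class = "vx_study")
}

#' @export
print.vx_study <- function(x, ...) {
  cat(sprintf("<vx_study> %d families, %d nest entries, %d call events\n",
              length(x$sessions), nrow(x$truth),
              sum(vapply(x$sessions, function(s) nrow(s$calls), 0L))))
  invisible(x)
}

#' Write a simulated study to canonical CSV files
#'
#' Emits `events.csv` and `stays.csv` in the [write_events()] formats plus
#' `sessions.csv` (session metadata: `session_id,family_id,litter_size,
#' duration`) and `ground_truth.csv` (per-entry latent labels).
#'
#' @param study a `vx_study` from [simulate_study()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  events <- do.call(rbind, lapply(study$sessions, `[[`, "calls"))
  stays <- do.call(rbind, lapply(study$sessions, `[[`, "stays"))
  paths <- c(events = file.path(dir, "events.csv"),
             stays = file.path(dir, "stays.csv"),
             sessions = file.path(dir, "sessions.csv"),
             truth = file.path(dir, "ground_truth.csv"))
  write_events(events, stays, paths["events"], paths["stays"])
  meta <- data.frame(
    session_id = vapply(study$sessions, `[[`, "", "session_id"),
    family_id = vapply(study$sessions, `[[`, "", "family_id"),
    litter_size = vapply(study$sessions, `[[`, 0L, "litter_size"),
    duration = vapply(study$sessions, `[[`, 0, "duration")
  )
  utils::write.csv(meta, paths["sessions"], row.names = FALSE, quote = FALSE)
  utils::write.csv(study$truth, paths["truth"], row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(paths)
}

#' Read sessions back from canonical CSV files
#'
#' Rebuilds validated [session()] objects from `events.csv`, `stays.csv`
#' and (optionally) `sessions.csv`. Without a metadata file each
#' `session_id` becomes its own family, the litter size defaults to the
#' number of distinct infant ids (or 1) and the duration to the last
#' observed time.
#'
#' @param events_path,stays_path canonical CSV files.
#' @param sessions_path optional session-metadata CSV.
#' @return a list of [session()] objects.
#' @export
read_sessions <- function(events_path, stays_path, sessions_path = NULL) {
  events <- read_call_events(events_path)
  stays <- read_nest_stays(stays_path)
  if (!is.null(sessions_path) && file.exists(sessions_path)) {
    meta <- utils::read.csv(sessions_path, stringsAsFactors = FALSE)
  } else {
    ids <- sort(unique(c(events$session_id, stays$session_id)))
    meta <- data.frame(session_id = ids, family_id = ids,
                       litter_size = NA_integer_, duration = NA_real_,
                       stringsAsFactors = FALSE)
  }
  lapply(seq_len(nrow(meta)), function(i) {
    sid <- meta$session_id[i]
    st <- stays[stays$session_id == sid, , drop = FALSE]
    ev <- events[events$session_id == sid, , drop = FALSE]
    litter <- meta$litter_size[i]
    if (is.na(litter)) {
      n_inf <- length(unique(st$individual_id[st$role == "infant"]))
      litter <- max(1L, n_inf)
    }
    duration <- meta$duration[i]
    if (is.na(duration)) {
      duration <- max(ev$offset, st$entry, st$exit, 60, na.rm = TRUE)
    }
    session(sid, meta$family_id[i], litter, duration, ev, st)
  })
}
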