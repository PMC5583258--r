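# Independent oracles and small fixture builders used across the suite.
# Each oracle re-derives the quantity under test by a different route
# (enumeration, brute-force scanning, direct Monte-Carlo) so that it never
# shares code with the implementation it checks.

# ---- exchange classification oracle ---------------------------------------

# Brute-force classification of a role string such as "MIMI": collapse
# consecutive repeats with an explicit loop, then scan for the longest
# contiguous stretch of alternating labels.
oracle_classify_roles <- function(role_string) {
  roles <- strsplit(role_string, "")[[1]]
  collapsed <- character(0)
  for (r in roles) {
    if (!length(collapsed) || collapsed[length(collapsed)] != r) {
      collapsed <- c(collapsed, r)
    }
  }
  longest_alt <- 0L
  i <- 1L
  while (i <= length(collapsed)) {
    j <- i
    while (j < length(collapsed) && collapsed[j + 1L] != collapsed[j]) j <- j + 1L
    longest_alt <- max(longest_alt, j - i + 1L)
    i <- j + 1L
  }
  reciprocal <- ("M" %in% roles) && ("I" %in% roles)
  list(
    reciprocal = reciprocal,
    sequential = reciprocal && longest_alt >= 3L,
    antiphonal = reciprocal && longest_alt >= 4L,
    initiator = if (!reciprocal) "none" else if (roles[1] == "M") "mother" else "infant",
    collapsed = paste(collapsed, collapse = "")
  )
}

# All role strings of lengths 1..max_len.
all_role_strings <- function(max_len = 6L) {
  unlist(lapply(seq_len(max_len), function(n) {
    grid <- expand.grid(rep(list(c("M", "I")), n), stringsAsFactors = FALSE)
    apply(grid, 1, paste, collapse = "")
  }))
}

# Build a one-row OI and matching call table realizing a role string with
# strictly increasing onsets (1 s apart).
oi_from_roles <- function(role_string, start = 0, t0 = 1, step = 1) {
  roles <- strsplit(role_string, "")[[1]]
  oi <- data.frame(session_id = "S1", family_id = "F1", condition = "reunion",
                   start = start, end = start + 60, anchor_time = start + 10,
                   stringsAsFactors = FALSE)
  n <- length(roles)
  calls <- call_events(
    session_id = rep("S1", n),
    onset = start + t0 + step * (seq_len(n) - 1),
    offset = start + t0 + step * (seq_len(n) - 1) + 0.2,
    role = ifelse(roles == "M", "mother", "infant"),
    call_type = ifelse(roles == "M", "trill", "stream")
  )
  list(oi = oi, calls = calls)
}

# ---- exact signed-rank oracle ---------------------------------------------

# Two-sided exact p by explicit enumeration of all 2^n sign vectors.
oracle_exact_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.vector(signs %*% r)
  center <- n * (n + 1) / 4
  w_obs <- sum(r[d > 0])
  mean(abs(w - center) >= abs(w_obs - center) - 1e-9)
}

# ---- interval extraction oracle -------------------------------------------

# Re-checks every mother entry and exit against the eligibility predicates
# with vectorized scans over the stay table (no sequential state).
oracle_extract_ois <- function(session, cfg = extraction_config()) {
  st <- session$stays
  m <- st[st$role == "mother", , drop = FALSE]
  m_exit <- ifelse(is.na(m$exit), session$duration, pmin(m$exit, session$duration))
  inf <- st[st$role == "infant", , drop = FALSE]
  inf_exit <- ifelse(is.na(inf$exit), session$duration, inf$exit)
  inf_overlaps <- function(a, b) {
    nrow(inf) > 0 && any(pmin(inf_exit, b) - pmax(inf$entry, a) > 0)
  }
  rows <- list()
  for (i in seq_len(nrow(m))) {
    entry <- m$entry[i]
    prior <- m_exit[m_exit <= entry]
    absence <- entry - if (length(prior)) max(prior) else 0
    a <- entry - cfg$pre_entry
    b <- entry + cfg$post_entry
    if (absence >= cfg$min_absence && a >= 0 && inf_overlaps(a, b)) {
      rows[[length(rows) + 1L]] <-
        data.frame(session_id = session$session_id,
                   family_id = session$family_id, condition = "reunion",
                   start = a, end = b, anchor_time = entry,
                   stringsAsFactors = FALSE)
    }
    if (!is.na(m$exit[i])) {
      ex <- m_exit[i]
      a2 <- ex - cfg$pre_exit
      if (ex - entry >= cfg$min_presence && a2 >= 0 && inf_overlaps(a2, ex)) {
        rows[[length(rows) + 1L]] <-
          data.frame(session_id = session$session_id,
                     family_id = session$family_id, condition = "leave_taking",
                     start = a2, end = ex, anchor_time = ex,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(session_id = character(), family_id = character(),
                      condition = character(), start = numeric(),
                      end = numeric(), anchor_time = numeric(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Small randomized sessions exercising all eligibility predicates:
# irregular mother bouts, infants that are present only part of the time,
# scattered calls.
random_session <- function(seed) {
  withr::with_seed(seed, {
    duration <- round(runif(1, 600, 3000), 3)
    t <- 0
    entries <- numeric(0); exits <- numeric(0)
    while (TRUE) {
      t <- t + round(runif(1, 20, 500), 3)
      if (t >= duration) break
      entry <- t
      t <- t + round(runif(1, 20, 500), 3)
      entries <- c(entries, entry)
      exits <- c(exits, if (t >= duration || runif(1) < 0.1) NA_real_ else t)
      if (is.na(exits[length(exits)])) break
    }
    n_inf <- sample(1:3, 1)
    inf_id <- character(0); inf_entry <- numeric(0); inf_exit <- numeric(0)
    for (k in seq_len(n_inf)) {
      cuts <- sort(round(runif(4, 0, duration), 3))
      picks <- sample(c(TRUE, FALSE), 2, replace = TRUE)
      if (!any(picks)) picks[1] <- TRUE
      for (j in which(picks)) {
        a <- cuts[2 * j - 1]; b <- cuts[2 * j]
        if (b > a) {
          inf_id <- c(inf_id, paste0("inf", k))
          inf_entry <- c(inf_entry, a)
          inf_exit <- c(inf_exit, b)
        }
      }
    }
    litter <- max(1L, length(unique(inf_id)))
    n_m <- length(entries)
    stays <- nest_stays(
      session_id = rep("S1", n_m + length(inf_id)),
      individual_id = c(rep("mom", n_m), inf_id),
      role = c(rep("mother", n_m), rep("infant", length(inf_id))),
      entry = c(entries, inf_entry),
      exit = c(exits, inf_exit)
    )
    n_calls <- rpois(1, 8)
    onset <- round(runif(n_calls, 0, duration - 5), 3)
    calls <- call_events(
      session_id = rep("S1", n_calls), onset = onset, offset = onset + 0.5,
      role = sample(c("mother", "infant"), n_calls, replace = TRUE),
      call_type = sample(c("trill", "stream"), n_calls, replace = TRUE)
    )
    session("S1", "F1", litter, duration, calls, stays)
  })
}

# ---- Monte-Carlo oracle for the generator's reciprocal probability --------

# Direct large-n simulation of the per-entry event rules: what fraction of
# reunion windows [-pre_entry, +post_entry) around an entry contain both a
# mother call and an infant call? Independent of the event-table pipeline.
oracle_reciprocal_prob <- function(cfg, n_entries = 2e5, seed = 1,
                                   pre_entry = 10, post_entry = 50) {
  withr::with_seed(seed, {
    reciprocal <- logical(n_entries)
    win_len <- pre_entry + post_entry
    lat_scale <- cfg$response_latency_mean / cfg$response_latency_shape
    mother_calls <- runif(n_entries) < cfg$p_mother_call_reunion
    n_base <- rpois(n_entries, cfg$infant_baseline_rate * win_len)
    k <- ifelse(mother_calls,
                1L + rpois(n_entries, cfg$mother_call_count_mean - 1), 0L)
    for (i in seq_len(n_entries)) {
      if (!mother_calls[i]) next
      offs <- runif(k[i], cfg$mother_call_offset_range[1],
                    cfg$mother_call_offset_range[2])
      mother_in <- any(offs >= -pre_entry & offs < post_entry)
      resp <- runif(k[i]) < cfg$p_infant_response
      resp_t <- offs[resp] + rgamma(sum(resp), shape = cfg$response_latency_shape,
                                    scale = lat_scale)
      infant_in <- any(resp_t >= -pre_entry & resp_t < post_entry) || n_base[i] > 0
      reciprocal[i] <- mother_in && infant_in
    }
    mean(reciprocal)
  })
}
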