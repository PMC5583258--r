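#' @keywords internal
"_PACKAGE"

# Controlled vocabularies for annotated events. Multiple infants are pooled
# under role "infant": exchange classification never attributes calls to
# individual littermates (individual_id is carried through but unused).
call_roles <- c("mother", "infant")
call_types <- c("trill", "proto_trill", "stream", "other")

#' Construct a call-event table
#'
#' A call event is one annotated vocalization: onset/offset in seconds from
#' session start (millisecond resolution), the caller role, and the call
#' type (`trill` for the adult female greeting call, `stream`/`proto_trill`
#' for infant vocal streams, `other` as catch-all).
#'
#' @param session_id character session identifiers.
#' @param onset,offset numeric, seconds from session start; `offset >= onset >= 0`.
#' @param role `"mother"` or `"infant"`.
#' @param call_type one of `"trill"`, `"proto_trill"`, `"stream"`, `"other"`.
#' @param individual_id optional caller identifier (`NA` allowed).
#' @return A `data.frame` with one row per event, sorted by onset.
#' @export
call_events <- function(session_id = character(), onset = numeric(),
                        offset = numeric(), role = character(),
                        call_type = character(),
                        individual_id = NA_character_) {
  individual_id <- rep(as.character(individual_id),
                       length.out = length(session_id))
  df <- data.frame(
    session_id = as.character(session_id),
    onset = round(as.numeric(onset), 3),
    offset = round(as.numeric(offset), 3),
    role = as.character(role),
    call_type = as.character(call_type),
    individual_id = as.character(individual_id),
    stringsAsFactors = FALSE
  )
  validate_call_events(df)
  df[order(df$session_id, df$onset), , drop = FALSE]
}

validate_call_events <- function(df, line = NULL) {
  where <- function(i) {
    if (is.null(line)) sprintf("event %d", i) else sprintf("line %d", line[i])
  }
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!df$role %in% call_roles)
  if (length(bad)) {
    stop(sprintf("unknown role '%s' (%s)", df$role[bad[1]], where(bad[1])),
         call. = FALSE)
  }
  bad <- which(!df$call_type %in% call_types)
  if (length(bad)) {
    stop(sprintf("unknown call_type '%s' (%s)", df$call_type[bad[1]],
                 where(bad[1])), call. = FALSE)
  }
  bad <- which(is.na(df$onset) | is.na(df$offset))
  if (length(bad)) {
    stop(sprintf("non-numeric onset/offset (%s)", where(bad[1])), call. = FALSE)
  }
  bad <- which(df$onset < 0)
  if (length(bad)) {
    stop(sprintf("negative onset %s (%s)", format(df$onset[bad[1]]),
                 where(bad[1])), call. = FALSE)
  }
  bad <- which(df$offset < df$onset)
  if (length(bad)) {
    stop(sprintf("offset %s precedes onset %s (%s)",
                 format(df$offset[bad[1]]), format(df$onset[bad[1]]),
                 where(bad[1])), call. = FALSE)
  }
  invisible(df)
}

#' Read annotated call events
#'
#' Two dialects are supported. `canonical_csv` is the package's
#' authoritative format: a header CSV with columns
#' `session_id,onset,offset,role,call_type[,individual_id]`.
#' `audacity_labels` imports a label track exported from an audio editor:
#' tab-separated `start<TAB>end<TAB>label` with the label encoding role and
#' call type as `role:call_type` (e.g. `mother:trill`); all labels are
#' assigned to `session_id`.
#'
#' @param path file to read.
#' @param dialect `"canonical_csv"` (default) or `"audacity_labels"`.
#' @param session_id session identifier used for `audacity_labels` input.
#' @return validated event table sorted by onset (see [call_events()]).
#' @export
read_call_events <- function(path, dialect = c("canonical_csv", "audacity_labels"),
                             session_id = "S1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "canonical_csv") {
    raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
    required <- c("session_id", "onset", "offset", "role", "call_type")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols)) {
      stop("missing column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    if (!"individual_id" %in% names(raw)) raw$individual_id <- NA_character_
    line <- seq_len(nrow(raw)) + 1L  # header on line 1
    onset <- parse_seconds(raw$onset, line, "onset")
    offset <- parse_seconds(raw$offset, line, "offset")
    df <- data.frame(session_id = raw$session_id, onset = onset,
                     offset = offset, role = raw$role,
                     call_type = raw$call_type,
                     individual_id = ifelse(raw$individual_id == "",
                                            NA_character_, raw$individual_id),
                     stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield < 3L)) {
      stop(sprintf("malformed label row (line %d): expected 3 tab-separated fields",
                   which(nfield < 3L)[1]), call. = FALSE)
    }
    line <- seq_along(lines)
    onset <- parse_seconds(vapply(parts, `[[`, "", 1L), line, "start")
    offset <- parse_seconds(vapply(parts, `[[`, "", 2L), line, "end")
    label <- vapply(parts, `[[`, "", 3L)
    tag <- strsplit(label, ":", fixed = TRUE)
    bad <- which(lengths(tag) != 2L)
    if (length(bad)) {
      stop(sprintf("label '%s' is not 'role:call_type' (line %d)",
                   label[bad[1]], line[bad[1]]), call. = FALSE)
    }
    df <- data.frame(session_id = session_id, onset = onset, offset = offset,
                     role = trimws(vapply(tag, `[[`, "", 1L)),
                     call_type = trimws(vapply(tag, `[[`, "", 2L)),
                     individual_id = NA_character_, stringsAsFactors = FALSE)
  }
  df$onset <- round(df$onset, 3)
  df$offset <- round(df$offset, 3)
  validate_call_events(df, line = line)
  df <- df[order(df$session_id, df$onset), , drop = FALSE]
  rownames(df) <- NULL
  df
}

parse_seconds <- function(x, line, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(is.na(x) | x == ""))
  if (length(bad)) {
    stop(sprintf("cannot parse %s '%s' as seconds (line %d)",
                 what, x[bad[1]], line[bad[1]]), call. = FALSE)
  }
  out
}

#' Construct a nest-stay table
#'
#' One row per continuous in-nest bout of one individual. `exit = NA` marks
#' a bout still ongoing at the end of the recording; downstream code clips
#' it at the session duration. Stays of the same individual must not
#' overlap.
#'
#' @param session_id,individual_id identifiers.
#' @param role `"mother"` or `"infant"`.
#' @param entry,exit seconds from session start; `exit > entry` when present.
#' @return a `data.frame` sorted by entry.
#' @export
nest_stays <- function(session_id = character(), individual_id = character(),
                       role = character(), entry = numeric(), exit = numeric()) {
  df <- data.frame(
    session_id = as.character(session_id),
    individual_id = as.character(individual_id),
    role = as.character(role),
    entry = round(as.numeric(entry), 3),
    exit = round(as.numeric(exit), 3),
    stringsAsFactors = FALSE
  )
  validate_nest_stays(df)
  df <- df[order(df$session_id, df$entry), , drop = FALSE]
  rownames(df) <- NULL
  df
}

validate_nest_stays <- function(df, line = NULL) {
  where <- function(i) {
    if (is.null(line)) sprintf("stay %d", i) else sprintf("line %d", line[i])
  }
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!df$role %in% call_roles)
  if (length(bad)) {
    stop(sprintf("unknown role '%s' (%s)", df$role[bad[1]], where(bad[1])),
         call. = FALSE)
  }
  bad <- which(is.na(df$entry) | df$entry < 0)
  if (length(bad)) {
    stop(sprintf("invalid entry time (%s)", where(bad[1])), call. = FALSE)
  }
  bad <- which(!is.na(df$exit) & df$exit <= df$entry)
  if (length(bad)) {
    stop(sprintf("exit %s does not follow entry %s (%s)",
                 format(df$exit[bad[1]]), format(df$entry[bad[1]]),
                 where(bad[1])), call. = FALSE)
  }
  # per-individual non-overlap (an NA exit is open-ended: must be the last)
  key <- split(seq_len(nrow(df)), paste(df$session_id, df$individual_id))
  for (idx in key) {
    o <- idx[order(df$entry[idx])]
    ent <- df$entry[o]
    ext <- df$exit[o]
    n <- length(o)
    if (n < 2L) next
    if (anyNA(ext[-n])) {
      stop(sprintf("open-ended stay is not the individual's last (%s)",
                   where(o[which(is.na(ext[-n]))[1]])), call. = FALSE)
    }
    ov <- which(ent[-1] < ext[-n])
    if (length(ov)) {
      stop(sprintf("overlapping stays of '%s' (%s)",
                   df$individual_id[o[1]], where(o[ov[1] + 1L])),
           call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a nest-stay table
#'
#' CSV with header `session_id,individual_id,role,entry,exit`; an empty
#' `exit` field marks an open-ended stay.
#'
#' @param path file to read.
#' @return validated stay table sorted by entry (see [nest_stays()]).
#' @export
read_nest_stays <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  required <- c("session_id", "individual_id", "role", "entry", "exit")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  line <- seq_len(nrow(raw)) + 1L
  df <- data.frame(
    session_id = raw$session_id,
    individual_id = raw$individual_id,
    role = raw$role,
    entry = round(parse_seconds(raw$entry, line, "entry"), 3),
    exit = round(parse_seconds(raw$exit, line, "exit"), 3),
    stringsAsFactors = FALSE
  )
  validate_nest_stays(df, line = line)
  df <- df[order(df$session_id, df$entry), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write call events and nest stays as canonical CSV
#'
#' Times are serialized with three decimals so that a write/read cycle
#' reproduces every field exactly at millisecond resolution.
#'
#' @param events call-event table.
#' @param stays nest-stay table.
#' @param events_path,stays_path output files.
#' @return invisibly, the two paths.
#' @export
write_events <- function(events, stays, events_path, stays_path) {
  validate_call_events(events)
  validate_nest_stays(stays)
  ev <- events
  ev$onset <- fmt_ms(ev$onset)
  ev$offset <- fmt_ms(ev$offset)
  utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE, na = "")
  st <- stays
  st$entry <- fmt_ms(st$entry)
  st$exit <- ifelse(is.na(st$exit), "", fmt_ms(st$exit))
  utils::write.csv(st, stays_path, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(events = events_path, stays = stays_path))
}

fmt_ms <- function(x) sprintf("%.3f", x)

#' Assemble and validate a recording session
#'
#' Bundles per-session metadata with its call events and nest stays and
#' checks cross-table consistency: all event times within the session
#' duration, and (when infant `individual_id`s are annotated) agreement
#' between `litter_size` and the number of distinct infants.
#'
#' @param session_id,family_id identifiers.
#' @param litter_size integer 1-3.
#' @param duration recording length in seconds.
#' @param calls call-event table for this session.
#' @param stays nest-stay table for this session.
#' @return an object of class `vx_session`.
#' @export
session <- function(session_id, family_id, litter_size, duration,
                    calls, stays) {
  litter_size <- as.integer(litter_size)
  if (is.na(litter_size) || litter_size < 1L || litter_size > 3L) {
    stop("litter_size must be 1, 2 or 3", call. = FALSE)
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be a positive number of seconds", call. = FALSE)
  }
  calls <- calls[calls$session_id == session_id, , drop = FALSE]
  stays <- stays[stays$session_id == session_id, , drop = FALSE]
  validate_call_events(calls)
  validate_nest_stays(stays)
  if (nrow(calls) && any(calls$offset > duration + 1e-9)) {
    stop("call event extends beyond session duration", call. = FALSE)
  }
  if (nrow(stays) && any(stays$entry > duration)) {
    stop("nest stay begins after session end", call. = FALSE)
  }
  inf_ids <- unique(stays$individual_id[stays$role == "infant"])
  if (length(inf_ids) && length(inf_ids) != litter_size) {
    stop(sprintf("litter_size %d but %d distinct infant ids in stays",
                 litter_size, length(inf_ids)), call. = FALSE)
  }
  calls <- calls[order(calls$onset), , drop = FALSE]
  stays <- stays[order(stays$entry), , drop = FALSE]
  rownames(calls) <- rownames(stays) <- NULL
  structure(
    list(session_id = session_id, family_id = family_id,
         litter_size = litter_size, duration = duration,
         calls = calls, stays = stays),
    class = "vx_session"
  )
}

#' @export
print.vx_session <- function(x, ...) {
  cat(sprintf("<vx_session> %s (family %s, litter %d): %.0f s, %d calls, %d stays\n",
              x$session_id, x$family_id, x$litter_size, x$duration,
              nrow(x$calls), nrow(x$stays)))
  invisible(x)
}
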