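#' Group-level statistics across family summaries
#'
#' Reproduces the study-level analysis: per-family percentages are
#' compared between the Reunion and Leave-taking conditions with paired
#' Wilcoxon signed-rank tests (mother calling, infant calling, reciprocal
#' calling), the initiator percentage is tested against the 50% chance
#' level with a one-sample signed-rank test, the per-family mean first
#' mother call time is compared with the mean first infant call time
#' (paired), and medians with interquartile ranges are reported for every
#' summary quantity. Optionally a binomial mixed model per binary outcome
#' (`outcome ~ condition + (1|family) + (1|litter size)`) cross-checks the
#' paired comparisons. Degenerate tests (e.g. all paired differences zero)
#' are reported with a note and a missing p-value rather than failing the
#' run.
#'
#' @param summaries per-family table from [summarize_families()].
#' @param classifications per-interval table from [classify_ois()]; needed
#'   for the mixed models (pass `NULL` with `glmm = FALSE`).
#' @param approximation Wilcoxon p-value mode, `"asymptotic"` (default) or
#'   `"exact"`.
#' @param quantile_type quartile convention for [describe_quartiles()].
#' @param glmm fit the binomial mixed models (requires `lme4`).
#' @param chance_level reference value for the initiator test (default 50).
#' @return a list with `tests` (named `vx_test` results) and
#'   `descriptives` (named [describe_quartiles()] results).
#' @export
group_statistics <- function(summaries, classifications = NULL,
                             approximation = c("asymptotic", "exact"),
                             quantile_type = 7, glmm = FALSE,
                             chance_level = 50) {
  approximation <- match.arg(approximation)
  re <- summaries[summaries$condition == "reunion", , drop = FALSE]
  lv <- summaries[summaries$condition == "leave_taking", , drop = FALSE]
  wide <- merge(re, lv, by = "family_id", suffixes = c("_reunion", "_leave"))

  safe_test <- function(expr) {
    tryCatch(expr, error = function(e) {
      structure(list(method = "degenerate", statistic = NA_real_,
                     n = NA_integer_, p_value = NA_real_,
                     approximation = approximation,
                     note = conditionMessage(e)),
                class = "vx_test")
    })
  }
  paired <- function(col) {
    safe_test(wilcoxon_paired(wide[[paste0(col, "_reunion")]],
                              wide[[paste0(col, "_leave")]],
                              approximation = approximation))
  }

  tests <- list(
    mother_calling = paired("pct_mother"),
    infant_calling = paired("pct_infant"),
    reciprocal_calling = paired("pct_reciprocal"),
    initiator_vs_chance = safe_test(
      wilcoxon_one_sample(re$pct_mother_initiated[!is.na(re$pct_mother_initiated)],
                          mu = chance_level, approximation = approximation)),
    timing_first_call = safe_test({
      ok <- !is.na(re$mean_first_mother) & !is.na(re$mean_first_infant)
      wilcoxon_paired(re$mean_first_mother[ok], re$mean_first_infant[ok],
                      approximation = approximation)
    })
  )

  if (glmm && !is.null(classifications) && nrow(classifications)) {
    litter <- litter_lookup(classifications)
    per_oi <- function(col) {
      data.frame(outcome = classifications[[col]],
                 condition = classifications$condition,
                 family_id = classifications$family_id,
                 litter_size = litter[classifications$family_id])
    }
    tests$glmm_mother <- safe_test(fit_condition_glmm(per_oi("mother_called")))
    tests$glmm_infant <- safe_test(fit_condition_glmm(per_oi("infant_called")))
    tests$glmm_reciprocal <- safe_test(fit_condition_glmm(per_oi("reciprocal")))
  }

  desc <- list()
  for (cond in c("reunion", "leave_taking")) {
    s <- summaries[summaries$condition == cond, , drop = FALSE]
    if (!nrow(s)) next
    for (col in c("pct_mother", "pct_infant", "pct_reciprocal")) {
      desc[[paste0(col, "_", cond)]] <- describe_quartiles(s[[col]],
                                                           type = quantile_type)
    }
  }
  for (col in c("pct_mother_initiated", "pct_sequential", "pct_antiphonal",
                "mean_first_mother", "mean_last_mother",
                "mean_first_infant", "mean_last_infant")) {
    vals <- re[[col]][!is.na(re[[col]])]
    if (length(vals)) desc[[paste0(col, "_reunion")]] <-
        describe_quartiles(vals, type = quantile_type)
  }

  list(tests = tests, descriptives = desc)
}

# family_id -> litter_size, taken from the per-interval table when the
# classification input carries it, otherwise 1.
litter_lookup <- function(classifications) {
  if ("litter_size" %in% names(classifications)) {
    u <- unique(classifications[, c("family_id", "litter_size")])
    stats::setNames(u$litter_size, u$family_id)
  } else {
    fams <- unique(classifications$family_id)
    stats::setNames(rep(1L, length(fams)), fams)
  }
}

#' Run the full analysis on a set of sessions
#'
#' Extracts observation intervals, classifies every interval, aggregates
#' per-family summaries and computes the group statistics.
#'
#' @param sessions list of [session()] objects.
#' @param extraction an [extraction_config()].
#' @param sequential_denominator see [summarize_families()].
#' @param approximation,quantile_type,glmm see [group_statistics()].
#' @return an object of class `vx_analysis`: list with `ois`,
#'   `classifications`, `summaries`, `statistics`.
#' @export
analyze_sessions <- function(sessions, extraction = extraction_config(),
                             sequential_denominator = c("reciprocal", "all"),
                             approximation = c("asymptotic", "exact"),
                             quantile_type = 7, glmm = FALSE) {
  sequential_denominator <- match.arg(sequential_denominator)
  approximation <- match.arg(approximation)
  ois <- do.call(rbind, lapply(sessions, extract_ois, cfg = extraction))
  calls <- do.call(rbind, lapply(sessions, `[[`, "calls"))
  cls <- classify_ois(ois, calls)
  if (nrow(cls)) {
    litter <- stats::setNames(
      vapply(sessions, `[[`, 0L, "litter_size"),
      vapply(sessions, `[[`, "", "family_id"))
    cls$litter_size <- unname(litter[cls$family_id])
  }
  summaries <- if (nrow(cls)) {
    summarize_families(cls, sequential_denominator)
  } else {
    data.frame()
  }
  statistics <- if (nrow(cls)) {
    group_statistics(summaries, cls, approximation = approximation,
                     quantile_type = quantile_type, glmm = glmm)
  } else {
    list(tests = list(), descriptives = list(),
         note = "no observation intervals: nothing to test")
  }
  structure(list(ois = ois, classifications = cls, summaries = summaries,
                 statistics = statistics),
            class = "vx_analysis")
}

#' @export
print.vx_analysis <- function(x, ...) {
  cat(sprintf("<vx_analysis> %d OIs (%d reunion, %d leave-taking), %d families\n",
              nrow(x$ois), sum(x$ois$condition == "reunion"),
              sum(x$ois$condition == "leave_taking"),
              length(unique(x$ois$family_id))))
  for (nm in names(x$statistics$tests)) {
    t <- x$statistics$tests[[nm]]
    cat(sprintf("  %-22s T = %6.2f  N = %2s  p = %s\n", nm,
                if (is.na(t$statistic)) NA else t$statistic,
                t$n, format.pval(t$p_value, digits = 3)))
  }
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles the simulation, extraction, classification and statistics
#' options of a full run. `seed` overrides the simulation seed so one
#' number controls all randomness.
#'
#' @param simulation a [simulation_config()].
#' @param extraction an [extraction_config()].
#' @param sequential_denominator,approximation,quantile_type,glmm see
#'   [analyze_sessions()].
#' @param seed optional integer overriding `simulation$seed`.
#' @return an object of class `vx_pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            extraction = extraction_config(),
                            sequential_denominator = "reciprocal",
                            approximation = "asymptotic",
                            quantile_type = 7, glmm = FALSE, seed = NULL) {
  if (!is.null(seed)) simulation$seed <- as.integer(seed)
  structure(list(simulation = simulation, extraction = extraction,
                 sequential_denominator = sequential_denominator,
                 approximation = approximation,
                 quantile_type = quantile_type, glmm = glmm),
            class = "vx_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any subset of the [pipeline_config()] fields may be given; unnamed
#' parameters keep their defaults. Nested blocks `simulation:` and
#' `extraction:` map onto [simulation_config()] and
#' [extraction_config()] arguments.
#'
#' @param path YAML file.
#' @param seed optional seed override (e.g. from a command line).
#' @return a `vx_pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  sim <- do.call(simulation_config, raw$simulation %||% list())
  ext <- do.call(extraction_config, raw$extraction %||% list())
  pipeline_config(
    simulation = sim, extraction = ext,
    sequential_denominator = raw$sequential_denominator %||% "reciprocal",
    approximation = raw$approximation %||% "asymptotic",
    quantile_type = raw$quantile_type %||% 7,
    glmm = isTRUE(raw$glmm),
    seed = seed %||% raw$seed
  )
}

#' Analyze event/stay files and write result tables
#'
#' File-level entry point mirroring the `analyze` subcommand: reads the
#' canonical CSVs, runs [analyze_sessions()] and writes the interval
#' table, the per-interval classifications, the per-family summaries and
#' the statistics report (JSON) to `out_dir`.
#'
#' @param events_path,stays_path,sessions_path input CSVs (see
#'   [read_sessions()]).
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if missing.
#' @return the [analyze_sessions()] result, invisibly.
#' @export
analyze_files <- function(events_path, stays_path, sessions_path = NULL,
                          config = pipeline_config(), out_dir) {
  sessions <- read_sessions(events_path, stays_path, sessions_path)
  res <- analyze_sessions(
    sessions, extraction = config$extraction,
    sequential_denominator = config$sequential_denominator,
    approximation = config$approximation,
    quantile_type = config$quantile_type, glmm = config$glmm
  )
  write_analysis(res, out_dir)
  invisible(res)
}

write_analysis <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$ois, file.path(out_dir, "ois.csv"), row.names = FALSE)
  utils::write.csv(res$classifications,
                   file.path(out_dir, "classifications.csv"), row.names = FALSE)
  utils::write.csv(res$summaries, file.path(out_dir, "family_summaries.csv"),
                   row.names = FALSE)
  jsonlite::write_json(statistics_report(res$statistics),
                       file.path(out_dir, "statistics.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       na = "null", pretty = TRUE)
  invisible(out_dir)
}

# strip classes so the report serializes as plain JSON
statistics_report <- function(statistics) {
  statistics$tests <- lapply(statistics$tests, unclass)
  statistics
}

#' Simulate, analyze and report in one reproducible run
#'
#' The `run` entry point: simulates a study from `config$simulation`,
#' writes the canonical event/stay/ground-truth files, reads them back
#' (exercising the round trip), analyzes them and writes all result
#' tables plus a `run_log.yaml` recording the configuration, seed and
#' package version.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return the analysis result, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(config$simulation)
  paths <- write_study(study, out_dir)
  res <- analyze_files(paths[["events"]], paths[["stays"]],
                       paths[["sessions"]], config, out_dir)
  log <- list(
    package = "vocalexchange",
    version = as.character(utils::packageVersion("vocalexchange")),
    seed = config$simulation$seed,
    config = list(
      simulation = unclass(config$simulation),
      extraction = unclass(config$extraction),
      sequential_denominator = config$sequential_denominator,
      approximation = config$approximation,
      quantile_type = config$quantile_type,
      glmm = config$glmm
    )
  )
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(res)
}
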