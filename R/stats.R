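#' Wilcoxon signed-rank test (paired or one-sample)
#'
#' Implements the signed-rank conventions used for the group-level
#' comparisons. Differences `d = x - y` (or `x - mu` in the one-sample
#' form) that are exactly zero are dropped; `n` is the number of non-zero
#' differences; absolute differences are ranked with mid-ranks for ties;
#' the reported statistic `T` is the smaller of the two signed rank sums
#' (so `T = 0` when every difference shares one sign).
#'
#' The asymptotic two-sided p-value is the normal approximation
#' *without* continuity correction,
#' `p = 2 * pnorm((T - n(n+1)/4) / sigma)` with
#' `sigma^2 = n(n+1)(2n+1)/24 - sum(t^3 - t)/48` over tie groups `t`.
#' The exact p-value is computed from the full permutation distribution of
#' the positive-rank sum over all `2^n` sign assignments (evaluated by
#' convolution over the observed ranks, so ties are handled exactly):
#' `p = P(|W - n(n+1)/4| >= |W_obs - n(n+1)/4|)`.
#'
#' @param x numeric vector (condition A, or the sample in one-sample use).
#' @param y optional numeric vector of the same length (condition B).
#' @param mu reference value for the one-sample form (ignored when `y` is
#'   given); default 0.
#' @param approximation `"asymptotic"` (default) or `"exact"`.
#' @return an object of class `vx_test` with fields `method`, `statistic`
#'   (T, the smaller rank sum), `n`, `p_value`, `approximation`, `w_plus`,
#'   `w_minus`.
#' @examples
#' # eleven per-family percentages, all larger under the first condition:
#' wilcoxon_paired(seq(40, 90, 5), rep(0, 11))   # T = 0, p = 0.003
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0,
                                 approximation = c("asymptotic", "exact")) {
  approximation <- match.arg(approximation)
  x <- as.numeric(x)
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
    if (length(x) < 2L) stop("need at least two pairs", call. = FALSE)
    d <- x - y
    method <- "wilcoxon_paired"
  } else {
    if (length(x) < 2L) stop("need at least two observations", call. = FALSE)
    d <- x - mu
    method <- "wilcoxon_one_sample"
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("all differences are zero: signed-rank test undefined", call. = FALSE)
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  statistic <- min(w_plus, w_minus)
  mean_w <- n * (n + 1) / 4

  if (approximation == "asymptotic") {
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      stop("zero variance in signed-rank statistic", call. = FALSE)
    }
    z <- (statistic - mean_w) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
  } else {
    p <- exact_signed_rank_p(r, w_plus)
  }
  structure(
    list(method = method, statistic = statistic, n = n, p_value = p,
         approximation = approximation, w_plus = w_plus, w_minus = w_minus),
    class = "vx_test"
  )
}

# Exact two-sided p for the signed-rank statistic given the observed
# (mid-)ranks: distribution of the positive-rank sum over all 2^n sign
# vectors, computed by convolution. Ranks are doubled so mid-ranks (k.5)
# stay integral.
exact_signed_rank_p <- function(r, w_plus_obs) {
  u <- as.integer(round(2 * r))
  s2 <- sum(u)
  dist <- numeric(s2 + 1L)
  dist[1L] <- 1
  for (ui in u) {
    shifted <- c(numeric(ui), dist[seq_len(s2 + 1L - ui)])
    dist <- 0.5 * dist + 0.5 * shifted
  }
  w2 <- 0:s2                          # possible doubled rank sums
  dev_obs <- abs(w_plus_obs - s2 / 4) # |W+ - n(n+1)/4| in rank units
  dev <- abs(w2 / 2 - s2 / 4)
  min(1, sum(dist[dev >= dev_obs - 1e-9]))
}

#' @rdname wilcoxon_signed_rank
#' @export
wilcoxon_paired <- function(x, y, approximation = c("asymptotic", "exact")) {
  wilcoxon_signed_rank(x, y = y, approximation = match.arg(approximation))
}

#' @rdname wilcoxon_signed_rank
#' @export
wilcoxon_one_sample <- function(x, mu,
                                approximation = c("asymptotic", "exact")) {
  wilcoxon_signed_rank(x, mu = mu, approximation = match.arg(approximation))
}

#' @export
print.vx_test <- function(x, ...) {
  cat(sprintf("<vx_test> %s: T = %.2f, N = %d, p = %.4g (%s)\n",
              x$method, x$statistic, x$n, x$p_value, x$approximation))
  invisible(x)
}

#' Median and interquartile range
#'
#' @param values numeric vector (at least one value).
#' @param type quantile convention passed to [stats::quantile()]; the
#'   default (7, linear interpolation) is R's default and is documented as
#'   the package convention — quartiles from other statistics packages may
#'   differ slightly.
#' @return a list with `median`, `q25`, `q75`, `n`.
#' @export
describe_quartiles <- function(values, type = 7) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values to describe", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  list(median = q[2], q25 = q[1], q75 = q[3], n = length(values))
}

#' Binomial mixed model for a per-interval binary outcome
#'
#' Optional cross-check of the paired nonparametric comparison: fits
#' `outcome ~ condition + (1 | family_id) + (1 | litter_size)` with a
#' binomial response via `lme4::glmer` and reports the Wald two-sided
#' p-value of the condition effect (reunion vs leave-taking). Litter size
#' enters as a random intercept even though it has at most three levels;
#' convergence problems are surfaced in the result, never hidden.
#'
#' @param per_oi data.frame with logical/0-1 `outcome`, `condition`
#'   (`"reunion"`/`"leave_taking"`), `family_id`, `litter_size`.
#' @return a `vx_test`-classed list: `method = "binomial_glmm"`,
#'   `estimate` (log-odds of reunion vs leave-taking), `p_value` (`NA`
#'   with a `note` on non-convergence), `n` (rows used).
#' @export
fit_condition_glmm <- function(per_oi) {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    stop("fit_condition_glmm requires the 'lme4' package", call. = FALSE)
  }
  need <- c("outcome", "condition", "family_id", "litter_size")
  missing_cols <- setdiff(need, names(per_oi))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(per_oi$family_id)) < 2L) {
    stop("need at least two families to fit a mixed model", call. = FALSE)
  }
  if (length(unique(per_oi$condition)) < 2L) {
    stop("both conditions must be present", call. = FALSE)
  }
  dat <- data.frame(
    outcome = as.integer(per_oi$outcome),
    condition = factor(per_oi$condition, levels = c("leave_taking", "reunion")),
    family_id = factor(per_oi$family_id),
    litter_size = factor(per_oi$litter_size)
  )
  note <- NULL
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(outcome ~ condition + (1 | family_id) + (1 | litter_size),
                  data = dat, family = stats::binomial()),
      error = function(e) e
    ),
    warning = function(w) {
      note <<- c(note, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (inherits(fit, "error")) {
    return(structure(list(method = "binomial_glmm", statistic = NA_real_,
                          estimate = NA_real_, n = nrow(dat),
                          p_value = NA_real_, approximation = "wald",
                          note = conditionMessage(fit)),
                     class = "vx_test"))
  }
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$messages)) note <- c(note, unlist(conv$messages))
  co <- summary(fit)$coefficients
  row <- grep("^condition", rownames(co))
  est <- co[row, "Estimate"]
  p <- co[row, "Pr(>|z|)"]
  failed <- any(grepl("failed to converge|Model failed", note %||% character()))
  structure(
    list(method = "binomial_glmm", statistic = co[row, "z value"],
         estimate = est, n = nrow(dat),
         p_value = if (failed) NA_real_ else unname(p),
         approximation = "wald",
         note = if (length(note)) paste(note, collapse = "; ") else NULL),
    class = "vx_test"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
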