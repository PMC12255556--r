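#' Summarize QA metrics across sessions
#'
#' Computes, for every scalar metric, the mean, sample standard deviation
#' and coefficient of variation (`cv = 100 * sd / mean`) across sessions,
#' flagging metrics whose CV is strictly above the threshold (10% by
#' convention). The summary is invariant under permutation of the
#' sessions.
#'
#' @param sessions A list of [qa_report()] objects, or a data.frame with
#'   one row per session and one numeric column per metric (e.g. from
#'   [reports_to_table()]).
#' @param cv_flag_threshold Flagging threshold for the CV in percent
#'   (strict inequality).
#' @return A data.frame of class `repeatability_summary` with columns
#'   `metric`, `mean`, `sd`, `cv_percent`, `flagged`, `n_sessions`.
#' @export
summarize_sessions <- function(sessions, cv_flag_threshold = 10) {
  tab <- if (is.data.frame(sessions)) sessions else reports_to_table(sessions)
  if (nrow(tab) < 2L) stop("insufficient sessions: need at least 2")
  num <- tab[vapply(tab, is.numeric, TRUE)]
  out <- do.call(rbind, lapply(names(num), function(m) {
    x <- num[[m]]
    mu <- mean(x)
    s <- sd(x)
    cv <- 100 * s / mu
    data.frame(metric = m, mean = mu, sd = s, cv_percent = cv,
               flagged = is.finite(cv) && cv > cv_flag_threshold,
               n_sessions = length(x), stringsAsFactors = FALSE)
  }))
  class(out) <- c("repeatability_summary", class(out))
  out
}

#' Control chart for longitudinal QA monitoring
#'
#' Computes control limits `grand mean +/- 3 * SEM` from a baseline set of
#' sample means, where `SEM = sd / sqrt(n)` uses the sample SD of the
#' (optionally grouped) means. A value is out of control iff it lies
#' strictly outside the limits. With identical inputs the limits have zero
#' width and nothing violates them.
#'
#' @param sample_means Numeric vector of per-sample (e.g. per-day) metric
#'   means, length >= 3 after grouping.
#' @param newdata Optional values to evaluate against the baseline limits
#'   (e.g. a new session).
#' @param group_size Average this many consecutive sessions into one sample
#'   mean before charting (trailing incomplete groups are dropped).
#' @return List with `center`, `sem`, `lower`, `upper`, `violations`
#'   (indices of baseline values outside the limits) and
#'   `newdata_violations` (indices into `newdata`).
#' @export
control_chart <- function(sample_means, newdata = NULL, group_size = 1L) {
  x <- as.numeric(sample_means)
  if (group_size > 1L) {
    ng <- length(x) %/% group_size
    if (ng < 1L) stop("insufficient sessions for the requested group size")
    x <- vapply(seq_len(ng), function(g)
      mean(x[((g - 1L) * group_size + 1L):(g * group_size)]), 0)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 sample means")
  center <- mean(x)
  sem <- sd(x) / sqrt(n)
  lower <- center - 3 * sem
  upper <- center + 3 * sem
  outside <- function(v) which(v < lower | v > upper)
  list(center = center, sem = sem, lower = lower, upper = upper,
       violations = outside(x),
       newdata_violations = if (is.null(newdata)) integer() else outside(as.numeric(newdata)))
}
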