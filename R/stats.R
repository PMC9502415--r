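#' One-way ANOVA over replicate summaries
#'
#' Classical fixed-effects one-way analysis of variance (F =
#' MS_between / MS_within) across condition groups of per-replicate summary
#' values, e.g. mean gate distance over the last 5 ns of each replicate.
#' The fit goes through [stats::aov()].
#'
#' @param groups a named list of numeric vectors (condition -> replicate
#'   values) or a data.frame with columns `condition` and `value`. At least
#'   2 conditions with >= 2 replicates each.
#' @return An `AnovaResult`: list with `F`, `df_between`, `df_within`,
#'   `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$condition)
  }
  if (length(groups) < 2) {
    stop("ANOVA needs at least 2 condition groups", call. = FALSE)
  }
  if (any(lengths(groups) < 2)) {
    stop("every condition needs at least 2 replicates", call. = FALSE)
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    condition = factor(rep(names(groups) %||%
                             as.character(seq_along(groups)),
                           lengths(groups))))
  if (all(vapply(groups, stats::var, numeric(1)) < 1e-300)) {
    stop("zero within-group variance: F is undefined", call. = FALSE)
  }
  fit <- stats::aov(value ~ condition, data = df)
  tab <- summary(fit)[[1]]
  structure(list(F = tab[["F value"]][1],
                 df_between = tab[["Df"]][1],
                 df_within = tab[["Df"]][2],
                 p_value = tab[["Pr(>F)"]][1]),
            class = "AnovaResult")
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}

#' Minimum replicates per condition for a two-sample comparison
#'
#' Normal-approximation sizing for detecting a difference of means `delta`
#' at standard deviation `sigma` with two-sided level `alpha` and the given
#' power: `n = ceiling(2 * ((z_{1-alpha/2} + z_{power}) * sigma/delta)^2)`,
#' floored at 2. A one-standard-deviation effect at alpha 0.05 / power 0.8
#' needs 16 replicates per group; small simulation campaigns typically
#' target larger effects, which is how replicate counts such as "at least
#' six" arise.
#'
#' @param delta difference of means to detect (same units as `sigma`,
#'   non-zero).
#' @param sigma common standard deviation (> 0).
#' @param alpha two-sided type-I level in (0, 1).
#' @param power target power in (0, 1).
#' @param refine_t iterate a t-quantile refinement instead of the plain
#'   normal approximation.
#' @return Minimum replicates per group (integer >= 2).
#' @export
required_replicates <- function(delta, sigma, alpha = 0.05, power = 0.8,
                                refine_t = FALSE) {
  if (!(is.numeric(delta) && delta != 0)) {
    stop("effect size delta must be non-zero", call. = FALSE)
  }
  stopifnot(sigma > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n <- max(2, ceiling(2 * ((za + zb) * sigma / abs(delta))^2))
  if (refine_t) {
    for (it in 1:20) {
      df <- 2 * n - 2
      ta <- stats::qt(1 - alpha / 2, df)
      tb <- stats::qt(power, df)
      n_new <- max(2, ceiling(2 * ((ta + tb) * sigma / abs(delta))^2))
      if (n_new == n) break
      n <- n_new
    }
  }
  as.integer(n)
}

#' Per-replicate summary of windowed gate distances
#'
#' Summarizes each replicate's gate-distance series over a window into one
#' number per replicate (`mode = "replicate-mean"`, the default, which
#' avoids frame-level pseudo-replication) or pools all windowed frames
#' (`mode = "pooled-frames"`).
#'
#' @param series_list named list (condition -> list of `TimeSeries`, one
#'   per replicate).
#' @param mode summary mode.
#' @return data.frame with columns `condition`, `replicate`, `value`
#'   (pooled mode repeats the replicate id per frame).
#' @export
replicate_summary <- function(series_list,
                              mode = c("replicate-mean", "pooled-frames")) {
  mode <- match.arg(mode)
  rows <- list()
  for (cond in names(series_list)) {
    reps <- series_list[[cond]]
    for (r in seq_along(reps)) {
      vals <- if (mode == "replicate-mean") mean(reps[[r]]$values) else
        reps[[r]]$values
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, replicate = r, value = vals,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
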