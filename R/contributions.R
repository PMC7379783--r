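#' Phase-wise individual muscle contributions
#'
#' Converts per-frame muscle forces into one contribution percentage per
#' muscle for a gait phase: the time integral of each muscle's force over the
#' phase divided by the integral of the summed force of all modelled muscles,
#' times 100. Integration is trapezoidal over the solved frames inside the
#' half-open interval. The vector sums to 100 by construction.
#'
#' @param solution A `muscle_force_solution` from [solve_trial()].
#' @param interval Numeric `c(start, end)` in seconds, or a `gait_phases`
#'   object plus `phase` name.
#' @param phase Phase name when `interval` is a `gait_phases` object
#'   (`"braking"`, `"push_off"`, `"stance"`).
#' @return Named numeric vector of contributions, percent, summing to 100.
#' @export
phase_contribution <- function(solution, interval, phase = "braking") {
  if (inherits(interval, "gait_phases")) interval <- interval$intervals[[phase]]
  if (is.null(interval) || length(interval) != 2)
    stop("interval must be c(start, end)")
  inside <- solution$time >= interval[1] & solution$time < interval[2]
  if (!any(inside)) stop("out of range: no frames inside the phase")
  solved <- inside & solution$status == "solved"
  if (mean(solution$status[inside] != "solved") > 0.20)
    stop("insufficient coverage: unsolved frames exceed 20% of phase")
  if (sum(solved) < 2) stop("insufficient coverage: fewer than 2 solved frames")
  tt <- solution$time[solved]
  Fm <- solution$forces[solved, , drop = FALSE]
  w <- .trapz_weights(tt)
  ints <- drop(w %*% Fm)
  total <- sum(ints)
  if (total <= 0) stop("no force in phase")
  stats::setNames(100 * ints / total, solution$muscle_order)
}

.trapz_weights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  dt <- diff(t)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-(n - 1)] + dt[-1]) / 2
  w
}

#' Build a contribution table row-block for one trial
#'
#' @param contrib Named contribution vector from [phase_contribution()].
#' @param subject,condition,phase Labels.
#' @return Data frame with one row per muscle.
#' @export
contribution_rows <- function(contrib, subject, condition, phase) {
  data.frame(subject = subject, condition = condition, phase = phase,
             muscle = names(contrib), contribution = as.numeric(contrib),
             row.names = NULL)
}

#' Aggregate a cohort contribution table
#'
#' Per-subject averages across that subject's trials are computed first, then
#' group mean and SD per muscle and condition (the repeated-measures layout of
#' the study table this mirrors). Every subject must be present in every
#' condition.
#'
#' @param table Long contribution table (`subject`, `condition`, `phase`,
#'   `muscle`, `contribution`), e.g. from [analyze_cohort()].
#' @param phase Phase to aggregate (default `"braking"`).
#' @return Data frame with columns `muscle`, `condition`, `mean`, `sd`, `n`;
#'   muscles in first-appearance order.
#' @export
aggregate_cohort <- function(table, phase = "braking") {
  tb <- table[table$phase == phase, , drop = FALSE]
  if (!nrow(tb)) stop("no rows for phase '", phase, "'")
  cells <- unique(tb[, c("subject", "condition")])
  tab <- table(cells$subject)
  ncond <- length(unique(tb$condition))
  if (any(tab != ncond)) stop("unbalanced design: missing subject x condition cell")
  per_subj <- stats::aggregate(contribution ~ subject + condition + muscle,
                               tb, mean)
  out <- stats::aggregate(contribution ~ muscle + condition, per_subj,
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  res <- data.frame(muscle = out$muscle, condition = out$condition,
                    mean = out$contribution[, "mean"],
                    sd = out$contribution[, "sd"],
                    n = out$contribution[, "n"], row.names = NULL)
  res$muscle <- factor(res$muscle, levels = unique(tb$muscle))
  res <- res[order(res$muscle, res$condition), ]
  res$muscle <- as.character(res$muscle)
  rownames(res) <- NULL
  res
}

#' Wide (study-table style) view of an aggregated cohort
#'
#' @param agg Output of [aggregate_cohort()].
#' @param digits Rounding for display.
#' @return Data frame, one row per muscle, one `mean ± SD` column per
#'   condition.
#' @export
contribution_wide <- function(agg, digits = 1) {
  conds <- unique(agg$condition)
  muscles <- unique(agg$muscle)
  out <- data.frame(muscle = muscles)
  for (cd in conds) {
    sub <- agg[agg$condition == cd, ]
    out[[paste0(format(cd), " kg")]] <-
      paste0(round(sub$mean[match(muscles, sub$muscle)], digits), " ± ",
             round(sub$sd[match(muscles, sub$muscle)], digits))
  }
  out
}
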