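#' Sample skewness
#'
#' Moment-based skewness `g1 = m3 / m2^(3/2)` with central moments
#' `m_r = mean((x - mean(x))^r)`. Used as a distribution screen before the
#' repeated-measures ANOVA; advisory only (reported, never gating).
#'
#' @param values Numeric sample, `n >= 3`, nonzero variance.
#' @return The g1 statistic.
#' @export
skewness <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("degenerate sample: need n >= 3")
  d <- values - mean(values)
  m2 <- mean(d^2)
  if (m2 <= 0) stop("degenerate sample: zero variance")
  mean(d^3) / m2^1.5
}

#' One-way repeated-measures ANOVA
#'
#' Classical subject-by-condition sum-of-squares decomposition for a complete
#' balanced design: `SS_total = SS_condition + SS_subject + SS_error`,
#' `F = MS_condition / MS_error` with degrees of freedom `(k - 1,
#' (n - 1)(k - 1))`. No sphericity correction is applied (mirroring the
#' analysis this package reimplements); the Greenhouse-Geisser epsilon is
#' reported informationally.
#'
#' @param data `n_subjects x k_conditions` numeric matrix (rows = subjects).
#' @return A list of class `rm_anova` with `F`, `df`, `p`, the sums of
#'   squares, mean squares, `gg_epsilon` and the condition means.
#' @export
rm_anova <- function(data) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("unbalanced design: missing cell")
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions")
  grand <- mean(data)
  cond_means <- colMeans(data)
  subj_means <- rowMeans(data)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((data - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  if (ms_err <= 0) {
    if (ss_cond > 0) stop("degenerate error term")
    f <- 0; p <- 1
  } else {
    f <- ms_cond / ms_err
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  # Greenhouse-Geisser epsilon from the double-centred covariance
  S <- stats::cov(data)
  Sc <- S - outer(rowMeans(S), colMeans(S), `+`) + mean(S)
  eps <- if (sum(Sc^2) > 0) sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2)) else NA_real_
  structure(list(F = f, df = c(df1, df2), p = p,
                 ss = c(condition = ss_cond, subject = ss_subj,
                        error = ss_err, total = ss_tot),
                 ms = c(condition = ms_cond, error = ms_err),
                 gg_epsilon = eps, n = n, k = k,
                 cond_means = cond_means),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("RM one-way ANOVA: F(%d, %d) = %.3f, p = %.4g (GG eps %.3f)\n",
              x$df[1], x$df[2], x$F, x$p, x$gg_epsilon))
  invisible(x)
}

#' Fisher LSD post hoc pairwise tests
#'
#' Uncorrected pairwise t-tests using the ANOVA error term:
#' `t = (mean_i - mean_j) / sqrt(2 MS_error / n)` with `(n - 1)(k - 1)`
#' degrees of freedom, two-sided p-values. With `k = 2` this reduces to the
#' paired t-test (and `F = t^2`).
#'
#' @param data The `n x k` matrix passed to [rm_anova()].
#' @param anova The corresponding [rm_anova()] result.
#' @return Data frame of class `lsd_posthoc`: one row per condition pair with
#'   `mean_diff`, `t`, `df`, `p`.
#' @export
lsd_posthoc <- function(data, anova = rm_anova(data)) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  labs <- colnames(data)
  if (is.null(labs)) labs <- as.character(seq_len(k))
  se <- sqrt(2 * anova$ms["error"] / n)
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    d <- anova$cond_means[i] - anova$cond_means[j]
    tt <- if (se > 0) d / se else 0
    data.frame(pair = paste(labs[i], "vs", labs[j]),
               mean_diff = unname(d), t = unname(tt), df = anova$df[2],
               p = if (se > 0) 2 * stats::pt(-abs(tt), anova$df[2]) else 1)
  }))
  class(out) <- c("lsd_posthoc", "data.frame")
  out
}

#' Compare shoe-mass conditions across all muscles
#'
#' The full statistical report of the pipeline: for one gait phase, pivots the
#' long contribution table into a subject-by-condition matrix per muscle, runs
#' the skewness screen, the one-way repeated-measures ANOVA and the LSD post
#' hoc tests, and flags muscles at the significance level. LSD p-values carry
#' no multiplicity correction (by design, mirroring the source analysis).
#'
#' @param table Long contribution table (`subject`, `condition`, `phase`,
#'   `muscle`, `contribution`).
#' @param phase Gait phase to analyse (default `"braking"`).
#' @param alpha Significance level (default 0.05).
#' @return A list of class `condition_comparison`: `anova` data frame (one
#'   row per muscle: F, df, p, GG epsilon, max |skewness|, flagged), `posthoc`
#'   named list of [lsd_posthoc()] tables, `alpha`, `phase`.
#' @export
compare_conditions <- function(table, phase = "braking", alpha = 0.05) {
  tb <- table[table$phase == phase, , drop = FALSE]
  if (!nrow(tb)) stop("no rows for phase '", phase, "'")
  conds <- sort(unique(tb$condition))
  if (length(conds) < 2) stop("need >= 2 conditions")
  muscles <- unique(tb$muscle)
  posthoc <- list()
  rows <- lapply(muscles, function(m) {
    sub <- tb[tb$muscle == m, ]
    per_subj <- stats::aggregate(contribution ~ subject + condition, sub, mean)
    wide <- stats::reshape(per_subj, idvar = "subject", timevar = "condition",
                           direction = "wide")
    mat <- as.matrix(wide[, -1, drop = FALSE])
    colnames(mat) <- sub("^contribution\\.", "", colnames(mat))
    mat <- mat[, as.character(conds), drop = FALSE]
    if (anyNA(mat)) stop("unbalanced design: missing subject x condition cell")
    an <- rm_anova(mat)
    posthoc[[m]] <<- lsd_posthoc(mat, an)
    # advisory screen only: zero-variance cells (e.g. a muscle never
    # recruited) report NA rather than failing the comparison
    sks <- apply(mat, 2, function(v)
      tryCatch(skewness(v), error = function(e) NA_real_))
    sk <- if (all(is.na(sks))) NA_real_ else max(abs(sks), na.rm = TRUE)
    data.frame(muscle = m, F = an$F, df1 = an$df[1], df2 = an$df[2],
               p = an$p, gg_epsilon = an$gg_epsilon, max_abs_skewness = sk,
               flagged = an$p < alpha)
  })
  structure(list(anova = do.call(rbind, rows), posthoc = posthoc,
                 alpha = alpha, phase = phase, conditions = conds),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Condition comparison (", x$phase, " phase, alpha = ", x$alpha,
      "; uncorrected LSD post hoc)\n", sep = "")
  df <- x$anova
  df$F <- round(df$F, 3); df$p <- signif(df$p, 3)
  df$gg_epsilon <- round(df$gg_epsilon, 3)
  df$max_abs_skewness <- round(df$max_abs_skewness, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write the statistics report TSVs
#' @param comparison A `condition_comparison`.
#' @param anova_path,posthoc_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_stats_report <- function(comparison, anova_path, posthoc_path) {
  utils::write.table(comparison$anova, anova_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ph <- do.call(rbind, lapply(names(comparison$posthoc), function(m)
    cbind(muscle = m, comparison$posthoc[[m]])))
  utils::write.table(ph, posthoc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(anova_path, posthoc_path))
}
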