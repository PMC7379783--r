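#' Analyse a single trial end to end
#'
#' Runs the full inference chain on one recording: low-pass filtering
#' (4th-order zero-phase Butterworth, 12 Hz kinematics / 50 Hz force), gait
#' event detection and phase partition, Newton-Euler inverse dynamics about
#' the model DOFs, frame-wise static optimization, and phase-wise muscle
#' contribution percentages.
#'
#' @param recording A [trial_recording()].
#' @param model A `model_definition` (default: the bundled 17-muscle model).
#' @param phases Phase set (`"braking"`, `"push_off"`, `"stance"`) for which
#'   contributions are computed. The preactivation window is reported in the
#'   phase partition but carries no optimization output (no ground contact,
#'   hence no GRF-based moments).
#' @param threshold vGRF contact threshold, N.
#' @return A list of class `trial_analysis`: `phases` (`gait_phases`),
#'   `moments` (`joint_moment_series`), `solution`
#'   (`muscle_force_solution`), `contributions` (named list of contribution
#'   vectors, percent).
#' @export
analyze_trial <- function(recording, model = load_model(),
                          phases = c("braking", "push_off", "stance"),
                          threshold = 10) {
  ph <- segment_phases(recording, threshold = threshold)
  mom <- inverse_dynamics(recording, model, ph, threshold = threshold)
  sol <- solve_trial(model, mom)
  contrib <- lapply(stats::setNames(phases, phases), function(p)
    phase_contribution(sol, ph, phase = p))
  structure(list(phases = ph, moments = mom, solution = sol,
                 contributions = contrib),
            class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat("<trial_analysis>\n")
  print(x$phases)
  cat("  top braking contributors (%):\n")
  cb <- sort(x$contributions$braking, decreasing = TRUE)
  print(round(utils::head(cb, 5), 1))
  invisible(x)
}

#' Analyse a synthetic cohort end to end
#'
#' Applies [analyze_trial()] to every trial of a [generate_cohort()] result
#' (or any list of labelled recordings) and assembles the long contribution
#' table consumed by [aggregate_cohort()] and [compare_conditions()].
#'
#' @param cohort A `synthetic_cohort`, or a list of
#'   `list(subject, condition, recording)` entries.
#' @param model A `model_definition`.
#' @param phases Phases to tabulate.
#' @return Long contribution table: `subject`, `condition`, `phase`,
#'   `muscle`, `contribution` (percent).
#' @export
analyze_cohort <- function(cohort, model = load_model(),
                           phases = c("braking", "push_off", "stance")) {
  entries <- if (inherits(cohort, "synthetic_cohort")) cohort$trials else cohort
  out <- lapply(entries, function(e) {
    rec <- if (!is.null(e$trial)) e$trial$recording else e$recording
    an <- analyze_trial(rec, model, phases = phases)
    do.call(rbind, lapply(phases, function(p)
      contribution_rows(an$contributions[[p]], e$subject, e$condition, p)))
  })
  do.call(rbind, out)
}

#' Ground-truth contribution table of a synthetic cohort
#'
#' Contributions computed directly from the generator's truth forces and
#' truth phases, bypassing the estimation pipeline; the comparison target for
#' parameter-recovery checks.
#'
#' @param cohort A `synthetic_cohort`.
#' @param phases Phases to tabulate.
#' @return Long contribution table like [analyze_cohort()].
#' @export
truth_contributions <- function(cohort,
                                phases = c("braking", "push_off", "stance")) {
  out <- lapply(cohort$trials, function(e) {
    do.call(rbind, lapply(phases, function(p)
      contribution_rows(
        phase_contribution(e$trial$truth_solution, e$trial$truth_phases,
                           phase = p),
        e$subject, e$condition, p)))
  })
  do.call(rbind, out)
}
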