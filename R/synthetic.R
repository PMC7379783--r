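#' Synthetic trial parameters
#'
#' Parameter set of one synthetic running trial. Defaults emulate the study
#' design this package validates against: adult male runners (body mass 68 kg),
#' four shoe-mass conditions between 175 g and 415 g, a stance of about 0.22 s
#' within a 0.70 s stride, a double-hump vertical GRF peaking near 2.5 body
#' weights, and a braking-to-propulsion transition at 45% of stance.
#'
#' @param body_mass Body mass, kg.
#' @param shoe_mass Shoe mass, kg (study conditions: 0.175, 0.255, 0.335,
#'   0.415).
#' @param stance_duration Stance duration, s.
#' @param stride_duration Stride duration, s (> stance).
#' @param peak_vgrf_bw Vertical GRF active peak, body weights.
#' @param braking_fraction Fraction of stance before the AP zero crossing.
#' @param noise_sd_marker Marker measurement noise SD, m.
#' @param noise_sd_force Force measurement noise SD, N.
#' @param seed Integer seed; identical seeds give bit-identical trials.
#' @return An object of class `trial_params`.
#' @export
trial_params <- function(body_mass = 68, shoe_mass = 0.175,
                         stance_duration = 0.22, stride_duration = 0.70,
                         peak_vgrf_bw = 2.5, braking_fraction = 0.45,
                         noise_sd_marker = 0, noise_sd_force = 0, seed = 1L) {
  if (body_mass <= 0 || shoe_mass <= 0) stop("all masses must be > 0")
  if (braking_fraction <= 0 || braking_fraction >= 1)
    stop("braking_fraction must be in (0, 1)")
  if (stance_duration >= stride_duration)
    stop("stance_duration must be shorter than stride_duration")
  structure(as.list(environment()), class = "trial_params")
}

# Raised-cosine bump centred at c with half-width w (tau in stance fractions).
.bump <- function(tau, c, w) ifelse(abs(tau - c) < w,
                                    0.5 * (1 + cos(pi * (tau - c) / w)), 0)

# Contact onset/offset ramps: a 12 N/ms build-up to 40 N followed by a
# gentler 4 N/ms hold. The 10 N contact threshold is then crossed within
# ~1 ms of the nominal stance bounds both on the raw rendering and after the
# 50 Hz zero-phase filter (a sharper edge would leak backward through the
# filter and shift the detected events by several ms).
.wedge_slope <- 12000  # N/s
.wedge_cap <- 40       # N
.wedge_hold <- 4000    # N/s
.wedge <- function(tl) pmin(.wedge_slope * tl,
                            .wedge_cap + .wedge_hold * pmax(tl - .wedge_cap / .wedge_slope, 0))

#' Ground-reaction-force profile of the synthetic stance
#'
#' Analytic GRF template: the vertical component is the sum of two
#' raised-cosine bumps (impact peak near 13% stance, active peak of
#' `peak_vgrf_bw` body weights near 55%) combined with sharp linear
#' onset/offset wedges emulating the heel-strike transient; the
#' anterior-posterior component is a braking (negative) sine lobe up to
#' `braking_fraction` of stance followed by a propulsive lobe, with a single
#' zero crossing. Both components are continuous and zero at the stance
#' endpoints; the mediolateral component is zero.
#'
#' @param t Time(s) within stance, s, `0 <= t <= stance_duration`.
#' @param params A [trial_params()].
#' @return `length(t) x 3` matrix with columns `Fx` (AP), `Fy` (ML), `Fz`
#'   (vertical), newtons.
#' @export
grf_profile <- function(t, params) {
  T <- params$stance_duration
  if (any(t < -1e-12 | t > T + 1e-12)) stop("out of range: t outside stance")
  t <- pmin(pmax(t, 0), T)
  tau <- t / T
  bw <- params$body_mass * .g
  P <- params$peak_vgrf_bw * bw
  base <- 0.55 * P * .bump(tau, 0.13, 0.13) + P * .bump(tau, 0.55, 0.45)
  won <- ifelse(tau < 0.5, .wedge(t), 0)
  woff <- ifelse(tau > 0.5, .wedge(T - t), 0)
  fz <- pmax(base, won, woff)
  fz[tau <= 0 | tau >= 1] <- 0
  b <- params$braking_fraction
  amp <- 0.30 * bw
  # propulsive amplitude slope-matched at the zero crossing (C1 template):
  # a derivative kink there would shift the filtered crossing by ~0.5 ms,
  # which downstream contribution integrals can resolve
  amp_p <- amp * (1 - b) / b
  fx <- ifelse(tau <= b, -amp * sin(pi * tau / b),
               amp_p * sin(pi * (tau - b) / (1 - b)))
  fx[tau <= 0 | tau >= 1] <- 0
  cbind(Fx = fx, Fy = 0, Fz = fz)
}

# Stance-pose marker constants (right foot, metres; X forward, Y left, Z up).
.stance_pose <- list(
  ankle = c(0.020, -0.090, 0.090),
  heel  = c(-0.045, -0.090, 0.020),
  toe   = c(0.200, -0.080, 0.020),
  mtp   = c(0.130, -0.085, 0.020)
)

#' Scene parameters of the synthetic generator
#'
#' Internal geometry of the rendered stance: the centre-of-pressure path
#' (heel-to-toe progression in the sagittal plane, small lateral excursion for
#' the subtalar demand) and optional extra moment demand used to induce
#' condition effects. All lengths relative to the ankle, metres; moment
#' amplitudes in N·m shaped by a `sin^2` stance bump.
#'
#' @param cop_x_start,cop_x_end Sagittal CoP endpoints relative to the ankle.
#' @param cop_y_base,cop_y_amp Lateral CoP offset (negative = lateral) and
#'   excursion amplitude.
#' @param dM_ankle_amp,dM_sub_amp Extra ankle/subtalar moment demand, N·m.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(cop_x_start = -0.028, cop_x_end = 0.122,
                         cop_y_base = -0.004, cop_y_amp = 0.005,
                         dM_ankle_amp = 0, dM_sub_amp = 0) {
  structure(as.list(environment()), class = "scene_params")
}

.smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# CoP trajectory (global coordinates) over stance times t, given the rendered
# vertical force fz (used to convert extra moment demand into CoP shifts).
.cop_path <- function(t, fz, params, scene) {
  T <- params$stance_duration
  tau <- t / T
  ax <- .stance_pose$ankle[1]; ay <- .stance_pose$ankle[2]
  relx <- scene$cop_x_start +
    (scene$cop_x_end - scene$cop_x_start) * .smoothstep(tau)
  rely <- scene$cop_y_base - scene$cop_y_amp * sin(pi * tau)
  # effect demand is concentrated in the first half of stance (braking-
  # targeted): a CoP shift emulating a strike-pattern change
  bump <- sin(pi * pmin(tau / 0.5, 1))^2
  denom <- pmax(fz, 200)
  relx <- relx - scene$dM_ankle_amp * bump / denom
  rely <- rely - scene$dM_sub_amp * bump / denom
  relx <- pmin(relx, .stance_pose$mtp[1] - ax + 0.012)
  cbind(x = ax + relx, y = ay + rely)
}

# Closed-form truth moments of the static-foot scene, using the same
# free-body formulas as the inverse-dynamics module.
.truth_moments <- function(t_rel, params, scene, model) {
  g <- grf_profile(t_rel, params)
  cop <- .cop_path(t_rel, g[, "Fz"], params, scene)
  anthro <- segment_params(model, "foot")
  mass <- anthro$mass_fraction * params$body_mass + params$shoe_mass
  p_a <- .stance_pose$ankle
  p_c <- foot_com(p_a, .stance_pose$toe, anthro$com_offset_m)
  M <- matrix(0, length(t_rel), length(model$dofs),
              dimnames = list(NULL, paste0("M_", model$dofs)))
  for (i in seq_along(t_rel)) {
    ms <- newton_euler_foot(p_a, p_c, c(0, 0, 0), 0, mass, 0,
                            g[i, ], c(cop[i, 1], cop[i, 2], 0))
    M[i, 1] <- ms[1]
    if (ncol(M) >= 2) M[i, 2] <- ms[2]
    if (ncol(M) >= 3)
      M[i, 3] <- mtp_moment(.stance_pose$mtp, g[i, ], c(cop[i, 1], cop[i, 2], 0))
  }
  M
}

# Analytic event times of the noiseless template (10 N crossings and AP sign
# change), found on a dense grid of the closed-form profile.
.template_events <- function(params, t_hs) {
  T <- params$stance_duration
  tt <- seq(0, T, by = 1e-5)
  g <- grf_profile(tt, params)
  up <- which(g[, "Fz"] > 10)
  hs <- tt[up[1]]; to <- tt[up[length(up)]]
  list(heel_strike = t_hs + hs, toe_off = t_hs + to,
       brake_end = t_hs + params$braking_fraction * T)
}

#' Generate one synthetic running trial
#'
#' Renders a complete trial - marker trajectories at 200 Hz, force-plate
#' records at 1000 Hz, metadata - from an analytically defined stance scene
#' with known ground truth. The foot is stationary on the plate during stance;
#' truth DOF moments follow in closed form from the GRF, CoP path, gravity and
#' the (shoe-inclusive) foot mass, and truth muscle forces are the
#' squared-activation-minimal distribution of those moments, so the full
#' inverse problem is exactly feasible by construction. Optional measurement
#' noise is added after the truth is computed. Identical seeds give
#' bit-identical output.
#'
#' @param model A `model_definition`.
#' @param params A [trial_params()].
#' @param scene A [scene_params()] (defaults render a plain stance).
#' @param perturb_sd Optional SD (activation units) of a smooth null-space
#'   perturbation added to the truth forces; it leaves the truth moments
#'   unchanged but makes the truth no longer squared-activation-minimal, so
#'   exact pipeline recovery is only guaranteed at `perturb_sd = 0`.
#' @return An object of class `synthetic_trial`: list with `recording`
#'   ([trial_recording()]), `truth_forces` (stance frames x muscles, N),
#'   `truth_moments` (`joint_moment_series`), `truth_phases` (`gait_phases`),
#'   `params`, `scene`.
#' @export
generate_trial <- function(model, params, scene = scene_params(),
                           perturb_sd = 0) {
  stopifnot(inherits(params, "trial_params"))
  withr::with_seed(params$seed, {
    T <- params$stance_duration
    stride <- params$stride_duration
    t_hs <- round(0.15 * stride, 3)
    nf <- round(stride * 1000)
    t_force <- (seq_len(nf) - 1) / 1000
    nm <- round(stride * 200)
    t_marker <- (seq_len(nm) - 1) / 200

    in_stance <- t_force >= t_hs & t_force <= t_hs + T
    g <- matrix(0, nf, 3, dimnames = list(NULL, c("Fx", "Fy", "Fz")))
    g[in_stance, ] <- grf_profile(t_force[in_stance] - t_hs, params)
    # CoP is rendered over a slightly extended window (clamped to the stance
    # path) so zero-phase filtering of the force stream never pairs a
    # supra-threshold force sample with an undefined CoP
    ext <- t_force >= t_hs - 0.015 & t_force <= t_hs + T + 0.015
    cop <- matrix(0, nf, 2)
    cop[ext, ] <- .cop_path(pmin(pmax(t_force[ext] - t_hs, 0), T),
                            pmax(g[ext, "Fz"], 10), params, scene)

    # truth on stance frames above the contact threshold
    truth_idx <- which(in_stance & g[, "Fz"] > 10)
    M <- .truth_moments(t_force[truth_idx] - t_hs, params, scene, model)
    moments <- data.frame(time = t_force[truth_idx], M, check.names = FALSE)
    class(moments) <- c("joint_moment_series", "data.frame")
    sol <- tryCatch(solve_trial(model, moments, max_infeasible = 0),
                    error = function(e) stop("infeasible scenario: ",
                                             conditionMessage(e)))
    truth_forces <- sol$forces
    if (perturb_sd > 0) {
      R <- moment_arm_matrix(model)$values
      A <- sweep(R, 2, muscle_fmax(model), `*`)
      N <- .null_basis(A)
      if (ncol(N) > 0) {
        w <- stats::rnorm(ncol(N))
        tau <- (moments$time - t_hs) / T
        da <- outer(sin(pi * tau)^2, drop(N %*% w)) * perturb_sd
        a <- sweep(truth_forces, 2, muscle_fmax(model), `/`)
        # per-frame shrink so perturbed activations stay inside [0, 1]
        sc <- vapply(seq_len(nrow(a)), function(i) {
          d <- da[i, ]
          lim <- ifelse(d > 0, (1 - a[i, ]) / d, ifelse(d < 0, -a[i, ] / d, Inf))
          min(1, suppressWarnings(min(lim[is.finite(lim)])), na.rm = TRUE)
        }, numeric(1))
        a <- pmin(pmax(a + da * sc, 0), 1) # guard float dust at the bounds
        truth_forces <- sweep(a, 2, muscle_fmax(model), `*`)
      }
    }

    markers <- .render_markers(t_marker, t_hs, T, stride)
    if (params$noise_sd_marker > 0)
      markers <- lapply(markers, function(m)
        m + matrix(stats::rnorm(length(m), 0, params$noise_sd_marker),
                   nrow(m), 3))
    if (params$noise_sd_force > 0)
      g <- g + matrix(stats::rnorm(length(g), 0, params$noise_sd_force), nf, 3)

    forces <- data.frame(time = t_force, Fx = g[, 1], Fy = g[, 2], Fz = g[, 3],
                         CoPx = cop[, 1], CoPy = cop[, 2])
    rec <- trial_recording(markers, t_marker, forces,
                           body_mass = params$body_mass,
                           shoe_mass = params$shoe_mass)
    ev <- .template_events(params, t_hs)
    phases <- structure(
      list(heel_strike = ev$heel_strike, toe_off = ev$toe_off,
           brake_end = ev$brake_end,
           preactivation_start = ev$heel_strike - 0.050,
           intervals = list(
             preactivation = c(ev$heel_strike - 0.050, ev$heel_strike),
             stance = c(ev$heel_strike, ev$toe_off),
             braking = c(ev$heel_strike, ev$brake_end),
             push_off = c(ev$brake_end, ev$toe_off))),
      class = "gait_phases")
    structure(
      list(recording = rec,
           truth_forces = truth_forces, truth_time = moments$time,
           truth_moments = moments, truth_phases = phases,
           truth_solution = structure(
             list(time = moments$time, forces = truth_forces,
                  activations = sweep(truth_forces, 2, muscle_fmax(model), `/`),
                  objective = rowSums(sweep(truth_forces, 2,
                                            muscle_fmax(model), `/`)^2),
                  residual = sol$residual,
                  status = rep("solved", nrow(truth_forces)),
                  muscle_order = muscle_names(model)),
             class = "muscle_force_solution"),
           params = params, scene = scene),
      class = "synthetic_trial")
  })
}

.null_basis <- function(A) {
  sv <- svd(A, nu = 0, nv = ncol(A))
  r <- sum(sv$d > 1e-10 * max(sv$d))
  sv$v[, seq.int(r + 1, ncol(A)), drop = FALSE]
}

# Marker kinematics: foot markers stationary during stance, C2 cubic
# approach/departure in flight; knee and hip follow smooth sagittal paths.
.render_markers <- function(t, t_hs, T, stride) {
  t_to <- t_hs + T
  w_app <- 0.12; w_dep <- 0.12
  u1 <- pmax((t_hs - t) / w_app, 0)
  u2 <- pmax((t - t_to) / w_dep, 0)
  dx <- -0.10 * u1^3 + 0.10 * u2^3
  dz <- 0.10 * u1^3 + 0.10 * u2^3
  foot <- function(p) cbind(p[1] + dx, p[2] + 0 * t, p[3] + dz)
  knee <- cbind(0.02 + 0.25 * sin(2 * pi * (t - t_hs) / stride),
                -0.090 + 0 * t,
                0.50 + 0.02 * cos(2 * pi * (t - t_hs) / stride))
  hip <- cbind(-0.02 + 0.15 * sin(2 * pi * (t - t_hs) / stride),
               -0.050 + 0 * t,
               0.93 + 0.02 * cos(2 * pi * (t - t_hs) / stride))
  list(toe = foot(.stance_pose$toe), mtp = foot(.stance_pose$mtp),
       heel = foot(.stance_pose$heel), ankle = foot(.stance_pose$ankle),
       knee = knee, hip = hip)
}

#' Condition-effect specification for synthetic cohorts
#'
#' Describes a shoe-mass condition effect targeted at one muscle: for each
#' condition, extra moment demand of the given amplitude (N·m, `sin^2` stance
#' envelope) is rendered into the scene along the direction of that muscle's
#' ankle/subtalar moment arms. Positive amplitudes load the muscle (raising
#' its contribution); the effect is visible to the downstream pipeline because
#' it changes the net moments, not just the truth force split.
#'
#' @param muscle Target muscle name (must exist in the model).
#' @param amplitude Numeric vector of per-condition amplitudes, N·m (recycled
#'   to the number of conditions).
#' @return A list of class `contribution_effect`.
#' @export
contribution_effect <- function(muscle, amplitude) {
  structure(list(muscle = muscle, amplitude = amplitude),
            class = "contribution_effect")
}

#' Generate a synthetic cohort of running trials
#'
#' One trial per subject x shoe-mass condition, with seeded between-subject
#' variation (body mass, GRF amplitude, stance/stride timing, CoP geometry)
#' and smaller within-subject trial-to-trial variation, so a null cohort has
#' realistic repeated-measures variance. An optional [contribution_effect()]
#' adds condition-dependent moment demand targeted at one muscle.
#'
#' @param model A `model_definition`.
#' @param n_subjects Number of subjects (>= 2; the emulated study used 20).
#' @param conditions Shoe masses, kg (>= 2 conditions; default the four study
#'   conditions).
#' @param effect `NULL` (null cohort) or a [contribution_effect()].
#' @param seed Integer master seed.
#' @param noise_sd_marker,noise_sd_force Measurement noise SDs (m, N).
#' @param base_params Baseline [trial_params()] shared by the cohort.
#' @return An object of class `synthetic_cohort`: list with `trials` (list of
#'   `list(subject, condition, trial)`), `conditions`, `n_subjects`.
#' @export
generate_cohort <- function(model, n_subjects = 20,
                            conditions = c(0.175, 0.255, 0.335, 0.415),
                            effect = NULL, seed = 1L,
                            noise_sd_marker = 0, noise_sd_force = 0,
                            base_params = trial_params()) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (length(conditions) < 2) stop("need >= 2 conditions")
  if (!is.null(effect)) {
    if (!inherits(effect, "contribution_effect"))
      stop("effect must be a contribution_effect")
    if (!effect$muscle %in% muscle_names(model))
      stop("unknown muscle: ", effect$muscle)
    effect$amplitude <- rep_len(effect$amplitude, length(conditions))
  }
  R <- moment_arm_matrix(model)$values
  trials <- withr::with_seed(seed, {
    subj <- lapply(seq_len(n_subjects), function(s) list(
      body_mass = max(45, stats::rnorm(1, 68, 4.32)),
      peak_mult = stats::runif(1, 0.92, 1.08),
      stance_mult = stats::runif(1, 0.95, 1.05),
      stride_mult = stats::runif(1, 0.95, 1.05),
      brake_shift = stats::runif(1, -0.03, 0.03),
      cop_x_shift = stats::runif(1, -0.005, 0.005),
      cop_y_amp = stats::runif(1, 0.003, 0.008)))
    out <- list()
    for (s in seq_len(n_subjects)) {
      for (ci in seq_along(conditions)) {
        sj <- subj[[s]]
        p <- trial_params(
          body_mass = sj$body_mass,
          shoe_mass = conditions[ci],
          stance_duration = base_params$stance_duration * sj$stance_mult *
            stats::runif(1, 0.99, 1.01),
          stride_duration = base_params$stride_duration * sj$stride_mult *
            stats::runif(1, 0.99, 1.01),
          peak_vgrf_bw = base_params$peak_vgrf_bw * sj$peak_mult *
            stats::runif(1, 0.985, 1.015),
          braking_fraction = base_params$braking_fraction + sj$brake_shift +
            stats::runif(1, -0.01, 0.01),
          noise_sd_marker = noise_sd_marker,
          noise_sd_force = noise_sd_force,
          seed = sample.int(2^31 - 1, 1))
        sc <- scene_params(
          cop_x_start = -0.028 + sj$cop_x_shift + stats::runif(1, -0.002, 0.002),
          cop_x_end = 0.122 + sj$cop_x_shift,
          cop_y_amp = sj$cop_y_amp * stats::runif(1, 0.95, 1.05))
        if (!is.null(effect)) {
          arm <- R[1:2, effect$muscle]
          dir <- arm / sqrt(sum(arm^2))
          sc$dM_ankle_amp <- effect$amplitude[ci] * dir[1]
          sc$dM_sub_amp <- effect$amplitude[ci] * dir[2]
        }
        out[[length(out) + 1]] <- list(
          subject = s, condition = conditions[ci],
          trial = generate_trial(model, p, sc))
      }
    }
    out
  })
  structure(list(trials = trials, conditions = conditions,
                 n_subjects = n_subjects, effect = effect, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", x$n_subjects, " subjects x ",
      length(x$conditions), " conditions (",
      paste(x$conditions, collapse = "/"), " kg), ",
      length(x$trials), " trials\n", sep = "")
  invisible(x)
}
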