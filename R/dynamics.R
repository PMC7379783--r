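#' Numerical differentiation of sampled kinematics
#'
#' Central differences in the interior (exact for polynomials up to degree two
#' at interior samples) and one-sided differences at the ends.
#'
#' @param x Numeric vector (or matrix, differentiated column-wise) of
#'   positions or angles.
#' @param rate Sampling rate, Hz.
#' @return List with `velocity` and `acceleration`, same shape as `x`.
#' @export
differentiate <- function(x, rate) {
  if (is.matrix(x)) {
    v <- a <- x
    for (j in seq_len(ncol(x))) {
      d <- differentiate(x[, j], rate)
      v[, j] <- d$velocity; a[, j] <- d$acceleration
    }
    return(list(velocity = v, acceleration = a))
  }
  n <- length(x)
  if (n < 3) stop("insufficient samples for differentiation")
  h <- 1 / rate
  v <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / h
  a <- (x[c(3, 3:n, n)] - 2 * x[c(2, 2:(n - 1), n - 1)] +
          x[c(1, 1:(n - 2), n - 2)]) / h^2
  list(velocity = v, acceleration = a)
}

.g <- 9.81 # m/s^2, +Z up

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Single-frame foot free-body moment balance
#'
#' Net internal ankle-complex moments on the foot from a single-segment
#' Newton-Euler free-body balance. Positions are 3-vectors (X forward, Y left,
#' Z up, metres); `alpha_y` is the foot angular acceleration about +Y, rad/s².
#' Gravity acts along -Z at 9.81 m/s².
#'
#' @param p_ankle,p_com Ankle joint and foot centre-of-mass positions.
#' @param a_com Linear acceleration of the foot CoM, m/s².
#' @param alpha_y Foot angular acceleration about +Y, rad/s².
#' @param mass Foot mass (anthropometric foot plus shoe), kg.
#' @param inertia_y Foot moment of inertia about its CoM (Y axis), kg·m².
#' @param F_grf Ground reaction force 3-vector, N.
#' @param cop Centre of pressure 3-vector (Z = 0), m.
#' @return `c(ankle_flexion, subtalar)` internal moments, N·m, with
#'   dorsiflexion and inversion positive (right foot; lateral = -Y).
#' @export
newton_euler_foot <- function(p_ankle, p_com, a_com, alpha_y, mass, inertia_y,
                              F_grf, cop) {
  F_joint <- mass * (a_com - c(0, 0, -.g)) - F_grf
  m_grf <- .cross3(cop - p_com, F_grf)
  m_joint <- .cross3(p_ankle - p_com, F_joint)
  M_int_y <- inertia_y * alpha_y - m_grf[2] - m_joint[2]
  M_int_x <- -m_grf[1] - m_joint[1]
  c(ankle_flexion = -M_int_y, subtalar = M_int_x)
}

#' Single-frame MTP moment
#'
#' Internal metatarsophalangeal moment (toe extension positive) from the GRF
#' applied distal to the MTP marker; zero when the CoP is at or behind the MTP
#' joint.
#'
#' @param p_mtp MTP marker position 3-vector, m.
#' @param F_grf Ground reaction force 3-vector, N.
#' @param cop Centre of pressure 3-vector, m.
#' @return Internal MTP moment, N·m.
#' @export
mtp_moment <- function(p_mtp, F_grf, cop) {
  if (cop[1] <= p_mtp[1]) return(0)
  .cross3(cop - p_mtp, F_grf)[2]
}

# Foot segment geometry shared by the inverse dynamics and the synthetic
# generator: CoM sits `com_offset` metres from the ankle along the ankle->toe
# axis.
foot_com <- function(p_ankle, p_toe, com_offset) {
  u <- p_toe - p_ankle
  p_ankle + com_offset * u / sqrt(sum(u^2))
}

foot_angle <- function(p_heel, p_toe) {
  atan2(p_toe[, 3] - p_heel[, 3], p_toe[, 1] - p_heel[, 1])
}

#' Net joint moments by inverse dynamics
#'
#' Computes the net internal moments about the model DOFs (ankle flexion with
#' dorsiflexion positive, subtalar with inversion positive, MTP with toe
#' extension positive) for every force frame inside stance where the vertical
#' GRF exceeds the contact threshold. The foot is treated as a single rigid
#' segment (its mass includes the shoe mass as a point mass at the foot CoM);
#' gravitational, inertial and ground-reaction terms all enter the balance.
#' Marker-derived kinematics are low-pass filtered at `marker_cutoff`,
#' differentiated at the marker rate and interpolated onto the force clock;
#' forces are filtered at `force_cutoff`.
#'
#' @param recording A [trial_recording()].
#' @param model A `model_definition` (for anthropometry and DOF order).
#' @param phases A `gait_phases` object from [segment_phases()].
#' @param threshold vGRF contact threshold, newtons.
#' @param marker_cutoff,force_cutoff Low-pass cutoffs, Hz (defaults 12 / 50).
#' @param filter Set `FALSE` if streams are already filtered.
#' @return A data frame of class `joint_moment_series` with `time` and one
#'   `M_<dof>` column per model DOF, N·m, at the force clock inside stance.
#' @export
inverse_dynamics <- function(recording, model, phases, threshold = 10,
                             marker_cutoff = 12, force_cutoff = 50,
                             filter = TRUE) {
  need <- c("heel", "toe", "ankle", "mtp")
  if (!all(need %in% names(recording$markers)))
    stop("recording must provide markers: ", paste(need, collapse = ", "))
  mrate <- recording$marker_rate
  mk <- lapply(recording$markers[need], function(m)
    if (filter) lowpass(m, mrate, filter_spec(marker_cutoff)) else m)
  fo <- recording$forces
  F_mat <- as.matrix(fo[, c("Fx", "Fy", "Fz")])
  if (filter) F_mat <- lowpass(F_mat, recording$force_rate,
                               filter_spec(force_cutoff))

  anthro <- segment_params(model, "foot")
  mass <- anthro$mass_fraction * recording$body_mass + recording$shoe_mass
  inertia_y <- mass * anthro$gyration_radius_m^2

  # foot CoM and orientation on the marker clock
  nfrm <- nrow(mk$ankle)
  com <- t(vapply(seq_len(nfrm), function(i)
    foot_com(mk$ankle[i, ], mk$toe[i, ], anthro$com_offset_m), numeric(3)))
  theta <- foot_angle(mk$heel, mk$toe)
  d_com <- differentiate(com, mrate)
  d_theta <- differentiate(theta, mrate)
  alpha_y <- -d_theta$acceleration  # dorsiflexion rotation is about -Y

  in_stance <- fo$time >= phases$heel_strike & fo$time <= phases$toe_off &
    F_mat[, 3] > threshold
  tq <- fo$time[in_stance]
  if (!length(tq)) stop("no stance frames above threshold")
  interp_cols <- function(m) vapply(seq_len(ncol(m)), function(j)
    stats::approx(recording$marker_time, m[, j], xout = tq, rule = 2)$y,
    numeric(length(tq)))
  ankle_q <- interp_cols(mk$ankle)
  mtp_q <- interp_cols(mk$mtp)
  com_q <- interp_cols(com)
  acc_q <- interp_cols(d_com$acceleration)
  alpha_q <- stats::approx(recording$marker_time, alpha_y, xout = tq,
                           rule = 2)$y

  cop <- cbind(fo$CoPx[in_stance], fo$CoPy[in_stance], 0)
  if (anyNA(cop)) stop("missing CoP while vGRF above threshold")
  Fq <- F_mat[in_stance, , drop = FALSE]

  M <- matrix(NA_real_, nrow = length(tq), ncol = length(model$dofs),
              dimnames = list(NULL, paste0("M_", model$dofs)))
  for (i in seq_along(tq)) {
    ms <- newton_euler_foot(ankle_q[i, ], com_q[i, ], acc_q[i, ], alpha_q[i],
                            mass, inertia_y, Fq[i, ], cop[i, ])
    M[i, 1] <- ms[1]
    if (ncol(M) >= 2) M[i, 2] <- ms[2]
    if (ncol(M) >= 3) M[i, 3] <- mtp_moment(mtp_q[i, ], Fq[i, ], cop[i, ])
  }
  out <- data.frame(time = tq, M, check.names = FALSE)
  class(out) <- c("joint_moment_series", "data.frame")
  out
}
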