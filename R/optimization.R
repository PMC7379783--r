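#' Solve one static-optimization frame
#'
#' Distributes a net DOF moment vector across muscles by minimizing the sum of
#' squared activations `sum((F_i / f_max_i)^2)` subject to moment balance
#' `R F = M` and bounds `0 <= F_i <= f_max_i`. The problem is a strictly
#' convex bounded quadratic program; in activation variables it is the
#' projection of the origin onto the constraint polytope, solved here by a
#' damped semismooth Newton iteration on the dual (equality multipliers) with
#' bound clipping handled in closed form. Infeasible moments (outside the
#' attainable polytope) are reported, never silently clamped.
#'
#' @param R Moment-arm matrix (`n_dof x n_muscle`, metres) or a
#'   `moment_arm_matrix` object.
#' @param M Net DOF moment vector, N·m.
#' @param f_max Maximum isometric forces, N (positive).
#' @param tol Equality-residual tolerance: a frame is solved when
#'   `||R F - M|| <= tol * (1 + ||M||)` (default 1e-8; the solution contract
#'   guarantees 1e-6).
#' @param lambda0 Optional warm-start multipliers.
#' @return List with `forces` (N), `activations`, `objective`
#'   (`sum(activations^2)`), `residual` (N·m), `status` (`"solved"` or
#'   `"infeasible"`) and `lambda` (dual multipliers, for warm starting).
#' @export
solve_frame <- function(R, M, f_max, tol = 1e-8, lambda0 = NULL) {
  if (inherits(R, "moment_arm_matrix")) R <- R$values
  R <- matrix(as.numeric(R), nrow = length(M))
  if (ncol(R) != length(f_max)) stop("dimension mismatch between R and f_max")
  if (any(!is.finite(f_max)) || any(f_max <= 0)) stop("f_max must be > 0")
  if (any(!is.finite(M))) stop("M must be finite")
  A <- sweep(R, 2, f_max, `*`)          # moments per unit activation
  nd <- length(M)
  scale <- 1 + sqrt(sum(M^2))
  a_of <- function(lam) pmin(pmax(drop(crossprod(A, lam)) / 2, 0), 1)
  # concave dual of the projection problem; gradient is the equality residual
  neg_g <- function(lam) {
    a <- a_of(lam)
    s2 <- drop(crossprod(A, lam))       # = 2 s
    -(sum(a^2 - s2 * a) + sum(lam * M))
  }
  neg_grad <- function(lam) drop(A %*% a_of(lam)) - M

  lam <- if (is.null(lambda0)) numeric(nd) else lambda0
  opt <- stats::optim(lam, neg_g, neg_grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
  lam <- opt$par
  # active-set polish: exact equality solve on the strictly free coordinates
  s <- drop(crossprod(A, lam)) / 2
  a <- a_of(lam)
  free <- s > 1e-9 & s < 1 - 1e-9
  if (any(free)) {
    Af <- A[, free, drop = FALSE]
    rhs <- M - drop(A[, !free, drop = FALSE] %*% a[!free])
    sv <- svd(Af)
    pos <- sv$d > 1e-12 * max(sv$d, 1)
    lam_f <- sv$u[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos]^2)
    a_pol <- a
    a_pol[free] <- drop(crossprod(Af, lam_f))
    if (all(a_pol >= -1e-12 & a_pol <= 1 + 1e-12)) {
      a_pol <- pmin(pmax(a_pol, 0), 1)
      if (sqrt(sum((M - drop(A %*% a_pol))^2)) <=
          sqrt(sum((M - drop(A %*% a))^2)) + 1e-12) {
        a <- a_pol
        lam <- lam + 0 # multipliers retained for warm starting
      }
    }
  }
  residual <- sqrt(sum((M - drop(A %*% a))^2))
  status <- if (residual <= max(tol, 1e-8) * scale) "solved" else "infeasible"
  forces <- a * f_max
  list(forces = forces, activations = a, objective = sum(a^2),
       residual = residual, status = status, lambda = lam)
}

#' Solve static optimization for a whole moment series
#'
#' Runs [solve_frame()] frame by frame over a joint-moment series, warm
#' starting each frame from the previous multipliers. Infeasible frames are
#' flagged and excluded from downstream integration; more than
#' `max_infeasible` of infeasible frames aborts.
#'
#' @param model A `model_definition`.
#' @param moments A `joint_moment_series` from [inverse_dynamics()] (columns
#'   `time`, then one `M_<dof>` per model DOF).
#' @param tol Per-frame equality tolerance passed to [solve_frame()].
#' @param max_infeasible Maximum tolerated fraction of infeasible frames
#'   (default 0.05).
#' @return An object of class `muscle_force_solution`: list with `time`,
#'   `forces` (frames x muscles matrix, N), `activations`, `objective` (per
#'   frame), `residual`, `status` (character per frame) and `muscle_order`.
#' @export
solve_trial <- function(model, moments, tol = 1e-8, max_infeasible = 0.05) {
  R <- moment_arm_matrix(model)$values
  fmax <- muscle_fmax(model)
  mcols <- paste0("M_", model$dofs)
  if (!all(mcols %in% names(moments)))
    stop("unsynchronized streams: moment columns do not match model DOFs")
  Mmat <- as.matrix(moments[, mcols, drop = FALSE])
  if (any(!is.finite(Mmat))) stop("moments must be finite over stance")
  n <- nrow(Mmat)
  forces <- acts <- matrix(NA_real_, n, length(fmax),
                           dimnames = list(NULL, names(fmax)))
  objective <- residual <- numeric(n)
  status <- character(n)
  lam <- NULL
  for (i in seq_len(n)) {
    sol <- solve_frame(R, Mmat[i, ], fmax, tol = tol, lambda0 = lam)
    if (sol$status == "infeasible" && !is.null(lam)) # retry cold
      sol <- solve_frame(R, Mmat[i, ], fmax, tol = tol)
    forces[i, ] <- sol$forces
    acts[i, ] <- sol$activations
    objective[i] <- sol$objective
    residual[i] <- sol$residual
    status[i] <- sol$status
    lam <- if (sol$status == "solved") sol$lambda else NULL
  }
  frac_bad <- mean(status != "solved")
  if (frac_bad > max_infeasible)
    stop("model too weak for trial: ", round(100 * frac_bad, 1),
         "% infeasible frames")
  structure(
    list(time = moments$time, forces = forces, activations = acts,
         objective = objective, residual = residual, status = status,
         muscle_order = names(fmax)),
    class = "muscle_force_solution"
  )
}

#' @export
print.muscle_force_solution <- function(x, ...) {
  cat("<muscle_force_solution> ", nrow(x$forces), " frames x ",
      ncol(x$forces), " muscles; ", sum(x$status != "solved"),
      " infeasible\n", sep = "")
  invisible(x)
}

#' Write a per-frame solution TSV
#' @param solution A `muscle_force_solution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_solution <- function(solution, path) {
  df <- data.frame(time_s = solution$time, solution$forces,
                   objective = solution$objective, status = solution$status,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
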