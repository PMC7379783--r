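# Shared fixtures: tiny models, file writers and the brute-force QP oracle.

default_segments <- function() {
  data.frame(segment = c("foot", "shank"),
             mass_fraction = c(0.0145, 0.0465),
             com_offset_m = c(0.05, 0.19),
             gyration_radius_m = c(0.069, 0.10))
}

# One-DOF two-muscle model (agonist +0.05 m, antagonist -0.04 m).
tiny_model <- function(f_max = c(1000, 500), arms = c(0.05, -0.04)) {
  model_definition(
    list(muscle_element("ago", "plantarflexor", f_max[1], c(dof = arms[1])),
         muscle_element("anta", "dorsiflexor", f_max[2], c(dof = arms[2]))),
    dofs = "dof", segments = default_segments())
}

# Write a minimal single-muscle model file and return its path.
write_tiny_model_file <- function(path = tempfile(fileext = ".tsv"),
                                  f_max = 1000, arm = 0.05) {
  writeLines(c("[dofs]", "dof", "[muscles]",
               "muscle\tgroup\tf_max_N\tr_dof_m",
               paste("solo", "plantarflexor", f_max, arm, sep = "\t"),
               "[segments]",
               "segment\tmass_fraction\tcom_offset_m\tgyration_radius_m",
               "foot\t0.0145\t0.05\t0.069",
               "shank\t0.0465\t0.19\t0.10"), path)
  path
}

# Independent brute-force oracle for 1-DOF problems with <= 3 muscles:
# exhaustive (vectorized) grid search at `grid` newtons over the free
# muscles, last muscle solved from the equality constraint. Keep f_max small
# for 3-muscle cases: the grid is exhaustive by design.
brute_force_qp <- function(R, M, f_max, grid = 0.1) {
  R <- as.numeric(R)
  n <- length(f_max)
  stopifnot(n <= 3, R[n] != 0)
  if (n == 1) {
    f <- M / R[1]
    if (f < -1e-9 || f > f_max[1] + 1e-9) return(NULL)
    return(min(max(f, 0), f_max[1]))
  }
  if (n == 2) {
    head <- matrix(seq(0, f_max[1], by = grid), ncol = 1)
  } else {
    head <- as.matrix(expand.grid(seq(0, f_max[1], by = grid),
                                  seq(0, f_max[2], by = grid)))
  }
  last <- (M - drop(head %*% R[-n])) / R[n]
  ok <- last >= -1e-9 & last <= f_max[n] + 1e-9
  if (!any(ok)) return(NULL)
  head <- head[ok, , drop = FALSE]
  last <- pmin(pmax(last[ok], 0), f_max[n])
  obj <- drop(sweep(head, 2, f_max[-n], `/`)^2 %*% rep(1, n - 1)) +
    (last / f_max[n])^2
  i <- which.min(obj)
  unname(c(head[i, ], last[i]))
}

# Construct a muscle_force_solution by hand (for contribution tests).
manual_solution <- function(time, forces, status = NULL) {
  forces <- as.matrix(forces)
  structure(
    list(time = time, forces = forces,
         activations = forces / max(forces, 1),
         objective = rowSums(forces^2),
         residual = rep(0, nrow(forces)),
         status = if (is.null(status)) rep("solved", nrow(forces)) else status,
         muscle_order = colnames(forces)),
    class = "muscle_force_solution")
}

# The seventeen muscle elements of the bundled model, in order.
table1_names <- c(
  "Tibialis anterior", "Extensor hallucis longus",
  "Extensor digitorum longus 1st", "Extensor digitorum longus 2nd",
  "Extensor digitorum longus 3rd", "Fibularis peroneus brevis",
  "Gastrocnemius lateralis", "Gastrocnemius medialis", "Soleus",
  "Flexor hallucis longus", "Flexor digitorum longus 1st",
  "Flexor digitorum longus 2nd", "Flexor digitorum longus 3rd",
  "Tibialis posterior 1st", "Tibialis posterior 2nd",
  "Tibialis posterior 3rd", "Tibialis posterior 4th")
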