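test_that("GRF template satisfies its shape contract", {
  p <- trial_params()
  T <- p$stance_duration
  expect_equal(unname(grf_profile(0, p)), matrix(c(0, 0, 0), 1),
               ignore_attr = TRUE)
  expect_equal(unname(grf_profile(T, p))[1, ], c(0, 0, 0))
  # AP zero crossing forced at braking_fraction * stance
  expect_equal(unname(grf_profile(p$braking_fraction * T, p)[1, "Fx"]), 0,
               tolerance = 1e-9)
  tt <- seq(0, T, by = 1e-4)
  g <- grf_profile(tt, p)
  expect_true(all(g[, "Fz"] >= 0))
  expect_equal(max(g[, "Fz"]), p$peak_vgrf_bw * p$body_mass * 9.81,
               tolerance = 0.02 * p$peak_vgrf_bw * p$body_mass * 9.81)
  # double hump: exactly two strict local maxima
  d <- diff(g[, "Fz"])
  n_max <- sum(d[-length(d)] > 1e-9 & d[-1] < -1e-9)
  expect_identical(n_max, 2L)
  # braking then propulsion with a single sign change
  sgn <- sign(g[-c(1, nrow(g)), "Fx"])
  expect_identical(sum(diff(sgn[sgn != 0]) != 0), 1L)
  expect_error(grf_profile(-0.01, p), "out of range")
  expect_error(grf_profile(T + 0.01, p), "out of range")
})

test_that("antisymmetric AP template integrates to zero at b = 0.5", {
  p <- trial_params(braking_fraction = 0.5)
  tt <- seq(0, p$stance_duration, by = 1e-5)
  g <- grf_profile(tt, p)
  impulse <- sum(g[, "Fx"]) * 1e-5
  expect_lt(abs(impulse), 1e-6 * sum(abs(g[, "Fx"])) * 1e-5 + 1e-9)
})

test_that("identical seeds give bit-identical trials", {
  model <- load_model()
  p <- trial_params(seed = 42, noise_sd_marker = 0.001, noise_sd_force = 2)
  expect_identical(generate_trial(model, p), generate_trial(model, p))
})

test_that("truth moments equal the moment-arm matrix times truth forces", {
  model <- load_model()
  for (seed in c(1, 6)) {
    tr <- generate_trial(model, trial_params(seed = seed))
    R <- moment_arm_matrix(model)$values
    M_rec <- tr$truth_forces %*% t(R)
    M_tru <- as.matrix(tr$truth_moments[, paste0("M_", model$dofs)])
    expect_lt(max(abs(M_rec - M_tru)), 1e-6 * (1 + max(abs(M_tru))))
    fm <- muscle_fmax(model)
    expect_true(all(tr$truth_forces >= 0))
    expect_true(all(sweep(tr$truth_forces, 2, fm, `/`) <= 1 + 1e-12))
  }
})

test_that("noiseless vGRF crosses the 10 N threshold exactly twice", {
  model <- load_model()
  tr <- generate_trial(model, trial_params(seed = 4))
  above <- tr$recording$forces$Fz > 10
  expect_identical(sum(abs(diff(above))), 2L)
})

test_that("null-space perturbation keeps moments and bounds intact", {
  model <- load_model()
  p <- trial_params(seed = 13)
  tr0 <- generate_trial(model, p)
  tr1 <- generate_trial(model, p, perturb_sd = 0.05)
  expect_gt(max(abs(tr1$truth_forces - tr0$truth_forces)), 1)
  R <- moment_arm_matrix(model)$values
  expect_equal(tr1$truth_forces %*% t(R), tr0$truth_forces %*% t(R),
               tolerance = 1e-8)
  expect_true(all(tr1$truth_forces >= 0))
})

test_that("impossible moment demands raise an infeasible-scenario error", {
  model <- load_model()
  expect_error(
    generate_trial(model, trial_params(seed = 1),
                   scene_params(dM_ankle_amp = 5000)),
    "infeasible scenario")
})

test_that("cohort generation validates its design", {
  model <- load_model()
  expect_error(generate_cohort(model, n_subjects = 1), "n_subjects")
  expect_error(generate_cohort(model, n_subjects = 4,
                               conditions = 0.175), "conditions")
  expect_error(
    generate_cohort(model, n_subjects = 2,
                    effect = contribution_effect("Quadriceps", 10)),
    "unknown muscle")
  coh <- generate_cohort(model, n_subjects = 2,
                         conditions = c(0.175, 0.415), seed = 3)
  expect_length(coh$trials, 4L)
  expect_identical(
    sort(unique(vapply(coh$trials, function(e) e$condition, numeric(1)))),
    c(0.175, 0.415))
  # cohort determinism
  coh2 <- generate_cohort(model, n_subjects = 2,
                          conditions = c(0.175, 0.415), seed = 3)
  expect_identical(coh, coh2)
})
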