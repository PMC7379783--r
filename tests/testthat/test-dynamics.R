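test_that("differentiation is exact on low-order polynomials", {
  rate <- 200
  t <- (0:99) / rate
  d <- differentiate(rep(3, 100), rate)
  expect_equal(d$velocity, rep(0, 100))
  expect_equal(d$acceleration, rep(0, 100))

  d <- differentiate(2 * t, rate)
  expect_equal(d$velocity[2:99], rep(2, 98), tolerance = 1e-10)

  d <- differentiate(t^2, rate)
  expect_equal(d$acceleration[2:99], rep(2, 98), tolerance = 1e-8)
  expect_error(differentiate(c(1, 2), rate), "insufficient samples")
})

test_that("static lever worked example: 600 N at 0.10 m gives 60 N·m", {
  M <- newton_euler_foot(p_ankle = c(0, 0, 0.08), p_com = c(0.05, 0, 0.03),
                         a_com = c(0, 0, 0), alpha_y = 0,
                         mass = 0, inertia_y = 0,
                         F_grf = c(0, 0, 600), cop = c(0.10, 0, 0))
  expect_equal(abs(M[["ankle_flexion"]]), 60, tolerance = 1e-9)
  expect_lt(M[["ankle_flexion"]], 0)  # plantarflexor internal moment
})

test_that("zero GRF, static, massless segments give zero moments", {
  M <- newton_euler_foot(c(0, 0, 0.08), c(0.05, 0, 0.03), c(0, 0, 0), 0,
                         0, 0, c(0, 0, 0), c(0, 0, 0))
  expect_equal(unname(M), c(0, 0))
  expect_equal(mtp_moment(c(0.13, 0, 0.02), c(0, 0, 0), c(0.2, 0, 0)), 0)
})

test_that("gravity term: 1 kg at 0.05 m anterior gives 0.4905 N·m", {
  M <- newton_euler_foot(p_ankle = c(0, 0, 0.08),
                         p_com = c(0.05, 0, 0.08), a_com = c(0, 0, 0),
                         alpha_y = 0, mass = 1, inertia_y = 0,
                         F_grf = c(0, 0, 0), cop = c(0, 0, 0))
  expect_equal(abs(M[["ankle_flexion"]]), 1 * 9.81 * 0.05, tolerance = 1e-12)
})

test_that("moments are superposable in the external load", {
  withr::with_seed(11, {
    for (k in 1:10) {
      pa <- c(0, 0, 0.08); pc <- rnorm(3, c(0.05, 0, 0.04), 0.01)
      ac <- rnorm(3); al <- rnorm(1); m <- runif(1, 0.5, 2)
      FA <- rnorm(3, sd = 300); FB <- rnorm(3, sd = 300)
      cop <- c(runif(1, -0.05, 0.15), runif(1, -0.11, -0.07), 0)
      M0 <- newton_euler_foot(pa, pc, ac, al, m, 0.01, c(0, 0, 0), cop)
      MA <- newton_euler_foot(pa, pc, ac, al, m, 0.01, FA, cop)
      MB <- newton_euler_foot(pa, pc, ac, al, m, 0.01, FB, cop)
      MAB <- newton_euler_foot(pa, pc, ac, al, m, 0.01, FA + FB, cop)
      expect_equal(MAB - M0, (MA - M0) + (MB - M0), tolerance = 1e-9)
    }
  })
})

test_that("MTP moment engages only when the CoP is distal of the MTP", {
  p_mtp <- c(0.13, -0.085, 0.02)
  expect_equal(mtp_moment(p_mtp, c(0, 0, 800), c(0.10, -0.085, 0)), 0)
  m <- mtp_moment(p_mtp, c(0, 0, 800), c(0.15, -0.085, 0))
  expect_equal(m, -0.02 * 800, tolerance = 1e-12)  # flexion demand
})

test_that("inverse dynamics reproduces noiseless generator truth moments", {
  model <- load_model()
  tr <- generate_trial(model, trial_params(seed = 9))
  ph <- segment_phases(tr$recording)
  mom <- inverse_dynamics(tr$recording, model, ph)
  tru <- tr$truth_moments
  key_est <- round(mom$time, 6); key_tru <- round(tru$time, 6)
  common <- intersect(key_est, key_tru)
  i1 <- match(common, key_est); i2 <- match(common, key_tru)
  for (col in paste0("M_", model$dofs)) {
    err <- mom[[col]][i1] - tru[[col]][i2]
    peak <- max(abs(tru[[col]]))
    expect_lt(sqrt(mean(err^2)) / peak, 0.02)
  }
})

test_that("shoe mass enters the gravity term monotonically", {
  model <- load_model()
  tr <- generate_trial(model, trial_params(seed = 10))
  ph <- segment_phases(tr$recording)
  means <- vapply(c(0.175, 0.295, 0.415), function(sm) {
    rec <- tr$recording
    rec$shoe_mass <- sm
    mean(inverse_dynamics(rec, model, ph)$M_ankle_flexion)
  }, numeric(1))
  # identical kinematics: moment changes strictly monotonically with the
  # added shoe mass, by the CoM lever arm times g per kg
  expect_true(all(diff(means) > 0) || all(diff(means) < 0))
  slope <- (means[3] - means[1]) / 0.24
  anthro <- segment_params(model, "foot")
  lever <- anthro$com_offset_m *
    (calfcontrib:::.stance_pose$toe[1] - calfcontrib:::.stance_pose$ankle[1]) /
    sqrt(sum((calfcontrib:::.stance_pose$toe - calfcontrib:::.stance_pose$ankle)^2))
  expect_equal(abs(slope), 9.81 * abs(lever), tolerance = 0.05)
})
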