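test_that("closed-form KKT examples are matched to 1e-6 relative error", {
  # equal arms: interior optimum splits in proportion to f_max^2
  s <- solve_frame(matrix(c(0.05, 0.05), 1), 25, c(1000, 500))
  expect_identical(s$status, "solved")
  expect_equal(s$forces, c(400, 100), tolerance = 1e-6)

  # symmetric problem
  s <- solve_frame(matrix(c(0.04, 0.04), 1), 40, c(1000, 1000))
  expect_equal(s$forces, c(500, 500), tolerance = 1e-6)

  # active upper bound on the stronger muscle
  s <- solve_frame(matrix(c(0.05, 0.05), 1), 72, c(1000, 500))
  expect_equal(s$forces, c(1000, 440), tolerance = 1e-6)

  # zero moment
  s <- solve_frame(matrix(c(0.05, 0.05), 1), 0, c(1000, 500))
  expect_equal(s$forces, c(0, 0))
  expect_equal(s$objective, 0)
})

test_that("solver matches the brute-force grid oracle on 1-DOF problems", {
  withr::with_seed(21, {
    checked <- 0
    while (checked < 12) {
      n <- sample(2:3, 1)
      R <- matrix(round(runif(n, 0.01, 0.06), 3), 1)
      fm <- if (n == 2) round(runif(n, 100, 1500)) else round(runif(n, 20, 80))
      M <- round(runif(1, 0.1, 0.9) * sum(R * fm), 1)
      oracle <- brute_force_qp(R, M, fm, grid = 0.1)
      if (is.null(oracle)) next
      s <- solve_frame(R, M, fm)
      expect_identical(s$status, "solved")
      expect_equal(s$forces, oracle, tolerance = 0.2)  # within grid resolution
      expect_lte(sum((s$forces / fm)^2), sum((oracle / fm)^2) + 1e-9)
      checked <- checked + 1
    }
  })
})

test_that("infeasible moments are reported, never clamped", {
  s <- solve_frame(matrix(c(0.05, 0.05), 1), 80, c(1000, 500))  # capacity 75
  expect_identical(s$status, "infeasible")
  # rank-deficient with inconsistent demands
  s <- solve_frame(matrix(c(0.05, 0.05, 0.05, 0.05), 2), c(10, 30),
                   c(1000, 1000))
  expect_identical(s$status, "infeasible")
})

test_that("solution invariants hold on random feasible problems", {
  withr::with_seed(22, {
    for (k in 1:50) {
      nd <- sample(1:3, 1); nm <- sample(nd:17, 1)
      R <- matrix(runif(nd * nm, -0.06, 0.06), nd)
      fm <- runif(nm, 100, 3000)
      M <- drop(R %*% (runif(nm) * fm))
      s <- solve_frame(R, M, fm)
      expect_identical(s$status, "solved")
      expect_true(all(s$forces >= -1e-9 & s$forces <= fm + 1e-9))
      expect_true(all(s$activations >= -1e-12 & s$activations <= 1 + 1e-12))
      expect_lte(s$residual, 1e-6 * (1 + sqrt(sum(M^2))))
    }
  })
})

test_that("scaling M and f_max by c scales forces and keeps activations", {
  R <- matrix(c(0.05, -0.03, 0.02, 0.04), 2)
  fm <- c(900, 700)
  M <- c(15, 9)
  s1 <- solve_frame(R, M, fm)
  for (c in c(0.5, 3)) {
    s2 <- solve_frame(R, c * M, c * fm)
    expect_equal(s2$forces, c * s1$forces, tolerance = 1e-6)
    expect_equal(s2$activations, s1$activations, tolerance = 1e-6)
  }
})

test_that("objective is monotone in |M| on a single DOF", {
  R <- matrix(c(0.05, -0.04, 0.03), 1)
  fm <- c(1000, 500, 800)
  obj <- vapply(seq(0, 60, by = 5), function(m)
    solve_frame(R, m, fm)$objective, numeric(1))
  expect_true(all(diff(obj) >= -1e-12))
})

test_that("muscles with all-zero moment-arm columns are silenced", {
  R <- matrix(c(0.05, 0, 0.04), 1)
  s <- solve_frame(R, 30, c(1000, 1000, 1000))
  expect_equal(s$forces[2], 0)
})

test_that("solve_trial flags and bounds infeasible frames", {
  model <- tiny_model()        # capacity 0.05*1000 = 50 N·m (agonist side)
  mom <- data.frame(time = (0:9) / 1000, M_dof = rep(500, 10))
  names(mom)[2] <- "M_dof"
  expect_error(solve_trial(model, mom), "model too weak for trial")

  mom_ok <- data.frame(time = (0:9) / 1000, M_dof = rep(20, 10))
  sol <- solve_trial(model, mom_ok)
  expect_true(all(sol$status == "solved"))
  # constant moments give identical per-frame solutions
  expect_equal(apply(sol$forces, 2, function(col) diff(range(col))),
               c(ago = 0, anta = 0), tolerance = 1e-6)
  # warm starting must not change results beyond solver tolerance
  cold <- solve_frame(moment_arm_matrix(model)$values, 20,
                      muscle_fmax(model))
  expect_equal(unname(sol$forces[5, ]), unname(cold$forces), tolerance = 1e-5)
})
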