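ramp_vgrf <- function() {
  t <- seq(0, 0.4, by = 0.001)
  v <- numeric(length(t))
  v[t >= 0.100 & t <= 0.102] <- (t[t >= 0.100 & t <= 0.102] - 0.100) * 1e4
  v[t > 0.102 & t < 0.300] <- 100
  v[t >= 0.300 & t <= 0.310] <- 100 * (0.310 - t[t >= 0.300 & t <= 0.310]) / 0.010
  list(t = t, v = v)
}

test_that("threshold crossings are located by linear interpolation", {
  s <- ramp_vgrf()
  st <- detect_stance(s$t, s$v)
  expect_equal(st$heel_strike, 0.101, tolerance = 1e-9)
  expect_equal(st$toe_off, 0.309, tolerance = 1e-9)
})

test_that("degenerate vGRF inputs are rejected", {
  t <- seq(0, 0.4, by = 0.001)
  expect_error(detect_stance(t, rep(0, length(t))), "ambiguous stance")
  spike <- rep(0, length(t)); spike[100:110] <- 50      # 10 ms spike
  expect_error(detect_stance(t, spike), "spike rejected")
  two <- rep(0, length(t)); two[50:150] <- 50; two[250:350] <- 50
  expect_error(detect_stance(t, two), "multiple")
})

test_that("raising the threshold never lengthens stance", {
  withr::with_seed(8, {
    for (rep in 1:20) {
      t <- seq(0, 0.5, by = 0.001)
      v <- pmax(0, 800 * sin(pi * (t - 0.1) / 0.25)) *
        (t > 0.1 & t < 0.35) + runif(length(t), 0, 1)
      prev <- NULL
      for (thr in c(10, 20, 40, 80)) {
        st <- detect_stance(t, v, threshold = thr)
        if (!is.null(prev)) {
          expect_gte(st$heel_strike, prev$heel_strike)
          expect_lte(st$toe_off, prev$toe_off)
        }
        prev <- st
      }
    }
  })
})

test_that("events are equivariant under time shifts", {
  s <- ramp_vgrf()
  st0 <- detect_stance(s$t, s$v)
  for (delta in c(-0.05, 0.123)) {
    st <- detect_stance(s$t + delta, s$v)
    expect_equal(st$heel_strike, st0$heel_strike + delta, tolerance = 1e-12)
    expect_equal(st$toe_off, st0$toe_off + delta, tolerance = 1e-12)
  }
})

test_that("braking/propulsion transition sits at the AP zero crossing", {
  t <- seq(0, 0.4, by = 0.001)
  T_st <- 0.2
  stance <- list(heel_strike = 0.1, toe_off = 0.3)
  ap <- ifelse(t > 0.1 & t < 0.3, -200 * sin(2 * pi * (t - 0.1) / T_st), 0)
  be <- detect_brake_end(t, ap, stance)
  expect_equal(be, 0.2, tolerance = 0.001)

  ap_neg <- ifelse(t > 0.1 & t < 0.3, -200 * sin(pi * (t - 0.1) / T_st), 0)
  expect_error(detect_brake_end(t, ap_neg, stance),
               "no braking/propulsion transition")
  expect_error(detect_brake_end(t, -ap, stance), "unexpected AP polarity")
})

test_that("phase partition satisfies its invariants", {
  model <- load_model()
  tr <- generate_trial(model, trial_params(seed = 2))
  ph <- segment_phases(tr$recording)
  expect_equal(ph$heel_strike - ph$preactivation_start, 0.050)
  expect_lt(ph$heel_strike, ph$brake_end)
  expect_lt(ph$brake_end, ph$toe_off)
  # braking and push-off partition stance exactly
  expect_identical(ph$intervals$braking[1], ph$intervals$stance[1])
  expect_identical(ph$intervals$braking[2], ph$intervals$push_off[1])
  expect_identical(ph$intervals$push_off[2], ph$intervals$stance[2])
})

test_that("a 0.5 s heel strike yields a [0.45, 0.5) preactivation window", {
  t <- seq(0, 1, by = 0.001)
  v <- ifelse(t > 0.5 & t < 0.8, 500 * sin(pi * (t - 0.5) / 0.3), 0)
  fx <- ifelse(t > 0.5 & t < 0.8, -100 * sin(2 * pi * (t - 0.5) / 0.3), 0)
  ph <- segment_phases(data.frame(time = t, Fz = v, Fx = fx), filter = FALSE)
  expect_equal(ph$intervals$preactivation[1], ph$heel_strike - 0.05)
  expect_equal(ph$heel_strike, 0.5, tolerance = 0.005)
})

test_that("recordings starting after heel_strike - 50 ms are rejected", {
  t <- seq(0.48, 1, by = 0.001)
  v <- ifelse(t > 0.5 & t < 0.8, 500 * sin(pi * (t - 0.5) / 0.3), 0)
  fx <- ifelse(t > 0.5 & t < 0.8, -100 * sin(2 * pi * (t - 0.5) / 0.3), 0)
  expect_error(
    segment_phases(data.frame(time = t, Fz = v, Fx = fx), filter = FALSE),
    "insufficient pre-contact data")
})

test_that("generator events round-trip through detection", {
  model <- load_model()
  p <- trial_params(seed = 5, stance_duration = 0.22, braking_fraction = 0.40)
  tr <- generate_trial(model, p)
  ph <- segment_phases(tr$recording, filter = FALSE)
  expect_lt(abs(diff(ph$intervals$stance) - 0.22), 0.002)
  bf <- (ph$brake_end - ph$heel_strike) / diff(ph$intervals$stance)
  expect_lt(abs(bf - 0.40), 0.01)
})
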