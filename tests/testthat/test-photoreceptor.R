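# phototransduction model: rate field, loop toggles, leak calibration,
# set-point, pulses, steps and the loop-dissection scenarios

test_that("default parameters carry the fitted constants and a near-unit CNG amplitude sum", {
  p <- photo_parameters()
  expect_equal(p[["k3"]], 50)
  expect_equal(p[["k8"]], 0.05749)
  expect_equal(p[["k11"]], 32.81)
  expect_equal(p[["k12"]], 0.622612)
  s <- p[["alpha"]] + p[["beta_prime"]]
  expect_gte(s, 0.99)
  expect_lte(s, 1.02)
  expect_error(photo_parameters(k99 = 1), "unknown")
})

test_that("the rate field honours limits and input checks", {
  p <- photo_parameters()
  p[["vleak"]] <- 0.264
  # Ca -> 0: CNG inhibition term tends to alpha + beta_prime
  d0 <- photo_rate_field(c(9, 1e-12, 2), p)
  cng_amp <- (d0[["Ca"]] + p[["k7"]] * 1e-12 * 2 - p[["vleak"]]) /
    (p[["k5"]] * 9^p[["n"]] / (p[["k11"]]^p[["n"]] + 9^p[["n"]]))
  expect_equal(cng_amp, p[["alpha"]] + p[["beta_prime"]], tolerance = 1e-6)
  # k12 = 0 saturates the PDE activation factor at 1
  p0 <- p; p0[["k12"]] <- 0
  d <- photo_rate_field(c(5, 0.1, 2), p0)
  gc <- p[["k3"]] * p[["k8"]]^p[["r"]] / (p[["k8"]]^p[["r"]] + 0.1^p[["r"]])
  expect_equal(d[["cGMP"]], gc - p[["k9"]] * 5 - (p[["k2"]] + p[["k4"]]) * 5,
               tolerance = 1e-12)
  expect_error(photo_rate_field(c(-1, 0.1, 2), p), "finite and >= 0")
  expect_error(photo_rate_field(c(9, 0.1, 2), p, light_overrides = c(zz = 1)),
               "unknown")
})

test_that("loop toggles implement the disabling conventions", {
  p <- photo_parameters()
  p1 <- loop_config(p, loop1_on = FALSE)
  expect_equal(p1[["k8"]], 1e9)
  expect_equal(p1[["r"]], 1)
  p2 <- loop_config(p, loop2_on = FALSE)
  expect_equal(p2[["k12"]], 0)
  p3 <- loop_config(p)  # all on
  expect_equal(unname(p3[names(p)]), unname(p))
  expect_error(loop_config(p, loop1_on = FALSE, loop2_on = FALSE),
               "at least one")
  # loop 3 off: the CNG Ca-modifier is the constant 1
  m3off <- photo_model(loop3_on = FALSE)
  st <- c(9, 0.5, 2)
  d_off <- rate_field(m3off, st)
  p_full <- m3off$pars
  inflow <- p_full[["k5"]] * st[1]^p_full[["n"]] /
    (p_full[["k11"]]^p_full[["n"]] + st[1]^p_full[["n"]])
  expect_equal(d_off[["Ca"]],
               inflow - p_full[["k7"]] * st[2] * st[3] + p_full[["vleak"]],
               tolerance = 1e-12)
})

test_that("leak calibration solves the calcium balance at reference states", {
  p <- photo_parameters()
  refs <- photo_reference_states()
  v_a <- calibrate_leak(p, refs$fig19a, loop3_on = FALSE)
  expect_equal(v_a, 0.2644, tolerance = 1e-3)
  v_d <- calibrate_leak(p, refs$fig19d, loop3_on = TRUE)
  expect_equal(v_d, 0.2632, tolerance = 1e-3)
  # the two independent calibrations agree closely
  expect_lt(abs(v_a - v_d) / v_a, 0.01)
  # a reference consistent with zero leak returns zero
  h <- function(cg) cg^p[["n"]] / (p[["k11"]]^p[["n"]] + cg^p[["n"]])
  cg0 <- p[["k11"]] * ((p[["k6"]] / p[["k5"]]) /
                         (1 - p[["k6"]] / p[["k5"]]))^(1 / p[["n"]])
  expect_equal(calibrate_leak(p, list(cGMP = cg0, Ca = 0.1),
                              loop3_on = FALSE), 0, tolerance = 1e-9)
  expect_error(calibrate_leak(p, list(cGMP = 20, Ca = 1e-6),
                              loop3_on = FALSE), "negative leak")
})

test_that("the closed-form cGMP set-point matches its limits", {
  ph <- photo_model(loop3_on = FALSE)
  expect_equal(cgmp_set_point(ph), 7.612, tolerance = 1e-3)
  # zero leak
  p0 <- photo_parameters()
  p0[["vleak"]] <- 0
  expect_equal(cgmp_set_point(p0), 9.135, tolerance = 1e-3)
  # boundary and error branches
  pb <- photo_parameters(); pb[["vleak"]] <- pb[["k6"]]
  expect_equal(cgmp_set_point(pb), 0)
  pw <- photo_parameters(); pw[["vleak"]] <- pb[["k6"]] + 0.1
  expect_error(cgmp_set_point(pw), class = "homeostat_windup")
  pl <- photo_parameters(k5 = 0.1); pl[["vleak"]] <- 0
  expect_error(cgmp_set_point(pl), "< 1")
})

test_that("steady states satisfy the K-balance to machine precision", {
  ph <- photo_model()
  for (k4 in c(0, 12, 162, 1280)) {
    ss <- find_steady_state(ph, overrides = list(k4 = k4))
    pump <- ph$pars[["k7"]] * ss[["Ca"]] * ss[["K"]]
    expect_equal(pump, ph$pars[["k6"]], tolerance = 1e-12)
    d <- rate_field(ph, ss, overrides = list(k4 = k4))
    expect_lt(max(abs(d)), 1e-8)
  }
})

test_that("printed steady states are reproduced once the leak is calibrated", {
  ph <- photo_model()
  dark <- find_steady_state(ph)
  expect_equal(dark[["cGMP"]], 9.04191, tolerance = 5e-3)
  expect_equal(dark[["Ca"]], 0.125717, tolerance = 5e-3)
  # dark-adapted states at the pulse-experiment backgrounds
  printed <- data.frame(
    k4 = c(3, 12, 41, 84, 162, 320, 640, 1280),
    cGMP = c(8.80039, 8.36375, 7.86039, 7.67946, 7.61322, 7.59537,
             7.59210, 7.59160),
    Ca = c(9.89550e-2, 6.80242e-2, 3.83237e-2, 2.34638e-2, 1.31981e-2,
           6.58562e-3, 3.09110e-3, 1.42894e-3))
  for (i in seq_len(nrow(printed))) {
    ss <- find_steady_state(ph, overrides = list(k4 = printed$k4[i]))
    expect_equal(ss[["cGMP"]], printed$cGMP[i], tolerance = 5e-3)
    expect_equal(ss[["Ca"]], printed$Ca[i], tolerance = 2e-2)
  }
})

test_that("with loop 3 off the set-point is defended over a perturbation grid", {
  ph <- photo_model(loop3_on = FALSE)
  sp <- cgmp_set_point(ph)
  for (k2 in c(0.5, 1, 4)) {
    for (k4 in c(0, 2, 8)) {
      ss <- find_steady_state(ph, overrides = list(k2 = k2, k4 = k4))
      expect_equal(ss[["cGMP"]], sp, tolerance = 1e-9)
    }
  }
})

test_that("with all loops on adaptation is imperfect and background-dependent", {
  ph <- photo_model()
  lv <- vapply(c(0, 2, 16, 128, 1024), function(k4) {
    find_steady_state(ph, overrides = list(k4 = k4))[["cGMP"]]
  }, numeric(1))
  expect_true(all(diff(lv) < 0))
  # post-step plateau differs from the pre-step plateau
  res <- run_step(ph, step_height = 50, background = 0, duration = 8)
  final <- res$trajectory$cGMP[nrow(res$trajectory)]
  expect_gt(abs(final - res$pre_step_state[["cGMP"]]), 0.5)
})

test_that("pulse responses shrink and accelerate with background", {
  ph <- photo_model()
  r_none <- run_pulse(ph, pulse_height = 1, background = 3)
  expect_lt(r_none$delta_cgmp, 1e-8)
  r_lo <- run_pulse(ph, pulse_height = 50, background = 3)
  r_hi <- run_pulse(ph, pulse_height = 50, background = 162)
  expect_lt(r_hi$delta_cgmp, r_lo$delta_cgmp)
  expect_lt(r_hi$metrics$resetting_time, r_lo$metrics$resetting_time)
})

test_that("step responses show the non-monotone peak time of the full model", {
  ph <- photo_model()
  tm <- vapply(c(0, 8, 64, 2048), function(bg) {
    run_step(ph, step_height = 50, background = bg,
             duration = 3)$metrics$t_max
  }, numeric(1))
  expect_lt(tm[2], tm[1])
  expect_lt(tm[3], tm[2])
  expect_gt(tm[4], tm[3])
  # step-off overshoot above the pre-step level
  res <- run_step(ph, step_height = 50, background = 0, duration = 150,
                  off_at = 100, dense_output_step = 0.01)
  post <- res$trajectory$cGMP[res$trajectory$time > 100]
  expect_gt(max(post), res$pre_step_state[["cGMP"]] + 0.5)
})

test_that("feedback scenarios reproduce the homeostatic dissection", {
  # antagonistic loops 1+2: cGMP back at the set-point in every phase
  tr_a <- feedback_scenario("a")
  sp <- cgmp_set_point(attr(tr_a, "model"))
  ends <- vapply(c(100, 200, 300), function(tc) {
    tr_a$cGMP[max(which(tr_a$time <= tc))]
  }, numeric(1))
  expect_equal(ends, rep(sp, 3), tolerance = 1e-4)

  # all loops: perfect adaptation lost, but phase-end levels within a few
  # percent of the dark level
  tr_d <- feedback_scenario("d")
  dark <- find_steady_state(photo_model())[["cGMP"]]
  ends_d <- vapply(c(100, 200, 300), function(tc) {
    tr_d$cGMP[max(which(tr_d$time <= tc))]
  }, numeric(1))
  expect_false(isTRUE(all.equal(ends_d[2], sp, tolerance = 1e-6)))
  expect_lt(max(abs(ends_d - dark) / dark), 0.10)

  # loop 2 alone needs a raised background; without it calcium winds up
  expect_error(feedback_scenario("b", scenario_b_background = 0),
               class = "homeostat_windup")
  tr_b <- feedback_scenario("b")
  end_b <- tr_b$cGMP[nrow(tr_b)]
  expect_equal(end_b, sp, tolerance = 1e-3)

  expect_error(feedback_scenario("x"))
})
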