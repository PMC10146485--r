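# integration engine, protocols, response metrics and sweeps

test_that("protocol validation catches malformed phase lists", {
  expect_error(perturbation_protocol(list(), 10), "non-empty")
  expect_error(perturbation_protocol(
    list(list(start = 1, overrides = list())), 10), "start at time 0")
  expect_error(perturbation_protocol(
    list(list(start = 0, overrides = list()),
         list(start = 0, overrides = list(k2 = 2))), 10),
    "strictly increasing")
  expect_error(perturbation_protocol(
    list(list(start = 0, overrides = list())), 0), "total_time")
  m1 <- motif_preset("fig4")
  bad <- perturbation_protocol(
    list(list(start = 0, overrides = list(k42 = 1))), 10)
  expect_error(simulate_model(m1, bad), "unknown parameters")
})

test_that("a model started at its steady state stays constant", {
  for (model in list(motif_preset("fig4"), motif_preset("fig8"),
                     photo_model())) {
    prot <- perturbation_protocol(list(list(start = 0, overrides = list())),
                                  total_time = 20, dense_output_step = 0.05)
    traj <- simulate_model(model, prot)
    x <- traj[[model$controlled]]
    expect_lt(max(abs(x - x[1])) / x[1], 1e-6)
  }
})

test_that("integration restarts exactly at phase boundaries", {
  # a 10 ms pulse must be applied for exactly its width: compare the pulse
  # integral against a manual two-stage integration
  ph <- photo_model()
  y0 <- find_steady_state(ph)
  prot <- pulse_protocol(onset = 0.5, overrides = list(k2 = 50),
                         width = 0.01, total_time = 2,
                         dense_output_step = 0.001)
  traj <- simulate_model(ph, prot, initial_state = y0)
  # boundary times are on the grid exactly once
  expect_equal(sum(traj$time == 0.5), 1L)
  expect_equal(sum(abs(traj$time - 0.51) < 1e-12), 1L)
  # response present and returning
  expect_lt(min(traj$cGMP), y0[["cGMP"]] - 0.2)
  expect_equal(traj$cGMP[nrow(traj)], y0[["cGMP"]], tolerance = 1e-2)
})

test_that("m1 step response dips below the set-point and resets", {
  m1 <- motif_preset("fig4")
  prot <- motif_step_protocol(m1, height = 5, onset = 10, total_time = 100)
  traj <- simulate_model(m1, prot)
  expect_lt(min(traj$A), 3.0)
  expect_equal(traj$A[nrow(traj)], 3.0, tolerance = 1e-3)
})

test_that("find_steady_state matches integrate-to-convergence", {
  # caption anchors
  expect_equal(find_steady_state(motif_preset("fig8"),
                                 overrides = list(k4 = 5))[["E"]],
               55.46, tolerance = 5e-4)
  expect_equal(find_steady_state(motif_preset("fig4"),
                                 overrides = list(k4 = 128))[["E"]],
               387.0, tolerance = 5e-4)
  expect_equal(find_steady_state(motif_preset("fig6"))[["E"]],
               11.11, tolerance = 5e-4)
  # closed form agrees with the relaxed state for every motif
  for (id in names(all_motifs())) {
    model <- all_motifs()[[id]]
    ss <- find_steady_state(model)
    prot <- perturbation_protocol(list(list(start = 0, overrides = list())),
                                  total_time = 8000, dense_output_step = 5)
    traj <- simulate_model(model, prot,
                           initial_state = ss * c(1.5, 0.7))
    final <- unlist(traj[nrow(traj), model$state_names])
    expect_equal(unname(final), unname(ss), tolerance = 1e-3, info = id)
  }
})

test_that("response metrics recover the properties of a known pulse shape", {
  # synthetic trajectory: A = 3 - 0.5 * exp(-(t-20)^2 / 8), reference 3
  tt <- seq(0, 60, by = 0.05)
  xx <- 3 - 0.5 * exp(-(tt - 20)^2 / 8)
  traj <- structure(data.frame(time = tt, A = xx),
                    class = c("trajectory", "data.frame"))
  met <- response_metrics(traj, reference_level = 3, onset_time = 0,
                          variable = "A")
  expect_equal(met$delta_max, 0.5, tolerance = 1e-6)
  expect_equal(met$t_max, 20, tolerance = 1e-3)
  expect_identical(met$direction, "below")
  # band re-entry: |dev| <= 0.03 when (t-20)^2 >= 8*log(0.5/0.03)
  t_in <- 20 + sqrt(8 * log(0.5 / 0.03))
  expect_equal(met$resetting_time, t_in, tolerance = 0.1)

  flat <- structure(data.frame(time = tt, A = rep(3, length(tt))),
                    class = c("trajectory", "data.frame"))
  met0 <- response_metrics(flat, 3, variable = "A")
  expect_equal(met0$delta_max, 0)
  expect_equal(met0$resetting_time, 0)

  # never re-entering the band is flagged, not truncated
  ramp <- structure(data.frame(time = tt, A = 3 + 0.01 * tt),
                    class = c("trajectory", "data.frame"))
  metr <- response_metrics(ramp, 3, variable = "A")
  expect_false(metr$resetting_resolved)
  expect_true(is.na(metr$resetting_time))
})

test_that("backgrounds reshape the m1 and m2 responses in opposite ways", {
  m1 <- motif_preset("fig4")
  met1 <- lapply(c(0, 16), function(bg) {
    prot <- motif_step_protocol(m1, 5, onset = 10, total_time = 400,
                                background = bg, step = 0.01)
    traj <- simulate_model(m1, prot)
    response_metrics(traj, m1$set_point, onset_time = 10)
  })
  expect_lt(met1[[2]]$delta_max, met1[[1]]$delta_max)
  expect_gt(met1[[2]]$resetting_time, met1[[1]]$resetting_time)

  m2 <- motif_preset("fig8")
  met2 <- lapply(c(0, 5, 80), function(bg) {
    prot <- motif_step_protocol(m2, 5, onset = 10, total_time = 300,
                                background = bg, step = 0.005)
    traj <- simulate_model(m2, prot)
    response_metrics(traj, m2$set_point, onset_time = 10)
  })
  dm <- vapply(met2, `[[`, numeric(1), "delta_max")
  rt <- vapply(met2, `[[`, numeric(1), "resetting_time")
  expect_true(all(diff(dm) < 0))
  expect_true(all(diff(rt) < 0))
})

test_that("sweeps tabulate metrics and expose step-size invariance of t_max", {
  m7 <- motif_preset("fig6")
  # step-size sweep at fixed background: t_max identical across steps
  prot <- motif_step_protocol(m7, 5, onset = 10, total_time = 200,
                              background = 4, step = 0.005)
  tab <- sweep_metrics(m7, prot, m7$perturbation_name, c(2, 5, 10),
                       phase = 2)
  expect_true(all(is.na(tab$error)))
  expect_lt(diff(range(tab$t_max)) / mean(tab$t_max), 0.02)
  expect_true(all(diff(tab$delta_max) > 0))

  # background sweep: delta_max decreases monotonically
  tab2 <- sweep_metrics(m7, prot, m7$background_name, c(0, 4, 16, 64))
  expect_true(all(diff(tab2$delta_max) < 0))

  # per-value failures are recorded without aborting the sweep
  m8 <- motif_preset("fig11")
  prot8 <- motif_step_protocol(m8, 5, onset = 10, total_time = 100)
  tab3 <- sweep_metrics(m8, prot8, "k4", c(1e4, 0.1))
  expect_true(is.na(tab3$error[1]))
  expect_false(is.na(tab3$error[2]))
})

test_that("halving solver tolerances leaves metrics unchanged", {
  m2 <- motif_preset("fig8")
  prot <- motif_step_protocol(m2, 5, onset = 10, total_time = 60,
                              background = 5, step = 0.005)
  y0 <- find_steady_state(m2, overrides = list(k4 = 5))
  t1 <- simulate_model(m2, prot, y0, rtol = 1e-8, atol = 1e-10)
  t2 <- simulate_model(m2, prot, y0, rtol = 5e-9, atol = 5e-11)
  d1 <- response_metrics(t1, 3, onset_time = 10)$delta_max
  d2 <- response_metrics(t2, 3, onset_time = 10)$delta_max
  expect_lt(abs(d1 - d2) / d1, 1e-4)
})

test_that("windup is reported as its own condition class", {
  leaky <- photo_model(vleak = 0.6)  # leak exceeds K inflow k6 = 0.5
  expect_error(find_steady_state(leaky), class = "homeostat_windup")
  prot <- perturbation_protocol(list(list(start = 0, overrides = list())),
                                total_time = 50, dense_output_step = 0.05)
  y0 <- c(cGMP = 9, Ca = 0.13, K = 2)
  traj <- simulate_model(leaky, prot, initial_state = y0)
  # calcium accumulates without settling (after the initial transient)
  expect_gt(traj$Ca[nrow(traj)], 3 * y0[["Ca"]])
  tail_ca <- utils::tail(traj$Ca, 200)
  expect_true(all(diff(tail_ca) > 0))
})

test_that("trajectories round-trip through the CSV writer with sidecar", {
  m1 <- motif_preset("fig4")
  prot <- motif_step_protocol(m1, 5, onset = 5, total_time = 20,
                              step = 0.05)
  traj <- simulate_model(m1, prot)
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(traj, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("time", "A", "E"))
  expect_equal(back$A, traj$A, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$model$motif_id, "m1")
  expect_equal(length(side$protocol$phases), 2L)
  unlink(c(path, paste0(path, ".json")))
})
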