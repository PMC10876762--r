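# AdamW descent and the design recipes.

test_that("free parameter count matches the waveform geometry", {
  maps <- med_maps()
  prob <- design_problem(maps, 10, 520e-6, 10e-6)
  # 16-channel case printed in the field: 52*16*2 + 52*3 = 1820
  prob16 <- prob
  prob16$n_channels <- 16L
  fit_n <- 2L * 16L * 52L + 3L * 52L
  expect_identical(fit_n, 1820L)
  cfg <- optimizer_config(n_iterations = 2L)
  fit <- optimize_pulse(prob, cfg)
  expect_identical(fit$n_params, 2L * 8L * 52L + 3L * 52L)
  prob_rf <- design_problem(maps, 10, 520e-6, 10e-6, optimize_grad = FALSE)
  expect_identical(optimize_pulse(prob_rf, cfg)$n_params, 2L * 8L * 52L)
})

test_that("running-best cost is non-increasing and the run is deterministic", {
  maps <- small_maps()
  prob <- design_problem(maps, 10, 2e-4, 2e-5)
  cfg <- optimizer_config(n_iterations = 60L, restart_period = 25L, seed = 4L)
  fit1 <- optimize_pulse(prob, cfg)
  fit2 <- optimize_pulse(prob, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$pulse$rf, fit2$pulse$rf)
  running_best <- cummin(fit1$history$total)
  expect_true(all(diff(running_best) <= 0))
  expect_equal(fit1$best_cost, min(fit1$history$total), tolerance = 1e-15)
})

test_that("the single-voxel problem converges to the closed-form solution", {
  maps <- one_voxel_maps()
  prob <- design_problem(maps, 10, 520e-6, 10e-6, optimize_grad = FALSE)
  fit <- optimize_pulse(prob, optimizer_config(n_iterations = 1200L,
                                               seed = 1L))
  sim <- bloch_simulate(fit$pulse, maps)
  expect_lt(abs(sim$fa - 10), 0.1)
})

test_that("multi-subject objective is the mean of per-subject objectives", {
  maps <- list(small_maps(),
               synth_fieldmaps(2L, c(5L, 5L, 5L), 0.04, 100, seed = 9L))
  p <- random_pulse(2L, 8L, seed = 3L)
  dctx <- ptxpulse:::.design_ctx(maps, 10)
  ev <- ptxpulse:::.cost_eval(p$rf, p$grad, p$raster, dctx, ptx_limits(),
                              NULL, "sta", want_grad = FALSE)
  per <- vapply(maps, function(m) {
    d1 <- ptxpulse:::.design_ctx(m, 10)
    ptxpulse:::.cost_eval(p$rf, p$grad, p$raster, d1, ptx_limits(),
                          NULL, "sta", want_grad = FALSE)$breakdown$pen_rmse
  }, numeric(1L))
  expect_equal(ev$breakdown$pen_rmse, mean(per), tolerance = 1e-12)
})

test_that("non-finite costs abort naming the offending term", {
  maps <- small_maps()
  start <- pulse_waveform(matrix(1e154 + 0i, 2L, 10L), raster = 2e-5)
  prob <- design_problem(maps, 10, 2e-4, 2e-5, initial_pulse = start)
  expect_error(optimize_pulse(prob, optimizer_config(n_iterations = 3L)),
               "err_volt|pen_power")
})

test_that("scaling to a mean flip angle is exact under STA, close under Bloch", {
  maps <- small_maps()
  pulse <- random_pulse(2L, 12L, seed = 6L, rf_sd = 5)
  for (target in c(3, 10)) {
    ps <- scale_pulse_to_mean_fa(pulse, maps, target, model = "sta")
    expect_equal(mean(sta_simulate(ps, maps)$fa), target, tolerance = 1e-10)
    pb <- scale_pulse_to_mean_fa(pulse, maps, target, model = "bloch")
    expect_lt(abs(mean(bloch_simulate(pb, maps)$fa) - target), 1e-3)
    # at small flip angles the two scalars agree within 1%
    expect_lt(abs(max(Mod(pb$rf)) / max(Mod(ps$rf)) - 1), 0.01)
  }
  pz <- scale_pulse_to_mean_fa(pulse, maps, 0, model = "sta")
  expect_true(all(pz$rf == 0))
})

test_that("a short small-FA design improves on its start and respects limits", {
  maps <- med_maps()
  vops <- synth_vops(20L, 8L, seed = 3L, scale = 1e-3)
  fit <- design_small_fa(maps, 10, 520e-6, 10e-6, iters_sta = 120L,
                         iters_bloch = 40L, vops = vops, seed = 0L)
  expect_lt(fit$best_cost, fit$history$total[1L])
  sim <- bloch_simulate(fit$pulse, maps)
  bd <- cost_terms(fit$pulse, sim$fa, 10, limits = ptx_limits(), vops = vops)
  expect_identical(bd$err_volt, 0)
  expect_identical(bd$err_maxG, 0)
  expect_identical(bd$err_slew, 0)
  expect_identical(bd$err_edge, 0)
  expect_identical(bd$err_sar, 0)
  expect_true(all(c("sta", "bloch") %in% fit$history$phase))
})

test_that("voltage scaling after design rescales the STA flip angle linearly", {
  maps <- med_maps()
  fit <- design_small_fa(maps, 10, 520e-6, 10e-6, iters_sta = 40L,
                         iters_bloch = 0L, seed = 0L)
  p9 <- scale_pulse(fit$pulse, 0.9)
  expect_equal(max(Mod(p9$rf)), 0.9 * max(Mod(fit$pulse$rf)),
               tolerance = 1e-12)
  expect_equal(sta_simulate(p9, maps)$fa, 0.9 * sta_simulate(fit$pulse, maps)$fa,
               tolerance = 1e-12)
})

test_that("large-FA recipe: scaled STA stage obeys limits, Bloch refines RF only", {
  maps <- med_maps()
  fit <- design_large_fa(maps, 90, 520e-6, 10e-6, iters_sta = 120L,
                         iters_bloch = 60L, seed = 0L)
  # the x10-scaled intermediate obeys the full voltage limit by construction
  expect_lte(max(Mod(fit$scaled_start$rf)), 185)
  # gradients bitwise unchanged by the RF-only refinement
  expect_identical(fit$pulse$grad, fit$scaled_start$grad)
  nr_refined <- nrmse(bloch_simulate(fit$pulse, maps)$fa, 90)
  nr_naive <- nrmse(bloch_simulate(fit$scaled_start, maps)$fa, 90)
  expect_lt(nr_refined, nr_naive)
})

test_that("transmit-chain robustness evaluation is seeded and well-behaved", {
  maps <- med_maps()
  fit <- design_small_fa(maps, 10, 520e-6, 10e-6, iters_sta = 60L,
                         iters_bloch = 0L, seed = 0L)
  r0 <- robustness_eval(fit$pulse, maps, 10, n_reps = 3L,
                        mag_sd = 0, phase_sd = 0, seed = 2L)
  expect_true(all(abs(r0 - attr(r0, "baseline")) < 1e-12))
  r1 <- robustness_eval(fit$pulse, maps, 10, n_reps = 5L, seed = 7L)
  r2 <- robustness_eval(fit$pulse, maps, 10, n_reps = 5L, seed = 7L)
  expect_identical(as.vector(r1), as.vector(r2))
  # 5% / 5-degree channel errors move the NRMSE by a few points at most
  expect_lt(max(abs(r1 - attr(r1, "baseline"))), 10)
})
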