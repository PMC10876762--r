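# Forward models and metrics.

test_that("on-resonance rotation matches the closed form", {
  maps <- one_voxel_maps()
  pulse <- pulse_waveform(matrix(1 + 0i, 1L, 10L), raster = 1e-5)
  sim <- bloch_simulate(pulse, maps)
  expected <- gamma_1h * 1e-6 * 1e-4 * 180 / pi   # 1 uT for 100 us
  expect_equal(sim$fa, expected, tolerance = 1e-9)
  # closed-form equivalence holds across amplitudes
  for (v in c(0.1, 5, 37)) {
    s <- bloch_simulate(scale_pulse(pulse, v), maps)
    expect_equal(s$fa, (gamma_1h * v * 1e-6 * 1e-4) * 180 / pi,
                 tolerance = 1e-6)
  }
})

test_that("zero pulse leaves magnetization unchanged", {
  maps <- small_maps()
  n <- sum(maps$mask)
  pulse <- pulse_waveform(matrix(0i, 2L, 8L), raster = 1e-5)
  init <- cbind(rnorm(n), rnorm(n), rnorm(n))
  maps0 <- maps
  maps0$b0[] <- 0
  sim <- bloch_simulate(pulse, maps0, initial = init)
  expect_equal(Re(sim$mxy), init[, 1L], tolerance = 1e-12)
  expect_equal(sim$mz, init[, 3L], tolerance = 1e-12)
})

test_that("gradient-only precession matches gamma*G*x*tau (clockwise)", {
  maps <- fieldmap_set(array(0i, c(1L, 3L, 1L, 1L)), array(0, c(3L, 1L, 1L)),
                       array(TRUE, c(3L, 1L, 1L)), 0.01)
  pulse <- pulse_waveform(matrix(0i, 1L, 10L),
                          rbind(rep(0.01, 10L), 0, 0), 1e-5)
  sim <- bloch_simulate(pulse, maps, initial = list(mxy = 1 + 0i, mz = 0))
  # voxels at x = -10, 0, +10 mm; phase accrual is -gamma*G*x*tau
  expected <- -gamma_1h * 0.01 * c(-0.01, 0, 0.01) * 1e-4
  expect_equal(sim$phase * pi / 180, expected, tolerance = 1e-9)
  expect_equal(abs(sim$phase[3L] * pi / 180), 2.67522, tolerance = 1e-5)
})

test_that("Bloch conserves the magnetization norm without relaxation", {
  maps <- small_maps()
  for (seed in 1:3) {
    pulse <- random_pulse(2L, 20L, seed = seed, rf_sd = 40, g_sd = 5e-4)
    sim <- bloch_simulate(pulse, maps)
    norms <- sqrt(Mod(sim$mxy)^2 + sim$mz^2)
    expect_lt(max(abs(norms - 1)), 1e-9)
  }
})

test_that("relaxation decays mxy and regrows mz at the exact rates", {
  maps <- one_voxel_maps()
  n <- 100L
  pulse <- pulse_waveform(matrix(0i, 1L, n), raster = 1e-4)  # 10 ms free
  relax <- relaxation_spec(t1 = 0.1, t2 = 0.02)
  sim <- bloch_simulate(pulse, maps, relax = relax,
                        initial = list(mxy = 1 + 0i, mz = 0))
  expect_equal(unname(Mod(sim$mxy)), exp(-0.01 / 0.02), tolerance = 1e-9)
  expect_equal(unname(sim$mz), 1 - exp(-0.01 / 0.1), tolerance = 1e-9)
})

test_that("STA system matrix has the documented structure", {
  maps <- small_maps()
  n <- sum(maps$mask)
  raster <- 1e-5
  maps0 <- maps
  maps0$b0[] <- 0
  A <- sta_system_matrix(maps0, matrix(0, 3L, 4L), raster)
  expect_identical(dim(A), c(n, 8L))
  b1m <- t(matrix(maps$b1, nrow = 2L)[, which(maps$mask)]) * 1e-9
  expect_equal(A[, 1L], 1i * gamma_1h * raster * b1m[, 1L], tolerance = 1e-12)
  expect_equal(A[, 8L], 1i * gamma_1h * raster * b1m[, 2L], tolerance = 1e-12)
  # k(T) = 0: last-sample columns carry no gradient phase even with gradients
  g <- matrix(rnorm(12L, 0, 1e-3), 3L, 4L)
  Ag <- sta_system_matrix(maps0, g, raster)
  expect_equal(Ag[, 7:8], A[, 7:8], tolerance = 1e-12)
})

test_that("STA b0 phase reference sits at the pulse end", {
  maps <- fieldmap_set(array(500 + 0i, c(1L, 1L, 1L, 1L)),
                       array(100, c(1L, 1L, 1L)),
                       array(TRUE, c(1L, 1L, 1L)), 0.01)
  # 2 samples at 5 ms raster: first sample is 5 ms before the end
  A <- sta_system_matrix(maps, matrix(0, 3L, 2L), 5e-3)
  phase_rel <- Arg(A[1L, 1L] / A[1L, 2L])
  expect_equal(phase_rel, -pi, tolerance = 1e-9)
})

test_that("STA is exactly linear in the RF voltage", {
  maps <- small_maps()
  pulse <- random_pulse(2L, 16L, seed = 4L)
  s1 <- sta_simulate(pulse, maps)
  s2 <- sta_simulate(scale_pulse(pulse, 2), maps)
  expect_identical(s2$mxy, 2 * s1$mxy)
  expect_true(all(sta_simulate(scale_pulse(pulse, 0), maps)$mxy == 0))
})

test_that("STA and Bloch agree for 10-degree pulses on synthetic maps", {
  maps <- med_maps()
  cp <- scale_pulse_to_mean_fa(cp_mode_pulse(8L, 1, 520e-6, 1e-5), maps, 10,
                               model = "sta")
  sb <- bloch_simulate(cp, maps)
  ss <- sta_simulate(cp, maps)
  expect_lt(sqrt(mean((sb$fa - ss$fa)^2)) / mean(ss$fa) * 100, 2)
})

test_that("fa/phase extraction follows the atan2 convention", {
  fp <- fa_phase_from_state(sin(10 * pi / 180) + 0i, cos(10 * pi / 180))
  expect_equal(fp$fa, 10, tolerance = 1e-12)
  fp0 <- fa_phase_from_state(0i, 1)
  expect_identical(c(fp0$fa, fp0$phase), c(0, 0))
  expect_equal(fa_phase_from_state(0i, -1)$fa, 180, tolerance = 1e-12)
  expect_equal(fa_phase_from_state(0.3i, 0.4)$phase, 90, tolerance = 1e-12)
})

test_that("nrmse matches hand-evaluated cases", {
  expect_identical(nrmse(rep(10, 5L), 10), 0)
  expect_equal(nrmse(rep(5, 8L), rep(10, 8L)), 50, tolerance = 1e-12)
  fa <- c(rep(11, 4L), rep(9, 4L))
  expect_equal(nrmse(fa, 10), 10, tolerance = 1e-12)
  expect_error(nrmse(c(1, 2), 0), "not positive")
})

test_that("adjoint model gradients match finite differences (2ch, 3^3)", {
  maps <- synth_fieldmaps(2L, c(3L, 3L, 3L), 0.05, 300, seed = 5L)
  ctx <- ptxpulse:::.masked_ctx(maps)
  tgt <- rep(10, ctx$n)
  Tn <- 6L
  p <- random_pulse(2L, Tn, seed = 7L, rf_sd = 20, g_sd = 3e-4)
  for (model in c("sta", "bloch")) {
    ev <- if (model == "sta") {
      ptxpulse:::.sta_rmse_grad(ctx, p$rf, p$grad, p$raster, tgt)
    } else {
      ptxpulse:::.bloch_rmse_grad(ctx, p$rf, p$grad, p$raster, tgt,
                                  relaxation_spec(), "equilibrium")
    }
    val <- function(rfv, gv) {
      rfm <- matrix(complex(real = rfv[seq_len(2L * Tn)],
                            imaginary = rfv[2L * Tn + seq_len(2L * Tn)]),
                    2L, Tn)
      gm <- matrix(gv, 3L, Tn)
      if (model == "sta")
        ptxpulse:::.sta_rmse_grad(ctx, rfm, gm, p$raster, tgt,
                                  want_grad = FALSE)$value
      else
        ptxpulse:::.bloch_rmse_grad(ctx, rfm, gm, p$raster, tgt,
                                    relaxation_spec(), "equilibrium",
                                    want_grad = FALSE)$value
    }
    rfv <- c(Re(p$rf), Im(p$rf))
    gv <- as.vector(p$grad)
    fd_rf <- fd_grad(function(x) val(x, gv), rfv)
    an_rf <- c(Re(ev$grad_rf), Im(ev$grad_rf))
    expect_lt(max(abs(an_rf - fd_rf)), 1e-3 * max(abs(fd_rf)))
    fd_g <- fd_grad(function(x) val(rfv, x), gv, h = 1e-7)
    an_g <- as.vector(ev$grad_g)
    expect_lt(max(abs(an_g - fd_g)), 1e-3 * max(abs(fd_g)))
  }
})
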