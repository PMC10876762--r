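# Eight-term design cost.

test_that("an all-zero pulse against a zero target costs exactly zero", {
  pulse <- pulse_waveform(matrix(0i, 2L, 6L), raster = 1e-5)
  bd <- cost_terms(pulse, rep(0, 10L), 0, limits = ptx_limits())
  expect_true(all(unlist(bd) == 0))
  expect_identical(total_cost(bd), 0)
})

test_that("hinge terms match hand-computed values at the printed weights", {
  lim <- ptx_limits(u_limit = 185)
  # one sample at 186 V -> err_volt = (186-185)^2 * 1e6 = 1e6
  rf <- matrix(0i, 1L, 4L)
  rf[1L, 2L] <- 186 + 0i
  pulse <- pulse_waveform(rf, matrix(0, 3L, 4L), 1e-5)
  bd <- cost_terms(pulse, rep(0, 5L), 0, limits = lim)
  expect_equal(bd$err_volt, 1e6, tolerance = 1e-9)
  # constant 100 V everywhere -> pen_power = (100*1e-2)^2 = 1
  pulse2 <- pulse_waveform(matrix(100 + 0i, 4L, 8L), raster = 1e-5)
  bd2 <- cost_terms(pulse2, rep(0, 5L), 0, limits = lim)
  expect_equal(bd2$pen_power, 1, tolerance = 1e-12)
})

test_that("waveforms strictly inside their limits incur zero err terms", {
  lim <- ptx_limits()
  for (seed in 1:4) {
    p <- random_pulse(2L, 10L, seed = seed, rf_sd = 30, g_sd = 2e-4)
    bd <- cost_terms(p, rep(10, 7L), 10, limits = lim)
    expect_identical(bd$err_volt, 0)
    expect_identical(bd$err_maxG, 0)
    expect_identical(bd$err_slew, 0)
    expect_identical(bd$err_sar, 0)
  }
})

test_that("err terms are non-decreasing in the violation magnitude", {
  lim <- ptx_limits()
  vals <- vapply(c(186, 190, 250), function(v) {
    rf <- matrix(v + 0i, 1L, 3L)
    cost_terms(pulse_waveform(rf, raster = 1e-5), 0, 0,
               limits = lim)$err_volt
  }, numeric(1L))
  expect_true(all(diff(vals) > 0))
  gvals <- vapply(c(0.066, 0.07, 0.1), function(g) {
    grad <- matrix(0, 3L, 6L)
    grad[1L, 3L] <- g
    cost_terms(pulse_waveform(matrix(0i, 1L, 6L), grad, 1e-3), 0, 0,
               limits = lim)$err_maxG
  }, numeric(1L))
  expect_true(all(diff(gvals) > 0))
})

test_that("slew includes the implicit-zero boundary ramps", {
  lim <- ptx_limits(s_limit = 100)
  # single gradient sample of 2 mT/m at 10 us raster: both edges slew at
  # 200 T/m/s -> two violations of 100 each
  grad <- matrix(c(2e-3, 0, 0), 3L, 1L)
  pulse <- pulse_waveform(matrix(0i, 1L, 1L), grad, 1e-5)
  bd <- cost_terms(pulse, 0, 0, limits = lim)
  expect_equal(bd$err_slew, 2 * 100^2 * 1e6, tolerance = 1e-9)
  # err_edge: first == last sample here, sum = 4e-3 * 1e3 = 4
  expect_equal(bd$err_edge, 16, tolerance = 1e-12)
})

test_that("total is the exact sum and permutation-invariant", {
  bd <- as.list(stats::setNames(abs(rnorm(8L)),
                                c("pen_rmse", "err_volt", "err_maxG",
                                  "err_slew", "err_edge", "pen_power",
                                  "pen_slew", "err_sar")))
  expect_equal(total_cost(bd), sum(unlist(bd)), tolerance = 1e-15)
  expect_equal(total_cost(rev(bd)), total_cost(bd), tolerance = 1e-15)
})

test_that("full-cost adjoint gradients match finite differences", {
  maps <- synth_fieldmaps(2L, c(3L, 3L, 3L), 0.05, 300, seed = 5L)
  vops <- synth_vops(4L, 2L, seed = 2L, scale = 1e-3)
  # tight limits so every hinge term is active
  lim <- ptx_limits(u_limit = 15, g_limit = 2e-4, s_limit = 40,
                    sar_limit = 1e-7, tr = 1e-3)
  dctx <- ptxpulse:::.design_ctx(maps, 10)
  Tn <- 6L
  p <- random_pulse(2L, Tn, seed = 8L, rf_sd = 15, g_sd = 2e-4)
  ev <- ptxpulse:::.cost_eval(p$rf, p$grad, p$raster, dctx, lim, vops, "sta")
  expect_true(all(unlist(ev$breakdown) > 0))
  val <- function(rfv, gv) {
    rfm <- matrix(complex(real = rfv[seq_len(2L * Tn)],
                          imaginary = rfv[2L * Tn + seq_len(2L * Tn)]),
                  2L, Tn)
    ptxpulse:::.cost_eval(rfm, matrix(gv, 3L, Tn), p$raster, dctx, lim,
                          vops, "sta", want_grad = FALSE)$total
  }
  rfv <- c(Re(p$rf), Im(p$rf))
  gv <- as.vector(p$grad)
  fd_rf <- fd_grad(function(x) val(x, gv), rfv, h = 1e-5)
  an_rf <- c(Re(ev$grad_rf), Im(ev$grad_rf))
  expect_lt(max(abs(an_rf - fd_rf)), 1e-3 * max(abs(fd_rf)))
  fd_g <- fd_grad(function(x) val(rfv, x), gv, h = 1e-9)
  an_g <- as.vector(ev$grad_g)
  expect_lt(max(abs(an_g - fd_g)), 1e-3 * max(abs(fd_g)))
})
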