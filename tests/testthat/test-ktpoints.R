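# 3-kT-point benchmark designer.

test_that("variable exchange solves the scalar case in closed form", {
  b <- variable_exchange_mls(matrix(2 + 0i, 1L, 1L), 4, n_iter = 5L)
  expect_equal(Mod(b), 2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(tail(attr(b, "residuals"), 1L), 1e-12)
})

test_that("the magnitude residual is non-increasing over iterations", {
  set.seed(12)
  A <- matrix(complex(real = rnorm(60L), imaginary = rnorm(60L)), 20L, 3L)
  tgt <- runif(20L, 0.5, 1.5)
  b <- variable_exchange_mls(A, tgt, n_iter = 20L)
  res <- attr(b, "residuals")
  expect_true(all(diff(res) <= 1e-9 * res[1L]))
})

test_that("the residual is invariant to a global phase on the system matrix", {
  set.seed(13)
  A <- matrix(complex(real = rnorm(40L), imaginary = rnorm(40L)), 10L, 4L)
  tgt <- runif(10L, 0.5, 1.5)
  r1 <- attr(variable_exchange_mls(A, tgt), "residuals")
  r2 <- attr(variable_exchange_mls(A * exp(0.7i), tgt), "residuals")
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_error(variable_exchange_mls(A[0, , drop = FALSE], numeric(0L)),
               "empty")
})

test_that("random position search is bounded, seeded, and self-consistent", {
  maps <- med_maps()
  s1 <- random_kt_search(maps, fa = 10, n_candidates = 25L, seed = 3L)
  s2 <- random_kt_search(maps, fa = 10, n_candidates = 25L, seed = 3L)
  expect_identical(s1$positions, s2$positions)
  expect_true(all(abs(s1$positions) <= 14))
  expect_identical(s1$positions[3L, ], c(0, 0, 0))
  expect_identical(attr(s1, "residual"), attr(s2, "residual"))
})

test_that("assembled 3-point pulse has the documented timing and blip areas", {
  spec <- kt_point_spec(rbind(c(5, -3, 8), c(-2, 7, 1), c(0, 0, 0)))
  w <- matrix(complex(real = rnorm(12L), imaginary = rnorm(12L)), 4L, 3L)
  pulse <- assemble_kt_pulse(spec, w)
  expect_equal(pulse_duration(pulse), 510e-6, tolerance = 1e-12)
  expect_identical(ncol(pulse$rf), 51L)
  # k-space position during each sub-pulse reproduces the spec positions
  k <- ptxpulse:::.k_traj(pulse$grad, pulse$raster)
  expect_lt(max(abs(k[, 7L] - spec$positions[1L, ])), 1e-6 * 14)
  expect_lt(max(abs(k[, 26L] - spec$positions[2L, ])), 1e-6 * 14)
  expect_true(all(abs(k[, 45L]) < 1e-12))
  # RF is zero during the blips, carries the weights during sub-pulses
  expect_true(all(pulse$rf[, 14:19] == 0))
  expect_identical(pulse$rf[, 1L], w[, 1L])
  # zero-displacement spec needs no gradients at all
  p0 <- assemble_kt_pulse(kt_point_spec(matrix(0, 3L, 3L)), w)
  expect_true(all(p0$grad == 0))
})

test_that("the third point must sit at the k-space origin", {
  expect_error(kt_point_spec(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))),
               "origin")
})

test_that("infeasible blips are rejected", {
  spec <- kt_point_spec(rbind(c(5e4, 0, 0), c(0, 0, 0), c(0, 0, 0)))
  w <- matrix(1 + 0i, 2L, 3L)
  expect_error(assemble_kt_pulse(spec, w, ptx_limits()), "infeasible")
})

test_that("coarse system matrix prediction matches the full-raster STA", {
  maps <- med_maps()
  des <- design_kt_pulse(maps, fa = 10, n_candidates = 30L, seed = 1L)
  ctx <- ptxpulse:::.masked_ctx(maps)
  pred <- Mod(ptxpulse:::.kt_system_matrix(ctx, des$spec) %*%
                as.vector(des$weights))
  got <- Mod(sta_simulate(des$pulse, maps)$mxy)
  expect_lt(sqrt(mean((got - pred)^2)) / mean(pred), 0.02)
})
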