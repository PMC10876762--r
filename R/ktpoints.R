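# 3-kT-point benchmark designer: magnitude-least-squares shimming over a
# small set of excitation k-space locations, solved by variable exchange.

#' kT-point timing and k-space positions
#'
#' @param positions 3 x 3 matrix: one k-space position (rad/m) per row, in
#'   playout order; the third must be the k-space origin.
#' @param subpulse_duration Rectangular sub-pulse duration in seconds
#'   (default 130 us).
#' @param gap_duration Gap between sub-pulses for gradient blips, seconds
#'   (default 60 us).
#' @param raster Sample interval in seconds.
#' @return Object of class `ptx_ktspec`; total duration is
#'   `3*subpulse + 2*gap`.
#' @export
kt_point_spec <- function(positions, subpulse_duration = 130e-6,
                          gap_duration = 60e-6, raster = 10e-6) {
  positions <- as.matrix(positions)
  stopifnot(all(dim(positions) == c(3L, 3L)))
  if (any(abs(positions[3L, ]) > 1e-12))
    stop("the third kT point must sit at the k-space origin")
  for (d in c(subpulse_duration, gap_duration)) {
    if (abs(d / raster - round(d / raster)) > 1e-9)
      stop("sub-pulse and gap durations must be raster multiples")
  }
  structure(list(positions = positions,
                 subpulse_duration = subpulse_duration,
                 gap_duration = gap_duration, raster = raster,
                 total_duration = 3 * subpulse_duration + 2 * gap_duration),
            class = "ptx_ktspec")
}

# Complex Moore-Penrose pseudo-inverse via SVD.
.pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d)
  keep <- s$d > tol
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * Conj(t(s$u[, keep, drop = FALSE])))
}

#' Magnitude-least-squares solve by variable exchange
#'
#' Alternating minimisation for `min_b || |A b| - target ||`: starting from
#' target phase 0, iterate `b <- pinv(A) (target * exp(1i * Arg(A b)))`.
#' The magnitude residual is non-increasing over iterations.
#'
#' @param A Complex system matrix (voxels x unknowns).
#' @param target_mag Non-negative target magnitudes, one per voxel.
#' @param n_iter Number of exchange iterations (default 20).
#' @return Complex weight vector (length `ncol(A)`) with the per-iteration
#'   residual norms as attribute `"residuals"`.
#' @export
variable_exchange_mls <- function(A, target_mag, n_iter = 20L) {
  target_mag <- as.double(target_mag)
  if (length(target_mag) == 0L) stop("empty target")
  stopifnot(nrow(A) == length(target_mag), all(target_mag >= 0))
  Ap <- .pinv(A)
  b <- Ap %*% target_mag
  res <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    z <- A %*% b
    res[i] <- sqrt(sum((Mod(z) - target_mag)^2))
    b <- Ap %*% (target_mag * exp(1i * Arg(z)))
  }
  structure(as.vector(b), residuals = res)
}

# Coarse STA system matrix at sub-pulse granularity: one effective sample
# per kT point, phase referenced to the sub-pulse centres.
.kt_system_matrix <- function(ctx, spec) {
  tau <- spec$subpulse_duration
  Ttot <- spec$total_duration
  centers <- (seq_len(3L) - 1L) * (tau + spec$gap_duration) + tau / 2
  blocks <- lapply(seq_len(3L), function(j) {
    ph <- drop(ctx$r %*% spec$positions[j, ]) +
      2 * pi * ctx$b0 * (centers[j] - Ttot)
    (1i * .gamma * tau) * exp(1i * ph) * ctx$B1
  })
  do.call(cbind, blocks)
}

# Ridge-regularized variable exchange (Tikhonov filter on the SVD); used for
# voltage-bounded seeding, not for the unregularized benchmark solve.
.ridge_ve <- function(A, target_mag, lambda, n_iter = 20L) {
  sv <- svd(A)
  filt <- sv$d / (sv$d^2 + lambda^2)
  solve_reg <- function(y) sv$v %*% (filt * (Conj(t(sv$u)) %*% y))
  b <- solve_reg(target_mag)
  for (i in seq_len(n_iter)) {
    z <- A %*% b
    b <- solve_reg(target_mag * exp(1i * Arg(z)))
  }
  as.vector(b)
}

# Candidate search over kT positions on a (possibly subsampled) masked
# context; shared by random_kt_search and the design warm start.
.kt_search_ctx <- function(ctx, target_rad, n_candidates, k_max, seed,
                           n_iter, n_score_voxels, subpulse_duration,
                           gap_duration, raster) {
  with_seed(seed, {
    sub <- if (ctx$n > n_score_voxels)
      sort(sample.int(ctx$n, n_score_voxels)) else seq_len(ctx$n)
    sctx <- list(B1 = ctx$B1[sub, , drop = FALSE],
                 r = ctx$r[sub, , drop = FALSE], b0 = ctx$b0[sub],
                 n = length(sub))
    stgt <- rep_len(target_rad, ctx$n)[sub]
    draws <- matrix(stats::runif(n_candidates * 6L, -k_max, k_max),
                    n_candidates, 6L)
    best <- Inf; best_i <- NA_integer_
    for (i in seq_len(n_candidates)) {
      pos <- rbind(draws[i, 1:3], draws[i, 4:6], c(0, 0, 0))
      spec <- kt_point_spec(pos, subpulse_duration, gap_duration, raster)
      b <- variable_exchange_mls(.kt_system_matrix(sctx, spec), stgt, n_iter)
      r <- attr(b, "residuals")[n_iter]
      if (r < best) { best <- r; best_i <- i }
    }
    spec <- kt_point_spec(rbind(draws[best_i, 1:3], draws[best_i, 4:6],
                                c(0, 0, 0)),
                          subpulse_duration, gap_duration, raster)
    structure(spec, residual = best, candidate = best_i)
  })
}

#' Random search for kT-point k-space positions
#'
#' Draws `n_candidates` uniform pairs of k-space positions for points 1-2
#' inside the cube `|k| <= k_max` (rad/m, componentwise), keeps point 3 at
#' the origin, scores every candidate by the magnitude-least-squares
#' residual after variable exchange on a coarse (sub-pulse granularity)
#' system matrix, and returns the best. Scoring uses a seeded random subset
#' of up to `n_score_voxels` masked voxels.
#'
#' @param maps A [fieldmap_set()].
#' @param fa Target flip angle in degrees.
#' @param n_candidates Number of random position pairs (default 5000).
#' @param k_max Componentwise position bound in rad/m (default 14).
#' @param seed Integer seed.
#' @param n_iter Variable-exchange iterations per candidate (default 20).
#' @param n_score_voxels Voxel subset size used during scoring.
#' @param subpulse_duration,gap_duration,raster Timing, see
#'   [kt_point_spec()].
#' @return The best [kt_point_spec()]; attributes `"residual"` (its score)
#'   and `"candidate"` (its index).
#' @export
random_kt_search <- function(maps, fa = 10, n_candidates = 5000L, k_max = 14,
                             seed = 0L, n_iter = 20L, n_score_voxels = 400L,
                             subpulse_duration = 130e-6, gap_duration = 60e-6,
                             raster = 10e-6) {
  ctx <- .masked_ctx(maps)
  .kt_search_ctx(ctx, fa * pi / 180, n_candidates, k_max, seed, n_iter,
                 n_score_voxels, subpulse_duration, gap_duration, raster)
}

#' Assemble a kT-point pulse waveform
#'
#' Rectangular sub-pulses carrying the per-point channel weights, with
#' triangular gradient blips in the gaps sized so the excitation k-space
#' trajectory visits the requested positions (RF is zero during blips).
#'
#' @param spec A [kt_point_spec()].
#' @param weights Complex matrix `(n_channels, 3)`: per-point channel
#'   voltages, or the stacked vector returned by [variable_exchange_mls()].
#' @param limits A [ptx_limits()] for blip feasibility.
#' @return A [pulse_waveform()] of duration `spec$total_duration`.
#' @export
assemble_kt_pulse <- function(spec, weights, limits = ptx_limits()) {
  stopifnot(inherits(spec, "ptx_ktspec"))
  raster <- spec$raster
  nsub <- as.integer(round(spec$subpulse_duration / raster))
  ngap <- as.integer(round(spec$gap_duration / raster))
  if (is.null(dim(weights))) weights <- matrix(weights, ncol = 3L)
  C <- nrow(weights)
  Tn <- 3L * nsub + 2L * ngap
  rf <- matrix(0i, C, Tn)
  grad <- matrix(0, 3L, Tn)
  sub_start <- (0:2) * (nsub + ngap)
  for (j in 1:3) rf[, sub_start[j] + seq_len(nsub)] <- weights[, j]
  # blip areas: with k(t) = -gamma int_t^T g, the k-position during
  # sub-pulse j equals -gamma times the summed area of all later blips
  areas <- rbind((spec$positions[2L, ] - spec$positions[1L, ]) / .gamma,
                 (0 - spec$positions[2L, ]) / .gamma)
  tri <- pmin(seq_len(ngap), rev(seq_len(ngap)))
  for (b in 1:2) {
    gi <- b * nsub + (b - 1L) * ngap + seq_len(ngap)
    for (ax in 1:3) {
      A <- areas[b, ax]
      if (A == 0) next
      delta <- A / (sum(tri) * raster)
      if (abs(delta) * max(tri) > limits$g_limit ||
          abs(delta) / raster > limits$s_limit)
        stop("gradient blip infeasible within the gap at the stated limits")
      grad[ax, gi] <- delta * tri
    }
  }
  pulse_waveform(rf, grad, raster)
}

#' Full kT-point benchmark design
#'
#' Runs the random position search, solves the magnitude-least-squares
#' problem on all masked voxels at the selected positions, and assembles
#' the playable pulse. No SAR constraint is applied.
#'
#' @inheritParams random_kt_search
#' @param limits A [ptx_limits()] for blip feasibility.
#' @return List with `pulse` (a [pulse_waveform()]), `spec`, `weights`, and
#'   `residual` (final MLS residual on all masked voxels).
#' @export
design_kt_pulse <- function(maps, fa = 10, n_candidates = 5000L, k_max = 14,
                            seed = 0L, n_iter = 20L, n_score_voxels = 400L,
                            limits = ptx_limits()) {
  spec <- random_kt_search(maps, fa, n_candidates, k_max, seed, n_iter,
                           n_score_voxels)
  ctx <- .masked_ctx(maps)
  b <- variable_exchange_mls(.kt_system_matrix(ctx, spec),
                             rep(fa * pi / 180, ctx$n), n_iter)
  C <- ncol(ctx$B1)
  pulse <- assemble_kt_pulse(spec, matrix(b, C, 3L), limits)
  list(pulse = pulse, spec = spec, weights = matrix(b, C, 3L),
       residual = attr(b, "residuals")[n_iter])
}
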