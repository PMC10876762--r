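# Forward models.
#
# Bloch: exact axis-angle rotation per raster step (hard-pulse approximation,
# unconditionally norm-preserving), with optional separable T1/T2 relaxation
# interleaved per step. Small-tip-angle (STA): spatial-domain system matrix
# accumulating k-space trajectory, B0 and B1+ phase.
#
# Sign conventions follow the rotating-frame Bloch equation
# dM/dt = gamma * (M x B): transverse phase accrues as -gamma*Bz*t, and the
# STA phase factor is exp(i * (k.r + 2*pi*b0*(t - T))) with
# k(t) = -gamma * int_t^T g(s) ds, so both models agree to first order.
# B1+ maps are nT/V on the user surface and converted to T/V internally.

#' Relaxation specification
#' @param t1,t2 Longitudinal / transverse relaxation times in seconds
#'   (`Inf` disables, the default: pulse design ignores relaxation).
#' @param m0 Equilibrium longitudinal magnetization (default 1).
#' @return Object of class `ptx_relax`.
#' @export
relaxation_spec <- function(t1 = Inf, t2 = Inf, m0 = 1) {
  stopifnot(t1 > 0, t2 > 0)
  structure(list(t1 = t1, t2 = t2, m0 = m0), class = "ptx_relax")
}

# Masked-voxel view of a fieldmap set; B1 converted to T/V.
.masked_ctx <- function(maps) {
  stopifnot(inherits(maps, "ptx_fieldmaps"))
  idx <- which(maps$mask)
  C <- dim(maps$b1)[1L]
  B1 <- t(matrix(maps$b1, nrow = C)[, idx, drop = FALSE]) * 1e-9
  list(B1 = B1, r = maps$coords[idx, , drop = FALSE],
       b0 = as.double(maps$b0[idx]), n = length(idx), idx = idx,
       grid_shape = maps$grid_shape)
}

# Excitation k-space trajectory (rad/m), 3 x T: k(t) = -gamma int_t^T g ds,
# right-aligned so that k(T) = 0 for the last sample.
.k_traj <- function(grad, raster) {
  cums <- apply(grad, 1L, cumsum)         # T x 3 (vector when T = 1)
  if (is.null(dim(cums))) cums <- matrix(cums, nrow = 1L)
  cums <- t(cums)
  -.gamma * raster * (cums[, ncol(cums)] - cums)
}

# STA phase matrix (masked voxels x T, radians).
.sta_phase <- function(ctx, grad, raster) {
  Tn <- ncol(grad)
  k <- .k_traj(grad, raster)
  tfac <- (seq_len(Tn) - Tn) * raster
  ctx$r %*% k + 2 * pi * outer(ctx$b0, tfac)
}

#' STA spatial-domain system matrix
#'
#' Assembles the linear operator mapping the stacked complex RF samples to
#' transverse magnetization per masked voxel under the small-tip-angle
#' approximation. Element (voxel r; channel c, sample t) is
#' `1i * gamma * b1_c(r) * raster * exp(1i * (k(t).r + 2*pi*b0(r)*(t - T)))`
#' with `k(t) = -gamma * int_t^T g`. Columns are ordered channel-fastest so
#' that `A %*% as.vector(rf)` works on an `(n_channels, n_samples)` RF
#' matrix. The matrix is rebuilt from the current gradients on every call.
#'
#' @param maps A [fieldmap_set()].
#' @param grad Gradient samples, matrix `(3, n_samples)` in T/m.
#' @param raster Sample interval in seconds.
#' @return Complex matrix `(n_masked_voxels, n_channels * n_samples)`.
#' @export
sta_system_matrix <- function(maps, grad, raster) {
  ctx <- .masked_ctx(maps)
  E <- exp(1i * .sta_phase(ctx, grad, raster))
  C <- ncol(ctx$B1)
  Tn <- ncol(grad)
  (1i * .gamma * raster) *
    E[, rep(seq_len(Tn), each = C), drop = FALSE] *
    ctx$B1[, rep(seq_len(C), times = Tn), drop = FALSE]
}

# STA forward on a masked context: returns mxy per masked voxel plus the
# intermediates the adjoint pass reuses.
.sta_forward <- function(ctx, rf, grad, raster) {
  E <- exp(1i * .sta_phase(ctx, grad, raster))
  S <- ctx$B1 %*% rf
  W <- (1i * .gamma * raster) * E * S
  list(mxy = rowSums(W), E = E, W = W)
}

#' Simulate a pulse under the small-tip-angle model
#'
#' `mxy = A %*% rf` per masked voxel; `mz` is reported as the equilibrium
#' `m0 = 1` (the STA assumption), and the flip angle is `|mxy|` in radians
#' converted to degrees.
#'
#' @param pulse A [pulse_waveform()].
#' @param maps A [fieldmap_set()].
#' @return Object of class `ptx_sim` with per-masked-voxel `mxy`, `mz`,
#'   `fa` (degrees), `phase` (degrees), plus `mask_index` and `grid_shape`.
#' @export
sta_simulate <- function(pulse, maps) {
  stopifnot(inherits(pulse, "ptx_pulse"))
  ctx <- .masked_ctx(maps)
  if (ncol(ctx$B1) != nrow(pulse$rf))
    stop("pulse has ", nrow(pulse$rf), " channels but maps have ",
         ncol(ctx$B1))
  mxy <- .sta_forward(ctx, pulse$rf, pulse$grad, pulse$raster)$mxy
  .sim_result(mxy, mz = rep(1, ctx$n), fa = Mod(mxy) * 180 / pi, ctx = ctx)
}

.sim_result <- function(mxy, mz, fa, ctx) {
  phase <- ifelse(Mod(mxy) > 0, Arg(mxy) * 180 / pi, 0)
  structure(list(mxy = mxy, mz = mz, fa = fa, phase = phase,
                 mask_index = ctx$idx, grid_shape = ctx$grid_shape),
            class = "ptx_sim")
}

#' @export
print.ptx_sim <- function(x, ...) {
  cat(sprintf(
    "<ptx_sim> %d voxels; FA mean %.3f deg, sd %.3f deg, range [%.3f, %.3f]\n",
    length(x$fa), mean(x$fa), stats::sd(x$fa), min(x$fa), max(x$fa)))
  invisible(x)
}

# Apply the per-step rotation solving dM/dt = gamma * (M x B) over one raster
# interval: rotation vector w = -gamma * raster * B. M is (n x 3); wx/wy/wz
# are length-n field-axis components already multiplied by -gamma*raster.
.rot_apply <- function(M, wx, wy, wz) {
  th <- sqrt(wx^2 + wy^2 + wz^2)
  safe <- pmax(th, .Machine$double.xmin)
  nx <- wx / safe; ny <- wy / safe; nz <- wz / safe
  ct <- cos(th); st <- sin(th)
  ndm <- nx * M[, 1L] + ny * M[, 2L] + nz * M[, 3L]
  cx <- ny * M[, 3L] - nz * M[, 2L]
  cy <- nz * M[, 1L] - nx * M[, 3L]
  cz <- nx * M[, 2L] - ny * M[, 1L]
  out <- cbind(ct * M[, 1L] + st * cx + (1 - ct) * ndm * nx,
               ct * M[, 2L] + st * cy + (1 - ct) * ndm * ny,
               ct * M[, 3L] + st * cz + (1 - ct) * ndm * nz)
  small <- th < 1e-14
  if (any(small)) out[small, ] <- M[small, , drop = FALSE]
  out
}

# Bloch forward pass on a masked context. Returns final state and, when
# keep_states = TRUE, all intermediate states for the adjoint pass.
.bloch_forward <- function(ctx, rf, grad, raster, relax, M0,
                           keep_states = FALSE) {
  Tn <- ncol(rf)
  S <- ctx$B1 %*% rf                      # n x T complex, Tesla
  BZ <- ctx$r %*% grad +                  # n x T, Tesla
    2 * pi * ctx$b0 / .gamma
  e1 <- if (is.finite(relax$t1)) exp(-raster / relax$t1) else 1
  e2 <- if (is.finite(relax$t2)) exp(-raster / relax$t2) else 1
  regrow <- relax$m0 * (1 - e1)
  M <- M0
  states <- if (keep_states) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    if (keep_states) states[[t]] <- M
    M <- .rot_apply(M, -.gamma * raster * Re(S[, t]),
                    -.gamma * raster * Im(S[, t]),
                    -.gamma * raster * BZ[, t])
    if (e1 != 1 || e2 != 1) {
      M[, 1L] <- M[, 1L] * e2
      M[, 2L] <- M[, 2L] * e2
      M[, 3L] <- M[, 3L] * e1 + regrow
    }
  }
  list(M = M, S = S, BZ = BZ, states = states, e1 = e1, e2 = e2)
}

.initial_state <- function(initial, relax, n) {
  if (is.character(initial) && identical(initial, "equilibrium"))
    return(cbind(rep(0, n), rep(0, n), rep(relax$m0, n)))
  if (is.list(initial) && !is.null(initial$mxy)) {
    mxy <- rep_len(initial$mxy, n)
    mz <- rep_len(if (is.null(initial$mz)) 0 else initial$mz, n)
    return(cbind(Re(mxy), Im(mxy), mz))
  }
  if (is.matrix(initial) && ncol(initial) == 3L && nrow(initial) == n)
    return(initial)
  stop("initial must be \"equilibrium\", a list(mxy=, mz=), or an n x 3 matrix")
}

#' Simulate a pulse with the Bloch equations
#'
#' Advances every masked voxel's magnetization through the pulse, one exact
#' axis-angle rotation about the voxel's effective field per raster step
#' (effective field: real/imaginary parts of the B1-weighted channel sum
#' transversally, `g.r + 2*pi*b0/gamma` longitudinally), with separable
#' T1/T2 relaxation applied per step when enabled.
#'
#' @param pulse A [pulse_waveform()].
#' @param maps A [fieldmap_set()].
#' @param relax A [relaxation_spec()]; defaults to no relaxation.
#' @param initial `"equilibrium"`, a `list(mxy=, mz=)` recycled over voxels,
#'   or an `(n_masked, 3)` state matrix.
#' @return A `ptx_sim` (see [sta_simulate()]); the flip angle is
#'   `atan2(|mxy|, mz)` in degrees.
#' @export
bloch_simulate <- function(pulse, maps, relax = relaxation_spec(),
                           initial = "equilibrium") {
  stopifnot(inherits(pulse, "ptx_pulse"))
  if (ncol(pulse$rf) == 0L) stop("zero-length pulse")
  ctx <- .masked_ctx(maps)
  if (ncol(ctx$B1) != nrow(pulse$rf))
    stop("pulse has ", nrow(pulse$rf), " channels but maps have ",
         ncol(ctx$B1))
  M0 <- .initial_state(initial, relax, ctx$n)
  M <- .bloch_forward(ctx, pulse$rf, pulse$grad, pulse$raster, relax, M0)$M
  mxy <- complex(real = M[, 1L], imaginary = M[, 2L])
  fp <- fa_phase_from_state(mxy, M[, 3L])
  .sim_result(mxy, mz = M[, 3L], fa = fp$fa, ctx = ctx)
}

#' Flip angle and phase from a magnetization state
#'
#' `fa = atan2(|mxy|, mz) * 180/pi`, `phase = Arg(mxy) * 180/pi` (0 by
#' convention where `|mxy| = 0`).
#'
#' @param mxy Complex transverse magnetization (M0-normalized).
#' @param mz Longitudinal magnetization.
#' @return List with numeric vectors `fa` and `phase` in degrees.
#' @export
fa_phase_from_state <- function(mxy, mz) {
  rho <- Mod(mxy)
  list(fa = atan2(rho, mz) * 180 / pi,
       phase = ifelse(rho > 0, Arg(mxy) * 180 / pi, 0))
}

#' Normalized root-mean-square flip-angle error
#'
#' `sqrt(mean((fa - target)^2)) / mean(target) * 100` over the masked voxels,
#' in percent.
#'
#' @param fa Achieved flip-angle map (degrees): vector, or array with `mask`.
#' @param target_fa Target flip angles (degrees), scalar or same shape.
#' @param mask Optional logical array selecting voxels when `fa` is an array.
#' @return NRMSE in percent.
#' @export
nrmse <- function(fa, target_fa, mask = NULL) {
  if (!is.null(mask)) {
    fa <- fa[mask]
    if (length(target_fa) > 1L) target_fa <- target_fa[mask]
  }
  target_fa <- rep_len(target_fa, length(fa))
  mt <- mean(target_fa)
  if (!is.finite(mt) || mt <= 0)
    stop("nrmse undefined: mean target flip angle is not positive")
  sqrt(mean((fa - target_fa)^2)) / mt * 100
}
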