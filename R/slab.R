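# Slab-selective excitation: conventional sinc + trapezoid seed pulse and
# free joint optimization against an in-slab/out-of-slab target pattern.

#' Conventional CP-mode sinc slab pulse
#'
#' Builds the classic slab-selective seed: a sinc envelope (time-bandwidth
#' product `tbw`) on CP-mode channel weights, played under the plateau of a
#' trapezoidal slice-selection gradient along the slab normal, followed by a
#' triangular refocusing lobe that rewinds the phase accrued from the pulse
#' centre. First and last gradient samples are zero.
#'
#' @param n_channels Number of transmit channels.
#' @param thickness Slab thickness in metres.
#' @param normal Slab normal (3-vector, normalised internally).
#' @param rf_duration Sinc envelope duration in seconds (default 1.2 ms).
#' @param total_duration Total pulse duration including gradient lobes
#'   (default 2.4 ms).
#' @param raster Sample interval in seconds.
#' @param tbw Time-bandwidth product (default 8).
#' @param voltage Peak sinc amplitude per channel in volts.
#' @param limits A [ptx_limits()] (slew/gradient feasibility of the lobes).
#' @return A [pulse_waveform()].
#' @export
sinc_slab_pulse <- function(n_channels, thickness, normal = c(0, 0, 1),
                            rf_duration = 1.2e-3, total_duration = 2.4e-3,
                            raster = 10e-6, tbw = 8, voltage = 1,
                            limits = ptx_limits()) {
  stopifnot(thickness > 0, rf_duration > 0, total_duration > rf_duration)
  nhat <- normal / sqrt(sum(normal^2))
  Tn <- as.integer(round(total_duration / raster))
  nrf <- as.integer(round(rf_duration / raster))
  bw <- tbw / rf_duration                         # Hz
  G <- bw / ((.gamma / (2 * pi)) * thickness)     # T/m
  if (G > limits$g_limit)
    stop("slice gradient infeasible: ", signif(G * 1e3, 3), " mT/m needed")
  nramp <- max(1L, as.integer(ceiling(G / (0.5 * limits$s_limit * raster))))
  nrem <- Tn - 2L * nramp - nrf
  if (nrem < 3L)
    stop("total_duration too short for the refocusing lobe")

  gwave <- numeric(Tn)
  gwave[seq_len(nramp)] <- G * (seq_len(nramp) - 1L) / nramp
  plateau <- nramp + seq_len(nrf)
  gwave[plateau] <- G
  gwave[nramp + nrf + seq_len(nramp)] <- G * rev(seq_len(nramp) - 1L) / nramp
  # refocus the area accrued from the centre of the RF envelope onward
  centre <- nramp + nrf / 2
  idx <- seq_len(Tn)
  area_right <- sum(gwave[idx > centre]) * raster +
    (if (centre == floor(centre)) 0 else 0.5 * gwave[ceiling(centre)] * raster)
  nref <- nrem - 1L
  tri <- pmin(seq_len(nref), rev(seq_len(nref)))
  delta <- area_right / (sum(tri) * raster)
  if (delta * max(tri) > limits$g_limit ||
      delta / raster > limits$s_limit)
    stop("refocusing lobe infeasible within the stated limits")
  gwave[2L * nramp + nrf + seq_len(nref)] <- -delta * tri
  grad <- outer(nhat, gwave)

  trel <- (seq_len(nrf) - (nrf + 1) / 2) * raster
  x <- pi * bw * trel
  env <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  phases <- 2 * pi * (seq_len(n_channels) - 1L) / n_channels
  rf <- matrix(0i, n_channels, Tn)
  rf[, plateau] <- voltage * outer(exp(1i * phases), env)
  pulse_waveform(rf, grad, raster)
}

#' Design a slab-selective pTx pulse
#'
#' Builds a target pattern with `fa` degrees inside the slab
#' (`|coords . normal| <= thickness/2`) and 0 degrees elsewhere over the
#' full mask, seeds from the CP-mode sinc pulse of [sinc_slab_pulse()]
#' scaled so the in-slab mean flip angle matches `fa`, then runs free joint
#' RF + gradient optimization on the small-tip-angle model.
#'
#' @param maps A [fieldmap_set()] or list of them.
#' @param thickness Slab thickness in metres.
#' @param normal Slab normal (3-vector).
#' @param fa In-slab target flip angle in degrees.
#' @param rf_duration,total_duration,raster,tbw Seed-pulse geometry, see
#'   [sinc_slab_pulse()].
#' @param iters Optimization iterations.
#' @param limits A [ptx_limits()].
#' @param vops Optional [vop_set()].
#' @param seed Integer seed.
#' @param learning_rate,restart_period Optimizer settings.
#' @return A [ptx_fit]-style list from [optimize_pulse()]; additionally
#'   `$seed_pulse` (the scaled sinc seed) and `$target` (per-subject target
#'   vectors, degrees).
#' @export
design_slab <- function(maps, thickness, normal = c(0, 0, 1), fa = 10,
                        rf_duration = 1.2e-3, total_duration = 2.4e-3,
                        raster = 10e-6, tbw = 8, iters = 20000L,
                        limits = ptx_limits(), vops = NULL, seed = 0L,
                        learning_rate = 4e-4, restart_period = 1000L) {
  if (inherits(maps, "ptx_fieldmaps")) maps <- list(maps)
  nhat <- normal / sqrt(sum(normal^2))
  target <- lapply(maps, function(m) {
    idx <- which(m$mask)
    proj <- abs(m$coords[idx, , drop = FALSE] %*% nhat)
    as.double(ifelse(proj <= thickness / 2, fa, 0))
  })
  if (all(vapply(target, function(t) all(t == 0), logical(1L))))
    stop("slab does not intersect the mask")
  C <- dim(maps[[1L]]$b1)[1L]
  seed_pulse <- sinc_slab_pulse(C, thickness, nhat, rf_duration,
                                total_duration, raster, tbw,
                                voltage = 1, limits = limits)
  # scale the seed so the mean in-slab STA flip angle hits the target
  in_fa <- mean(unlist(lapply(seq_along(maps), function(i) {
    sim <- sta_simulate(seed_pulse, maps[[i]])
    sim$fa[target[[i]] > 0]
  })))
  if (in_fa > 0) seed_pulse <- scale_pulse(seed_pulse, fa / in_fa)
  prob <- design_problem(maps, target, total_duration, raster,
                         limits = limits, model = "sta",
                         initial_pulse = seed_pulse, vops = vops,
                         zero_edge_grad = TRUE)
  fit <- optimize_pulse(prob, optimizer_config(
    n_iterations = iters, learning_rate = learning_rate,
    restart_period = restart_period, seed = seed))
  fit$pulse <- .zero_edge_grad(fit$pulse)
  fit$seed_pulse <- seed_pulse
  fit$target <- target
  fit
}
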