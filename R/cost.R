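# Composite design cost: flip-angle RMSE plus hardware/regulatory terms.
#
# err_* terms are exactly zero until their limit is exceeded (hinge-squared,
# with fixed published weights); pen_* terms are small and always active.
# Reduction over violating samples is a SUM for err_volt/err_maxG/err_slew
# (every violating sample must receive gradient); set
# options(ptxpulse.err_reduction = "mean") to switch to a mean reduction.

#' Hardware and regulatory limits
#'
#' @param u_limit Per-channel RF voltage limit in V (default 185).
#' @param g_limit Gradient magnitude limit in T/m (default 65 mT/m).
#' @param s_limit Slew-rate limit in T/m/s (default 185).
#' @param sar_limit Maximum local SAR limit in W/kg (default 2.3).
#' @param tr Average repetition time in seconds for SAR duty-cycle
#'   accounting (default 19.7 ms).
#' @return Object of class `ptx_limits`.
#' @export
ptx_limits <- function(u_limit = 185, g_limit = 65e-3, s_limit = 185,
                       sar_limit = 2.3, tr = 19.7e-3) {
  stopifnot(u_limit > 0, g_limit > 0, s_limit > 0, sar_limit > 0, tr > 0)
  structure(list(u_limit = u_limit, g_limit = g_limit, s_limit = s_limit,
                 sar_limit = sar_limit, tr = tr), class = "ptx_limits")
}

.err_reduce <- function(x) {
  if (identical(getOption("ptxpulse.err_reduction", "sum"), "mean"))
    mean(x) else sum(x)
}

# Gradient slew including the ramps from/to the implicit zero before the
# first and after the last sample: 3 x (T+1) forward differences / raster.
.slew <- function(grad, raster) {
  Tn <- ncol(grad)
  (cbind(grad, 0) - cbind(0, grad)) / raster
}

#' Evaluate all cost terms of a pulse
#'
#' Computes the eight-term design cost for a given simulated flip-angle map:
#' flip-angle RMSE (degrees), hinge-squared penalties for per-channel voltage,
#' gradient magnitude, slew rate (including the edge ramps from implicit
#' zero), non-zero edge gradient samples, mean pulse power, mean squared slew,
#' and local SAR excess (0 when `vops` is `NULL`).
#'
#' @param pulse A [pulse_waveform()].
#' @param sim_fa Simulated flip-angle map in degrees (vector over masked
#'   voxels, or array combined with `mask`).
#' @param target_fa Target flip angles in degrees (scalar or same shape).
#' @param mask Optional logical array when `sim_fa`/`target_fa` are arrays.
#' @param limits A [ptx_limits()].
#' @param vops A [vop_set()] or `NULL`.
#' @return Object of class `ptx_cost`: named list of the eight terms plus
#'   `total`, their sum. The attribute `"sar"` records the predicted SAR.
#' @export
cost_terms <- function(pulse, sim_fa, target_fa, mask = NULL,
                       limits = ptx_limits(), vops = NULL) {
  stopifnot(inherits(pulse, "ptx_pulse"), inherits(limits, "ptx_limits"))
  if (!is.null(mask)) {
    sim_fa <- sim_fa[mask]
    if (length(target_fa) > 1L) target_fa <- target_fa[mask]
  }
  target_fa <- rep_len(target_fa, length(sim_fa))
  rf <- pulse$rf; g <- pulse$grad
  sar <- if (is.null(vops)) 0 else as.numeric(local_sar(pulse, vops, limits$tr))
  dgdt <- .slew(g, pulse$raster)
  terms <- list(
    pen_rmse  = sqrt(mean((abs(sim_fa) - abs(target_fa))^2)),
    err_volt  = .err_reduce(pmax(0, Mod(rf) - limits$u_limit)^2) * 1e6,
    err_maxG  = .err_reduce(pmax(0, abs(g) - limits$g_limit)^2) * 1e15,
    err_slew  = .err_reduce(pmax(0, abs(dgdt) - limits$s_limit)^2) * 1e6,
    err_edge  = sum(((g[, 1L] + g[, ncol(g)]) * 1e3)^2),
    pen_power = mean((Mod(rf) * 1e-2)^2),
    pen_slew  = mean(dgdt^2) * 1e-6,
    err_sar   = max(0, sar - limits$sar_limit)^2 * 1e2)
  structure(c(terms, list(total = sum(unlist(terms)))),
            class = "ptx_cost", sar = sar)
}

#' Total cost from a breakdown
#' @param breakdown A `ptx_cost` (or named list of term values).
#' @return The exact sum of the eight terms.
#' @export
total_cost <- function(breakdown) {
  nm <- setdiff(names(breakdown), "total")
  sum(unlist(breakdown[nm]))
}

#' @export
print.ptx_cost <- function(x, ...) {
  v <- unlist(x)
  cat("<ptx_cost>\n")
  for (nm in names(v)) cat(sprintf("  %-9s %.6g\n", nm, v[[nm]]))
  invisible(x)
}
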