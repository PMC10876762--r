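# Waveform container and elementary pulses.

# Gyromagnetic ratio of 1H, rad/s/T.
.gamma <- 267.522e6

#' Construct a pulse waveform
#'
#' Multi-channel complex RF voltage waveforms and 3-axis gradient waveforms
#' on a common raster.
#'
#' @param rf Complex matrix `(n_channels, n_samples)`, volts.
#' @param grad Numeric matrix `(3, n_samples)`, T/m. Defaults to zeros.
#' @param raster Sample interval in seconds.
#' @return Object of class `ptx_pulse` with elements `rf`, `grad`, `raster`.
#' @export
pulse_waveform <- function(rf, grad = NULL, raster) {
  if (is.null(dim(rf))) rf <- matrix(rf, nrow = 1L)
  if (!is.complex(rf)) rf <- rf + 0i
  if (is.null(grad)) grad <- matrix(0, 3L, ncol(rf))
  if (is.null(dim(grad))) grad <- matrix(grad, nrow = 3L)
  if (nrow(grad) != 3L) stop("grad must have 3 rows (x, y, z axes)")
  if (ncol(grad) != ncol(rf))
    stop("rf and grad must share n_samples (got ", ncol(rf), " vs ",
         ncol(grad), ")")
  if (!is.numeric(raster) || length(raster) != 1L || raster <= 0)
    stop("raster must be a single positive number (seconds)")
  if (!all(is.finite(Re(rf))) || !all(is.finite(Im(rf))) ||
      !all(is.finite(grad)))
    stop("pulse waveforms contain non-finite values")
  structure(list(rf = rf, grad = grad, raster = as.double(raster)),
            class = "ptx_pulse")
}

#' @export
print.ptx_pulse <- function(x, ...) {
  cat(sprintf(
    "<ptx_pulse> %d channels x %d samples, raster %.3g us, duration %.3g us\n",
    nrow(x$rf), ncol(x$rf), x$raster * 1e6, pulse_duration(x) * 1e6))
  cat(sprintf("  max |RF| %.4g V, max |G| %.4g mT/m\n",
              max(Mod(x$rf)), max(abs(x$grad)) * 1e3))
  invisible(x)
}

#' Pulse duration in seconds
#' @param pulse A [pulse_waveform()].
#' @return Duration `n_samples * raster` in seconds.
#' @export
pulse_duration <- function(pulse) ncol(pulse$rf) * pulse$raster

#' Rectangular CP-mode pulse
#'
#' Circularly-polarised (birdcage-like) mode: equal per-channel magnitude
#' with phase `2*pi*c/n_channels` for channel `c = 0..n_channels-1`, matching
#' the ring azimuth of the synthetic coil layout; zero gradients.
#'
#' @param n_channels Number of transmit channels.
#' @param voltage Per-channel amplitude in volts.
#' @param duration Pulse duration in seconds; must be a multiple of `raster`.
#' @param raster Sample interval in seconds.
#' @return A [pulse_waveform()].
#' @export
cp_mode_pulse <- function(n_channels, voltage, duration, raster) {
  n <- duration / raster
  if (abs(n - round(n)) > 1e-9)
    stop("duration (", duration, " s) is not a multiple of the raster (",
         raster, " s)")
  n <- as.integer(round(n))
  phases <- 2 * pi * (seq_len(n_channels) - 1L) / n_channels
  rf <- matrix(voltage * exp(1i * phases), n_channels, n)
  pulse_waveform(rf, matrix(0, 3L, n), raster)
}

#' Scale the RF voltages of a pulse
#' @param pulse A [pulse_waveform()].
#' @param factor Real scalar applied to all RF samples.
#' @return The scaled [pulse_waveform()] (gradients untouched).
#' @export
scale_pulse <- function(pulse, factor) {
  pulse$rf <- pulse$rf * factor
  pulse
}

# Evaluate seeded code without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
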