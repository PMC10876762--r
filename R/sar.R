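# Local SAR prediction from Virtual Observation Point (VOP) matrices.

#' Maximum local SAR of a pulse
#'
#' Time-averages the per-VOP quadratic form over the repetition time:
#' `max_v (raster / tr) * sum_t Re(p(t)^H V_v p(t))`. Dead time between the
#' pulse end and the next TR contributes zero.
#'
#' @param pulse A [pulse_waveform()].
#' @param vops A [vop_set()].
#' @param tr Average repetition time in seconds; must be at least the pulse
#'   duration (duty cycle <= 1).
#' @return Maximum local SAR in W/kg. The attribute `"which_vop"` records the
#'   maximizing VOP index.
#' @export
local_sar <- function(pulse, vops, tr) {
  stopifnot(inherits(pulse, "ptx_pulse"), inherits(vops, "ptx_vops"))
  if (tr < pulse_duration(pulse))
    stop("tr (", tr, " s) is shorter than the pulse duration (",
         pulse_duration(pulse), " s): duty cycle > 1")
  s <- .sar_per_vop(pulse$rf, vops$matrices, pulse$raster, tr)
  structure(max(s), which_vop = which.max(s))
}

# Per-VOP time-averaged SAR, length n_vops.
.sar_per_vop <- function(rf, matrices, raster, tr) {
  nv <- dim(matrices)[3L]
  vapply(seq_len(nv), function(v) {
    sum(Re(Conj(rf) * (matrices[, , v] %*% rf)))
  }, numeric(1L)) * raster / tr
}

#' Read a VOP file
#'
#' Loads a stack of SAR matrices from a MATLAB v5 container holding a 3-D
#' complex array `(n_channels, n_channels, n_vops)`; matrices are
#' Hermitianized on load, with a warning when the relative asymmetry exceeds
#' 1e-9.
#'
#' @param path Path to the container.
#' @param key In-file variable name (default `"VOP"`).
#' @return A [vop_set()].
#' @export
read_vops <- function(path, key = "VOP") {
  if (!file.exists(path)) stop("file not found: ", path)
  vars <- mat_read(path)
  if (!key %in% names(vars))
    stop("VOP file is missing the '", key, "' array: ", path)
  vop_set(vars[[key]])
}

#' Write a VOP file
#' @param vops A [vop_set()].
#' @param path Output path.
#' @param key In-file variable name (default `"VOP"`).
#' @return Invisibly, `path`.
#' @export
write_vops <- function(vops, path, key = "VOP") {
  stopifnot(inherits(vops, "ptx_vops"))
  vars <- list(vops$matrices)
  names(vars) <- key
  mat_write(vars, path)
}
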