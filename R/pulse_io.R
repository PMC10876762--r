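# Text (ini-style) pulse serialization.
#
# Dialect: a [pTXPulse] header section (n_channels, n_samples, raster in
# seconds, nominal_fa in degrees, free-text comment), one [Gradient] section
# with n_samples rows "gx gy gz" in mT/m, and one [RF_ch<k>] section per
# channel with n_samples rows "magnitude_V phase_deg". Values carry 9
# significant digits so a round-trip is faithful to ~1e-8 relative.
# Vendor-specific pulse formats differ; converters can be layered on top.

#' Pulse file header
#' @param n_channels,n_samples Waveform geometry.
#' @param raster Sample interval in seconds.
#' @param nominal_fa Nominal flip angle in degrees.
#' @param comment Free-text comment (single line).
#' @return Object of class `ptx_pulse_header`.
#' @export
pulse_header <- function(n_channels, n_samples, raster, nominal_fa = 0,
                         comment = "") {
  structure(list(n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 raster = as.double(raster),
                 nominal_fa = as.double(nominal_fa),
                 comment = as.character(comment)[1L]),
            class = "ptx_pulse_header")
}

#' Write a pulse to an ini-style text file
#'
#' @param pulse A [pulse_waveform()].
#' @param path Output path.
#' @param header Optional [pulse_header()]; defaults to one derived from
#'   the pulse.
#' @return Invisibly, `path`.
#' @export
write_pulse_ini <- function(pulse, path, header = NULL) {
  stopifnot(inherits(pulse, "ptx_pulse"))
  if (anyNA(pulse$rf) || anyNA(pulse$grad))
    stop("waveforms contain NaN; refusing to write")
  C <- nrow(pulse$rf); Tn <- ncol(pulse$rf)
  if (is.null(header))
    header <- pulse_header(C, Tn, pulse$raster)
  stopifnot(header$n_channels == C, header$n_samples == Tn)
  num <- function(x) sprintf("%.9g", x)
  lines <- c(
    "[pTXPulse]",
    paste0("n_channels = ", C),
    paste0("n_samples = ", Tn),
    paste0("raster = ", num(pulse$raster)),
    paste0("nominal_fa = ", num(header$nominal_fa)),
    paste0("comment = ", gsub("[\r\n]", " ", header$comment)),
    "",
    "[Gradient]",
    paste(num(pulse$grad[1L, ] * 1e3), num(pulse$grad[2L, ] * 1e3),
          num(pulse$grad[3L, ] * 1e3)),
    "")
  for (c in seq_len(C)) {
    lines <- c(lines, sprintf("[RF_ch%d]", c),
               paste(num(Mod(pulse$rf[c, ])),
                     num(Arg(pulse$rf[c, ]) * 180 / pi)),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

# Split ini-style lines into named sections of content lines.
.ini_sections <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  heads <- grep("^\\[.*\\]$", lines)
  if (length(heads) == 0L) stop("no sections found; not a pulse file")
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    nm <- sub("^\\[(.*)\\]$", "\\1", lines[heads[i]])
    body <- if (bounds[i] + 1L <= bounds[i + 1L] - 1L)
      lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)] else character(0L)
    out[[nm]] <- body
  }
  out
}

.parse_rows <- function(body, ncol_expected, what) {
  rows <- lapply(strsplit(body, "[[:space:]]+"), as.numeric)
  if (any(vapply(rows, length, integer(1L)) != ncol_expected) ||
      any(vapply(rows, anyNA, logical(1L))))
    stop("malformed numeric rows in section [", what, "]")
  do.call(rbind, rows)
}

#' Read a pulse from an ini-style text file
#'
#' Inverse of [write_pulse_ini()]. Structural problems (missing sections,
#' row counts disagreeing with the header) raise errors naming the section.
#'
#' @param path Path to the file.
#' @return List with `pulse` (a [pulse_waveform()]) and `header`
#'   (a [pulse_header()]).
#' @export
read_pulse_ini <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sec <- .ini_sections(readLines(path, warn = FALSE))
  if (!"pTXPulse" %in% names(sec)) stop("missing section [pTXPulse]")
  kv <- sec$pTXPulse
  pairs <- regmatches(kv, regexec("^([^=]+?)\\s*=\\s*(.*)$", kv))
  if (any(vapply(pairs, length, integer(1L)) != 3L))
    stop("malformed key = value line in [pTXPulse]")
  vals <- stats::setNames(vapply(pairs, `[`, character(1L), 3L),
                          vapply(pairs, `[`, character(1L), 2L))
  need <- c("n_channels", "n_samples", "raster")
  if (!all(need %in% names(vals)))
    stop("[pTXPulse] is missing: ",
         paste(setdiff(need, names(vals)), collapse = ", "))
  C <- as.integer(vals[["n_channels"]])
  Tn <- as.integer(vals[["n_samples"]])
  header <- pulse_header(C, Tn, as.double(vals[["raster"]]),
                         if ("nominal_fa" %in% names(vals))
                           as.double(vals[["nominal_fa"]]) else 0,
                         if ("comment" %in% names(vals))
                           vals[["comment"]] else "")
  if (!"Gradient" %in% names(sec)) stop("missing section [Gradient]")
  gm <- .parse_rows(sec$Gradient, 3L, "Gradient")
  if (nrow(gm) != Tn)
    stop("section [Gradient] has ", nrow(gm), " rows but the header says ",
         Tn, " samples")
  rf <- matrix(0i, C, Tn)
  for (c in seq_len(C)) {
    nm <- sprintf("RF_ch%d", c)
    if (!nm %in% names(sec)) stop("missing section [", nm, "]")
    rm <- .parse_rows(sec[[nm]], 2L, nm)
    if (nrow(rm) != Tn)
      stop("section [", nm, "] has ", nrow(rm), " rows but the header says ",
           Tn, " samples")
    rf[c, ] <- rm[, 1L] * exp(1i * rm[, 2L] * pi / 180)
  }
  list(pulse = pulse_waveform(rf, t(gm) * 1e-3, header$raster),
       header = header)
}
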