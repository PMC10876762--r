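# Minimal MATLAB v5 container I/O.
#
# Only the subset needed for field maps, masks and VOP stacks is supported:
# uncompressed files holding full numeric / complex / logical N-D arrays of
# the basic storage classes. Compressed elements, cells, structs, sparse and
# character arrays are rejected with a clear error.

.mi_sizes <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 2, `5` = 4, `6` = 4,
               `7` = 4, `9` = 8)
.mi_signed <- c(`1` = TRUE, `2` = FALSE, `3` = TRUE, `4` = FALSE, `5` = TRUE,
                `6` = FALSE, `7` = TRUE, `9` = TRUE)

.pad8 <- function(n) (8L - (n %% 8L)) %% 8L

#' Read a MATLAB v5 file
#'
#' Parses an uncompressed MATLAB v5 container and returns its numeric,
#' complex or logical arrays as a named list. Logical arrays are returned as
#' R `logical`, everything else as `double` or `complex`, with dimensions
#' preserved.
#'
#' @param path Path to a `.mat` file (MATLAB v5, uncompressed).
#' @return Named list of arrays.
#' @export
mat_read <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 128L)
    stop("not a MATLAB v5 file (shorter than the 128-byte header): ", path)
  endtag <- rawToChar(raw[127:128])
  endian <- if (endtag == "IM") "little" else if (endtag == "MI") "big" else
    stop("not a MATLAB v5 file (bad endian indicator): ", path)

  rd_int <- function(at, size, n = 1L, signed = TRUE) {
    readBin(raw[at:(at + size * n - 1L)], "integer", n = n, size = size,
            signed = signed, endian = endian)
  }
  rd_num <- function(at, mitype, n) {
    sz <- .mi_sizes[as.character(mitype)]
    if (is.na(sz)) stop("unsupported MAT data type code ", mitype)
    if (mitype %in% c(7L, 9L)) {
      readBin(raw[at:(at + sz * n - 1L)], "double", n = n, size = sz,
              endian = endian)
    } else {
      as.double(rd_int(at, sz, n, signed = .mi_signed[as.character(mitype)]))
    }
  }
  # returns list(type, nbytes, data_at, next_at) handling small-element format
  rd_tag <- function(at) {
    t1 <- rd_int(at, 4L)
    small <- bitwAnd(bitwShiftR(t1, 16L), 0xFFFFL)
    if (small != 0L) {
      list(type = bitwAnd(t1, 0xFFFFL), nbytes = small,
           data_at = at + 4L, next_at = at + 8L)
    } else {
      nb <- rd_int(at + 4L, 4L)
      list(type = t1, nbytes = nb, data_at = at + 8L,
           next_at = at + 8L + nb + .pad8(nb))
    }
  }

  out <- list()
  at <- 129L
  while (at + 7L <= length(raw)) {
    tag <- rd_tag(at)
    if (tag$type == 15L)
      stop("compressed MAT elements are not supported; save uncompressed")
    if (tag$type != 14L) { at <- tag$next_at; next }  # skip non-matrix
    p <- tag$data_at
    # array flags
    ft <- rd_tag(p)
    flags <- rd_int(ft$data_at, 4L, 2L)
    cls <- bitwAnd(flags[1L], 0xFFL)
    fbits <- bitwAnd(bitwShiftR(flags[1L], 8L), 0xFFL)
    is_complex <- bitwAnd(fbits, 0x08L) != 0L
    is_logical <- bitwAnd(fbits, 0x02L) != 0L
    p <- ft$next_at
    # dimensions
    dt <- rd_tag(p)
    dims <- rd_int(dt$data_at, 4L, dt$nbytes %/% 4L)
    p <- dt$next_at
    # name
    nt <- rd_tag(p)
    nm <- rawToChar(raw[nt$data_at:(nt$data_at + nt$nbytes - 1L)])
    p <- nt$next_at
    if (!(cls %in% 6:13)) {
      warning("skipping unsupported array class ", cls, " for variable '",
              nm, "'")
      at <- tag$next_at
      next
    }
    nel <- prod(dims)
    prt <- rd_tag(p)
    re <- rd_num(prt$data_at, prt$type, nel)
    p <- prt$next_at
    val <- if (is_complex) {
      pit <- rd_tag(p)
      complex(real = re, imaginary = rd_num(pit$data_at, pit$type, nel))
    } else if (is_logical) re != 0 else re
    dim(val) <- dims
    out[[nm]] <- val
    at <- tag$next_at
  }
  out
}

#' Write a MATLAB v5 file
#'
#' Writes a named list of numeric, complex or logical arrays as an
#' uncompressed MATLAB v5 container (double-precision storage throughout;
#' logical arrays carry the logical flag). Round-trips bitwise with
#' [mat_read()].
#'
#' @param vars Named list of arrays (numeric, complex or logical).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
mat_write <- function(vars, path) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars),
            all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("MATLAB 5.0 MAT-file, created by ptxpulse on %s",
                           format(Sys.time(), "%Y-%m-%d")))
  hdr <- c(hdr, raw(116L - length(hdr)))
  writeBin(hdr, con)
  writeBin(raw(8L), con)                                   # subsystem offset
  writeBin(c(0x00L, 0x01L, as.integer(charToRaw("I")),
             as.integer(charToRaw("M"))), con, size = 1L)  # version + endian

  w_tag <- function(type, nbytes) {
    writeBin(as.integer(c(type, nbytes)), con, size = 4L, endian = "little")
  }
  w_pad <- function(n) if (.pad8(n) > 0L) writeBin(raw(.pad8(n)), con)

  for (nm in names(vars)) {
    x <- vars[[nm]]
    if (is.null(dim(x))) dim(x) <- c(length(x), 1L)
    dims <- dim(x)
    is_c <- is.complex(x)
    is_l <- is.logical(x)
    nel <- length(x)
    nmraw <- charToRaw(nm)
    nbytes <- 16L +                                        # array flags
      8L + 4L * length(dims) + .pad8(4L * length(dims)) +  # dimensions
      8L + length(nmraw) + .pad8(length(nmraw)) +          # name
      (8L + 8L * nel) * (1L + is_c)                        # pr (+ pi)
    w_tag(14L, nbytes)
    flagword <- 6L + 256L * (8L * is_c + 2L * is_l)        # mxDOUBLE class
    w_tag(6L, 8L)
    writeBin(as.integer(c(flagword, 0L)), con, size = 4L, endian = "little")
    w_tag(5L, 4L * length(dims))
    writeBin(as.integer(dims), con, size = 4L, endian = "little")
    w_pad(4L * length(dims))
    w_tag(1L, length(nmraw))
    writeBin(nmraw, con)
    w_pad(length(nmraw))
    re <- as.vector(if (is_c) Re(x) else as.double(x))
    w_tag(9L, 8L * nel)
    writeBin(re, con, size = 8L, endian = "little")
    if (is_c) {
      w_tag(9L, 8L * nel)
      writeBin(as.vector(Im(x)), con, size = 8L, endian = "little")
    }
  }
  invisible(path)
}
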