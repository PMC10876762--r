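# Spatial data model: per-channel complex transmit sensitivities (B1+, nT/V),
# off-resonance (B0, Hz), binary region-of-interest mask, and a centered
# isotropic coordinate grid.

#' Construct a field-map set
#'
#' Bundles per-channel complex transmit sensitivity maps (B1+, in nT/V), an
#' off-resonance map (B0, in Hz), and a region-of-interest mask on a common
#' isotropic grid. Voxel coordinates (metres, origin at the grid centre) are
#' derived from the grid shape and resolution.
#'
#' @param b1 Complex array of shape `(n_channels, nx, ny, nz)`, in nT/V.
#' @param b0 Numeric array of shape `(nx, ny, nz)`, in Hz.
#' @param mask Logical (or 0/1) array of shape `(nx, ny, nz)`.
#' @param resolution Isotropic voxel edge length in metres.
#' @return Object of class `ptx_fieldmaps` with elements `b1`, `b0`, `mask`,
#'   `grid_shape`, `resolution`, `coords` (N-voxel-by-3 matrix, metres).
#' @export
fieldmap_set <- function(b1, b0, mask, resolution) {
  if (length(dim(b1)) != 4L)
    stop("b1 must be a 4-D array (n_channels, nx, ny, nz)")
  gs <- dim(b1)[-1L]
  if (is.null(dim(b0)) || !all(dim(b0) == gs))
    stop("shape mismatch: b0 has dims (", paste(dim(b0), collapse = ","),
         ") but b1 spatial dims are (", paste(gs, collapse = ","), ")")
  if (is.null(dim(mask)) || !all(dim(mask) == gs))
    stop("shape mismatch: mask has dims (", paste(dim(mask), collapse = ","),
         ") but b1 spatial dims are (", paste(gs, collapse = ","), ")")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive number (metres); ",
         "only isotropic grids are supported")
  mask <- array(as.logical(mask), gs)
  if (anyNA(mask)) stop("mask contains NA")
  if (!any(mask)) stop("mask has no true voxel")
  storage.mode(b0) <- "double"
  if (!is.complex(b1)) b1 <- b1 + 0i
  if (!all(is.finite(Re(b1))) || !all(is.finite(Im(b1))) ||
      !all(is.finite(b0)))
    stop("b1/b0 contain non-finite values")
  structure(list(b1 = b1, b0 = b0, mask = mask,
                 grid_shape = as.integer(gs),
                 resolution = as.double(resolution),
                 coords = build_coords(gs, resolution)),
            class = "ptx_fieldmaps")
}

#' @export
print.ptx_fieldmaps <- function(x, ...) {
  cat(sprintf(
    "<ptx_fieldmaps> %d channels, grid %s, %.4g mm isotropic, %d masked voxels\n",
    dim(x$b1)[1L], paste(x$grid_shape, collapse = "x"),
    x$resolution * 1e3, sum(x$mask)))
  invisible(x)
}

#' Centered voxel coordinate grid
#'
#' Coordinates of every voxel of an isotropic grid, origin at the grid centre.
#' Along an axis of length `N`, voxel `i` (1-based) sits at
#' `(i - 1 - (N - 1)/2) * resolution`, so odd axes have a voxel exactly at 0
#' and even axes straddle it symmetrically.
#'
#' @param grid_shape Integer vector of 3 positive axis lengths.
#' @param resolution Voxel edge length in metres.
#' @return Matrix with `prod(grid_shape)` rows and columns `x`, `y`, `z`
#'   (metres), rows in array (column-major) order.
#' @export
build_coords <- function(grid_shape, resolution) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  if (resolution <= 0) stop("resolution must be positive")
  ax <- lapply(grid_shape, function(n) (seq_len(n) - 1 - (n - 1) / 2) * resolution)
  g <- expand.grid(x = ax[[1L]], y = ax[[2L]], z = ax[[3L]],
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' Read a field-map container
#'
#' Reads B1+, B0 and mask arrays from a MATLAB v5 container. The on-disk
#' channel axis of the B1+ array is auto-detected: if the array's last three
#' dims match the B0 grid the channel axis is last, if its first dim is the
#' extra one it is first; when both layouts are consistent (all dims equal)
#' the first axis is taken as channels. Internally the layout is always
#' `(channel, x, y, z)`.
#'
#' @param path Path to the container file.
#' @param keys Named character vector mapping the roles `b1`, `b0`, `mask`
#'   (and optionally `resolution`) to in-file variable names.
#' @param resolution Fallback isotropic resolution in metres, used when the
#'   file carries no resolution variable.
#' @return A [fieldmap_set()].
#' @export
read_fieldmap_file <- function(path,
                               keys = c(b1 = "B1", b0 = "B0", mask = "mask",
                                        resolution = "resolution"),
                               resolution = 3.5e-3) {
  if (!file.exists(path)) stop("file not found: ", path)
  vars <- mat_read(path)
  for (role in c("b1", "b0", "mask")) {
    if (!keys[[role]] %in% names(vars))
      stop("field-map file is missing the '", keys[[role]],
           "' array (role: ", role, "): ", path)
  }
  b1 <- vars[[keys[["b1"]]]]
  b0 <- drop3(vars[[keys[["b0"]]]])
  mask <- drop3(vars[[keys[["mask"]]]])
  gs <- dim(b0)
  d <- dim(b1)
  if (length(d) == 3L) d <- dim(b1) <- c(1L, d)  # single channel stored 3-D
  if (length(d) != 4L)
    stop("b1 array must have 3 or 4 dimensions, got ", length(d))
  if (all(d[2:4] == gs)) {
    # channel-first already (ties also land here by convention)
  } else if (all(d[1:3] == gs)) {
    b1 <- aperm(b1, c(4L, 1L, 2L, 3L))
  } else {
    stop("shape mismatch: b1 dims (", paste(d, collapse = ","),
         ") do not contain the b0/mask grid (", paste(gs, collapse = ","), ")")
  }
  if (!is.na(keys["resolution"]) && keys[["resolution"]] %in% names(vars))
    resolution <- as.double(vars[[keys[["resolution"]]]])[1L]
  fieldmap_set(b1, b0, mask, resolution)
}

# Normalise a grid array to exactly 3 dims (drop extra singletons, pad with
# 1s), e.g. for slabs stored as (nx, ny) or grids stored as (nx, ny, nz, 1).
drop3 <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  dn <- d[d > 1L]
  if (length(dn) > 3L) stop("grid array has more than 3 non-singleton dims")
  if (length(dn) == 0L) dn <- 1L
  dim(x) <- c(dn, rep(1L, 3L - length(dn)))
  x
}

#' Write a field-map container
#'
#' Inverse of [read_fieldmap_file()]: stores B1+ (channel-first), B0, mask
#' and the resolution in a MATLAB v5 container.
#'
#' @param maps A [fieldmap_set()].
#' @param path Output path.
#' @param keys Named character vector as in [read_fieldmap_file()].
#' @return Invisibly, `path`.
#' @export
write_fieldmap_file <- function(maps, path,
                                keys = c(b1 = "B1", b0 = "B0", mask = "mask",
                                         resolution = "resolution")) {
  stopifnot(inherits(maps, "ptx_fieldmaps"))
  vars <- list(maps$b1, maps$b0, maps$mask, maps$resolution)
  names(vars) <- keys[c("b1", "b0", "mask", "resolution")]
  mat_write(vars, path)
}
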