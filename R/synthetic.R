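# Synthetic field maps, VOPs and reference pulses.
#
# The phantom emulates what the design code needs from measured head data:
# smooth, mutually distinct complex per-channel sensitivities from a ring of
# coil elements around an ellipsoidal "brain" mask, a smooth low-order B0
# field, and Hermitian PSD SAR matrices. It does not emulate electromagnetic
# tissue interactions.

#' Generate synthetic field maps
#'
#' Builds an ellipsoidal mask (semi-axes ~45% of the grid extent), per-channel
#' complex sensitivities from `n_channels` coil elements equally spaced on a
#' ring around the mask (Gaussian magnitude decay with distance from each
#' element, smoothly varying propagation-like phase anchored so that the
#' CP-mode combination is strictly positive over the mask), and a smooth
#' low-order polynomial B0 field scaled to peak magnitude `b0_range`.
#' Magnitudes are scaled so the CP-mode combination gives ~25 nT/V at the
#' grid centre (typical head-coil scale at ultra-high field).
#'
#' @param n_channels Number of transmit channels (>= 1).
#' @param grid_shape 3 integers, all >= 2.
#' @param resolution Isotropic voxel edge length in metres.
#' @param b0_range Peak off-resonance magnitude in Hz (>= 0).
#' @param seed Integer seed; outputs are deterministic given the seed.
#' @return A [fieldmap_set()].
#' @export
synth_fieldmaps <- function(n_channels = 16L, grid_shape = c(32L, 32L, 32L),
                            resolution = 7e-3, b0_range = 300, seed = 0L) {
  stopifnot(n_channels >= 1L, b0_range >= 0)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 2L))
    stop("degenerate grid: need at least 2 voxels per axis")
  with_seed(seed, {
    co <- build_coords(grid_shape, resolution)
    extent <- max(grid_shape) * resolution
    semi <- 0.45 * grid_shape * resolution
    u <- sweep(co, 2L, semi, "/")
    mask <- array(rowSums(u^2) <= 1, grid_shape)

    # coil ring in the xy-plane, just outside the mask
    ring_r <- 0.52 * extent
    az <- 2 * pi * (seq_len(n_channels) - 1L) / n_channels
    cp_target <- 25                      # nT/V, CP-mode |B1+| at grid centre
    sigma <- 0.22 * extent               # per-element decay: strong local dominance
    amp0 <- cp_target / n_channels / exp(-ring_r^2 / (2 * sigma^2))
    k_w <- 2.5 / extent                  # rad/m, propagation-like phase slope

    nvox <- nrow(co)
    b1 <- array(0i, c(n_channels, grid_shape))
    un <- co / (extent / 2)              # normalised coords for perturbations
    # elements alternate between two sub-rows (dual-row head array layout),
    # giving the channels distinct superior-inferior profiles
    z_off <- 0.15 * extent * rep_len(c(1, -1), n_channels)
    for (c in seq_len(n_channels)) {
      pc <- c(ring_r * cos(az[c]), ring_r * sin(az[c]), z_off[c])
      d <- sqrt(rowSums(sweep(co, 2L, pc, "-")^2))
      mag <- amp0 * exp(-d^2 / (2 * sigma^2)) *
        (1 + 0.1 * drop(un %*% stats::rnorm(3L, 0, 1)) / 3)
      mag <- pmax(mag, 0.02 * amp0)
      # per-channel smooth phase perturbation, kept below 0.3 rad so the
      # CP-mode sum provably never cancels inside the mask
      pert <- 0.3 * tanh(drop(un %*% stats::rnorm(3L, 0, 0.5)))
      ph <- -az[c] - k_w * (d - ring_r) + pert
      b1[c, , , ] <- mag * exp(1i * ph)
    }

    b0 <- array(0, grid_shape)
    if (b0_range > 0) {
      cf <- stats::rnorm(9L)
      poly <- cf[1L] + un %*% cf[2:4] +
        (un^2) %*% cf[5:7] + cf[8L] * un[, 1L] * un[, 2L] +
        cf[9L] * un[, 2L] * un[, 3L]
      b0 <- array(poly / max(abs(poly)) * b0_range, grid_shape)
    }
    fieldmap_set(b1, b0, mask, resolution)
  })
}

#' Construct a VOP set
#'
#' Validates and bundles a stack of Hermitian positive-semidefinite matrices
#' mapping channel voltages to local SAR (W/kg per V^2).
#'
#' @param matrices Complex array `(n_channels, n_channels, n_vops)`.
#' @param overestimation_factor Optional dimensionless metadata.
#' @param hermitian_tol Relative tolerance for the Hermitian symmetry check;
#'   larger asymmetry is Hermitianized with a warning.
#' @return Object of class `ptx_vops`.
#' @export
vop_set <- function(matrices, overestimation_factor = NULL,
                    hermitian_tol = 1e-9) {
  d <- dim(matrices)
  if (length(d) == 2L) {
    matrices <- array(matrices, c(d, 1L))
    d <- dim(matrices)
  }
  if (length(d) != 3L || d[1L] != d[2L])
    stop("VOP matrices must form an array (n_channels, n_channels, n_vops) ",
         "of square matrices")
  if (!is.complex(matrices)) matrices <- matrices + 0i
  herm <- (matrices + Conj(aperm(matrices, c(2L, 1L, 3L)))) / 2
  asym <- max(Mod(matrices - herm)) / max(Mod(matrices), .Machine$double.eps)
  if (asym > hermitian_tol)
    warning(sprintf("VOP matrices Hermitianized (relative asymmetry %.2e)",
                    asym))
  structure(list(matrices = herm,
                 overestimation_factor = overestimation_factor),
            class = "ptx_vops")
}

#' @export
print.ptx_vops <- function(x, ...) {
  d <- dim(x$matrices)
  cat(sprintf("<ptx_vops> %d VOPs of %dx%d channels\n", d[3L], d[1L], d[2L]))
  invisible(x)
}

#' Generate synthetic VOP matrices
#'
#' Each matrix is built as a rank-2 Gram matrix of random complex vectors,
#' rescaled so its largest eigenvalue is of order `scale`; the construction
#' is Hermitian positive-semidefinite by design.
#'
#' @param n_vops Number of matrices (>= 1).
#' @param n_channels Matrix dimension.
#' @param seed Integer seed.
#' @param scale Eigenvalue scale in W/kg per V^2.
#' @return A [vop_set()].
#' @export
synth_vops <- function(n_vops, n_channels, seed = 0L, scale = 1e-3) {
  stopifnot(n_vops >= 1L, n_channels >= 1L, scale > 0)
  with_seed(seed, {
    m <- array(0i, c(n_channels, n_channels, n_vops))
    for (v in seq_len(n_vops)) {
      B <- matrix(complex(real = stats::rnorm(2L * n_channels),
                          imaginary = stats::rnorm(2L * n_channels)),
                  n_channels, 2L)
      G <- B %*% Conj(t(B))
      lmax <- max(abs(eigen(G, symmetric = TRUE, only.values = TRUE)$values))
      m[, , v] <- G / lmax * scale * stats::runif(1L, 0.5, 1)
    }
    vop_set(m)
  })
}
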