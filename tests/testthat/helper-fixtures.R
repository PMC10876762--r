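# Shared fixtures, built lazily once per test run.

.fix <- new.env(parent = emptyenv())

fix_get <- function(name, builder) {
  if (!exists(name, envir = .fix, inherits = FALSE))
    assign(name, builder(), envir = .fix)
  get(name, envir = .fix, inherits = FALSE)
}

# small 2-channel maps for unit tests
small_maps <- function() fix_get("small_maps", function()
  synth_fieldmaps(n_channels = 2L, grid_shape = c(5L, 5L, 5L),
                  resolution = 0.04, b0_range = 200, seed = 3L))

# medium 8-channel maps for workflow tests
med_maps <- function() fix_get("med_maps", function()
  synth_fieldmaps(n_channels = 8L, grid_shape = c(12L, 12L, 12L),
                  resolution = 18e-3, b0_range = 300, seed = 2L))

# single-voxel map set with a real 1000 nT/V sensitivity
one_voxel_maps <- function(b0 = 0) {
  fieldmap_set(array(1000 + 0i, c(1L, 1L, 1L, 1L)),
               array(b0, c(1L, 1L, 1L)),
               array(TRUE, c(1L, 1L, 1L)), 0.01)
}

# the scaled-down design-study conditions (shared by the acceptance blocks)
study_maps <- function() fix_get("study_maps", function()
  synth_fieldmaps(n_channels = 16L, grid_shape = c(32L, 32L, 32L),
                  resolution = 7e-3, b0_range = 300, seed = 0L))

study_vops <- function() fix_get("study_vops", function()
  synth_vops(208L, 16L, seed = 1L, scale = 1e-3))

study_fit <- function() fix_get("study_fit", function()
  design_small_fa(study_maps(), fa = 10, duration = 520e-6, raster = 10e-6,
                  iters_sta = 500L, iters_bloch = 0L,
                  vops = study_vops(), seed = 0L))

# fully-converged tailored pulse (the standard single-subject recipe)
study_fit_tp <- function() fix_get("study_fit_tp", function()
  design_small_fa(study_maps(), fa = 10, duration = 520e-6, raster = 10e-6,
                  iters_sta = 2500L, iters_bloch = 0L,
                  vops = study_vops(), seed = 0L))

# random feasible pulse (smooth small gradients, moderate RF)
random_pulse <- function(n_channels, n_samples, seed = 1L, rf_sd = 10,
                         g_sd = 2e-4, raster = 1e-5) {
  with_seed(seed, {
    rf <- matrix(complex(real = rnorm(n_channels * n_samples, 0, rf_sd),
                         imaginary = rnorm(n_channels * n_samples, 0, rf_sd)),
                 n_channels, n_samples)
    g <- matrix(rnorm(3L * n_samples, 0, g_sd), 3L, n_samples)
    pulse_waveform(rf, g, raster)
  })
}

# central finite differences of f over a real vector
fd_grad <- function(f, x, h = NULL) {
  vapply(seq_along(x), function(i) {
    hi <- if (is.null(h)) 1e-4 * max(abs(x[i]), 1) else h
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + hi
    x2[i] <- x2[i] - hi
    (f(x1) - f(x2)) / (2 * hi)
  }, numeric(1L))
}

gamma_1h <- 267.522e6
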