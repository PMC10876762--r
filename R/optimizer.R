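# Joint RF + gradient waveform optimization by adaptive gradient descent
# through the differentiable forward models, plus the standard design
# recipes built on it.
#
# Free parameters are the real and imaginary part of every RF sample of
# every channel and every gradient sample of every axis, each normalised by
# its hardware limit (RF by u_limit, gradients by g_limit) so that a single
# learning rate is meaningful across both parameter groups.

#' Specify a pulse design problem
#'
#' @param maps A [fieldmap_set()] or a list of them (several subjects =
#'   universal-pulse design; the cost is the unweighted mean of the
#'   per-subject costs).
#' @param target_fa Target flip-angle pattern in degrees: scalar (uniform
#'   over the mask), full-grid array, or list of per-subject masked vectors.
#' @param duration Pulse duration in seconds (a multiple of `raster`).
#' @param raster Sample interval in seconds.
#' @param limits A [ptx_limits()].
#' @param model Forward model for the flip-angle term: `"sta"` or `"bloch"`.
#' @param optimize_rf,optimize_grad Which waveform groups are free; at least
#'   one must be `TRUE`.
#' @param initial_pulse A [pulse_waveform()] to start from, or `"random"`
#'   (complex Gaussian RF at 1 V scale, zero gradients).
#' @param vops Optional [vop_set()] enabling the SAR term.
#' @param relax A [relaxation_spec()] (Bloch model only).
#' @param zero_edge_grad Keep the first and last gradient samples frozen at
#'   zero during optimization (scanner requirement; the edge penalty alone
#'   cannot see equal-and-opposite non-zero edges). Default `FALSE` for the
#'   generic optimizer; the design recipes enable it.
#' @return Object of class `ptx_problem`.
#' @export
design_problem <- function(maps, target_fa, duration, raster,
                           limits = ptx_limits(), model = c("sta", "bloch"),
                           optimize_rf = TRUE, optimize_grad = TRUE,
                           initial_pulse = "random", vops = NULL,
                           relax = relaxation_spec(), zero_edge_grad = FALSE) {
  model <- match.arg(model)
  n <- duration / raster
  if (abs(n - round(n)) > 1e-9)
    stop("duration must be an integral multiple of the raster")
  if (!optimize_rf && !optimize_grad)
    stop("at least one of optimize_rf / optimize_grad must be TRUE")
  if (inherits(maps, "ptx_fieldmaps")) maps <- list(maps)
  structure(list(maps = maps, target_fa = target_fa,
                 duration = duration, raster = raster,
                 n_samples = as.integer(round(n)),
                 n_channels = dim(maps[[1L]]$b1)[1L],
                 limits = limits, model = model,
                 optimize_rf = optimize_rf, optimize_grad = optimize_grad,
                 initial_pulse = initial_pulse, vops = vops, relax = relax,
                 zero_edge_grad = isTRUE(zero_edge_grad)),
            class = "ptx_problem")
}

#' Optimizer configuration
#'
#' @param n_iterations Number of descent iterations.
#' @param learning_rate Step size on the limit-normalised parameters
#'   (default 4e-4).
#' @param restart_period The optimizer's internal momentum state is
#'   reinitialised after every this many iterations, restarting from the
#'   best-performing pulse seen so far (default 1000).
#' @param seed Integer seed (used for random initialisation).
#' @param beta1,beta2,eps AdamW moment/stabilisation constants.
#' @param weight_decay Decoupled weight-decay coefficient (default 0).
#' @return Object of class `ptx_optcfg`.
#' @export
optimizer_config <- function(n_iterations = 1000L, learning_rate = 4e-4,
                             restart_period = 1000L, seed = 0L,
                             beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                             weight_decay = 0) {
  stopifnot(learning_rate > 0, restart_period >= 1L, n_iterations >= 1L)
  structure(list(n_iterations = as.integer(n_iterations),
                 learning_rate = learning_rate,
                 restart_period = as.integer(restart_period),
                 seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
                 eps = eps, weight_decay = weight_decay),
            class = "ptx_optcfg")
}

.initial_design_pulse <- function(problem, seed) {
  ip <- problem$initial_pulse
  if (inherits(ip, "ptx_pulse")) {
    stopifnot(nrow(ip$rf) == problem$n_channels,
              ncol(ip$rf) == problem$n_samples)
    return(ip)
  }
  if (!identical(ip, "random"))
    stop("initial_pulse must be a ptx_pulse or \"random\"")
  with_seed(seed, {
    rf <- matrix(complex(real = stats::rnorm(problem$n_channels *
                                               problem$n_samples),
                         imaginary = stats::rnorm(problem$n_channels *
                                                    problem$n_samples)),
                 problem$n_channels, problem$n_samples)
    pulse_waveform(rf, matrix(0, 3L, problem$n_samples), problem$raster)
  })
}

#' Jointly optimize RF and gradient waveforms
#'
#' AdamW (decoupled-weight-decay adaptive moment) descent over the free
#' real-valued parameters, driven by analytic reverse-mode gradients of the
#' full design cost through the chosen forward model. The best-cost pulse
#' ever seen is tracked; at every `restart_period` boundary the momentum
#' state is reset and the parameters reload from that best pulse.
#'
#' @param problem A [design_problem()].
#' @param cfg An [optimizer_config()].
#' @return Object of class `ptx_fit`: `pulse` (best-cost
#'   [pulse_waveform()]), `history` (per-iteration data.frame of all cost
#'   terms), `best_cost`, `best_iter`, `n_params`.
#' @export
optimize_pulse <- function(problem, cfg = optimizer_config()) {
  stopifnot(inherits(problem, "ptx_problem"), inherits(cfg, "ptx_optcfg"))
  dctx <- .design_ctx(problem$maps, problem$target_fa)
  lim <- problem$limits
  p0 <- .initial_design_pulse(problem, cfg$seed)
  rf <- p0$rf
  g <- p0$grad
  C <- nrow(rf); Tn <- ncol(rf)
  n_params <- 2L * C * Tn * problem$optimize_rf +
    3L * Tn * problem$optimize_grad

  pack <- function(rf, g) {
    th <- numeric(0L)
    if (problem$optimize_rf)
      th <- c(as.vector(Re(rf)), as.vector(Im(rf))) / lim$u_limit
    if (problem$optimize_grad) th <- c(th, as.vector(g) / lim$g_limit)
    th
  }
  unpack <- function(th) {
    off <- 0L
    if (problem$optimize_rf) {
      nn <- C * Tn
      rf <<- matrix(complex(real = th[seq_len(nn)],
                            imaginary = th[nn + seq_len(nn)]),
                    C, Tn) * lim$u_limit
      off <- 2L * nn
    }
    if (problem$optimize_grad)
      g <<- matrix(th[off + seq_len(3L * Tn)], 3L, Tn) * lim$g_limit
  }
  grad_pack <- function(ev) {
    gv <- numeric(0L)
    if (problem$optimize_rf)
      gv <- c(as.vector(Re(ev$grad_rf)), as.vector(Im(ev$grad_rf))) *
        lim$u_limit
    if (problem$optimize_grad)
      gv <- c(gv, as.vector(ev$grad_g) * lim$g_limit)
    gv
  }

  if (problem$zero_edge_grad && problem$optimize_grad)
    g[, c(1L, Tn)] <- 0
  th <- pack(rf, g)
  frozen <- rep(FALSE, length(th))
  if (problem$zero_edge_grad && problem$optimize_grad) {
    off <- 2L * C * Tn * problem$optimize_rf
    frozen[off + c(seq_len(3L), 3L * (Tn - 1L) + seq_len(3L))] <- TRUE
  }
  m <- v <- numeric(length(th))
  tstep <- 0L
  best_cost <- Inf
  best_th <- th
  best_iter <- 0L
  hist <- vector("list", cfg$n_iterations)

  for (it in seq_len(cfg$n_iterations)) {
    ev <- .cost_eval(rf, g, problem$raster, dctx, lim, problem$vops,
                     problem$model, problem$relax)
    bd <- unlist(ev$breakdown)
    if (any(!is.finite(bd))) {
      bad <- names(bd)[!is.finite(bd)][1L]
      stop("non-finite cost at iteration ", it, ": term '", bad, "'")
    }
    hist[[it]] <- bd
    if (ev$total < best_cost) {
      best_cost <- ev$total
      best_th <- th
      best_iter <- it
    }
    gv <- grad_pack(ev)
    gv[frozen] <- 0
    tstep <- tstep + 1L
    m <- cfg$beta1 * m + (1 - cfg$beta1) * gv
    v <- cfg$beta2 * v + (1 - cfg$beta2) * gv^2
    mhat <- m / (1 - cfg$beta1^tstep)
    vhat <- v / (1 - cfg$beta2^tstep)
    th <- th - cfg$learning_rate *
      (mhat / (sqrt(vhat) + cfg$eps) + cfg$weight_decay * th)
    if (it %% cfg$restart_period == 0L && it < cfg$n_iterations) {
      th <- best_th
      m <- v <- numeric(length(th))
      tstep <- 0L
    }
    unpack(th)
  }
  unpack(best_th)
  history <- as.data.frame(do.call(rbind, hist))
  history$iter <- seq_len(nrow(history))
  structure(list(pulse = pulse_waveform(rf, g, problem$raster),
                 history = history, best_cost = best_cost,
                 best_iter = best_iter, n_params = n_params,
                 problem = problem),
            class = "ptx_fit")
}

#' @export
print.ptx_fit <- function(x, ...) {
  cat(sprintf(
    "<ptx_fit> %d iterations over %d parameters; best cost %.6g at iter %d\n",
    nrow(x$history), x$n_params, x$best_cost, x$best_iter))
  print(x$pulse)
  invisible(x)
}

# The scanner requires zero first/last gradient samples; the design recipes
# project the returned pulse exactly onto that constraint (the penalty term
# already drives the edges to ~1e-5 of the limit, so the change is inert).
.zero_edge_grad <- function(pulse) {
  pulse$grad[, c(1L, ncol(pulse$grad))] <- 0
  pulse
}

.mean_fa <- function(pulse, maps, model, relax = relaxation_spec()) {
  if (inherits(maps, "ptx_fieldmaps")) maps <- list(maps)
  mean(vapply(maps, function(m) {
    sim <- if (model == "sta") sta_simulate(pulse, m) else
      bloch_simulate(pulse, m, relax)
    mean(sim$fa)
  }, numeric(1L)))
}

#' Scale a pulse to a target mean flip angle
#'
#' Multiplies the RF by a real scalar so that the mean flip angle over the
#' masked voxels (averaged across subjects when several map sets are given)
#' equals `target_mean_fa`. Closed-form under the STA (linearity); bisection
#' to `tol` degrees under the Bloch model.
#'
#' @param pulse A [pulse_waveform()].
#' @param maps A [fieldmap_set()] or list of them.
#' @param target_mean_fa Target mean flip angle in degrees.
#' @param model `"sta"` or `"bloch"`.
#' @param tol Bisection tolerance in degrees (Bloch only).
#' @return The scaled [pulse_waveform()].
#' @export
scale_pulse_to_mean_fa <- function(pulse, maps, target_mean_fa,
                                   model = c("sta", "bloch"), tol = 1e-4) {
  model <- match.arg(model)
  if (target_mean_fa == 0) return(scale_pulse(pulse, 0))
  cur <- .mean_fa(pulse, maps, model)
  if (cur <= 0) stop("pulse excites zero mean flip angle; cannot scale")
  if (model == "sta") return(scale_pulse(pulse, target_mean_fa / cur))
  lo <- 0
  hi <- target_mean_fa / cur * 1.5
  while (.mean_fa(scale_pulse(pulse, hi), maps, "bloch") < target_mean_fa) {
    hi <- hi * 1.5
    if (hi > 1e6 / max(Mod(pulse$rf), 1e-12))
      stop("cannot reach the target mean flip angle by scaling")
  }
  repeat {
    mid <- (lo + hi) / 2
    fmid <- .mean_fa(scale_pulse(pulse, mid), maps, "bloch")
    if (abs(fmid - target_mean_fa) < tol) break
    if (fmid < target_mean_fa) lo <- mid else hi <- mid
    if (hi - lo < 1e-12 * max(1, hi)) break
  }
  scale_pulse(pulse, mid)
}

# Concatenate the masked contexts of several subjects into one.
.pooled_ctx <- function(maps) {
  if (inherits(maps, "ptx_fieldmaps")) maps <- list(maps)
  subj <- lapply(maps, .masked_ctx)
  list(B1 = do.call(rbind, lapply(subj, `[[`, "B1")),
       r = do.call(rbind, lapply(subj, `[[`, "r")),
       b0 = unlist(lapply(subj, `[[`, "b0")),
       n = sum(vapply(subj, `[[`, integer(1L), "n")))
}

.start_noise <- function(pulse, seed) {
  with_seed(seed + 1L, {
    sd0 <- 0.02 * mean(Mod(pulse$rf))
    pulse$rf <- pulse$rf +
      matrix(complex(real = stats::rnorm(length(pulse$rf), 0, sd0),
                     imaginary = stats::rnorm(length(pulse$rf), 0, sd0)),
             nrow(pulse$rf), ncol(pulse$rf))
    pulse
  })
}

# Coarse 3-kT-point warm start: random position search on subsampled voxels,
# then a ridge-regularized variable-exchange solve (smallest ridge on a fixed
# grid that keeps the weights within 80% of the voltage limit), assembled and
# zero-padded to the design duration. Falls back to the CP start when the
# kT geometry does not fit the requested raster/duration.
.kt_start <- function(maps, fa, duration, raster, limits, seed,
                      n_candidates = 200L) {
  sub_d <- 130e-6; gap_d <- 60e-6
  fits <- abs(sub_d / raster - round(sub_d / raster)) < 1e-9 &&
    abs(gap_d / raster - round(gap_d / raster)) < 1e-9 &&
    duration >= 3 * sub_d + 2 * gap_d - 1e-12
  if (!fits) return(.cp_start(maps, fa, duration, raster, seed))
  ctx <- .pooled_ctx(maps)
  spec <- .kt_search_ctx(ctx, fa * pi / 180, n_candidates, 14, seed, 20L,
                         600L, sub_d, gap_d, raster)
  A <- .kt_system_matrix(ctx, spec)
  sv <- svd(A)
  tgt <- rep(fa * pi / 180, ctx$n)
  ve <- function(lam) {
    filt <- sv$d / (sv$d^2 + lam^2)
    solve_reg <- function(y) sv$v %*% (filt * (Conj(t(sv$u)) %*% y))
    b <- solve_reg(tgt)
    for (i in 1:20) b <- solve_reg(tgt * exp(1i * Arg(A %*% b)))
    as.vector(b)
  }
  # bisect the ridge weight so the seed sits just under the voltage limit
  vcap <- 0.95 * limits$u_limit
  lo <- 1e-4 * sv$d[1L]; hi <- sv$d[1L]
  b <- ve(hi)
  if (max(Mod(ve(lo))) <= vcap) {
    b <- ve(lo)
  } else {
    for (i in 1:12) {
      mid <- sqrt(lo * hi)
      bm <- ve(mid)
      if (max(Mod(bm)) > vcap) lo <- mid else { hi <- mid; b <- bm }
    }
  }
  if (max(Mod(b)) > vcap) b <- b * (vcap / max(Mod(b)))
  C <- ncol(ctx$B1)
  kt <- assemble_kt_pulse(spec, matrix(b, C, 3L), limits)
  pad <- as.integer(round(duration / raster)) - ncol(kt$rf)
  pulse <- pulse_waveform(cbind(kt$rf, matrix(0i, C, pad)),
                          cbind(kt$grad, matrix(0, 3L, pad)), raster)
  .start_noise(pulse, seed)
}

# CP-mode warm start at the target operating point, with a small seeded
# perturbation to break the symmetry of the start.
.cp_start <- function(maps, fa, duration, raster, seed) {
  if (inherits(maps, "ptx_fieldmaps")) maps <- list(maps)
  C <- dim(maps[[1L]]$b1)[1L]
  cp <- cp_mode_pulse(C, 1, duration, raster)
  cp <- scale_pulse_to_mean_fa(cp, maps, fa, model = "sta")
  .start_noise(cp, seed)
}

#' Design a small-flip-angle pTx pulse
#'
#' Standard non-selective design recipe: joint RF + gradient optimization on
#' the small-tip-angle model for `iters_sta` iterations, optionally followed
#' by `iters_bloch` refinement iterations on the Bloch model starting from
#' the STA result (a tailored pulse uses the STA phase only, i.e.
#' `iters_bloch = 0`). By default the descent is seeded from a coarse
#' voltage-bounded 3-kT-point solution (`init = "kt"`), the standard warm
#' start for free pTx design; `init = "cp"` starts from the CP-mode pulse
#' scaled to the target mean flip angle, `init = "random"` from a 1 V
#' complex-Gaussian cold start.
#'
#' @param maps A [fieldmap_set()] or list of them (universal pulse).
#' @param fa Target flip angle in degrees, uniform over the mask.
#' @param duration,raster Pulse timing in seconds.
#' @param iters_sta,iters_bloch Iteration counts for the two phases.
#' @param limits A [ptx_limits()].
#' @param vops Optional [vop_set()] enabling the SAR constraint.
#' @param seed Integer seed.
#' @param learning_rate,restart_period Optimizer settings, see
#'   [optimizer_config()].
#' @param init `"kt"` (default), `"cp"`, or `"random"`.
#' @param bloch_refine_grad Whether the Bloch phase also updates the
#'   gradient waveforms (default) or refines the RF only.
#' @return A [ptx_fit]-style list as from [optimize_pulse()]; `$pulse` holds
#'   the designed pulse, `$history` the concatenated iteration log.
#' @export
design_small_fa <- function(maps, fa = 10, duration = 520e-6, raster = 10e-6,
                            iters_sta = 7500L, iters_bloch = 2500L,
                            limits = ptx_limits(), vops = NULL, seed = 0L,
                            learning_rate = 4e-4, restart_period = 1000L,
                            init = c("kt", "cp", "random"),
                            bloch_refine_grad = TRUE) {
  init <- match.arg(init)
  start <- switch(init,
                  kt = .kt_start(maps, fa, duration, raster, limits, seed),
                  cp = .cp_start(maps, fa, duration, raster, seed),
                  random = "random")
  prob <- design_problem(maps, fa, duration, raster, limits = limits,
                         model = "sta", initial_pulse = start, vops = vops,
                         zero_edge_grad = TRUE)
  fit <- optimize_pulse(prob, optimizer_config(
    n_iterations = iters_sta, learning_rate = learning_rate,
    restart_period = restart_period, seed = seed))
  fit$history$phase <- "sta"
  if (iters_bloch > 0L) {
    prob2 <- design_problem(maps, fa, duration, raster, limits = limits,
                            model = "bloch", optimize_rf = TRUE,
                            optimize_grad = bloch_refine_grad,
                            initial_pulse = fit$pulse, vops = vops,
                            zero_edge_grad = TRUE)
    fit2 <- optimize_pulse(prob2, optimizer_config(
      n_iterations = iters_bloch, learning_rate = learning_rate,
      restart_period = restart_period, seed = seed + 1L))
    fit2$history$phase <- "bloch"
    fit2$history$iter <- fit2$history$iter + nrow(fit$history)
    fit2$history <- rbind(fit$history, fit2$history)
    fit2$pulse <- .zero_edge_grad(fit2$pulse)
    return(fit2)
  }
  fit$pulse <- .zero_edge_grad(fit$pulse)
  fit
}

#' Design a large-flip-angle pulse
#'
#' Designs at `fa/10` on the small-tip-angle model under a voltage limit
#' scaled down by 10, scales the RF up by 10, then refines with Bloch-model
#' iterations optimizing the RF waveforms only (gradients stay fixed).
#' No SAR constraint is applied by default (preparation-pulse use case).
#'
#' @inheritParams design_small_fa
#' @param iters_sta STA iterations at the scaled-down flip angle.
#' @param iters_bloch Bloch refinement iterations (RF only).
#' @return A [ptx_fit]-style list; `$pulse` is the final pulse.
#' @export
design_large_fa <- function(maps, fa = 90, duration = 520e-6, raster = 10e-6,
                            iters_sta = 3500L, iters_bloch = 1000L,
                            limits = ptx_limits(), seed = 0L,
                            learning_rate = 4e-4, restart_period = 1000L) {
  lim_small <- limits
  lim_small$u_limit <- limits$u_limit / 10
  fit1 <- design_small_fa(maps, fa / 10, duration, raster,
                          iters_sta = iters_sta, iters_bloch = 0L,
                          limits = lim_small, vops = NULL, seed = seed,
                          learning_rate = learning_rate,
                          restart_period = restart_period)
  scaled <- scale_pulse(fit1$pulse, 10)
  prob <- design_problem(maps, fa, duration, raster, limits = limits,
                         model = "bloch", optimize_rf = TRUE,
                         optimize_grad = FALSE, initial_pulse = scaled)
  fit2 <- optimize_pulse(prob, optimizer_config(
    n_iterations = iters_bloch, learning_rate = learning_rate,
    restart_period = restart_period, seed = seed + 1L))
  fit2$pulse <- .zero_edge_grad(fit2$pulse)
  fit2$sta_fit <- fit1
  fit2$scaled_start <- scaled
  fit2
}

#' Simulate transmit-chain imperfections
#'
#' Applies a per-channel multiplicative magnitude factor drawn from
#' `N(1, mag_sd)` and a phase offset drawn from `N(0, phase_sd)` degrees to
#' the RF, simulates with the Bloch model, and records the NRMSE against the
#' target flip angle; repeated `n_reps` times.
#'
#' @param pulse A [pulse_waveform()].
#' @param maps A [fieldmap_set()].
#' @param target_fa Target flip angle in degrees.
#' @param n_reps Number of repetitions (default 10).
#' @param mag_sd Amplitude standard deviation as a fraction (default 0.05).
#' @param phase_sd Phase standard deviation in degrees (default 5).
#' @param seed Integer seed.
#' @return Numeric vector of NRMSE values (percent), one per repetition,
#'   with the unperturbed NRMSE as attribute `"baseline"`.
#' @export
robustness_eval <- function(pulse, maps, target_fa, n_reps = 10L,
                            mag_sd = 0.05, phase_sd = 5, seed = 0L) {
  stopifnot(inherits(pulse, "ptx_pulse"))
  C <- nrow(pulse$rf)
  base <- nrmse(bloch_simulate(pulse, maps)$fa, target_fa)
  res <- with_seed(seed, {
    vapply(seq_len(n_reps), function(rep) {
      fac <- stats::rnorm(C, 1, mag_sd)
      ph <- stats::rnorm(C, 0, phase_sd) * pi / 180
      p2 <- pulse
      p2$rf <- p2$rf * (fac * exp(1i * ph))
      nrmse(bloch_simulate(p2, maps)$fa, target_fa)
    }, numeric(1L))
  })
  attr(res, "baseline") <- base
  res
}
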