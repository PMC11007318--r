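#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style difference of two gamma densities (response peak 6 s,
#' undershoot peak 16 s, peak-to-undershoot ratio 6), evaluated on a fine
#' time grid. The kernel is normalized so that its convolution with a 4 s
#' unit boxcar peaks at exactly 1, which puts voxel gains on the scale of
#' the peak occupation response.
#'
#' @param dt Microtime resolution (s). Default 0.1.
#' @param duration Kernel length (s). Default 32.
#' @param peak,undershoot,ratio Shape parameters of the two gamma densities.
#' @return Numeric kernel sampled at `dt`.
#' @export
hrf_double_gamma <- function(dt = 0.1, duration = 32, peak = 6,
                             undershoot = 16, ratio = 6) {
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  box <- rep(1, round(4 / dt))
  ref <- stats::convolve(c(h, numeric(length(box))), rev(c(box, numeric(length(h)))),
                         type = "open")
  h / max(ref)
}

## FFT convolution of each column of `x` with kernel `h`, causal, same length
convolve_columns <- function(x, h) {
  n <- nrow(x); m <- length(h)
  L <- stats::nextn(n + m - 1L, 2)
  H <- stats::fft(c(h, numeric(L - m)))
  X <- stats::mvfft(rbind(x, matrix(0, L - n, ncol(x))))
  out <- Re(stats::mvfft(X * H, inverse = TRUE)) / L
  out[seq_len(n), , drop = FALSE]
}

#' Noise model for synthetic BOLD runs
#'
#' @param white_sd Marginal standard deviation of the AR(1)+white noise
#'   process (signal units; gains are scaled so that a typical single-trial
#'   response peak is about 0.5, giving single-trial CNR near 0.5 at the
#'   default).
#' @param ar1 AR(1) coefficient phi, `|phi| < 1`.
#' @param drift_order Order of the per-voxel polynomial drift. Default 2.
#' @param drift_sd Standard deviation of the random drift amplitude per
#'   polynomial basis function.
#' @param motion_amplitude Scale of motion-correlated nuisance loadings.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(white_sd = 1, ar1 = 0.3, drift_order = 2,
                        drift_sd = 0.5, motion_amplitude = 0.1) {
  if (abs(ar1) >= 1) stop("ar1 coefficient must satisfy |phi| < 1")
  structure(list(white_sd = white_sd, ar1 = ar1, drift_order = drift_order,
                 drift_sd = drift_sd, motion_amplitude = motion_amplitude),
            class = "noise_model")
}

## coordinates of n voxels on a compact 3-D grid, x the long axis
voxel_grid <- function(n) {
  nx <- ceiling(n^(1/2)); ny <- ceiling(sqrt(n / nx)); nz <- ceiling(n / (nx * ny))
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  as.matrix(g[seq_len(n), , drop = FALSE])
}

draw_maps <- function(n, span, sigma, centers_at, layout,
                      gain_range, s_range) {
  center <- if (identical(centers_at, "locations")) {
    sample(layout$location_positions, n, replace = TRUE) + rnorm(n, 0, sigma)
  } else {
    runif(n, span[1], span[2])
  }
  list(center = center, width = rep(sigma, n),
       gain = runif(n, gain_range[1], gain_range[2]),
       s = runif(n, s_range[1], s_range[2]))
}

#' Sample a voxel population with cue-dependent location tuning
#'
#' Each voxel carries, per cue (and optionally per environment), a Gaussian
#' tuning curve over track position (center, width), a response gain, and a
#' repetition-suppression strength `s` in \[0, 1\]. Sharp tuning (small
#' sigma) yields identity-like suppression — overlap vanishes already at the
#' 4 m spacing — whereas broad tuning yields distance-graded suppression.
#'
#' @param n_voxels Number of voxels.
#' @param sigma_landmark,sigma_self_motion Tuning widths (m) per cue.
#'   Defaults 0.5 (sharp) and 6 (broad).
#' @param cue_specific If `TRUE` (default) the landmark and self-motion
#'   parameter maps are drawn independently; if `FALSE` they are shared.
#' @param env_specific Named logical per cue: draw independent maps per
#'   environment? Defaults mirror environment-independent landmark coding
#'   and environment-specific self-motion coding.
#' @param layout A [track_layout()]; tuning centers are drawn over the span
#'   from the arrow anchor to the tree anchor.
#' @param center_mode Per-cue center draw: `"uniform"` over the track span or
#'   `"locations"` (at a random test location plus `N(0, sigma)` jitter).
#'   Sharp populations default to `"locations"`, reflecting units tuned to
#'   the discrete familiar locations; broad populations tile the span.
#' @param gain_range,s_range Uniform ranges for gain and suppression
#'   strength.
#' @param seed Integer seed.
#' @return An object of class `voxel_population` with `maps[[cue]][[env]]`
#'   parameter lists, voxel grid `coords`, and `portion_label` (1-10, by
#'   position along the long axis).
#' @export
sample_population <- function(n_voxels, sigma_landmark = 0.5,
                              sigma_self_motion = 6, cue_specific = TRUE,
                              env_specific = c(landmark = FALSE,
                                               self_motion = TRUE),
                              layout = track_layout(),
                              center_mode = NULL,
                              gain_range = c(0.5, 1.5), s_range = c(0.25, 0.75),
                              seed = NULL) {
  stopifnot(n_voxels >= 1, sigma_landmark > 0, sigma_self_motion > 0)
  if (!is.null(seed)) set.seed(seed)
  span <- c(layout$arrow_position, layout$tree_position)
  sig <- c(landmark = sigma_landmark, self_motion = sigma_self_motion)
  if (is.null(center_mode))
    center_mode <- ifelse(sig < layout$spacing / 2, "locations", "uniform")
  center_mode <- setNames(rep_len(center_mode, 2), names(sig))
  envs <- c("city", "nature")
  env_specific <- setNames(rep_len(env_specific, 2), names(sig))

  maps <- list()
  base <- NULL
  for (cue in names(sig)) {
    if (cue_specific || is.null(base)) {
      m1 <- draw_maps(n_voxels, span, sig[[cue]], center_mode[[cue]], layout,
                      gain_range, s_range)
      if (!cue_specific) base <- m1
    } else {
      m1 <- base
      m1$width <- rep(sig[[cue]], n_voxels)
    }
    percue <- list()
    for (env in envs) {
      percue[[env]] <- if (env == envs[1] || !env_specific[[cue]]) m1 else {
        m2 <- draw_maps(n_voxels, span, sig[[cue]], center_mode[[cue]], layout,
                        gain_range, s_range)
        if (!cue_specific) { m2$center <- m1$center; m2$gain <- m1$gain; m2$s <- m1$s }
        m2
      }
    }
    maps[[cue]] <- percue
  }
  coords <- voxel_grid(n_voxels)
  portion <- balanced_partition(order(coords[, "x"], seq_len(n_voxels)), 10L,
                                n_voxels)
  structure(list(n_voxels = n_voxels, maps = maps, coords = coords,
                 layout = layout, cue_specific = cue_specific,
                 env_specific = env_specific,
                 portion_label = portion),
            class = "voxel_population")
}

## labels voxels 1..n_portions by rank order; sizes differ by <= 1
balanced_partition <- function(ord, n_portions, n) {
  sizes <- rep(n %/% n_portions, n_portions)
  extra <- n %% n_portions
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  lab <- integer(n)
  lab[ord] <- rep(seq_len(n_portions), sizes)
  lab
}

#' @export
print.voxel_population <- function(x, ...) {
  cat(sprintf("<voxel_population> %d voxels | cue_specific=%s | widths %s m\n",
              x$n_voxels, x$cue_specific,
              paste(vapply(x$maps, function(m) m$city$width[1], numeric(1)),
                    collapse = "/")))
  invisible(x)
}

tuning_value <- function(map, x) exp(-(x - map$center)^2 / (2 * map$width^2))

#' Neural response amplitude under tuning-overlap repetition suppression
#'
#' The amplitude of a voxel's occupation response is
#' `gain * T(current) * (1 - s * Omega(current, prev))`, where `T` is the
#' Gaussian tuning value and `Omega` is the tuning overlap between the two
#' locations, `exp(-(dx)^2 / (2 sigma^2))` (self-overlap 1). Trials without
#' an adaptable predecessor (`prev = NULL`) carry no suppression term.
#'
#' @param pop A `voxel_population`.
#' @param cue `"landmark"` or `"self_motion"`.
#' @param current_loc_m Current location (m); scalar.
#' @param prev_loc_m Preceding location (m) or `NULL`.
#' @param environment `"city"` or `"nature"`.
#' @param voxel Optional voxel index; default all voxels.
#' @return Amplitude vector over the selected voxels.
#' @export
neural_amplitude <- function(pop, cue, current_loc_m, prev_loc_m = NULL,
                             environment = "city", voxel = NULL) {
  map <- pop$maps[[cue]][[environment]]
  if (!is.null(voxel))
    map <- lapply(map, `[`, voxel)
  amp <- map$gain * tuning_value(map, current_loc_m)
  if (!is.null(prev_loc_m) && !is.na(prev_loc_m)) {
    omega <- exp(-(current_loc_m - prev_loc_m)^2 / (2 * map$width^2))
    amp <- amp * (1 - map$s * omega)
  }
  amp
}

frame_count <- function(run, tr = 2, pad = 20)
  as.integer(ceiling((run$total_duration + pad) / tr))

#' Synthesize a BOLD run from a realized design and voxel population
#'
#' For each voxel, a neural boxcar of height [neural_amplitude()] during
#' each occupation phase plus a cue-constant movement-phase response
#' (`movement_amplitude * gain`) is convolved with the canonical
#' double-gamma HRF at 0.1 s microtime, sampled at the repetition time, and
#' summed with polynomial drift, AR(1)+white noise, and motion-correlated
#' nuisance signal.
#'
#' @param run A `run_spec`.
#' @param pop A `voxel_population`.
#' @param noise A [noise_model()]; pass `noise_model(white_sd = 0,
#'   drift_sd = 0, motion_amplitude = 0)` for a noiseless run.
#' @param seed Integer seed.
#' @param tr Repetition time (s). Default 2.
#' @param pad Seconds appended after the last event to capture the
#'   hemodynamic tail.
#' @param movement_amplitude Cue-constant movement response per unit gain.
#' @param correct_boost Fractional amplitude boost of the occupation
#'   response on correct trials (requires simulated behavior when nonzero).
#' @param dt Microtime resolution (s).
#' @return An object of class `bold_run`: `signal` (voxels x frames),
#'   `tr`, `frame_times`, `motion` (frames x 6), and run metadata.
#' @export
synthesize_bold <- function(run, pop, noise = noise_model(), seed = NULL,
                            tr = 2, pad = 20, movement_amplitude = 0.5,
                            correct_boost = 0, dt = 0.1) {
  stopifnot(inherits(run, "run_spec"), inherits(pop, "voxel_population"))
  if (!isTRUE(all.equal(run$layout$location_positions,
                        pop$layout$location_positions)))
    stop("run and population disagree on the track layout")
  if (!is.null(seed)) set.seed(seed)
  ev <- run$events
  V <- pop$n_voxels
  n_frames <- frame_count(run, tr, pad)
  n_bins <- ceiling((run$total_duration + pad) / dt)
  cue <- run$cue; env <- run$environment
  map <- pop$maps[[cue]][[env]]

  ## one microtime boxcar per location trial (the neural signal factors as
  ## trial-column x per-voxel-amplitude, so only the trial columns need
  ## convolving)
  loc_rows <- which(!ev$is_null)
  amps <- matrix(0, V, length(loc_rows))
  cols <- matrix(0, n_bins, length(loc_rows) + 1L)
  prev_by_row <- rep(NA_real_, nrow(ev))
  prev_loc <- NA_real_
  for (i in seq_len(nrow(ev))) {
    if (ev$is_null[i]) { prev_loc <- NA_real_; next }
    prev_by_row[i] <- prev_loc
    prev_loc <- run$layout$location_positions[ev$type_index[i]]
  }
  for (k in seq_along(loc_rows)) {
    i <- loc_rows[k]
    cur <- run$layout$location_positions[ev$type_index[i]]
    amp <- neural_amplitude(pop, cue, cur,
                            prev_loc_m = if (is.na(prev_by_row[i])) NULL else
                              prev_by_row[i],
                            environment = env)
    if (correct_boost != 0) {
      if (is.na(ev$correct[i])) stop("correct_boost requires simulated behavior")
      if (isTRUE(ev$correct[i])) amp <- amp * (1 + correct_boost)
    }
    amps[, k] <- amp
    cols[, k] <- microtime_boxcar(ev$occupation_onset[i],
                                  ev$occupation_duration[i], 1, n_bins, dt)
  }
  cols[, length(loc_rows) + 1L] <-
    microtime_boxcar(ev$movement_onset[loc_rows],
                     ev$movement_duration[loc_rows],
                     rep(1, length(loc_rows)), n_bins, dt)
  conv <- convolve_columns(cols, cached_hrf(dt)$h)
  idx <- pmin(n_bins, floor((seq_len(n_frames) - 1L) * tr / dt) + 1L)
  conv <- conv[idx, , drop = FALSE]                # frames x (trials + 1)
  signal <- amps %*% t(conv[, seq_along(loc_rows), drop = FALSE]) +
    outer(movement_amplitude * map$gain, conv[, length(loc_rows) + 1L])

  ## nuisance: motion random walks with per-voxel loadings
  motion <- apply(matrix(rnorm(n_frames * 6, sd = 0.05), n_frames, 6), 2, cumsum)
  if (noise$motion_amplitude > 0) {
    loadings <- matrix(rnorm(V * 6, sd = noise$motion_amplitude), V, 6)
    signal <- signal + loadings %*% t(motion)
  }
  if (noise$drift_sd > 0 && noise$drift_order > 0) {
    tt <- seq(-1, 1, length.out = n_frames)
    basis <- sapply(seq_len(noise$drift_order), function(p) tt^p)
    coefs <- matrix(rnorm(V * noise$drift_order, sd = noise$drift_sd),
                    V, noise$drift_order)
    signal <- signal + coefs %*% t(basis)
  }
  if (noise$white_sd > 0) {
    innov_sd <- noise$white_sd * sqrt(1 - noise$ar1^2)
    eps <- matrix(rnorm(V * n_frames, sd = innov_sd), n_frames, V)
    if (noise$ar1 != 0)
      eps <- apply(eps, 2, function(e)
        as.numeric(stats::filter(e, noise$ar1, method = "recursive")))
    signal <- signal + t(eps)
  }
  structure(list(signal = signal, tr = tr,
                 frame_times = (seq_len(n_frames) - 1L) * tr,
                 motion = motion, cue = cue, environment = env,
                 session_day = run$session_day, run_index = run$run_index),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %d voxels x %d frames (TR %.1f s) | cue %s | env %s | day %d\n",
              nrow(x$signal), ncol(x$signal), x$tr, x$cue, x$environment,
              x$session_day))
  invisible(x)
}

#' Per-cue behavioral accuracy parameters
#'
#' Accuracy is a linear function of the location index (1 = nearest the
#' arrows, 4 = nearest the tree): landmark accuracy rises toward the tree
#' (the landmark anchor), self-motion accuracy falls away from the arrows
#' (the path-integration anchor), so the two cues cross over.
#'
#' @param landmark_intercept,landmark_slope Accuracy at location 1 and
#'   change per index step for the landmark cue.
#' @param self_motion_intercept,self_motion_slope Same for self-motion.
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(landmark_intercept = 0.90, landmark_slope = 0.025,
                            self_motion_intercept = 0.90,
                            self_motion_slope = -0.09) {
  structure(list(landmark = c(intercept = landmark_intercept,
                              slope = landmark_slope),
                 self_motion = c(intercept = self_motion_intercept,
                                 slope = self_motion_slope)),
            class = "behavior_params")
}

#' Simulate behavioral responses for a run
#'
#' Correctness is Bernoulli with a cue-specific monotone accuracy over the
#' location index (chance floor 0.25 enforced by clipping with a warning);
#' wrong responses are drawn from the other locations with weights halving
#' per index step.
#'
#' @param run A `run_spec`.
#' @param params A [behavior_params()].
#' @param seed Integer seed.
#' @return The run with `response` and `correct` filled for location events.
#' @export
simulate_behavior <- function(run, params = behavior_params(), seed = NULL) {
  stopifnot(inherits(run, "run_spec"))
  if (!is.null(seed)) set.seed(seed)
  p <- params[[run$cue]]
  ev <- run$events
  n_loc <- length(run$layout$location_positions)
  probs <- p["intercept"] + p["slope"] * (seq_len(n_loc) - 1)
  if (any(probs > 1 | probs < 0.25)) {
    warning("accuracy probability clipped to [0.25, 1]")
    probs <- pmin(1, pmax(0.25, probs))
  }
  for (i in seq_len(nrow(ev))) {
    if (ev$is_null[i]) next
    idx <- ev$type_index[i]
    ok <- runif(1) < probs[idx]
    if (ok) resp <- idx else {
      others <- setdiff(seq_len(n_loc), idx)
      w <- 2^(-abs(others - idx))
      resp <- sample(others, 1, prob = w / sum(w))
    }
    ev$response[i] <- paste0("loc", resp)
    ev$correct[i] <- ok
  }
  run$events <- ev
  run
}

#' Write a BOLD run as a 4-D NIfTI volume with an ROI mask
#'
#' Voxels are placed on the population's 3-D grid; a sidecar JSON records
#' the repetition time and run metadata. Requires the RNifti package.
#'
#' @param bold A `bold_run`.
#' @param pop The `voxel_population` that generated it (for the grid).
#' @param path Output NIfTI path (e.g. `"run.nii"`); the mask is written
#'   alongside as `<path>_mask.nii` and the sidecar as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(bold, pop, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("write_bold_nifti requires the RNifti package")
  dims <- apply(pop$coords, 2, max)
  arr <- array(0, c(dims, ncol(bold$signal)))
  mask <- array(0L, dims)
  for (v in seq_len(pop$n_voxels)) {
    arr[pop$coords[v, 1], pop$coords[v, 2], pop$coords[v, 3], ] <- bold$signal[v, ]
    mask[pop$coords[v, 1], pop$coords[v, 2], pop$coords[v, 3]] <- 1L
  }
  RNifti::writeNifti(arr, path)
  RNifti::writeNifti(mask, paste0(sub("\\.nii(\\.gz)?$", "", path), "_mask.nii"))
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(list(RepetitionTime = bold$tr, cue = bold$cue,
                              environment = bold$environment,
                              day = bold$session_day),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
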