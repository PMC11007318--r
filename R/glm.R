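#' Parametric adaptation modulators
#'
#' Computes the trial-wise covariate that scales the adaptable occupation
#' regressor. A trial is *adaptable* when it is an effective location trial
#' whose immediately preceding presented event is a location event
#' (including the duplicated initial event); trials preceded by a null
#' event, and the duplicated first trial itself, are routed to the
#' non-adaptable regressor.
#'
#' Kinds:
#' * `distance` — inter-location distance `|x_t - x_(t-1)|` in meters
#'   (values in \{0, 4, 8, 12\} for the default layout);
#' * `identity` — 0 if the preceding test location was the same, 1 if
#'   different;
#' * `path_length` — absolute difference in traveled path length
#'   `|L_t - L_(t-1)|` (e.g. 10 m then 8 m gives 2 m);
#' * `response` — the location metric computed from reported rather than
#'   true locations (`response_metric` chooses distance or identity);
#' * `temporal_distance` — seconds between successive occupation onsets.
#'
#' @param run A realized `run_spec` (with responses for `kind = "response"`).
#' @param kind Modulator kind (see above).
#' @param response_metric Metric used for `kind = "response"`.
#' @return An object of class `modulator_spec`: `kind`, `values` (one per
#'   adaptable trial), `rows` (row indices of adaptable events in the run),
#'   and `adaptable` (logical over presented events).
#' @export
build_modulator <- function(run, kind = c("distance", "identity",
                                          "path_length", "response",
                                          "temporal_distance"),
                            response_metric = c("distance", "identity")) {
  kind <- match.arg(kind)
  response_metric <- match.arg(response_metric)
  stopifnot(inherits(run, "run_spec"))
  ev <- run$events
  n <- nrow(ev)
  eff <- effective_trials(run)
  prev_ok <- c(FALSE, !ev$is_null[-n])       # predecessor is a location event
  adaptable <- eff & prev_ok
  rows <- which(adaptable)
  xpos <- run$layout$location_positions
  if (kind == "response" && all(is.na(ev$response[rows])))
    stop("response modulator requires simulated or recorded responses")
  val <- vapply(rows, function(i) {
    j <- i - 1L
    switch(kind,
      distance = abs(xpos[ev$type_index[i]] - xpos[ev$type_index[j]]),
      identity = as.numeric(ev$type_index[i] != ev$type_index[j]),
      path_length = abs(ev$path_length[i] - ev$path_length[j]),
      temporal_distance = ev$occupation_onset[i] - ev$occupation_onset[j],
      response = {
        ri <- as.integer(sub("loc", "", ev$response[i]))
        rj <- as.integer(sub("loc", "", ev$response[j]))
        if (is.na(ri) || is.na(rj))
          stop("missing response on an adaptable trial")
        if (response_metric == "distance") abs(xpos[ri] - xpos[rj])
        else as.numeric(ri != rj)
      })
  }, numeric(1))
  structure(list(kind = kind, values = val, rows = rows,
                 adaptable = adaptable), class = "modulator_spec")
}

hrf_cache <- new.env(parent = emptyenv())

cached_hrf <- function(dt) {
  key <- format(dt)
  if (is.null(hrf_cache[[key]])) {
    h <- hrf_double_gamma(dt)
    hrf_cache[[key]] <- list(h = h, hd = c(diff(h), 0) / dt)
  }
  hrf_cache[[key]]
}

microtime_boxcar <- function(onsets, durations, heights, n_bins, dt) {
  x <- numeric(n_bins)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1L
    b <- min(n_bins, floor((onsets[i] + durations[i]) / dt))
    if (b >= a) x[a:b] <- x[a:b] + heights[i]
  }
  x
}

## convolve a named list of microtime regressors, sample at frames,
## optionally append temporal derivatives
convolved_block <- function(cols, n_bins, n_frames, tr, dt, derivatives) {
  k <- cached_hrf(dt)
  M <- do.call(cbind, cols)
  conv <- convolve_columns(M, k$h)
  idx <- pmin(n_bins, floor((seq_len(n_frames) - 1L) * tr / dt) + 1L)
  out <- conv[idx, , drop = FALSE]
  colnames(out) <- names(cols)
  if (derivatives) {
    dconv <- convolve_columns(M, k$hd)[idx, , drop = FALSE]
    colnames(dconv) <- paste0(names(cols), "_deriv")
    out <- cbind(out, dconv)
  }
  out
}

movement_spec <- function(ev, movement_model) {
  loc <- which(!ev$is_null)
  switch(movement_model,
    none = NULL,
    phase2_only = list(onsets = ev$movement_onset[loc],
                       durations = ev$movement_duration[loc]),
    phases123 = list(onsets = ev$onset[loc],
                     durations = ev$occupation_onset[loc] - ev$onset[loc]))
}

design_nuisance <- function(n_frames, motion, drift_order, suffix = "") {
  tt <- seq(-1, 1, length.out = n_frames)
  drift <- sapply(0:drift_order, function(p) tt^p)
  colnames(drift) <- paste0("drift", 0:drift_order, suffix)
  if (!is.null(motion)) {
    motion <- scale(motion, scale = FALSE)
    colnames(motion) <- paste0("motion", 1:6, suffix)
    cbind(drift, motion)
  } else drift
}

finalize_design <- function(X, frame_times, groups, run_id) {
  if (any(colMeans(abs(X)) < 1e-12)) {
    bad <- colnames(X)[colMeans(abs(X)) < 1e-12]
    stop("all-zero modeled column(s): ", paste(bad, collapse = ", "))
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[seq.int(q$rank + 1L, ncol(X))]]
    stop("rank-deficient design; dependent columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, frame_times = frame_times, groups = groups,
                 run_id = run_id), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d frames x %d columns\n", nrow(x$X), ncol(x$X)))
  tab <- table(x$groups)
  cat(" ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

single_run_design <- function(run, modulators, movement_model, motion,
                              tr, pad, dt, derivatives, drift_order,
                              occupation_bins = NULL,
                              nonadapt_by_location = FALSE) {
  ev <- run$events
  n_frames <- frame_count(run, tr, pad)
  n_bins <- ceiling((run$total_duration + pad) / dt)
  eff <- effective_trials(run)
  prev_ok <- c(FALSE, !ev$is_null[-nrow(ev)])
  adaptable <- eff & prev_ok
  nonadapt <- !ev$is_null & !adaptable   # duplicated or post-null trials

  cols <- list()
  occ <- function(rows, heights = rep(1, length(rows)))
    microtime_boxcar(ev$occupation_onset[rows], ev$occupation_duration[rows],
                     heights, n_bins, dt)
  if (is.null(occupation_bins)) {
    cols$occ_adapt <- occ(which(adaptable))
  } else {
    bins <- factor(occupation_bins)
    if (length(bins) != sum(adaptable))
      stop("occupation_bins must align with the run's adaptable trials")
    for (lv in levels(bins))
      cols[[paste0("occ_", lv)]] <- occ(which(adaptable)[bins == lv])
  }
  if (nonadapt_by_location) {
    for (ix in sort(unique(ev$type_index[nonadapt])))
      cols[[paste0("occ_nonadapt_loc", ix)]] <- occ(which(nonadapt & ev$type_index == ix))
  } else {
    cols$occ_nonadapt <- occ(which(nonadapt))
  }
  mv <- movement_spec(ev, movement_model)
  if (!is.null(mv))
    cols$movement <- microtime_boxcar(mv$onsets, mv$durations,
                                      rep(1, length(mv$onsets)), n_bins, dt)
  n_event <- length(cols)
  for (m in modulators) {
    stopifnot(inherits(m, "modulator_spec"))
    if (!identical(m$rows, which(adaptable)))
      stop("modulator is misaligned with the run's adaptable trials")
    cols[[paste0("mod_", m$kind)]] <- occ(m$rows, m$values - mean(m$values))
  }
  X <- convolved_block(cols, n_bins, n_frames, tr, dt, derivatives = FALSE)
  groups <- c(rep("event", n_event),
              rep("modulator", length(modulators)))
  if (derivatives) {
    Xd <- convolved_block(cols[seq_len(n_event)], n_bins, n_frames, tr, dt,
                          derivatives = TRUE)[, -seq_len(n_event), drop = FALSE]
    X <- cbind(X, Xd)
    groups <- c(groups, rep("derivative", n_event))
  }
  nuis <- design_nuisance(n_frames, motion, drift_order)
  X <- cbind(X, nuis)
  groups <- c(groups, rep("nuisance", ncol(nuis)))
  names(groups) <- colnames(X)
  list(X = X, groups = groups,
       frame_times = (seq_len(n_frames) - 1L) * tr)
}

#' Build a first-level design matrix
#'
#' Event boxcars (occupation 4 s; movement per its realized duration)
#' convolved with the canonical HRF, a temporal derivative per event
#' regressor, parametric modulators attached to the adaptable-occupation
#' regressor with mean-centering only (no serial orthogonalization), a
#' separate regressor for occupation periods not suitable for adaptation
#' (preceded by a null event or the duplicated first trial), and per-run
#' nuisance columns (polynomial drift and, when supplied, 6 motion series).
#'
#' @param runs A `run_spec` or list of them; with several runs the event and
#'   modulator columns are stacked and nuisance columns are per run.
#' @param modulators List of [build_modulator()] results (per run, a list of
#'   lists when several runs are given).
#' @param movement_model `"phase2_only"` (movement phase only, the default),
#'   `"phases123"` (entire navigation stage), or `"none"`.
#' @param motion Optional frames x 6 motion matrix (list of them for
#'   several runs), e.g. `bold$motion`.
#' @param tr,pad,dt Sampling grid; must match the synthesized runs.
#' @param derivatives Append temporal derivatives per event regressor?
#' @param drift_order Per-run polynomial drift order.
#' @return A `design_matrix`: matrix `X`, `frame_times`, column `groups`
#'   (event / modulator / derivative / nuisance), and `run_id`.
#' @export
build_design <- function(runs, modulators = list(),
                         movement_model = c("phase2_only", "phases123", "none"),
                         motion = NULL, tr = 2, pad = 20, dt = 0.1,
                         derivatives = TRUE, drift_order = 2) {
  movement_model <- match.arg(movement_model)
  if (inherits(runs, "run_spec")) {
    d <- single_run_design(runs, modulators, movement_model, motion,
                           tr, pad, dt, derivatives, drift_order)
    return(finalize_design(d$X, d$frame_times, d$groups,
                           rep(1L, nrow(d$X))))
  }
  stopifnot(is.list(runs), length(runs) >= 1)
  if (length(modulators) && !is.list(modulators[[1]]))
    stop("with several runs, pass one modulator list per run")
  parts <- lapply(seq_along(runs), function(i)
    single_run_design(runs[[i]],
                      if (length(modulators)) modulators[[i]] else list(),
                      movement_model,
                      if (is.null(motion)) NULL else motion[[i]],
                      tr, pad, dt, derivatives, drift_order))
  shared <- names(parts[[1]]$groups)[parts[[1]]$groups != "nuisance"]
  blocks <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    nuis <- p$X[, p$groups == "nuisance", drop = FALSE]
    colnames(nuis) <- paste0(colnames(nuis), "_run", i)
    list(shared = p$X[, shared, drop = FALSE], nuis = nuis,
         ft = p$frame_times, n = nrow(p$X))
  })
  Xs <- do.call(rbind, lapply(blocks, `[[`, "shared"))
  nuis_all <- matrix(0, nrow(Xs), sum(vapply(blocks, function(b) ncol(b$nuis), 0L)))
  cn <- character(0); r0 <- 0L; c0 <- 0L
  for (b in blocks) {
    nuis_all[r0 + seq_len(b$n), c0 + seq_len(ncol(b$nuis))] <- b$nuis
    cn <- c(cn, colnames(b$nuis)); r0 <- r0 + b$n; c0 <- c0 + ncol(b$nuis)
  }
  colnames(nuis_all) <- cn
  X <- cbind(Xs, nuis_all)
  groups <- c(parts[[1]]$groups[shared], setNames(rep("nuisance", ncol(nuis_all)), cn))
  run_id <- rep(seq_along(blocks), vapply(blocks, `[[`, 0L, "n"))
  finalize_design(X, unlist(lapply(blocks, `[[`, "ft")), groups, run_id)
}

#' Design with separate occupation regressors per condition bin
#'
#' Splits the adaptable-occupation regressor into one event regressor per
#' level of `bins` — per inter-location distance (0/4/8/12 m) for
#' visualization of the adaptation profile, or per (previous, current)
#' location pair for trial-wise neural-distance estimation. No parametric
#' modulators are included.
#'
#' @param run A `run_spec`.
#' @param bins `"distance"`, `"pair"`, or a factor over the run's adaptable
#'   trials.
#' @param nonadapt_by_location Split the non-adaptable occupation regressor
#'   by current location (needed for exact recovery of injected per-pair
#'   amplitudes on noiseless data)?
#' @inheritParams build_design
#' @return A `design_matrix`.
#' @export
build_binned_design <- function(run, bins = "distance",
                                nonadapt_by_location = FALSE,
                                movement_model = c("phase2_only", "phases123",
                                                   "none"),
                                motion = NULL, tr = 2, pad = 20, dt = 0.1,
                                derivatives = TRUE, drift_order = 2) {
  movement_model <- match.arg(movement_model)
  ev <- run$events
  eff <- effective_trials(run)
  adaptable <- eff & c(FALSE, !ev$is_null[-nrow(ev)])
  rows <- which(adaptable)
  if (is.character(bins) && length(bins) == 1) {
    bins <- switch(bins,
      distance = {
        m <- build_modulator(run, "distance")
        factor(paste0("d", m$values),
               levels = paste0("d", sort(unique(m$values))))
      },
      pair = factor(paste0("p", ev$type_index[rows - 1L], ev$type_index[rows])),
      stop("unknown bin specification"))
  }
  d <- single_run_design(run, list(), movement_model, motion, tr, pad, dt,
                         derivatives, drift_order, occupation_bins = bins,
                         nonadapt_by_location = nonadapt_by_location)
  finalize_design(d$X, d$frame_times, d$groups, rep(1L, nrow(d$X)))
}

#' Fit a GLM by ordinary least squares
#'
#' @param bold A `bold_run` or list of them (concatenated fits); time
#'   dimensions must match the design.
#' @param design A `design_matrix`.
#' @return An object of class `glm_fit`: `betas` (columns x voxels),
#'   `residuals` (frames x voxels), `dof`, the design column correlation
#'   matrix `colcor`, and run metadata.
#' @export
fit_glm <- function(bold, design) {
  stopifnot(inherits(design, "design_matrix"))
  bolds <- if (inherits(bold, "bold_run")) list(bold) else bold
  Y <- do.call(rbind, lapply(bolds, function(b) t(b$signal)))
  if (anyNA(Y)) stop("NaN/NA values in the BOLD data")
  if (nrow(Y) != nrow(design$X))
    stop("time dimension mismatch: ", nrow(Y), " frames vs ",
         nrow(design$X), " design rows")
  q <- qr(design$X)
  betas <- qr.coef(q, Y)
  resid <- qr.resid(q, Y)
  sdx <- apply(design$X, 2, sd)
  cc <- suppressWarnings(cor(design$X[, sdx > 0, drop = FALSE]))
  meta <- data.frame(cue = vapply(bolds, `[[`, "", "cue"),
                     environment = vapply(bolds, `[[`, "", "environment"),
                     session_day = vapply(bolds, function(b) as.integer(b$session_day), 0L),
                     run_index = vapply(bolds, function(b) as.integer(b$run_index), 0L))
  structure(list(betas = betas, residuals = resid,
                 dof = nrow(Y) - q$rank, colcor = cc,
                 columns = colnames(design$X), groups = design$groups,
                 meta = meta), class = "glm_fit")
}

#' @export
coef.glm_fit <- function(object, ...) object$betas

#' @export
residuals.glm_fit <- function(object, ...) object$residuals

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d regressors x %d voxels | dof %d | runs: %s\n",
              nrow(x$betas), ncol(x$betas), x$dof,
              paste(x$meta$cue, collapse = ", ")))
  invisible(x)
}

#' Extract the signed voxel-wise adaptation vector from a fit
#'
#' @param fit A `glm_fit` from a single-run design.
#' @param modulator_name Design column holding the adaptation modulator
#'   (e.g. `"mod_distance"`).
#' @param mask Optional logical or integer voxel selector.
#' @return Numeric vector of signed modulator betas with `cue`, `day`,
#'   `environment` and `run` attributes.
#' @export
adaptation_vector <- function(fit, modulator_name = "mod_distance",
                              mask = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  if (!modulator_name %in% rownames(fit$betas))
    stop("no such modulator column: ", modulator_name)
  v <- fit$betas[modulator_name, ]
  if (!is.null(mask)) {
    if (is.logical(mask) && !any(mask)) stop("empty voxel mask")
    v <- v[mask]
    if (!length(v)) stop("empty voxel mask")
  }
  attr(v, "cue") <- fit$meta$cue[1]
  attr(v, "day") <- fit$meta$session_day[1]
  attr(v, "environment") <- fit$meta$environment[1]
  attr(v, "run") <- fit$meta$run_index[1]
  v
}

#' Concatenated design for the successful-navigation contrast
#'
#' Builds the success-contrast model: exactly four occupation event
#' regressors (cue type x correctness, collapsed across the four test
#' locations) with temporal derivatives, a movement regressor per run, one
#' mean regressor per run, and per-run motion/drift nuisance columns. Runs
#' are concatenated because single runs may contain no incorrect trials.
#'
#' @param runs List of `run_spec` with simulated or recorded behavior.
#' @param motion Optional list of frames x 6 motion matrices.
#' @inheritParams build_design
#' @return A `design_matrix` whose `groups` tag the four cue x correctness
#'   occupation regressors as `"event_cc"`.
#' @export
success_design <- function(runs, motion = NULL,
                           movement_model = c("phase2_only", "phases123"),
                           tr = 2, pad = 20, dt = 0.1, derivatives = TRUE,
                           drift_order = 2) {
  movement_model <- match.arg(movement_model)
  stopifnot(is.list(runs), length(runs) >= 1)
  cells <- expand.grid(correct = c(TRUE, FALSE),
                       cue = c("landmark", "self_motion"),
                       stringsAsFactors = FALSE)
  counts <- setNames(numeric(4), paste0(cells$cue, "_",
                                        ifelse(cells$correct, "correct", "incorrect")))
  blocks <- list()
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    ev <- run$events
    if (all(is.na(ev$correct[!ev$is_null])))
      stop("success_design requires behavioral responses in every run")
    n_frames <- frame_count(run, tr, pad)
    n_bins <- ceiling((run$total_duration + pad) / dt)
    eff <- effective_trials(run) & !is.na(ev$correct)
    cols <- list()
    for (j in seq_len(nrow(cells))) {
      nm <- names(counts)[j]
      rows <- which(eff & ev$correct == cells$correct[j])
      if (run$cue != cells$cue[j]) rows <- integer(0)
      counts[nm] <- counts[nm] + length(rows)
      cols[[nm]] <- microtime_boxcar(ev$occupation_onset[rows],
                                     ev$occupation_duration[rows],
                                     rep(1, length(rows)), n_bins, dt)
    }
    mv <- movement_spec(ev, movement_model)
    cols$movement <- microtime_boxcar(mv$onsets, mv$durations,
                                      rep(1, length(mv$onsets)), n_bins, dt)
    X <- convolved_block(cols, n_bins, n_frames, tr, dt, derivatives)
    nuis <- design_nuisance(n_frames, if (is.null(motion)) NULL else motion[[i]],
                            drift_order, suffix = paste0("_run", i))
    shared_names <- c(names(counts),
                      if (derivatives) paste0(names(counts), "_deriv"))
    blocks[[i]] <- list(shared = X[, shared_names, drop = FALSE],
                        other = cbind(X[, setdiff(colnames(X), shared_names),
                                        drop = FALSE], nuis),
                        n = n_frames,
                        ft = (seq_len(n_frames) - 1L) * tr)
  }
  empty <- names(counts)[counts == 0]
  if (length(empty))
    stop("empty cue x correctness cell(s): ", paste(empty, collapse = ", "),
         "; drop this participant from the success-contrast analysis")
  shared <- do.call(rbind, lapply(blocks, `[[`, "shared"))
  nother <- vapply(blocks, function(b) ncol(b$other), 0L)
  other <- matrix(0, nrow(shared), sum(nother))
  cn <- character(0); r0 <- 0L; c0 <- 0L
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    nm <- colnames(b$other)
    nm[!grepl("_run", nm)] <- paste0(nm[!grepl("_run", nm)], "_run", i)
    other[r0 + seq_len(b$n), c0 + seq_len(ncol(b$other))] <- b$other
    cn <- c(cn, nm); r0 <- r0 + b$n; c0 <- c0 + ncol(b$other)
  }
  colnames(other) <- cn
  X <- cbind(shared, other)
  shared_groups <- setNames(c(rep("event_cc", 4),
                              rep("derivative", ncol(shared) - 4L)),
                            colnames(shared))
  groups <- c(shared_groups,
              setNames(ifelse(grepl("movement", cn) & !grepl("deriv", cn),
                              "event",
                              ifelse(grepl("deriv", cn), "derivative",
                                     "nuisance")), cn))
  finalize_design(X, unlist(lapply(blocks, `[[`, "ft")), groups,
                  rep(seq_along(blocks), vapply(blocks, `[[`, 0L, "n")))
}
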