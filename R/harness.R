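#' Study configuration
#'
#' Bundles every tunable of the simulated study. The defaults mirror the
#' study conditions: 20 participants, 2 scanning sessions of 8 runs (2 per
#' cue x environment combination in 2 blocks), 26 presented events per run
#' (25-event carry-over sequence plus the duplicated initial event), sharp
#' landmark tuning (0.5 m) versus broad self-motion tuning (6 m),
#' cue-specific suppression maps, and a reduced voxel grid of 200 ROI
#' voxels for desk-scale computation.
#'
#' @param n_participants,n_sessions,n_blocks_per_session Cohort structure.
#' @param n_voxels ROI voxels per participant.
#' @param sigma_landmark,sigma_self_motion Tuning widths (m).
#' @param cue_specific,env_specific Map-sharing flags, see
#'   [sample_population()].
#' @param gain_range,s_range Voxel gain and suppression-strength ranges.
#' @param noise A [noise_model()].
#' @param movement_amplitude Cue-constant movement response per unit gain.
#' @param movement_model Movement regressor variant for the GLMs.
#' @param modulator_by_cue Named character: which adaptation modulator is
#'   used per cue (identity for landmarks, distance for self-motion, as
#'   dictated by the sharp/broad tuning formats).
#' @param behavior A [behavior_params()].
#' @param layout A [track_layout()].
#' @param tr,pad Sampling grid (s).
#' @param master_seed Master seed from which all per-participant/run seeds
#'   are derived by counter-based splitting.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_participants = 20, n_sessions = 2,
                         n_blocks_per_session = 2, n_voxels = 200,
                         sigma_landmark = 0.5, sigma_self_motion = 6,
                         cue_specific = TRUE,
                         env_specific = c(landmark = FALSE, self_motion = TRUE),
                         gain_range = c(0.5, 1.5), s_range = c(0.25, 0.75),
                         noise = noise_model(), movement_amplitude = 0.5,
                         movement_model = "phase2_only",
                         modulator_by_cue = c(landmark = "identity",
                                              self_motion = "distance"),
                         behavior = behavior_params(), layout = track_layout(),
                         tr = 2, pad = 20, master_seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_participants >= 1, cfg$n_voxels >= 1)
  class(cfg) <- "study_config"
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(paste0("<study_config> %d participants | %d sessions x %d runs | ",
                     "%d voxels | sigma %s/%s m | cue_specific=%s | seed %d\n"),
              x$n_participants, x$n_sessions, 4 * x$n_blocks_per_session,
              x$n_voxels, x$sigma_landmark, x$sigma_self_motion,
              x$cue_specific, x$master_seed))
  invisible(x)
}

#' Serialize / restore a study configuration
#'
#' @param config A `study_config`.
#' @param path JSON file path.
#' @return `read_config` returns a `study_config` equal to the one written.
#' @export
write_config <- function(config, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("config serialization requires the jsonlite package")
  plain <- lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$noise <- do.call(noise_model, as.list(raw$noise))
  raw$behavior <- structure(lapply(raw$behavior, function(v)
    setNames(as.numeric(v), c("intercept", "slope"))),
    class = "behavior_params")
  raw$layout <- do.call(track_layout, raw$layout[c("location_positions",
                                                  "arrow_position",
                                                  "tree_position")])
  raw$env_specific <- unlist(raw$env_specific)
  raw$modulator_by_cue <- unlist(raw$modulator_by_cue)
  do.call(study_config, raw[setdiff(names(raw), "spacing")])
}

#' Derive a child seed by counter-based splitting
#'
#' Deterministic 32-bit mixing of the master seed with an index path, so
#' that every participant/run/stage draws from an independent, reproducible
#' stream.
#'
#' @param master Integer master seed.
#' @param ... Integer indices (participant, run, stage, ...).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, ...) {
  s <- as.double(master) %% 2147483647
  for (x in c(...)) s <- (s * 69621 + as.double(x) * 7919 + 1) %% 2147483647
  as.integer(s + 1)
}

#' Simulate one participant's design, behavior and voxel population
#'
#' Builds the session plan, realizes every run (sequence, duplicate
#' prepending, timing, behavior) and samples the voxel population. BOLD
#' data are synthesized on demand by [participant_bold()] so cohorts stay
#' memory-light.
#'
#' @param config A [study_config()].
#' @param participant Participant index (seeds the participant stream).
#' @return A list of class `participant`: `runs`, `pop`, `plan`, `id`.
#' @export
simulate_participant <- function(config, participant = 1L) {
  plan <- plan_sessions(config$n_sessions, config$n_blocks_per_session,
                        seed = child_seed(config$master_seed, participant, 0))
  runs <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    s <- generate_debruijn(5, seed = child_seed(config$master_seed,
                                                participant, i, 1))
    s <- prepend_duplicate(s)
    run <- realize_timing(s, config$layout, cue = plan$cue[i],
                          environment = plan$environment[i],
                          session_day = plan$session_day[i],
                          run_index = plan$run_index[i],
                          seed = child_seed(config$master_seed,
                                            participant, i, 2))
    runs[[i]] <- simulate_behavior(run, config$behavior,
                                   seed = child_seed(config$master_seed,
                                                     participant, i, 3))
  }
  pop <- sample_population(config$n_voxels, config$sigma_landmark,
                           config$sigma_self_motion, config$cue_specific,
                           config$env_specific, config$layout,
                           gain_range = config$gain_range,
                           s_range = config$s_range,
                           seed = child_seed(config$master_seed,
                                             participant, 0, 4))
  structure(list(runs = runs, pop = pop, plan = plan, id = participant,
                 config = config), class = "participant")
}

#' Synthesize the BOLD run for one of a participant's runs
#'
#' @param part A [simulate_participant()] result.
#' @param run_idx Run index within the participant.
#' @param correct_boost Optional correct-trial amplitude boost.
#' @return A `bold_run`.
#' @export
participant_bold <- function(part, run_idx, correct_boost = 0) {
  cfg <- part$config
  synthesize_bold(part$runs[[run_idx]], part$pop, cfg$noise,
                  seed = child_seed(cfg$master_seed, part$id, run_idx, 5),
                  tr = cfg$tr, pad = cfg$pad,
                  movement_amplitude = cfg$movement_amplitude,
                  correct_boost = correct_boost)
}

roi_mean_bold <- function(bold) {
  bold$signal <- matrix(colMeans(bold$signal), nrow = 1)
  bold
}

#' First-level adaptation analysis of one participant
#'
#' For every run: synthesizes the BOLD data, fits the single-modulator GLM
#' of that run's cue (identity for landmarks, distance for self-motion by
#' default), the joint distance+identity GLM, and a (previous, current)
#' pair-binned GLM on the ROI-mean signal for neural-distance estimation.
#'
#' @param part A [simulate_participant()] result.
#' @param joint Fit the joint distance+identity model?
#' @param cells Fit the pair-binned ROI-mean model?
#' @param keep_residuals Accumulate ROI residuals (for segmentation)?
#' @return A list of class `participant_fit`: `vectors`
#'   (an [adaptation_vectors()] set), `roi` (per-run mean adaptation
#'   betas), `joint` (per-run unique contributions), `cells` (trial-cell
#'   activations), `residuals`, `behavior` (per-trial accuracy table).
#' @export
analyze_participant <- function(part, joint = TRUE, cells = TRUE,
                                keep_residuals = FALSE) {
  cfg <- part$config
  vectors <- list(); roi <- list(); jn <- list(); cl <- list(); res <- list()
  behav <- list()
  for (i in seq_along(part$runs)) {
    run <- part$runs[[i]]
    bold <- participant_bold(part, i)
    kind <- cfg$modulator_by_cue[[run$cue]]
    mod <- build_modulator(run, kind)
    des <- build_design(run, modulators = list(mod),
                        movement_model = cfg$movement_model,
                        motion = bold$motion, tr = cfg$tr, pad = cfg$pad)
    fit <- fit_glm(bold, des)
    v <- adaptation_vector(fit, paste0("mod_", kind))
    vectors[[i]] <- v
    roi[[i]] <- data.frame(run = i, cue = run$cue, day = run$session_day,
                           environment = run$environment,
                           block = (run$run_index - 1L) %/% 4L + 1L,
                           beta = mean(v), stringsAsFactors = FALSE)
    if (keep_residuals) res[[i]] <- residuals(fit)
    if (joint) {
      modj <- list(build_modulator(run, "distance"),
                   build_modulator(run, "identity"))
      desj <- build_design(run, modulators = modj,
                           movement_model = cfg$movement_model,
                           motion = bold$motion, tr = cfg$tr, pad = cfg$pad)
      fj <- fit_glm(bold, desj)
      jn[[i]] <- data.frame(run = i, cue = run$cue,
                            distance = mean(fj$betas["mod_distance", ]),
                            identity = mean(fj$betas["mod_identity", ]),
                            stringsAsFactors = FALSE)
    }
    if (cells) {
      desc <- build_binned_design(run, "pair", nonadapt_by_location = TRUE,
                                  movement_model = cfg$movement_model,
                                  motion = bold$motion, tr = cfg$tr,
                                  pad = cfg$pad)
      fc <- fit_glm(roi_mean_bold(bold), desc)
      nm <- grep("^occ_p[0-9][0-9]$", rownames(fc$betas), value = TRUE)
      cl[[i]] <- data.frame(run = i, cue = run$cue,
                            prev = as.integer(substr(nm, 6, 6)),
                            current = as.integer(substr(nm, 7, 7)),
                            beta = fc$betas[nm, 1], stringsAsFactors = FALSE)
    }
    ev <- run$events
    eff <- effective_trials(run)
    behav[[i]] <- data.frame(cue = run$cue, day = run$session_day,
                             environment = run$environment,
                             location = ev$type_index[eff],
                             correct = as.numeric(ev$correct[eff]),
                             stringsAsFactors = FALSE)
  }
  av <- adaptation_vectors(vectors)
  structure(list(vectors = av, roi = do.call(rbind, roi),
                 joint = if (joint) do.call(rbind, jn),
                 cells = if (cells) do.call(rbind, cl),
                 residuals = if (keep_residuals) do.call(rbind, res),
                 behavior = do.call(rbind, behav), id = part$id,
                 portions = part$pop$portion_label),
            class = "participant_fit")
}

#' Run the full simulated study
#'
#' Simulates the cohort and executes the complete analysis path: behavioral
#' repeated-measures ANOVA with the cue x linear-trend contrast, group
#' univariate adaptation tests (winsorized directional t tests, JZS Bayes
#' factors, maximum-statistic correction), joint-modulator unique
#' contributions, the adaptation-pattern distinction analysis with
#' jackknife portion contributions, and the group neural-space
#' reconstruction per cue.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, result tables and a
#'   manifest (seeds, parameters) are written as TSV/JSON.
#' @param progress Print per-participant progress?
#' @return A list of class `study_result` with elements `behavior_anova`,
#'   `behavior_trend`, `univariate`, `joint`, `pattern`, `jackknife`,
#'   `reconstruction`, `portion_anova`, and `manifest`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      progress = FALSE) {
  t0 <- Sys.time()
  fits <- vector("list", config$n_participants)
  for (pid in seq_len(config$n_participants)) {
    part <- simulate_participant(config, pid)
    fits[[pid]] <- analyze_participant(part, keep_residuals = (pid == 1))
    if (progress) message("participant ", pid, " done")
  }

  ## behavior: accuracy per subject x cue x location x day x environment
  behav <- do.call(rbind, lapply(seq_along(fits), function(i)
    cbind(subject = i, fits[[i]]$behavior)))
  behavior_anova <- rm_anova(behav, "correct", "subject",
                             c("cue", "location", "day", "environment"))
  behavior_trend <- trend_contrast(behav, "correct", "subject", "location",
                                   interaction_with = "cue")

  ## univariate group tests per cue (mean over runs per participant)
  uni <- do.call(rbind, lapply(seq_along(fits), function(i) {
    r <- fits[[i]]$roi
    aggregate(beta ~ cue, r, mean)
  }))
  cues <- sort(unique(uni$cue))
  uni_mat <- sapply(cues, function(cu) uni$beta[uni$cue == cu])
  univariate <- lapply(cues, function(cu)
    one_sample_t(winsorize(uni_mat[, cu])$values, tail = "greater"))
  names(univariate) <- cues
  uni_corr <- max_stat_correction(apply(uni_mat, 2, function(v)
    winsorize(v)$values), tail = "greater")

  ## joint-modulator unique contributions (landmark regime focus)
  joint <- do.call(rbind, lapply(seq_along(fits), function(i) {
    j <- fits[[i]]$joint
    cbind(subject = i, aggregate(cbind(distance, identity) ~ cue, j, mean))
  }))
  joint_tests <- list()
  for (cu in cues) {
    sel <- joint[joint$cue == cu, ]
    joint_tests[[paste0(cu, "_identity_unique")]] <-
      one_sample_t(winsorize(sel$identity)$values, tail = "greater")
    joint_tests[[paste0(cu, "_distance_unique")]] <-
      one_sample_t(winsorize(sel$distance)$values, tail = "greater")
  }

  ## pattern distinction (environment averaged out)
  scores <- t(sapply(fits, function(f) {
    d <- distinction(similarity_table(average_environments(f$vectors)))
    c(within = d$score[d$day_relation == "within"],
      between = if ("between" %in% d$day_relation)
        d$score[d$day_relation == "between"] else NA_real_,
      between_cue_z = d$between_cue_z[d$day_relation == "within"])
  }))
  pattern <- list(
    within_day = one_sample_t(winsorize(scores[, "within"])$values,
                              tail = "greater"),
    between_day = if (!anyNA(scores[, "between"]))
      one_sample_t(winsorize(scores[, "between"])$values, tail = "greater"),
    between_cue_z_mean = mean(scores[, "between_cue_z"]),
    scores = scores)

  ## jackknife portion contributions -> portion RM-ANOVA
  jack <- do.call(rbind, lapply(seq_along(fits), function(i) {
    jk <- jackknife_portions(average_environments(fits[[i]]$vectors),
                             fits[[i]]$portions)
    data.frame(subject = i, portion = names(jk), score = jk,
               stringsAsFactors = FALSE)
  }))
  jack_anova <- rm_anova(jack, "score", "subject", "portion")

  ## neural-space reconstruction per cue (group-pooled cell activations)
  cells <- do.call(rbind, lapply(seq_along(fits), function(i)
    cbind(subject = i, fits[[i]]$cells)))
  reconstruction <- lapply(cues, function(cu) {
    D <- neural_distances(cells[cells$cue == cu, ],
                          n_locations = length(config$layout$location_positions))
    procrustes_test(embed_1d(D),
                    physical = config$layout$location_positions -
                      config$layout$location_positions[1])
  })
  names(reconstruction) <- cues

  ## portion x cue univariate adaptation (first participant's segmentation)
  seg <- local({
    f1 <- fits[[1]]
    fp <- fingerprints(t(f1$residuals), t(f1$residuals))
    g <- partition_gradient(dominant_gradient(fp$similarity))
    g$portion_label
  })

  manifest <- list(master_seed = config$master_seed,
                   n_participants = config$n_participants,
                   n_voxels = config$n_voxels,
                   elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out <- structure(list(behavior_anova = behavior_anova,
                        behavior_trend = behavior_trend,
                        univariate = univariate,
                        univariate_corrected = uni_corr,
                        joint = joint_tests, pattern = pattern,
                        jackknife = jack_anova,
                        reconstruction = reconstruction,
                        segmentation_portions = seg,
                        manifest = manifest),
                   class = "study_result")
  if (!is.null(out_dir)) write_study_result(out, behav, out_dir)
  out
}

write_study_result <- function(result, behav, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$behavior_anova,
                     file.path(out_dir, "behavior_anova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  uni <- do.call(rbind, lapply(names(result$univariate), function(cu) {
    s <- result$univariate[[cu]]
    data.frame(cue = cu, mean = s$estimate, t = s$t, df = s$dof, p = s$p,
               bf10 = s$bf10)
  }))
  utils::write.table(uni, file.path(out_dir, "univariate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  for (cu in names(x$univariate)) {
    cat(sprintf("  univariate %-12s ", cu)); print(x$univariate[[cu]])
  }
  cat("  within-day pattern distinction: "); print(x$pattern$within_day)
  for (cu in names(x$reconstruction)) {
    cat(sprintf("  reconstruction %-12s ", cu)); print(x$reconstruction[[cu]])
  }
  invisible(x)
}

fixture_cache <- new.env(parent = emptyenv())

#' Deterministic cached fixture datasets
#'
#' `tiny` is 3 participants x 2 runs (one per cue) x 50 voxels for unit
#' tests; `desk` keeps the full run/session counts at the reduced voxel
#' grid. Both are pure functions of the seed and are cached per session.
#'
#' @param scale `"tiny"` or `"desk"`.
#' @param seed Master seed.
#' @return For `tiny`, a list of `participant` objects with 2 runs each;
#'   for `desk`, a list of full `participant` objects.
#' @export
fixtures <- function(scale = c("tiny", "desk"), seed = 1L) {
  scale <- match.arg(scale)
  key <- paste(scale, seed, sep = "_")
  if (!is.null(fixture_cache[[key]])) return(fixture_cache[[key]])
  out <- if (scale == "tiny") {
    cfg <- study_config(n_participants = 3, n_voxels = 50, master_seed = seed)
    lapply(1:3, function(pid) {
      part <- simulate_participant(cfg, pid)
      keep <- c(which(part$plan$cue == "landmark")[1],
                which(part$plan$cue == "self_motion")[1])
      part$runs <- part$runs[keep]
      part$plan <- part$plan[keep, ]
      part
    })
  } else {
    cfg <- study_config(master_seed = seed)
    lapply(seq_len(cfg$n_participants),
           function(pid) simulate_participant(cfg, pid))
  }
  fixture_cache[[key]] <- out
  out
}
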