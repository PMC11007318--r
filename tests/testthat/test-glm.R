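test_that("modulator values follow the coding rules", {
  # crafted sequence: loc2, loc2 (8 m, 8 m) then loc1, loc4 (4 m -> 16 m)
  s <- prepend_duplicate(make_sequence(c(2, 2, 1, 4), k = 5))
  run <- realize_timing(s, track_layout(), seed = 1)
  dist <- build_modulator(run, "distance")
  iden <- build_modulator(run, "identity")
  # presented: [4] 2 2 1 4; adaptable trials: all four effective trials
  expect_equal(dist$values, c(8, 0, 4, 12))
  expect_equal(iden$values, c(1, 0, 1, 1))
  expect_true(all(dist$values %in% c(0, 4, 8, 12)))

  # path-length example: travel 10 m then 8 m -> modulator 2 m
  s2 <- prepend_duplicate(make_sequence(c(3, 4), k = 5))
  run2 <- realize_timing(s2, track_layout(), seed = 2,
                         start_range = c(-10, -10), speed_range = c(4, 4))
  run2$events$start_position[2:3] <- c(2, 8)   # paths 10 m then 8 m
  run2$events$path_length[2:3] <- c(10, 8)
  pl <- build_modulator(run2, "path_length")
  expect_equal(pl$values[2], 2)

  # temporal distance equals the occupation-onset gap
  td <- build_modulator(run, "temporal_distance")
  occ <- run$events$occupation_onset
  expect_equal(td$values, diff(occ[!run$events$is_null]))

  # trials after null events are excluded from the adaptable set
  s3 <- prepend_duplicate(make_sequence(c(1, 5, 2, 3), k = 5))
  run3 <- realize_timing(s3, track_layout(), seed = 3)
  m3 <- build_modulator(run3, "distance")
  expect_equal(length(m3$values), 2)   # first effective and post-null excluded

  expect_error(build_modulator(run, "response"), "response")
})

test_that("design matrices have the specified structure", {
  run <- generate_run(seed = 15, cue = "landmark")
  mods <- list(build_modulator(run, "distance"),
               build_modulator(run, "identity"))
  d <- build_design(run, modulators = mods)
  expect_false(any(duplicated(colnames(d$X))))
  expect_true(all(c("mod_distance", "mod_identity", "occ_adapt",
                    "occ_nonadapt", "movement") %in% colnames(d$X)))
  expect_equal(unname(d$groups[c("mod_distance", "mod_identity")]),
               rep("modulator", 2))
  # one derivative per event regressor
  expect_equal(sum(d$groups == "derivative"), sum(d$groups == "event"))

  # movement variants change only movement columns
  d123 <- build_design(run, modulators = mods, movement_model = "phases123")
  dn <- build_design(run, modulators = mods, movement_model = "none")
  shared <- setdiff(colnames(d$X), c("movement", "movement_deriv"))
  expect_equal(d$X[, shared], d123$X[, shared])
  expect_equal(colnames(dn$X), setdiff(colnames(d$X),
                                       c("movement", "movement_deriv")))

  # modulator betas identical under movement variants when the data carry no
  # movement response: noiseless data generated in the design span with a
  # zero movement coefficient
  set.seed(16)
  b_true <- rnorm(ncol(d$X))
  b_true[colnames(d$X) %in% c("movement", "movement_deriv")] <- 0
  bold <- synthesize_bold(run, sample_population(2, seed = 16), zero_noise(),
                          seed = 1)
  bold$signal <- t(d$X %*% cbind(b_true, 2 * b_true))
  b1 <- fit_glm(bold, d)$betas["mod_identity", ]
  b2 <- fit_glm(bold, dn)$betas["mod_identity", ]
  expect_lt(max(abs(b1 - b2)), 1e-6)
})

test_that("movement regressors are nearly orthogonal to adaptation
           modulators on generated designs", {
  rs <- vapply(1:10, function(s) {
    run <- generate_run(seed = s, cue = "self_motion")
    d <- build_design(run, modulators = list(build_modulator(run, "distance")))
    cor(d$X[, "movement"], d$X[, "mod_distance"])
  }, numeric(1))
  expect_lt(max(abs(rs)), 0.05)
})

test_that("distance and temporal-distance modulators are minimally correlated
           when pooled over a session's worth of runs", {
  vals <- do.call(rbind, lapply(1:16, function(i) {
    run <- generate_run(seed = 400 + i)
    a <- build_modulator(run, "distance")
    b <- build_modulator(run, "temporal_distance")
    cbind(a$values - mean(a$values), b$values - mean(b$values))
  }))
  expect_lt(abs(cor(vals[, 1], vals[, 2])), 0.1)
})

test_that("OLS fitting matches the normal-equations oracle and basic
           equivariances", {
  set.seed(20)
  w <- tiny_world()
  d <- build_design(w$run,
                    modulators = list(build_modulator(w$run, "distance")))
  X <- d$X
  Y <- X %*% matrix(rnorm(ncol(X) * 4), ncol(X), 4)
  bold <- w$bold; bold$signal <- t(Y)
  fit <- fit_glm(bold, d)
  # exact recovery of the generating coefficients
  b_true <- solve(crossprod(X), crossprod(X, Y))
  expect_lt(max(abs(fit$betas - b_true)), 1e-8)
  # residual orthogonality to the design (normal equations)
  expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-6)
  # voxel permutation equivariance
  perm <- c(3, 1, 4, 2)
  boldp <- bold; boldp$signal <- bold$signal[perm, ]
  expect_equal(fit_glm(boldp, d)$betas, fit$betas[, perm])
  # NaN rejection
  boldn <- bold; boldn$signal[1, 1] <- NaN
  expect_error(fit_glm(boldn, d), "NaN")
})

test_that("rank-deficient designs fail with the offending columns named", {
  run <- generate_run(seed = 17)
  m <- build_modulator(run, "distance")
  m2 <- m  # duplicated modulator -> collinear columns
  m2$kind <- "path_length"
  m2$values <- m$values
  expect_error(build_design(run, modulators = list(m, m2)),
               "dependent columns")
})

test_that("adaptation vectors carry labels, respect masks, and are positive
           for suppressing voxels on noiseless broad-tuning data", {
  w <- tiny_world()
  d <- build_design(w$run,
                    modulators = list(build_modulator(w$run, "distance")))
  fit <- fit_glm(w$bold, d)
  v <- adaptation_vector(fit, "mod_distance")
  expect_length(v, w$pop$n_voxels)
  expect_equal(attr(v, "cue"), "self_motion")
  expect_length(adaptation_vector(fit, "mod_distance", mask = 3), 1)
  expect_error(adaptation_vector(fit, "mod_distance",
                                 mask = rep(FALSE, w$pop$n_voxels)), "empty")
  expect_error(adaptation_vector(fit, "mod_nope"), "no such")
  # all suppressing voxels show positive distance-modulated adaptation
  expect_true(all(v[w$pop$maps$self_motion$city$s > 0] > 0))
})

test_that("the success-contrast design has exactly four occupation event
           regressors and recovers a correct-trial boost", {
  cfg <- study_config(n_voxels = 10, noise = zero_noise(),
                      behavior = behavior_params(0.7, 0, 0.7, 0),
                      master_seed = 5)
  part <- simulate_participant(cfg, 1)
  runs <- part$runs[1:4]
  bolds <- lapply(1:4, function(i)
    synthesize_bold(runs[[i]], part$pop, cfg$noise, seed = i,
                    correct_boost = 0.3))
  des <- success_design(runs, motion = lapply(bolds, `[[`, "motion"))
  expect_equal(sum(des$groups == "event_cc"), 4)
  fit <- fit_glm(bolds, des)
  for (cu in c("landmark", "self_motion")) {
    contrast <- mean(fit$betas[paste0(cu, "_correct"), ] -
                       fit$betas[paste0(cu, "_incorrect"), ])
    expect_gt(contrast, 0)
  }
  # an all-correct participant cannot enter the concatenated model
  cfg2 <- study_config(behavior = behavior_params(1, 0, 1, 0), master_seed = 6)
  part2 <- simulate_participant(cfg2, 1)
  expect_error(success_design(part2$runs[1:4]), "drop this participant")
})

test_that("distance-binned designs expose one occupation regressor per
           inter-location distance", {
  run <- generate_run(seed = 18)
  d <- build_binned_design(run, "distance")
  bins <- grep("^occ_d[0-9]+$", colnames(d$X), value = TRUE)
  m <- build_modulator(run, "distance")
  expect_setequal(bins, paste0("occ_d", sort(unique(m$values))))
})
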