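test_that("cue-shared populations have bitwise identical parameter maps and
           the cue-specific flag is honored", {
  shared <- sample_population(40, sigma_landmark = 6, sigma_self_motion = 6,
                              cue_specific = FALSE,
                              env_specific = c(landmark = FALSE,
                                               self_motion = FALSE),
                              seed = 1)
  expect_identical(shared$maps$landmark$city$s,
                   shared$maps$self_motion$city$s)
  expect_identical(shared$maps$landmark$city$center,
                   shared$maps$self_motion$city$center)
  spec <- sample_population(40, cue_specific = TRUE, seed = 1)
  expect_false(identical(spec$maps$landmark$city$s,
                         spec$maps$self_motion$city$s))
  # determinism
  again <- sample_population(40, cue_specific = TRUE, seed = 1)
  expect_identical(spec$maps, again$maps)
})

test_that("Gaussian tuning overlap is negligible at 4 m for sharp tuning and
           declines monotonically for broad tuning", {
  # overlap oracle: normalized Gaussian density ratio at distance dx
  overlap <- function(dx, sigma) exp(-dx^2 / (2 * sigma^2))
  expect_lt(overlap(4, 0.5), 1e-8)
  broad <- overlap(c(0, 4, 8, 12), 6)
  expect_true(all(diff(broad) < 0))
})

test_that("neural amplitudes implement overlap-based suppression", {
  pop <- sample_population(10, seed = 3)
  map <- pop$maps$self_motion$city
  # full suppression on exact repeat with s = 1
  pop1 <- pop; pop1$maps$self_motion$city$s <- rep(1, 10)
  expect_equal(neural_amplitude(pop1, "self_motion", 8, 8), rep(0, 10))
  # s = 0: amplitude independent of the previous location
  pop0 <- pop; pop0$maps$self_motion$city$s <- rep(0, 10)
  expect_equal(neural_amplitude(pop0, "self_motion", 8, 4),
               neural_amplitude(pop0, "self_motion", 8, NULL))
  # no suppression term after null (prev = NULL) but suppression with prev
  expect_true(all(neural_amplitude(pop, "self_motion", 8, 8) <
                    neural_amplitude(pop, "self_motion", 8, NULL)))
})

test_that("broad-tuning population amplitude increases with the distance of
           the preceding location (exact evaluation)", {
  pop <- sample_population(30, sigma_landmark = 6, seed = 4,
                           center_mode = "uniform")
  means <- vapply(c(0, 4, 8, 12), function(d)
    mean(neural_amplitude(pop, "self_motion", 4, 4 + d)), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("sharp tuning yields identity-like and broad tuning distance-graded
           population adaptation profiles", {
  pop <- sample_population(60, seed = 5)
  prof <- function(cue) {
    base <- neural_amplitude(pop, cue, 8, NULL)
    sel <- base > 0.1 * max(base)          # voxels responsive at 8 m
    vapply(c(0, 4, 8, 12), function(d)
      mean(neural_amplitude(pop, cue, 8, 8 + d)[sel] / base[sel]), numeric(1))
  }
  lm <- prof("landmark"); sm <- prof("self_motion")
  # landmark: distance 0 suppressed, all nonzero distances flat and unsuppressed
  expect_lt(lm[1], 0.9)
  expect_true(all(abs(lm[2:4] - 1) < 1e-6))
  # self-motion: graded recovery with distance
  expect_true(all(diff(sm) > 0))
  expect_lt(sm[1], sm[4] - 0.1)
})

test_that("BOLD synthesis is deterministic, zero for zero gain and noise,
           and peaks 4-8 s after occupation onset for a single event", {
  run <- generate_run(seed = 12)
  pop0 <- sample_population(5, gain_range = c(0, 0), seed = 6)
  b0 <- synthesize_bold(run, pop0, zero_noise(), seed = 1)
  expect_true(all(b0$signal == 0))

  w <- tiny_world()
  b1 <- synthesize_bold(w$run, w$pop, noise_model(), seed = 2)
  b2 <- synthesize_bold(w$run, w$pop, noise_model(), seed = 2)
  expect_identical(b1$signal, b2$signal)

  # single-event run, no movement response: HRF peak latency oracle
  s <- make_sequence(c(2), k = 5)
  run1 <- realize_timing(s, track_layout(), seed = 3)
  popg <- sample_population(3, gain_range = c(1, 1), seed = 7)
  popg$maps$landmark$city$s[] <- 0
  bb <- synthesize_bold(run1, popg, zero_noise(), seed = 1,
                        movement_amplitude = 0)
  onset <- run1$events$occupation_onset[1]
  peak_t <- bb$frame_times[which.max(bb$signal[1, ])] - onset
  expect_gte(peak_t, 4); expect_lte(peak_t, 8)
  # oracle: direct convolution of the 4 s boxcar with the kernel
  h <- hrf_double_gamma(0.1)
  resp <- stats::convolve(c(rep(1, 40), numeric(length(h))),
                          rev(c(h, numeric(40))), type = "open")
  oracle_peak <- (which.max(resp) - 1) * 0.1
  expect_lt(abs(peak_t - oracle_peak), bb$tr)
})

test_that("a matching GLM recovers injected amplitudes exactly on noiseless
           data", {
  w <- tiny_world()
  des <- build_binned_design(w$run, "pair", nonadapt_by_location = TRUE)
  fit <- fit_glm(w$bold, des)
  nm <- grep("^occ_p[0-9][0-9]$", rownames(fit$betas), value = TRUE)
  xs <- w$run$layout$location_positions
  for (n in nm) {
    i <- as.integer(substr(n, 6, 6)); j <- as.integer(substr(n, 7, 7))
    amp <- neural_amplitude(w$pop, "self_motion", xs[j], xs[i])
    expect_lt(max(abs(fit$betas[n, ] - amp) / pmax(abs(amp), 1e-9)), 1e-6)
  }
  # movement response recovered as movement_amplitude * gain
  expect_lt(max(abs(fit$betas["movement", ] -
                      0.5 * w$pop$maps$self_motion$city$gain)), 1e-6)
})

test_that("behavioral simulation respects accuracy parameters, the chance
           floor, and cue-specific gradients", {
  run <- generate_run(seed = 41, cue = "landmark")
  all_correct <- simulate_behavior(run, behavior_params(1, 0, 1, 0), seed = 1)
  expect_true(all(all_correct$events$correct[!all_correct$events$is_null]))

  # chance-level accuracy: ~0.25 over many trials
  s <- prepend_duplicate(make_sequence(rep(1:4, 250), k = 5))
  long <- realize_timing(s, track_layout(), seed = 2)
  ch <- simulate_behavior(long, behavior_params(0.25, 0, 0.25, 0), seed = 3)
  acc <- mean(ch$events$correct[!ch$events$is_null])
  expect_lt(abs(acc - 0.25), 0.03)

  # probabilities outside [0.25, 1] are clipped with a warning
  expect_warning(simulate_behavior(run, behavior_params(1.2, 0, 1, 0),
                                   seed = 4), "clipped")

  # opposite gradients: landmark accuracy rises, self-motion falls with index
  accs <- function(cue) {
    out <- matrix(0, 0, 2)
    for (seed in 1:8) {
      r <- simulate_behavior(generate_run(seed = seed, cue = cue), seed = seed)
      ev <- r$events[effective_trials(r), ]
      out <- rbind(out, cbind(ev$type_index, as.numeric(ev$correct)))
    }
    tapply(out[, 2], out[, 1], mean)
  }
  lm <- accs("landmark"); sm <- accs("self_motion")
  expect_gt(lm[4], lm[1] - 0.05)
  expect_gt(sm[1], sm[4] + 0.1)
})

test_that("the noise model validates stationarity and population portions are
           balanced", {
  expect_error(noise_model(ar1 = 1), "phi")
  pop <- sample_population(101, seed = 9)
  expect_equal(sort(as.integer(table(pop$portion_label)), decreasing = TRUE),
               c(11L, rep(10L, 9)))
})
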