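test_that("winsorization follows the boxplot rule with interpolated
           quartiles and is idempotent", {
  # oracle: quartiles by linear interpolation (type 7)
  x <- c(1, 2, 3, 4, 100)
  q <- quantile(x, c(.25, .75), type = 7)
  expect_true(100 > q[2] + 3 * (q[2] - q[1]))
  w <- winsorize(x)
  expect_equal(w$values, c(1, 2, 3, 4, 4))
  expect_equal(w$n_replaced, 1L)

  # no outliers -> identity
  expect_equal(winsorize(1:10)$n_replaced, 0L)
  expect_equal(winsorize(rep(2, 5))$n_replaced, 0L)   # all-equal degenerate

  # symmetric outliers clipped on both sides
  y <- c(-100, 1, 2, 3, 4, 5, 6, 100)
  w2 <- winsorize(y)
  expect_equal(range(w2$values), c(1, 6))
  expect_equal(w2$n_replaced, 2L)

  # idempotence
  expect_equal(winsorize(w2$values)$values, w2$values)
  expect_error(winsorize(1:3), "n >= 4")
})

test_that("the directional one-sample t test handles the degenerate all-zero
           case and rejects zero-variance nonzero data", {
  r0 <- one_sample_t(rep(0, 8))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 0.5)
  expect_error(one_sample_t(rep(1, 8)), "zero variance")
  # agreement with t.test
  set.seed(1); x <- rnorm(15, 0.3)
  r <- one_sample_t(x, tail = "greater")
  tt <- t.test(x, alternative = "greater")
  expect_equal(r$t, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)
})

test_that("the JZS Bayes factor matches brute-force quadrature and is
           monotone in |t|", {
  # independent oracle: Riemann sum of the noncentral-t marginal likelihood
  bf_riemann <- function(t, n, r = 0.707) {
    delta <- seq(1e-4, 60, length.out = 40000)
    f <- suppressWarnings(dt(t, n - 1, ncp = sqrt(n) * delta)) *
      2 * dcauchy(delta, 0, r)
    sum(f) * (delta[2] - delta[1]) / dt(t, n - 1)
  }
  for (tv in c(-1, 0.5, 2.2, 3.5))
    expect_equal(bf_jzs(tv, 20), bf_riemann(tv, 20), tolerance = 0.01)

  bfs <- vapply(c(0, 1, 2, 3, 4), function(tv) bf_jzs(tv, 20), numeric(1))
  expect_true(all(diff(bfs) > 0))
  # symmetric-prior variant is even in t
  expect_equal(bf_jzs(2, 20, directional = FALSE),
               bf_jzs(-2, 20, directional = FALSE), tolerance = 1e-6)
})

test_that("maximum-statistic correction reproduces the exhaustive sign-flip
           enumeration and its validity properties", {
  x <- c(1, 2, 3)
  res <- max_stat_correction(matrix(x, 3, 1), tail = "greater")
  # oracle: all 2^3 sign patterns by hand
  S <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  ts <- apply(S, 1, function(s) { y <- s * x; mean(y) / (sd(y) / sqrt(3)) })
  expect_equal(res$corrected_p, mean(ts >= ts[1] - 1e-12))
  expect_equal(res$n_perm_used, 8L)

  # duplicated test columns get identical corrected p
  set.seed(3)
  d <- matrix(rnorm(12 * 3), 12, 3)
  d <- cbind(d, d[, 2])
  r <- max_stat_correction(d, tail = "two.sided")
  expect_equal(r$corrected_p[2], r$corrected_p[4])

  # corrected >= uncorrected; identity inclusion bounds p away from 0
  set.seed(4)
  cohort <- matrix(rnorm(20 * 8, mean = 0.4), 20, 8)
  rc <- max_stat_correction(cohort, tail = "greater", n_perm = 300, seed = 1)
  expect_true(all(rc$corrected_p >= rc$p - 1e-12))
  expect_true(all(rc$corrected_p >= 1 / 300))
  expect_warning(max_stat_correction(cohort, n_perm = 50, seed = 1), "100")
})

test_that("repeated-measures ANOVA agrees with stats::aov strata and the
           paired-t equivalence", {
  set.seed(5)
  dat <- expand.grid(subject = 1:7, a = 1:2, b = 1:3)
  dat$y <- rnorm(nrow(dat)) + 0.6 * (dat$a == 2)
  an <- rm_anova(dat, "y", "subject", c("a", "b"))
  av <- summary(stats::aov(y ~ factor(a) * factor(b) +
                             Error(factor(subject) /
                                     (factor(a) * factor(b))), data = dat))
  get_f <- function(stratum, row)
    av[[stratum]][[1]][row, "F value"]
  expect_equal(an$F[an$effect == "a"],
               get_f("Error: factor(subject):factor(a)", 1), tolerance = 1e-8)
  expect_equal(an$F[an$effect == "b"],
               get_f("Error: factor(subject):factor(b)", 1), tolerance = 1e-8)
  expect_equal(an$F[an$effect == "a:b"],
               get_f("Error: factor(subject):factor(a):factor(b)", 1),
               tolerance = 1e-8)

  # 2-level within factor: F equals the squared paired t
  two <- dat[dat$b == 1, ]
  an2 <- rm_anova(two, "y", "subject", "a")
  tt <- t.test(two$y[two$a == 2], two$y[two$a == 1], paired = TRUE)
  expect_equal(an2$F[1], unname(tt$statistic)^2, tolerance = 1e-8)

  # constant data give F = 0; incomplete grids error
  datc <- dat; datc$y <- 1
  expect_true(all(rm_anova(datc, "y", "subject", c("a", "b"))$F == 0))
  expect_error(rm_anova(dat[-1, ], "y", "subject", c("a", "b")), "balanced")
})

test_that("the linear trend contrast detects a crossover interaction in
           simulated behavior", {
  cfg <- study_config(master_seed = 9)
  behav <- do.call(rbind, lapply(1:10, function(pid) {
    part <- simulate_participant(cfg, pid)
    do.call(rbind, lapply(part$runs, function(run) {
      ev <- run$events[effective_trials(run), ]
      data.frame(subject = pid, cue = run$cue, location = ev$type_index,
                 correct = as.numeric(ev$correct))
    }))
  }))
  tc <- trend_contrast(behav, "correct", "subject", "location",
                       interaction_with = "cue")
  expect_equal(tc$dof, 3 * 9)
  expect_lt(tc$p, 0.01)
  # within the self-motion cue the trend is negative
  sm <- behav[behav$cue == "self_motion", ]
  tm <- trend_contrast(sm, "correct", "subject", "location")
  expect_lt(tm$estimate, 0)
})

test_that("voxel-wise group maps control error and detect injected blocks", {
  mask <- array(TRUE, c(5, 5, 2))
  nvox <- sum(mask)
  set.seed(11)
  betas <- matrix(rnorm(14 * nvox, 0, 1), 14, nvox)
  signal_vox <- which(array(slice.index(mask, 1) <= 2 &
                              slice.index(mask, 2) <= 2, dim(mask))[mask])
  betas[, signal_vox] <- betas[, signal_vox] + 2
  gm <- voxelwise_group_map(betas, mask, n_perm = 300, seed = 2)
  # the injected block survives voxel-level correction
  expect_true(all(gm$voxel_fwe_p[signal_vox] < 0.05))
  # and forms a surviving cluster
  expect_true(any(gm$clusters$fwe_p < 0.05 & gm$clusters$size >= 8))

  # single-voxel mask reduces to the one-sample t test
  m1 <- array(FALSE, c(5, 5, 2)); m1[1] <- TRUE
  g1 <- voxelwise_group_map(betas[, 1, drop = FALSE], m1, n_perm = NULL)
  r1 <- one_sample_t(betas[, 1], tail = "greater")
  expect_lt(abs(g1$voxel_fwe_p[1] - r1$p), 0.02)
  expect_error(voxelwise_group_map(betas, array(FALSE, c(5, 5, 2))), "empty")
})

test_that("cluster labeling respects 26- and 6-connectivity", {
  x <- array(FALSE, c(3, 3, 3))
  x[1, 1, 1] <- TRUE; x[2, 2, 2] <- TRUE   # diagonal neighbors
  expect_equal(max(label_clusters(x, 26)), 1L)
  expect_equal(max(label_clusters(x, 6)), 2L)
})
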