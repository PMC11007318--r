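#' Winsorize by the boxplot rule
#'
#' Values larger than `Q3 + 3 IQR` or smaller than `Q1 - 3 IQR` (quartiles
#' by linear interpolation, `quantile` type 7) are replaced by the nearest
#' remaining inlier; all other values are untouched.
#'
#' @param values Numeric vector, `n >= 4`.
#' @return A list with `values` (winsorized) and `n_replaced`.
#' @export
#' @examples
#' winsorize(c(1, 2, 3, 4, 100))$values
winsorize <- function(values) {
  if (length(values) < 4) stop("winsorize requires n >= 4")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - 3 * iqr
  hi <- q[2] + 3 * iqr
  out <- values < lo | values > hi
  if (!any(out)) return(list(values = values, n_replaced = 0L))
  inliers <- values[!out]
  values[values < lo] <- min(inliers)
  values[values > hi] <- max(inliers)
  list(values = values, n_replaced = sum(out))
}

#' JZS Bayes factor for a one-sample t test
#'
#' Evidence for a nonzero (or, directionally, positive) standardized effect
#' under a Cauchy prior of scale `r` on the effect size, against the point
#' null. Computed by adaptive quadrature of the noncentral-t marginal
#' likelihood; the directional variant truncates the prior to positive
#' effects, which reproduces the default one-sided Bayesian t test.
#'
#' @param t Observed t statistic.
#' @param n Sample size (paired/one-sample).
#' @param r Cauchy prior scale. Default 0.707.
#' @param directional Truncate the prior to positive effects? Default `TRUE`.
#' @return The Bayes factor BF10 (alternative over null).
#' @export
#' @examples
#' bf_jzs(2.940, 20)   # about 11.77
bf_jzs <- function(t, n, r = 0.707, directional = TRUE) {
  stopifnot(n >= 2, r > 0)
  nu <- n - 1
  dens <- function(delta)
    suppressWarnings(dt(t, nu, ncp = sqrt(n) * delta)) *
      dcauchy(delta, 0, r) * (if (directional) 2 else 1)
  marg <- integrate(dens, lower = if (directional) 0 else -Inf, upper = Inf,
                    rel.tol = 1e-9, stop.on.error = FALSE)$value
  marg / dt(t, nu)
}

#' One-sample t test with directional Bayes factor
#'
#' Directional (`tail = "greater"`) or two-sided one-sample t test against
#' `mu`, with the JZS Bayes factor at Cauchy scale 0.707 (truncated prior
#' for the directional test).
#'
#' @param values Numeric vector, `n >= 2`.
#' @param tail `"greater"` or `"two.sided"`.
#' @param mu Null value. Default 0.
#' @param winsorize_first Apply [winsorize()] before testing?
#' @param r Cauchy prior scale for the Bayes factor.
#' @return A list of class `stat_result`: `estimate`, `t`, `dof`, `p`,
#'   `tail`, `bf10`, `n`, `n_outliers_winsorized`.
#' @export
one_sample_t <- function(values, tail = c("greater", "two.sided"), mu = 0,
                         winsorize_first = FALSE, r = 0.707) {
  tail <- match.arg(tail)
  if (length(values) < 2) stop("need n >= 2")
  nw <- 0L
  if (winsorize_first) {
    w <- winsorize(values)
    values <- w$values; nw <- w$n_replaced
  }
  n <- length(values)
  if (sd(values) == 0) {
    if (abs(mean(values) - mu) > 0) stop("zero variance with nonzero effect")
    tt <- 0
  } else {
    tt <- (mean(values) - mu) / (sd(values) / sqrt(n))
  }
  p <- if (tail == "greater") pt(tt, n - 1, lower.tail = FALSE)
       else 2 * pt(abs(tt), n - 1, lower.tail = FALSE)
  structure(list(estimate = mean(values), t = tt, dof = n - 1, p = p,
                 tail = tail,
                 bf10 = bf_jzs(tt, n, r = r, directional = tail == "greater"),
                 n = n, n_outliers_winsorized = nw),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("mean %.4f, t(%d) = %.3f, p%s = %.4g, BF10 = %.3f%s\n",
              x$estimate, x$dof, x$t,
              if (x$tail == "greater") "[1-tailed]" else "",
              x$p, x$bf10,
              if (x$n_outliers_winsorized > 0)
                sprintf(" (%d winsorized)", x$n_outliers_winsorized) else ""))
  invisible(x)
}

## one-sample t statistics for every column of B under sign pattern rows of S
flip_t_matrix <- function(B, S) {
  n <- nrow(B)
  ssq <- colSums(B^2)                     # invariant under sign flips
  M <- (S %*% B) / n
  varm <- sweep(-n * M^2, 2, ssq, "+") / (n - 1)
  varm[varm < 0] <- 0
  M / sqrt(varm / n)
}

sign_patterns <- function(n, n_perm, seed = NULL) {
  if (is.null(n_perm) && n <= 14) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(S) <- NULL
    return(S)
  }
  if (is.null(n_perm)) n_perm <- 1000L
  if (n_perm < 100) warning("fewer than 100 permutations")
  if (!is.null(seed)) set.seed(seed)
  S <- matrix(sample(c(1, -1), (n_perm - 1L) * n, replace = TRUE),
              n_perm - 1L, n)
  rbind(rep(1, n), S)                     # identity permutation included
}

#' Maximum-statistic sign-flip permutation correction
#'
#' Familywise-error-corrected p values for a family of one-sample tests
#' sharing the same participants, by the nonparametric maximum t statistic
#' approach: each permutation flips the signs of whole participant rows,
#' all t statistics are recomputed, and the corrected p of each test is the
#' proportion of permutations (identity included) whose maximum statistic
#' meets or exceeds the observed one.
#'
#' @param data Participants x tests numeric matrix.
#' @param tail `"greater"` (signed max t) or `"two.sided"` (max |t|).
#' @param n_perm Number of permutations; `NULL` (default) enumerates all
#'   `2^n` sign patterns when `n <= 14` and uses 1000 random flips
#'   otherwise.
#' @param seed Integer seed for random flips.
#' @return A list with `t` (observed), `p` (uncorrected), `corrected_p`,
#'   and `n_perm_used`.
#' @export
max_stat_correction <- function(data, tail = c("greater", "two.sided"),
                                n_perm = NULL, seed = NULL) {
  tail <- match.arg(tail)
  data <- as.matrix(data)
  n <- nrow(data)
  S <- sign_patterns(n, n_perm, seed)
  Tm <- flip_t_matrix(data, S)
  obs <- Tm[1, ]                          # identity row
  stat <- if (tail == "greater") Tm else abs(Tm)
  maxes <- apply(stat, 1, max)
  obs_stat <- if (tail == "greater") obs else abs(obs)
  corrected <- vapply(obs_stat, function(o) mean(maxes >= o - 1e-12), numeric(1))
  p_unc <- if (tail == "greater") pt(obs, n - 1, lower.tail = FALSE)
           else 2 * pt(abs(obs), n - 1, lower.tail = FALSE)
  list(t = obs, p = p_unc, corrected_p = pmax(corrected, p_unc),
       n_perm_used = nrow(S))
}

u_term <- function(df, dv, vars) {
  if (!length(vars)) return(sum(df[[dv]])^2 / nrow(df))
  tot <- aggregate(df[[dv]], df[vars], sum)
  r <- nrow(df) / nrow(tot)
  sum(tot$x^2) / r
}

#' Repeated-measures ANOVA for balanced fully-within designs
#'
#' Classical decomposition for a complete, balanced subject x within-factor
#' grid: each effect is tested against its own effect-by-subject
#' interaction stratum. Replicate observations within a subject/cell are
#' averaged first. Reports F, p and partial eta squared per effect.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector of within-subject factor columns.
#' @return A data frame of class `rm_anova` with one row per effect.
#' @export
rm_anova <- function(data, dv, subject, within) {
  stopifnot(all(c(dv, subject, within) %in% names(data)))
  for (v in c(subject, within)) data[[v]] <- factor(data[[v]])
  ## aggregate replicates to subject x cell means
  df <- aggregate(data[[dv]], data[c(subject, within)], mean)
  names(df)[ncol(df)] <- dv
  cells <- unique(df[, within, drop = FALSE])
  n_s <- nlevels(df[[subject]])
  if (nrow(df) != n_s * nrow(cells))
    stop("design is not complete/balanced: missing subject x cell entries")
  lev <- vapply(within, function(v) nlevels(df[[v]]), 0L)

  effect_ss <- function(vars) {
    ss <- 0
    for (k in 0:length(vars)) {
      subs <- if (k == 0) list(character(0)) else
        asplit(combn(vars, k), 2)
      for (tset in subs)
        ss <- ss + (-1)^(length(vars) - k) * u_term(df, dv, as.character(tset))
    }
    ss
  }
  out <- list()
  for (k in seq_along(within)) {
    for (A in asplit(combn(within, k), 2)) {
      A <- as.character(A)
      ss <- effect_ss(A)
      sse <- effect_ss(c(A, subject))
      df1 <- prod(lev[A] - 1L)
      df2 <- df1 * (n_s - 1L)
      ms <- ss / df1; mse <- sse / df2
      f <- if (mse > 0) ms / mse else 0
      out[[paste(A, collapse = ":")]] <-
        data.frame(effect = paste(A, collapse = ":"),
                   df1 = df1, df2 = df2, F = f,
                   p = if (mse > 0) stats::pf(f, df1, df2, lower.tail = FALSE) else 1,
                   pes = if (ss + sse > 0) ss / (ss + sse) else 0)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("rm_anova", "data.frame")
  res
}

#' Linear trend contrast over an ordered within-subject factor
#'
#' Tests the linear trend of a (typically 4-level) ordered factor, or its
#' interaction with a second factor, using normalized contrast weights
#' (default `c(-3, -1, 1, 3)`) and the corresponding effect-by-subject
#' error stratum.
#'
#' @inheritParams rm_anova
#' @param factor_name The ordered factor (levels in order).
#' @param weights Contrast weights, one per level.
#' @param interaction_with Optional 2-level factor; if given, the trend x
#'   factor interaction contrast is tested.
#' @return A list of class `stat_result` (estimate, t, dof, p, bf10).
#' @export
trend_contrast <- function(data, dv, subject, factor_name,
                           weights = c(-3, -1, 1, 3),
                           interaction_with = NULL) {
  for (v in c(subject, factor_name, interaction_with))
    data[[v]] <- factor(data[[v]])
  w <- weights / sqrt(sum(weights^2))
  vars <- c(factor_name, interaction_with)
  df <- aggregate(data[[dv]], data[c(subject, vars)], mean)
  names(df)[ncol(df)] <- dv
  n_s <- nlevels(df[[subject]])
  if (is.null(interaction_with)) {
    cw <- w[as.integer(df[[factor_name]])]
  } else {
    b <- df[[interaction_with]]
    if (nlevels(b) != 2) stop("interaction_with must have 2 levels")
    cw <- w[as.integer(df[[factor_name]])] * ifelse(as.integer(b) == 1, 1, -1) /
      sqrt(2)
  }
  ## per-subject contrast scores
  sc <- tapply(df[[dv]] * cw, df[[subject]], sum)
  est <- mean(sc)
  ## error stratum: the effect x subject interaction
  ss_err <- local({
    full <- c(vars, subject)
    ss <- 0
    for (k in 0:length(full)) {
      subs <- if (k == 0) list(character(0)) else asplit(combn(full, k), 2)
      for (tset in subs)
        ss <- ss + (-1)^(length(full) - k) * u_term(df, dv, as.character(tset))
    }
    ss
  })
  df_err <- prod(vapply(vars, function(v) nlevels(df[[v]]) - 1L, 0L)) * (n_s - 1L)
  ## Var(mean contrast) = MSE * sum(cw^2) / n_s
  se <- sqrt((ss_err / df_err) * sum(cw^2) / n_s)
  tt <- est / se
  p <- 2 * pt(abs(tt), df_err, lower.tail = FALSE)
  structure(list(estimate = est, t = tt, dof = df_err, p = p,
                 tail = "two.sided", bf10 = NA_real_, n = n_s,
                 n_outliers_winsorized = 0L),
            class = "stat_result")
}

neighbor_offsets <- function(connectivity = 26) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  as.matrix(g)
}

#' Label connected clusters in a 3-D logical array
#'
#' @param x Logical 3-D array.
#' @param connectivity 26 (default) or 6.
#' @return Integer array of cluster labels (0 = background).
#' @export
label_clusters <- function(x, connectivity = 26) {
  stopifnot(length(dim(x)) == 3)
  off <- neighbor_offsets(connectivity)
  lab <- array(0L, dim(x))
  nxt <- 0L
  idx <- which(x, arr.ind = TRUE)
  d <- dim(x)
  inside <- function(p) all(p >= 1) && all(p <= d)
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (lab[p0[1], p0[2], p0[3]] != 0L) next
    nxt <- nxt + 1L
    queue <- list(p0)
    lab[p0[1], p0[2], p0[3]] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(off))) {
        q <- p + off[k, ]
        if (inside(q) && x[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          queue <- c(queue, list(q))
        }
      }
    }
  }
  lab
}

#' Voxel-wise group inference with sign-flip permutation correction
#'
#' One-sample t map over participants with familywise error control by the
#' maximum-statistic approach, at the voxel level and at the cluster level
#' (cluster-forming threshold `cluster_T`, 26-connectivity).
#'
#' @param betas Participants x voxels matrix; columns correspond to
#'   `which(mask)`.
#' @param mask Logical 3-D array defining the voxel grid.
#' @param tail `"greater"` or `"two.sided"`.
#' @param n_perm Number of sign-flip permutations (identity included).
#' @param cluster_T Cluster-forming t threshold. Default 3.
#' @param connectivity Cluster connectivity (26 or 6).
#' @param seed Integer seed.
#' @return A list of class `group_map`: `t` (voxel t values),
#'   `voxel_fwe_p`, `clusters` (data frame of observed clusters with
#'   FWE-corrected p), and the null distributions.
#' @export
voxelwise_group_map <- function(betas, mask, tail = c("greater", "two.sided"),
                                n_perm = 1000, cluster_T = 3,
                                connectivity = 26, seed = NULL) {
  tail <- match.arg(tail)
  betas <- as.matrix(betas)
  if (!any(mask)) stop("empty mask")
  stopifnot(ncol(betas) == sum(mask))
  n <- nrow(betas)
  S <- sign_patterns(n, n_perm, seed)
  Tm <- flip_t_matrix(betas, S)
  stat <- if (tail == "greater") Tm else abs(Tm)
  obs <- Tm[1, ]
  obs_stat <- stat[1, ]
  max_t <- apply(stat, 1, max)
  vox <- which(mask)
  d <- dim(mask)
  cluster_sizes <- function(svec) {
    supra <- array(FALSE, d)
    supra[vox] <- svec > cluster_T
    if (!any(supra)) return(integer(0))
    lab <- label_clusters(supra, connectivity)
    tabulate(lab[lab > 0])
  }
  max_clus <- vapply(seq_len(nrow(stat)), function(i) {
    cs <- cluster_sizes(stat[i, ])
    if (length(cs)) max(cs) else 0L
  }, integer(1))
  voxel_fwe <- vapply(obs_stat, function(o) mean(max_t >= o - 1e-12), numeric(1))
  supra <- array(FALSE, d); supra[vox] <- obs_stat > cluster_T
  lab <- label_clusters(supra, connectivity)
  labs <- sort(unique(lab[lab > 0]))
  clusters <- data.frame(cluster = labs,
                         size = vapply(labs, function(l) sum(lab == l), 0L))
  clusters$fwe_p <- vapply(clusters$size, function(s) mean(max_clus >= s),
                           numeric(1))
  structure(list(t = obs, voxel_fwe_p = voxel_fwe, clusters = clusters,
                 cluster_labels = lab, null_max_t = max_t,
                 null_max_cluster = max_clus, tail = tail),
            class = "group_map")
}
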