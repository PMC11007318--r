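#' Neural distance matrix from trial-wise activations
#'
#' Cell (i, j) is the mean region activation at current location j when
#' preceded by location i. Under repetition suppression, lower activation
#' means stronger overlap — i.e. the two locations sit closer in neural
#' space — so activation is read directly as neural distance. The matrix is
#' symmetrized, `D = (M + t(M)) / 2`, and normalized (default min-max to
#' \[0, 1\]); same-location cells provide the baseline minimum.
#'
#' @param trials Data frame with columns `prev`, `current` (location
#'   indices 1..k) and `beta` (trial-wise activation); trials with a valid
#'   predecessor only.
#' @param n_locations Number of locations. Default 4.
#' @param normalize `"minmax"` (subtract the minimum, divide by the range),
#'   `"z"` (center/scale by the cell SD), or `"none"`.
#' @return A `k x k` matrix of class `neural_distance_matrix` with a
#'   `counts` attribute.
#' @export
neural_distances <- function(trials, n_locations = 4,
                             normalize = c("minmax", "z", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(all(c("prev", "current", "beta") %in% names(trials)))
  k <- n_locations
  M <- matrix(NA_real_, k, k)
  counts <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    sel <- trials$prev == i & trials$current == j
    counts[i, j] <- sum(sel)
    if (counts[i, j] > 0) M[i, j] <- mean(trials$beta[sel])
  }
  if (any(counts == 0))
    stop("empty (previous, current) cell(s); provide more runs — a full ",
         "carry-over sequence covers every ordered pair")
  D <- (M + t(M)) / 2
  D <- switch(normalize,
              minmax = if (max(D) > min(D)) (D - min(D)) / (max(D) - min(D))
                       else D - min(D),
              z = (D - mean(D)) / sd(D),
              none = D)
  structure(D, class = c("neural_distance_matrix", "matrix"),
            counts = counts, normalize = normalize)
}

#' Embed a neural distance matrix on one dimension
#'
#' Classical (Torgerson) multidimensional scaling: double-centering of the
#' squared distances and scaling of the leading eigenvector by the square
#' root of its eigenvalue. The diagonal is treated as zero (same-location
#' baseline). A distance matrix cannot distinguish a configuration from its
#' mirror image, so the sign of the axis is fixed by convention — the
#' coordinates correlate non-negatively with the location labeling axis —
#' and scale is left free for the Procrustes step.
#'
#' @param D A symmetric `neural_distance_matrix` (or plain matrix).
#' @return Numeric coordinates, one per location, with the eigenvalue
#'   spectrum as attribute `eig`.
#' @export
embed_1d <- function(D) {
  D <- unclass(as.matrix(D))
  stopifnot(isSymmetric(unname(D), tol = 1e-8))
  diag(D) <- 0
  mds <- suppressWarnings(cmdscale(stats::as.dist(D), k = 1, eig = TRUE))
  if (mds$eig[1] <= 1e-12)
    stop("degenerate geometry: leading MDS eigenvalue is not positive")
  coords <- drop(mds$points)
  if (sum(coords * seq_along(coords)) < 0) coords <- -coords
  attr(coords, "eig") <- mds$eig
  coords
}

procrustes_d <- function(coords, physical, allow_reflection = FALSE) {
  x <- coords - mean(coords)
  y <- physical - mean(physical)
  if (sd(x) == 0 || sd(y) == 0) return(1)
  r <- cor(x, y)
  if (allow_reflection) 1 - r^2 else if (r > 0) 1 - r^2 else 1
}

#' Procrustes alignment test of a 1-D reconstruction against physical space
#'
#' Aligns the embedded coordinates to the physical location coordinates by
#' the optimal translation and scaling and reports the normalized squared
#' residual `d` in \[0, 1\]. Significance is one-tailed on small `d` over
#' the exhaustive null of all `4! = 24` location-label permutations
#' (identity included). By default reflection is *not* allowed: under the
#' adaptation polarity convention (higher activation = larger neural
#' distance) the sign of the embedding is meaningful, and an allowed
#' reflection would make every labeling indistinguishable from its mirror
#' image, capping the attainable one-sided p at 2/24.
#'
#' @param coords Embedded coordinates from [embed_1d()].
#' @param physical Physical coordinates (default `c(0, 4, 8, 12)` m).
#' @param allow_reflection Permit a sign flip in the alignment?
#' @return A list of class `reconstruction_result`: `coords`,
#'   `procrustes_d`, `p_perm`, `perm_d` (all 24 permutation residuals).
#' @export
procrustes_test <- function(coords, physical = c(0, 4, 8, 12),
                            allow_reflection = FALSE) {
  coords <- as.numeric(coords)
  k <- length(coords)
  stopifnot(length(physical) == k)
  perms <- permutations_of(k)
  d_all <- vapply(seq_len(nrow(perms)), function(r)
    procrustes_d(coords[perms[r, ]], physical, allow_reflection), numeric(1))
  d_obs <- d_all[1]                       # identity is the first permutation
  p <- mean(d_all <= d_obs + 1e-12)
  structure(list(coords = coords, physical = physical,
                 procrustes_d = d_obs, p_perm = p, perm_d = d_all,
                 allow_reflection = allow_reflection),
            class = "reconstruction_result")
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- t(apply(sub, 1, function(r) append(r, k, after = pos - 1L)))
    out <- rbind(out, block)
  }
  ## put the identity first
  id <- which(apply(out, 1, function(r) all(r == seq_len(k))))
  rbind(out[id, , drop = FALSE], out[-id, , drop = FALSE])
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("<reconstruction> d = %.4f, p_perm = %.4f (%d permutations%s)\n",
              x$procrustes_d, x$p_perm, length(x$perm_d),
              if (x$allow_reflection) ", reflection allowed" else ""))
  invisible(x)
}
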