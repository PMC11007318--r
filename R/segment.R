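#' Connectivity fingerprints and voxel-to-voxel similarity
#'
#' Each ROI voxel's fingerprint is its vector of correlations with the
#' dominant temporal components of the reference time series (SVD reduction
#' of the reference region); the ROI similarity matrix is the correlation
#' between fingerprints. GLM residual scans serve as a proxy for
#' resting-state data.
#'
#' @param roi_ts ROI voxels x time matrix (e.g. `t(residuals(fit))`).
#' @param reference_ts Reference voxels x time matrix (may be the ROI
#'   itself).
#' @param svd_rank Number of reference components to keep. Default 20.
#' @return A list with `similarity` (ROI voxel x ROI voxel) and
#'   `fingerprints`.
#' @export
fingerprints <- function(roi_ts, reference_ts, svd_rank = 20) {
  roi_ts <- as.matrix(roi_ts); reference_ts <- as.matrix(reference_ts)
  if (ncol(roi_ts) != ncol(reference_ts))
    stop("ROI and reference time axes do not match")
  if (any(apply(roi_ts, 1, sd) == 0) || any(apply(reference_ts, 1, sd) == 0))
    stop("constant time series in input")
  r <- min(svd_rank, nrow(reference_ts), ncol(reference_ts) - 1L)
  sv <- svd(scale(t(reference_ts)), nu = r, nv = 0)
  comp <- sv$u[, seq_len(r), drop = FALSE]      # time x components
  fp <- cor(t(roi_ts), comp)                    # voxels x components
  sim <- cor(t(fp))
  list(similarity = sim, fingerprints = fp)
}

## connected components of a nonnegative affinity matrix (edges where w > 0)
graph_components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Dominant functional-connectivity gradient
#'
#' Spectral embedding of the voxel similarity graph: negative similarities
#' are clipped to zero, the symmetric normalized graph Laplacian is formed,
#' and the eigenvector of the first nontrivial (second smallest) eigenvalue
#' — mapped back through `D^(-1/2)` — is the gradient. The sign is fixed so
#' the gradient correlates positively with `axis`.
#'
#' @param similarity Symmetric voxel similarity matrix.
#' @param axis Voxel coordinate axis used to orient the gradient (default
#'   voxel index).
#' @return A list of class `gradient_map`: `gradient`, `eigenvalues`,
#'   `portion_label` (filled by [partition_gradient()]).
#' @export
dominant_gradient <- function(similarity, axis = seq_len(nrow(similarity))) {
  W <- as.matrix(similarity)
  stopifnot(isSymmetric(unname(W), tol = 1e-8))
  W[W < 0] <- 0
  diag(W) <- 0
  if (max(graph_components(W)) > 1)
    stop("similarity graph is disconnected; no single dominant gradient")
  deg <- rowSums(W)
  dhalf <- 1 / sqrt(deg)
  L <- diag(nrow(W)) - dhalf * W * rep(dhalf, each = nrow(W))
  e <- eigen(L, symmetric = TRUE)
  idx <- ncol(W) - 1L                     # second-smallest eigenvalue
  g <- e$vectors[, idx] * dhalf           # random-walk eigenvector
  if (cor(g, axis) < 0) g <- -g
  structure(list(gradient = g, eigenvalues = rev(e$values),
                 portion_label = NULL), class = "gradient_map")
}

#' Partition a gradient into equally sized ordered portions
#'
#' Voxels are rank-ordered by gradient value (ties broken by voxel index)
#' and split into `n_portions` contiguous groups whose sizes differ by at
#' most one voxel.
#'
#' @param gradient A `gradient_map` or numeric gradient vector.
#' @param n_portions Number of portions. Default 10.
#' @return The `gradient_map` with `portion_label` filled (or, for a
#'   numeric input, the integer label vector).
#' @export
partition_gradient <- function(gradient, n_portions = 10) {
  g <- if (inherits(gradient, "gradient_map")) gradient$gradient else gradient
  n <- length(g)
  if (n_portions > n) stop("more portions than voxels")
  lab <- balanced_partition(order(g, seq_len(n)), as.integer(n_portions), n)
  if (inherits(gradient, "gradient_map")) {
    gradient$portion_label <- lab
    gradient
  } else lab
}
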