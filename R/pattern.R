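#' Collect adaptation vectors into an analysis set
#'
#' @param vectors List of voxel-wise adaptation vectors (as produced by
#'   [adaptation_vector()], or plain numeric vectors) sharing one voxel
#'   dimension and ordering.
#' @param info Optional data frame with one row per vector (`cue`, `day`,
#'   `environment`, `run`); taken from vector attributes when absent.
#' @return An object of class `adaptation_vectors`: `values` (voxels x
#'   vectors matrix) and `info`.
#' @export
adaptation_vectors <- function(vectors, info = NULL) {
  lens <- vapply(vectors, length, 0L)
  if (length(unique(lens)) != 1)
    stop("all adaptation vectors must share the voxel dimension")
  values <- vapply(vectors, as.numeric, numeric(lens[1]))
  if (is.null(info))
    info <- data.frame(
      cue = vapply(vectors, function(v) attr(v, "cue") %||% NA_character_, ""),
      day = vapply(vectors, function(v) as.integer(attr(v, "day") %||% NA), 0L),
      environment = vapply(vectors, function(v)
        attr(v, "environment") %||% NA_character_, ""),
      run = vapply(vectors, function(v) as.integer(attr(v, "run") %||% NA), 0L),
      stringsAsFactors = FALSE)
  stopifnot(nrow(info) == ncol(values))
  structure(list(values = values, info = info), class = "adaptation_vectors")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.adaptation_vectors <- function(x, ...) {
  cat(sprintf("<adaptation_vectors> %d voxels x %d vectors\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$info$cue, x$info$day))
  invisible(x)
}

#' Average out the environment factor
#'
#' Within each (cue, day) the two same-cue vectors from adjacent runs in
#' different environments (one per block) are averaged voxel-by-voxel,
#' dropping the environment label: 8 vectors per cue become 4.
#'
#' @param av An `adaptation_vectors` set with a `block` column (or `run`
#'   order from which blocks can be inferred: runs 1-4 = block 1,
#'   5-8 = block 2).
#' @return An `adaptation_vectors` set without the environment label.
#' @export
average_environments <- function(av) {
  stopifnot(inherits(av, "adaptation_vectors"))
  info <- av$info
  if (is.null(info$block)) info$block <- (info$run - 1L) %/% 4L + 1L
  key <- interaction(info$cue, info$day, info$block, drop = TRUE)
  vals <- list(); meta <- list()
  for (k in levels(key)) {
    sel <- which(key == k)
    if (length(sel) != 2 || length(unique(info$environment[sel])) != 2)
      stop("unpaired adaptation vector in (cue, day, block) group ", k)
    vals[[k]] <- rowMeans(av$values[, sel, drop = FALSE])
    meta[[k]] <- data.frame(cue = info$cue[sel[1]], day = info$day[sel[1]],
                            environment = NA_character_,
                            run = NA_integer_, block = info$block[sel[1]],
                            stringsAsFactors = FALSE)
  }
  structure(list(values = do.call(cbind, vals), info = do.call(rbind, meta)),
            class = "adaptation_vectors")
}

#' Pairwise Fisher-z similarity table
#'
#' Pearson correlations between all unordered pairs of adaptation vectors
#' (no self-pairs; cross-validation holds because every vector comes from a
#' different run), Fisher transformed before any averaging, and labeled by
#' cue relation and day relation.
#'
#' @param av An `adaptation_vectors` set (at least 2 vectors per cue).
#' @return A data frame of class `similarity_table` with one row per pair:
#'   `i`, `j`, `r`, `z`, `cue_relation`, `day_relation`, and
#'   `environment_relation` when environments are resolved.
#' @export
similarity_table <- function(av) {
  stopifnot(inherits(av, "adaptation_vectors"))
  info <- av$info
  m <- ncol(av$values)
  if (m < 2) stop("need at least two adaptation vectors")
  pairs <- combn(m, 2)
  flat <- apply(av$values, 2, sd) == 0
  if (any(flat))
    warning("zero-variance adaptation vector(s); ",
            "pairs involving them are skipped")
  rows <- list()
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    if (flat[i] || flat[j]) next
    vi <- av$values[, i]; vj <- av$values[, j]
    r <- cor(vi, vj)
    rows[[p]] <- data.frame(
      i = i, j = j, r = r, z = atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)),
      cue_relation = if (info$cue[i] == info$cue[j]) "within" else "between",
      day_relation = if (info$day[i] == info$day[j]) "within" else "between",
      environment_relation =
        if (!all(is.na(info$environment[c(i, j)])))
          ifelse(info$environment[i] == info$environment[j],
                 "within", "between") else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("similarity_table", "data.frame")
  out
}

#' Adaptation-pattern distinction score
#'
#' Mean within-cue minus mean between-cue Fisher-z similarity, reported
#' separately for within-day and between-day pairings. A positive score
#' means the voxel-to-voxel adaptation pattern differs between cue types.
#'
#' @param table A [similarity_table()].
#' @return A data frame with one row per day relation: `day_relation`,
#'   `within_cue_z`, `between_cue_z`, `score`.
#' @export
distinction <- function(table) {
  stopifnot(inherits(table, "similarity_table") || is.data.frame(table))
  out <- lapply(unique(table$day_relation), function(dr) {
    sub <- table[table$day_relation == dr, ]
    wz <- sub$z[sub$cue_relation == "within"]
    bz <- sub$z[sub$cue_relation == "between"]
    if (!length(wz) || !length(bz))
      stop("empty cue-relation stratum for day relation '", dr, "'")
    data.frame(day_relation = dr, within_cue_z = mean(wz),
               between_cue_z = mean(bz), score = mean(wz) - mean(bz),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Jackknife contribution of voxel portions to the distinction score
#'
#' Recomputes the within-day adaptation-pattern distinction score with each
#' of the 10 voxel portions left out; comparable scores across left-out
#' portions indicate spatially distributed cue-specific coding.
#'
#' @param av An `adaptation_vectors` set (environment-averaged or not).
#' @param portion_labels Integer vector over voxels partitioning them into
#'   nonempty groups (typically 1-10).
#' @return Named numeric vector: within-day distinction score per left-out
#'   portion.
#' @export
jackknife_portions <- function(av, portion_labels) {
  stopifnot(inherits(av, "adaptation_vectors"),
            length(portion_labels) == nrow(av$values))
  portions <- sort(unique(portion_labels))
  if (any(tabulate(factor(portion_labels)) == 0))
    stop("portion labels must partition the voxels into nonempty groups")
  out <- vapply(portions, function(p) {
    keep <- portion_labels != p
    if (!any(keep)) stop("a portion covers all voxels")
    sub <- structure(list(values = av$values[keep, , drop = FALSE],
                          info = av$info), class = "adaptation_vectors")
    d <- distinction(similarity_table(sub))
    d$score[d$day_relation == "within"]
  }, numeric(1))
  names(out) <- paste0("portion", portions)
  out
}

#' Environment distinction score per cue type
#'
#' Within-environment minus between-environment mean Fisher-z similarity
#' among same-cue, within-day pairs of environment-resolved vectors;
#' positive scores indicate environment-specific adaptation patterns.
#'
#' @param av An `adaptation_vectors` set with environments resolved (not
#'   averaged).
#' @return Data frame with one row per cue: `cue`, `within_env_z`,
#'   `between_env_z`, `score`.
#' @export
environment_distinction <- function(av) {
  stopifnot(inherits(av, "adaptation_vectors"))
  if (length(unique(stats::na.omit(av$info$environment))) < 2)
    stop("need vectors from both environments")
  tab <- similarity_table(av)
  tab <- tab[tab$cue_relation == "within" & tab$day_relation == "within", ]
  out <- lapply(unique(av$info$cue), function(cue) {
    sel <- tab[av$info$cue[tab$i] == cue, ]
    wz <- sel$z[sel$environment_relation == "within"]
    bz <- sel$z[sel$environment_relation == "between"]
    if (!length(wz) || !length(bz))
      stop("missing environment-relation stratum for cue ", cue)
    data.frame(cue = cue, within_env_z = mean(wz), between_env_z = mean(bz),
               score = mean(wz) - mean(bz), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
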