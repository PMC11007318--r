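#' Geometry of the linear track
#'
#' The virtual environment is a linear track with four test locations at a
#' fixed spacing, an arrow set anchoring path integration at 0 m, and a tree
#' anchoring landmark-based navigation beyond the far end of the track.
#'
#' @param location_positions Numeric, strictly increasing coordinates (m) of
#'   the test locations. Default `c(4, 8, 12, 16)` so all passive movement is
#'   in +x from starting positions sampled in `[-18, -4]` m.
#' @param arrow_position Position (m) of the arrow anchor. Default 0.
#' @param tree_position Position (m) of the tree anchor, beyond the last
#'   location. Default 20.
#' @return An object of class `track_layout`.
#' @export
#' @examples
#' track_layout()
track_layout <- function(location_positions = c(4, 8, 12, 16),
                         arrow_position = 0, tree_position = 20) {
  stopifnot(length(location_positions) >= 2, is.numeric(location_positions))
  d <- diff(location_positions)
  if (any(d <= 0)) stop("location positions must be strictly increasing")
  if (max(d) - min(d) > 1e-9) stop("locations must be evenly spaced")
  structure(list(location_positions = as.numeric(location_positions),
                 arrow_position = arrow_position,
                 tree_position = tree_position,
                 spacing = d[1]),
            class = "track_layout")
}

#' @export
print.track_layout <- function(x, ...) {
  cat("<track_layout> locations at",
      paste(x$location_positions, collapse = ", "),
      "m; arrows", x$arrow_position, "m; tree", x$tree_position, "m\n")
  invisible(x)
}

default_labels <- function(k) {
  if (k == 5) c(paste0("loc", 1:4), "null") else LETTERS[seq_len(k)]
}

#' Generate a second-order counterbalanced (de Bruijn) event sequence
#'
#' Produces a cyclic sequence of length `k^2` over `k` event types in which
#' every ordered pair of types (including repeats) occurs exactly once —
#' the property that balances first-order carry-over and makes sequential
#' (adaptation) effects estimable. Sampling is by Hierholzer's algorithm with
#' randomized edge choice on the complete transition multigraph, i.e. a
#' random Eulerian circuit.
#'
#' @param k_types Number of event types (default 5: four locations plus a
#'   null event).
#' @param order Counterbalancing order; only 2 is supported.
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @param labels Optional character labels for the types.
#' @return An object of class `event_sequence` with elements `events`
#'   (integer vector of length `k_types^2`), `labels`, and `k`.
#' @export
#' @examples
#' s <- generate_debruijn(5, seed = 1)
#' length(s$events)        # 25
#' table(s$events)         # five repetitions of each type
generate_debruijn <- function(k_types = 5, order = 2, seed = NULL,
                              labels = default_labels(k_types)) {
  if (!identical(as.integer(order), 2L))
    stop("unsupported counterbalancing order: only order = 2 is implemented")
  k <- as.integer(k_types)
  if (is.na(k) || k < 2) stop("k_types must be >= 2")
  if (length(labels) != k) stop("need one label per event type")
  if (!is.null(seed)) set.seed(seed)

  ## adjacency: from every node, one edge to every node (self-loops included)
  adj <- lapply(seq_len(k), function(i) sample.int(k))
  ptr <- rep(1L, k)
  stack <- c(1L)
  circuit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    if (ptr[v] <= k) {
      u <- adj[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
      stack <- c(stack, u)
    } else {
      circuit <- c(circuit, v)
      stack <- stack[-length(stack)]
    }
  }
  circuit <- rev(circuit)           # node walk of length k^2 + 1, closed
  events <- circuit[-1L]            # cyclic symbol sequence of length k^2
  structure(list(events = events, labels = labels, k = k),
            class = "event_sequence")
}

#' @export
print.event_sequence <- function(x, ...) {
  cat("<event_sequence> k =", x$k, "| length", length(x$events),
      if (!is.null(x$presented)) sprintf("| presented %d", length(x$presented)),
      "\n ", paste(x$labels[x$events], collapse = " "), "\n")
  invisible(x)
}

#' Duplicate the final event at the front of a sequence
#'
#' The realized run prepends a copy of the last event so that the
#' hemodynamic response reaches a steady state before the cyclic sequence
#' starts; the duplicated trial is modeled in first-level GLMs but excluded
#' from effective-trial counts.
#'
#' @param seq An `event_sequence`.
#' @return The sequence with a `presented` element (length `k^2 + 1`) and an
#'   `is_duplicate` logical flag aligned with `presented`.
#' @export
prepend_duplicate <- function(seq) {
  stopifnot(inherits(seq, "event_sequence"))
  if (length(seq$events) == 0) stop("cannot duplicate the final event of an empty sequence")
  seq$presented <- c(seq$events[length(seq$events)], seq$events)
  seq$is_duplicate <- c(TRUE, rep(FALSE, length(seq$events)))
  seq
}

#' Count cyclic ordered-pair occurrences in a sequence
#'
#' Brute-force tally of all ordered type pairs read cyclically; for a valid
#' second-order counterbalanced sequence every count is exactly 1.
#'
#' @param events Integer (or factor-coded) event vector.
#' @param k Number of types.
#' @return A `k x k` matrix of pair counts (row = preceding type).
#' @export
pair_counts <- function(events, k = max(events)) {
  m <- matrix(0L, k, k)
  n <- length(events)
  for (t in seq_len(n)) {
    a <- events[t]
    b <- events[if (t == n) 1L else t + 1L]
    m[a, b] <- m[a, b] + 1L
  }
  m
}

#' Plan scanning sessions as Latin-square-style run orders
#'
#' Each session contains `n_blocks_per_session` blocks of the four condition
#' combinations (2 cues x 2 environments), in a randomized order with no
#' combination repeated in consecutive runs within a session.
#'
#' @param n_sessions Number of scanning sessions (days). Default 2.
#' @param n_blocks_per_session Blocks of 4 runs per session. Default 2.
#' @param seed Integer seed.
#' @return A data frame with one row per run: `session_day`, `block`,
#'   `run_index` (within session), `cue`, `environment`.
#' @export
plan_sessions <- function(n_sessions = 2, n_blocks_per_session = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  combos <- expand.grid(cue = c("landmark", "self_motion"),
                        environment = c("city", "nature"),
                        stringsAsFactors = FALSE)
  out <- list()
  for (s in seq_len(n_sessions)) {
    order <- integer(0)
    for (b in seq_len(n_blocks_per_session)) {
      repeat {
        perm <- sample.int(4L)
        if (!length(order) || order[length(order)] != perm[1L]) break
      }
      order <- c(order, perm)
    }
    out[[s]] <- data.frame(session_day = s,
                           block = rep(seq_len(n_blocks_per_session), each = 4L),
                           run_index = seq_along(order),
                           cue = combos$cue[order],
                           environment = combos$environment[order],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Realize trial timing and kinematics for one run
#'
#' Turns a presented event sequence into a run with onsets and phase
#' durations. Each location trial has six phases: start (0.7 s), passive
#' movement (path length / speed), arrival (camera pan-down), location
#' occupation (4 s), response, and feedback. Start positions are drawn from
#' U\[-18, -4\] m and movement speeds from U\[2, 5\] m/s per trial. Null
#' events are a fixation of `null_duration` seconds.
#'
#' @param seq An `event_sequence`; the `presented` list is used if present
#'   (see [prepend_duplicate()]), else the base sequence.
#' @param layout A [track_layout()].
#' @param cue `"landmark"` or `"self_motion"`.
#' @param environment `"city"` or `"nature"`.
#' @param session_day,run_index Metadata carried on the run.
#' @param seed Integer seed; realization is deterministic given `seed`.
#' @param start_range,speed_range Uniform sampling ranges for the start
#'   position (m) and movement speed (m/s).
#' @param phase_durations Named list of the fixed phase durations (s):
#'   `start` 0.7, `arrival` 2, `occupation` 4, `response` 2, `feedback` 1.
#' @param null_duration Fixation duration (s) of null events. Default 4,
#'   matching the occupation duration.
#' @return An object of class `run_spec`: a list with `events` (data frame,
#'   one row per presented event), `cue`, `environment`, `session_day`,
#'   `run_index`, and `layout`.
#' @export
realize_timing <- function(seq, layout, cue = "landmark",
                           environment = "city", session_day = 1L,
                           run_index = 1L, seed = NULL,
                           start_range = c(-18, -4), speed_range = c(2, 5),
                           phase_durations = list(start = 0.7, arrival = 2,
                                                  occupation = 4, response = 2,
                                                  feedback = 1),
                           null_duration = 4) {
  stopifnot(inherits(seq, "event_sequence"), inherits(layout, "track_layout"))
  if (!is.null(seed)) set.seed(seed)
  events <- if (!is.null(seq$presented)) seq$presented else seq$events
  is_dup <- if (!is.null(seq$is_duplicate)) seq$is_duplicate else rep(FALSE, length(events))
  lab <- seq$labels[events]
  n_loc <- length(layout$location_positions)
  is_null <- events > n_loc      # the null type is coded after the locations
  pd <- phase_durations

  n <- length(events)
  onset <- numeric(n); movement_duration <- rep(NA_real_, n)
  occupation_onset <- rep(NA_real_, n)
  start_position <- rep(NA_real_, n); speed <- rep(NA_real_, n)
  path_length <- rep(NA_real_, n); duration <- numeric(n)
  t <- 0
  for (i in seq_len(n)) {
    onset[i] <- t
    if (is_null[i]) {
      duration[i] <- null_duration
    } else {
      x <- layout$location_positions[events[i]]
      sp <- runif(1, start_range[1], start_range[2])
      v <- runif(1, speed_range[1], speed_range[2])
      if (x <= sp) stop("location coordinate must exceed the start position")
      start_position[i] <- sp; speed[i] <- v
      path_length[i] <- x - sp
      movement_duration[i] <- path_length[i] / v
      occupation_onset[i] <- t + pd$start + movement_duration[i] + pd$arrival
      duration[i] <- pd$start + movement_duration[i] + pd$arrival +
        pd$occupation + pd$response + pd$feedback
    }
    t <- t + duration[i]
  }
  ev <- data.frame(event_type = lab, type_index = events,
                   is_duplicate = is_dup, is_null = is_null,
                   onset = onset, duration = duration,
                   occupation_onset = occupation_onset,
                   occupation_duration = ifelse(is_null, NA_real_, pd$occupation),
                   movement_onset = ifelse(is_null, NA_real_, onset + pd$start),
                   movement_duration = movement_duration,
                   start_position = start_position, speed = speed,
                   path_length = path_length,
                   response = NA_character_, correct = NA,
                   stringsAsFactors = FALSE)
  structure(list(events = ev, cue = cue, environment = environment,
                 session_day = session_day, run_index = run_index,
                 layout = layout, phase_durations = pd,
                 total_duration = t),
            class = "run_spec")
}

#' @export
print.run_spec <- function(x, ...) {
  cat(sprintf("<run_spec> day %d run %d | cue %s | env %s | %d events (%d effective) | %.0f s\n",
              x$session_day, x$run_index, x$cue, x$environment,
              nrow(x$events), sum(effective_trials(x)), x$total_duration))
  invisible(x)
}

#' Logical mask of effective trials in a run
#'
#' Effective trials are location events that are neither null events nor the
#' duplicated initial event; for the standard 5-type sequence there are 20
#' per run, 5 per location.
#'
#' @param run A `run_spec`.
#' @return Logical vector over the run's presented events.
#' @export
effective_trials <- function(run) {
  stopifnot(inherits(run, "run_spec"))
  !run$events$is_null & !run$events$is_duplicate
}

#' Convenience constructor for a fully realized run
#'
#' Generates a sequence, prepends the duplicate, and realizes timing.
#'
#' @inheritParams realize_timing
#' @param seed Integer seed used for both the sequence and the timing draws.
#' @export
generate_run <- function(layout = track_layout(), cue = "landmark",
                         environment = "city", session_day = 1L,
                         run_index = 1L, seed = NULL, ...) {
  s <- generate_debruijn(5, seed = seed)
  s <- prepend_duplicate(s)
  realize_timing(s, layout, cue = cue, environment = environment,
                 session_day = session_day, run_index = run_index,
                 seed = if (is.null(seed)) NULL else seed + 1L, ...)
}

glm_efficiency <- function(X, column) {
  keep <- colnames(X) == column
  if (!any(keep)) stop("no such design column: ", column)
  cvec <- as.numeric(keep)
  if (all(abs(X[, keep]) < 1e-12)) return(0)
  XtX <- crossprod(X)
  q <- qr(XtX)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[seq.int(q$rank + 1L, ncol(X))]]
    stop("singular design; collinear columns: ", paste(bad, collapse = ", "))
  }
  1 / drop(t(cvec) %*% solve(XtX, cvec))
}

#' Relative detection power of a realized design
#'
#' GLM efficiency of a named parametric contrast — the inverse variance of
#' its OLS estimator under the run's design matrix — expressed as a
#' percentile against the efficiency distribution of freshly generated
#' candidate sequences realized with the same timing statistics.
#'
#' @param run A realized `run_spec` (with responses, for
#'   `contrast = "response"`).
#' @param contrast One of `"location_distance"`, `"location_identity"`,
#'   `"path_length"`, `"response"`.
#' @param candidates Number of candidate designs for normalization.
#' @param seed Integer seed driving candidate generation.
#' @param tr Repetition time (s) of the sampled design.
#' @return A list of class `design_power`: `dp_rel` (percent in \[0, 100\]),
#'   `efficiency`, and `reference` (candidate efficiencies).
#' @export
relative_detection_power <- function(run, contrast = c("location_distance",
                                                       "location_identity",
                                                       "path_length",
                                                       "response"),
                                     candidates = 100, seed = 1L, tr = 2) {
  contrast <- match.arg(contrast)
  kind <- switch(contrast, location_distance = "distance",
                 location_identity = "identity",
                 path_length = "path_length", response = "response")
  eff_of <- function(r) {
    mod <- build_modulator(r, kind)
    if (all(abs(mod$values - mean(mod$values)) < 1e-12)) return(0)
    X <- build_design(r, modulators = list(mod), tr = tr)$X
    glm_efficiency(X, paste0("mod_", kind))
  }
  observed <- eff_of(run)
  ref <- vapply(seq_len(candidates), function(i) {
    r <- generate_run(run$layout, cue = run$cue, environment = run$environment,
                      seed = seed * 1000L + i)
    if (kind == "response")
      r <- simulate_behavior(r, seed = seed * 1000L + i + 500000L)
    eff_of(r)
  }, numeric(1))
  dp <- if (observed == 0) 0 else 100 * mean(ref <= observed)
  structure(list(dp_rel = dp, efficiency = observed, reference = ref,
                 contrast = contrast), class = "design_power")
}

#' Write a run's events as a BIDS-style TSV
#'
#' @param run A `run_spec`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(run, path) {
  ev <- run$events
  out <- data.frame(onset = ev$onset, duration = ev$duration,
                    trial_type = ev$event_type, cue = run$cue,
                    environment = run$environment,
                    location = ifelse(ev$is_null, NA_real_,
                                      run$layout$location_positions[ev$type_index]),
                    start_position = ev$start_position, speed = ev$speed,
                    path_length = ev$path_length, response = ev$response,
                    correct = ev$correct, is_duplicate = ev$is_duplicate)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}

#' Read a BIDS-style events TSV written by [write_events_tsv()]
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                    stringsAsFactors = FALSE)
}
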