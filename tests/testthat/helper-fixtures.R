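# shared fixtures, built lazily and cached for the session

.cache <- new.env()

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# hand-crafted event sequence (bypasses the generator)
make_sequence <- function(events, k = max(events),
                          labels = if (k == 5) c(paste0("loc", 1:4), "null")
                                   else paste0("loc", seq_len(k))) {
  structure(list(events = as.integer(events), labels = labels, k = k),
            class = "event_sequence")
}

zero_noise <- function() noise_model(white_sd = 0, drift_sd = 0,
                                     motion_amplitude = 0)

# a realized noiseless run + population + bold, reused across GLM tests
tiny_world <- function() cached("tiny_world", {
  run <- generate_run(seed = 7, cue = "self_motion")
  pop <- sample_population(15, seed = 8)
  bold <- synthesize_bold(run, pop, zero_noise(), seed = 9)
  list(run = run, pop = pop, bold = bold)
})

# synthetic adaptation-vector sets built directly from patterns + noise
make_vectors <- function(n_voxels, patterns, noise_sd, seed,
                         cues = c("landmark", "self_motion"),
                         days = 1:2, blocks = 1:2,
                         envs = c("city", "nature")) {
  set.seed(seed)
  vecs <- list(); info <- list(); idx <- 0
  for (day in days) for (block in blocks) for (cue in cues) for (env in envs) {
    idx <- idx + 1
    true <- if (is.list(patterns[[cue]])) patterns[[cue]][[env]]
            else patterns[[cue]]
    vecs[[idx]] <- true + rnorm(n_voxels, 0, noise_sd)
    info[[idx]] <- data.frame(cue = cue, day = day, environment = env,
                              run = (block - 1L) * 4L + idx %% 4L + 1L,
                              block = block, stringsAsFactors = FALSE)
  }
  adaptation_vectors(vecs, do.call(rbind, info))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
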