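# cohort-level summaries for the acceptance battery, cached across test
# blocks; one cohort = 20 participants x 16 runs x 200 voxels under the
# default study conditions

acceptance_cohort <- function(seed) cached(paste0("cohort_", seed), {
  cfg <- study_config(master_seed = seed)
  joint <- list(); roi <- list(); scores <- list(); cells <- list()
  for (pid in seq_len(cfg$n_participants)) {
    part <- simulate_participant(cfg, pid)
    fit <- analyze_participant(part, joint = TRUE, cells = TRUE)
    roi[[pid]] <- aggregate(beta ~ cue, fit$roi, mean)
    joint[[pid]] <- aggregate(cbind(distance, identity) ~ cue, fit$joint, mean)
    d <- distinction(similarity_table(average_environments(fit$vectors)))
    scores[[pid]] <- c(score = d$score[d$day_relation == "within"],
                       between_cue_z = d$between_cue_z[d$day_relation == "within"])
    cells[[pid]] <- fit$cells
  }
  list(roi = do.call(rbind, roi), joint = do.call(rbind, joint),
       scores = do.call(rbind, scores), cells = do.call(rbind, cells))
})

shared_map_cohort <- function(seed) cached(paste0("shared_", seed), {
  # cue-shared regime: identical suppression maps and equal (broad) tuning
  # for both cues, distance modulator throughout
  cfg <- study_config(master_seed = seed, cue_specific = FALSE,
                      sigma_landmark = 6,
                      env_specific = c(landmark = FALSE, self_motion = FALSE),
                      modulator_by_cue = c(landmark = "distance",
                                           self_motion = "distance"))
  t(vapply(seq_len(cfg$n_participants), function(pid) {
    part <- simulate_participant(cfg, pid)
    fit <- analyze_participant(part, joint = FALSE, cells = FALSE)
    d <- distinction(similarity_table(average_environments(fit$vectors)))
    c(score = d$score[d$day_relation == "within"],
      between_cue_z = d$between_cue_z[d$day_relation == "within"])
  }, numeric(2)))
})

cohort_group_tests <- function(co) {
  lm_id <- one_sample_t(winsorize(co$roi$beta[co$roi$cue == "landmark"])$values,
                        tail = "greater")
  sm_gr <- one_sample_t(winsorize(co$roi$beta[co$roi$cue == "self_motion"])$values,
                        tail = "greater")
  dist_unique <- one_sample_t(
    winsorize(co$joint$distance[co$joint$cue == "landmark"])$values,
    tail = "greater")
  recon <- lapply(c("landmark", "self_motion"), function(cu)
    procrustes_test(embed_1d(neural_distances(
      co$cells[co$cells$cue == cu, ]))))
  names(recon) <- c("landmark", "self_motion")
  list(lm_identity_p = lm_id$p, sm_graded_p = sm_gr$p,
       lm_distance_unique_p = dist_unique$p,
       recon_lm_p = recon$landmark$p_perm,
       recon_sm_p = recon$self_motion$p_perm)
}
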