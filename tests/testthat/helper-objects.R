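# Small builders shared across test files.

# Rating matrix from a plain matrix, raw continuous scale.
rm_raw <- function(values, domain = "art", scale = "raw_monetary") {
  values <- as.matrix(values)
  rating_matrix(values,
                item_ids = sprintf("i%02d", seq_len(nrow(values))),
                participant_ids = sprintf("P%02d", seq_len(ncol(values))),
                domain = domain, scale = scale)
}

# Similarity matrix object with prescribed values (bypasses estimation).
sim_from <- function(values, domain = "art") {
  values <- as.matrix(values)
  pid <- sprintf("P%02d", seq_len(ncol(values)))
  dimnames(values) <- list(pid, pid)
  structure(list(values = values, participant_ids = pid, domain = domain),
            class = "similarity_matrix")
}

# SLIM weights object with prescribed values.
weights_from <- function(values, domain = "art") {
  values <- as.matrix(values)
  pid <- sprintf("P%02d", seq_len(ncol(values)))
  dimnames(values) <- list(pid, pid)
  structure(list(values = values, participant_ids = pid,
                 source_domain = domain, beta = 0, lam = 0),
            class = "slim_weights")
}

# A small fast study configuration used by pipeline-level tests.
small_cfg <- function(seed = 1L) {
  study_config(beta_grid = 10^c(-2, 0, 2), lam_grid = 10^c(-3, -1),
               grid_repeats = 3L, permutation_B = 200L,
               ablation_sizes = c(5L, 8L), ablation_repeats = 3L,
               seed = seed)
}

# A small synthetic cohort (12 participants) for pipeline-level tests.
small_cohort <- function(seed = 1L, consistency = 0.7, gender_strength = 0.3,
                         noise_sd = 0.3) {
  synthetic_config(n_participants = 12L, n_male = 4L,
                   items_per_domain = c(art = 60L, face_male = 40L,
                                        face_female = 40L, scene = 80L),
                   rank_block = 40L, consistency = consistency,
                   gender_strength = gender_strength, noise_sd = noise_sd,
                   seed = seed)
}
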