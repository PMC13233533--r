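# Condition orchestration: within/cross-domain runs, cohort-size ablation,
# gender-stratified conditions, and the full study driver.

#' Study configuration
#'
#' Bundles every tunable of the analysis pipeline. Defaults follow the study
#' protocol the package models: 75/25 item splits, decade-spaced penalty
#' grids (beta over 1e-4..1e12, lambda over 1e-3..1e2), 20 half-split
#' validation repeats, 1000 permutations, and ablation cohort sizes
#' 5/10/20/30. All randomness flows from the single `seed`.
#'
#' @param domains domain labels to include.
#' @param split_fraction test fraction of the item split.
#' @param beta_grid,lam_grid SLIM penalty grids.
#' @param grid_repeats half-split validation repeats per pair.
#' @param grid_metric `"fisher_r"` or `"mse"`.
#' @param permutation_B permutation count.
#' @param ablation_sizes cohort sizes for the participant ablation.
#' @param ablation_repeats seeded subsamples per ablation size.
#' @param synthetic a [synthetic_config()] used when no data are supplied.
#' @param seed master integer seed.
#' @return object of class `study_config`.
#' @export
study_config <- function(domains = c("art", "face_male", "face_female", "scene"),
                         split_fraction = 0.25,
                         beta_grid = 10^seq(-4, 12),
                         lam_grid = 10^seq(-3, 2),
                         grid_repeats = 20L,
                         grid_metric = "fisher_r",
                         permutation_B = 1000L,
                         ablation_sizes = c(5L, 10L, 20L, 30L),
                         ablation_repeats = 20L,
                         synthetic = synthetic_config(),
                         seed = 1L) {
  structure(list(domains = domains, split_fraction = split_fraction,
                 beta_grid = beta_grid, lam_grid = lam_grid,
                 grid_repeats = as.integer(grid_repeats),
                 grid_metric = grid_metric,
                 permutation_B = as.integer(permutation_B),
                 ablation_sizes = as.integer(ablation_sizes),
                 ablation_repeats = as.integer(ablation_repeats),
                 synthetic = synthetic, seed = as.integer(seed)),
            class = "study_config")
}

# Resolve a condition label to a normalized rating matrix. "face" means the
# concatenation of the male and female face subsets.
resolve_domain <- function(ratings, label) {
  if (label %in% names(ratings)) return(ratings[[label]])
  if (label == "face" && all(c("face_male", "face_female") %in% names(ratings)))
    return(bind_items(ratings[["face_male"]], ratings[["face_female"]],
                      domain = "face"))
  stop("unknown domain '", label, "'; available: ",
       paste(names(ratings), collapse = ", "), call. = FALSE)
}

#' Run one (source, target) prediction condition
#'
#' The pipeline for a single cell of the study design: split the source
#' domain's items 75/25, tune (beta, lambda) by half-split grid search on the
#' source training items, fit the SLIM weights on those items, predict the
#' target domain's held-out test items, and evaluate. Within-domain
#' conditions (`source == target`) share one split, so the evaluated items
#' were never seen during fitting; cross-domain conditions split each domain
#' independently. The label `"face"` denotes the combined male + female face
#' subsets.
#'
#' @param source,target domain labels.
#' @param data list with `ratings` (named list of normalized
#'   [rating_matrix()]) and optionally `cohort`.
#' @param cfg a [study_config()].
#' @return object of class `condition_result`: `report`
#'   ([evaluate()] output), `grid` ([grid_search()] output), `weights`,
#'   `provenance`.
#' @export
run_condition <- function(source, target, data, cfg = study_config()) {
  seeds <- derive_seeds(cfg$seed, 3L)
  src_rm <- resolve_domain(data$ratings, source)
  within <- identical(source, target)
  tgt_rm <- if (within) src_rm else resolve_domain(data$ratings, target)
  src_split <- split_items(src_rm, cfg$split_fraction, seeds[1])
  tgt_split <- if (within) src_split
               else split_items(tgt_rm, cfg$split_fraction, seeds[2])
  train_rm <- subset_items(src_rm, src_split$train_items)
  gs <- grid_search(train_rm, cfg$beta_grid, cfg$lam_grid,
                    repeats = cfg$grid_repeats, seed = seeds[3],
                    metric = cfg$grid_metric)
  pred <- predict_slim(gs$weights, tgt_rm, tgt_split$test_items)
  pred$condition$source_domain <- source
  pred$condition$target_domain <- target
  report <- evaluate(pred, tgt_rm)
  structure(list(report = report, grid = gs, weights = gs$weights,
                 prediction = pred,
                 provenance = list(source = source, target = target,
                                   master_seed = cfg$seed,
                                   split_seeds = seeds[1:2],
                                   grid_seed = seeds[3],
                                   split_fraction = cfg$split_fraction,
                                   best_beta = gs$best_beta,
                                   best_lam = gs$best_lam)),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Cohort-size ablation of cross-domain transfer
#'
#' For each cohort size, draws `repeats` seeded participant subsamples,
#' reruns the full cross-domain condition (grid search included) inside the
#' subsample, and averages the resulting group correlations. Shows how
#' transfer accuracy depends on the density of the inter-subject similarity
#' space.
#'
#' @param data as in [run_condition()].
#' @param cfg a [study_config()].
#' @param source,target domain labels (default face -> art).
#' @param sizes cohort sizes (each between 3 and the cohort size).
#' @param repeats subsamples per size.
#' @param seed integer seed for the subsampling.
#' @return data.frame with columns `size`, `mean_group_r`, `sd_group_r`,
#'   `repeats`.
#' @export
run_ablation <- function(data, cfg = study_config(), source = "face",
                         target = "art", sizes = cfg$ablation_sizes,
                         repeats = cfg$ablation_repeats, seed = cfg$seed) {
  all_ids <- data$ratings[[1]]$participant_ids
  n <- length(all_ids)
  if (any(sizes < 3L)) stop("run_ablation: sizes must be >= 3", call. = FALSE)
  if (any(sizes > n))
    stop("run_ablation: size exceeds cohort size ", n, call. = FALSE)
  sub_seeds <- matrix(derive_seeds(seed, length(sizes) * repeats),
                      nrow = length(sizes))
  rows <- lapply(seq_along(sizes), function(si) {
    rs <- vapply(seq_len(repeats), function(rep) {
      ids <- with_seed(sub_seeds[si, rep],
                       sample(all_ids, sizes[si]))
      sub <- list(ratings = lapply(data$ratings, subset_participants,
                                   participants = ids),
                  cohort = data$cohort)
      run_condition(source, target, sub, cfg)$report$group_r
    }, numeric(1))
    data.frame(size = sizes[si], mean_group_r = mean(rs),
               sd_group_r = stats::sd(rs), repeats = repeats)
  })
  do.call(rbind, rows)
}

#' Gender-stratified prediction conditions
#'
#' Implements the 2 x 2 x 2 design crossing participant group (male, female)
#' with the face subset used for training (same-gender vs opposite-gender
#' faces) and the prediction target (art, scene). Weights are fit on the full
#' cohort's responses to the designated face subset; evaluation is restricted
#' to the participant group. Same-vs-opposite paired t-tests are computed per
#' group and target on the Fisher-transformed per-participant correlations
#' and on the per-participant MSEs.
#'
#' @param data list with normalized `ratings` (including `face_male` and
#'   `face_female`) and a `cohort` with gender labels.
#' @param cfg a [study_config()].
#' @param targets prediction targets (default art and scene).
#' @return list with `table` (8-row data.frame: group, condition, source,
#'   target, group_r, mse, n_participants), `paired` (t-tests), and
#'   `reports` (the underlying evaluation reports, keyed
#'   `group.condition.target`).
#' @export
run_gender_conditions <- function(data, cfg = study_config(),
                                  targets = c("art", "scene")) {
  ch <- data$cohort
  if (is.null(ch)) stop("run_gender_conditions: cohort with gender labels ",
                        "required", call. = FALSE)
  groups <- list(male = ch$participant_id[ch$gender == "male"],
                 female = ch$participant_id[ch$gender == "female"])
  for (g in names(groups))
    if (length(groups[[g]]) < 3L)
      stop("run_gender_conditions: fewer than 3 ", g, " participants",
           call. = FALSE)
  face_of <- function(group, condition) {
    if (condition == "same") {
      if (group == "male") "face_male" else "face_female"
    } else {
      if (group == "male") "face_female" else "face_male"
    }
  }
  seeds <- derive_seeds(cfg$seed, 2L + length(targets))
  # one grid-search fit per face subset, shared across groups and targets
  fits <- lapply(stats::setNames(nm = c("face_male", "face_female")),
                 function(fd) {
    grid_search(data$ratings[[fd]], cfg$beta_grid, cfg$lam_grid,
                repeats = cfg$grid_repeats,
                seed = seeds[if (fd == "face_male") 1L else 2L],
                metric = cfg$grid_metric)
  })
  tgt_splits <- lapply(seq_along(targets), function(i)
    split_items(data$ratings[[targets[i]]], cfg$split_fraction, seeds[2L + i]))
  names(tgt_splits) <- targets
  design <- expand.grid(group = c("male", "female"),
                        condition = c("same", "opposite"),
                        target = targets, stringsAsFactors = FALSE)
  reports <- list()
  rows <- lapply(seq_len(nrow(design)), function(i) {
    group <- design$group[i]; condition <- design$condition[i]
    target <- design$target[i]
    fd <- face_of(group, condition)
    pred <- predict_slim(fits[[fd]]$weights, data$ratings[[target]],
                         tgt_splits[[target]]$test_items)
    pred$condition$source_domain <- fd
    rep_ <- evaluate(pred, data$ratings[[target]],
                     participants = groups[[group]])
    reports[[paste(group, condition, target, sep = ".")]] <<- rep_
    data.frame(group = group, condition = condition, source = fd,
               target = target, group_r = rep_$group_r, mse = rep_$mse,
               n_participants = length(groups[[group]]))
  })
  tbl <- do.call(rbind, rows)
  paired <- list()
  for (group in c("male", "female")) for (target in targets) {
    same <- reports[[paste(group, "same", target, sep = ".")]]
    opp <- reports[[paste(group, "opposite", target, sep = ".")]]
    tt_r <- paired_ttest(fisher_z(same$per_participant_r),
                         fisher_z(opp$per_participant_r))
    tt_mse <- paired_ttest(same$per_participant_mse, opp$per_participant_mse)
    paired[[length(paired) + 1L]] <- data.frame(
      group = group, target = target,
      metric = c("fisher_r", "mse"),
      t = c(tt_r$t, tt_mse$t), dof = c(tt_r$dof, tt_mse$dof),
      p_two_tailed = c(tt_r$p_two_tailed, tt_mse$p_two_tailed),
      mean_diff = c(tt_r$mean_diff, tt_mse$mean_diff))
  }
  list(table = tbl, paired = do.call(rbind, paired), reports = reports)
}

#' Run the full study end-to-end
#'
#' Orchestrates every analysis on one cohort: per-domain inter-subject
#' similarity and the second-order inter-domain matrix; within-domain
#' (art-to-art, face-to-face) and cross-domain (face-to-art, art-to-face)
#' prediction conditions; weight-shuffling permutation tests for both
#' cross-domain directions (weights refit on the full source domain at the
#' condition's selected penalties); the cohort-size ablation; and the
#' gender-stratified conditions. If no data are supplied a synthetic cohort
#' is generated from `cfg$synthetic`. With `out_dir` set, all artifacts are
#' written as CSV/JSON along with a machine-readable manifest; outputs are
#' byte-identical across reruns with the same configuration.
#'
#' @param cfg a [study_config()].
#' @param data optional list with raw `ratings` and `cohort`; defaults to a
#'   cohort generated from `cfg$synthetic`.
#' @param out_dir optional output directory.
#' @return a results bundle (list) with elements `similarity`, `conditions`,
#'   `permutations`, `ablation`, `gender`, `manifest`.
#' @export
run_full_study <- function(cfg = study_config(), data = NULL, out_dir = NULL) {
  if (is.null(data)) {
    gen <- generate_cohort(cfg$synthetic)
    data <- list(ratings = gen$ratings, cohort = gen$cohort)
  }
  ratings <- prepare_ratings(data$ratings)
  study <- list(ratings = ratings, cohort = data$cohort)

  sims <- lapply(ratings, pairwise_similarity)
  similarity <- list(
    matrices = sims,
    mean_r = vapply(sims, mean_similarity, numeric(1)),
    inter_domain = inter_domain_matrix(sims))

  cond_specs <- list(c("art", "art"), c("face", "face"),
                     c("face", "art"), c("art", "face"))
  conditions <- lapply(cond_specs, function(sp)
    run_condition(sp[1], sp[2], study, cfg))
  names(conditions) <- vapply(cond_specs, paste, character(1), collapse = "_to_")

  perm_seeds <- derive_seeds(cfg$seed + 1L, 2L)
  permutations <- lapply(seq_along(perm_seeds), function(i) {
    sp <- cond_specs[[2L + i]]   # the two cross-domain conditions
    cond <- conditions[[2L + i]]
    W_full <- fit_slim(resolve_domain(ratings, sp[1]),
                       cond$grid$best_beta, cond$grid$best_lam)
    permutation_test(W_full, resolve_domain(ratings, sp[2]),
                     B = cfg$permutation_B, seed = perm_seeds[i])
  })
  names(permutations) <- names(conditions)[3:4]

  ablation <- run_ablation(study, cfg, source = "face", target = "art",
                           sizes = unique(c(cfg$ablation_sizes,
                                            length(data$cohort$participant_id))),
                           repeats = cfg$ablation_repeats,
                           seed = cfg$seed + 2L)
  gender <- run_gender_conditions(study, cfg)

  bundle <- list(similarity = similarity, conditions = conditions,
                 permutations = permutations, ablation = ablation,
                 gender = gender, seed = cfg$seed)
  if (!is.null(out_dir)) bundle$manifest <- write_study(bundle, out_dir)
  bundle
}

# Serialize a study bundle to out_dir; returns the manifest data.frame.
write_study <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  emit <- function(file, stage, writer) {
    path <- file.path(out_dir, file)
    writer(path)
    manifest[[length(manifest) + 1L]] <<- data.frame(file = file, stage = stage)
  }
  for (d in names(bundle$similarity$matrices))
    emit(paste0("similarity_", d, ".csv"), "similarity",
         function(p) write_similarity(bundle$similarity$matrices[[d]], p))
  emit("inter_domain.csv", "similarity",
       function(p) write_similarity(bundle$similarity$inter_domain, p))
  emit("conditions.json", "conditions", function(p) {
    out <- lapply(bundle$conditions, function(cond) {
      r <- cond$report
      list(source = cond$provenance$source, target = cond$provenance$target,
           group_r = r$group_r, mse = r$mse,
           per_participant_r = as.list(r$per_participant_r),
           n_items_tested = r$n_items_tested,
           best_beta = cond$provenance$best_beta,
           best_lam = cond$provenance$best_lam)
    })
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA)
  })
  for (nm in names(bundle$permutations)) {
    pr <- bundle$permutations[[nm]]
    emit(paste0("permutation_", nm, ".json"), "permutation", function(p)
      jsonlite::write_json(list(observed = pr$observed, p_value = pr$p_value,
                                B = pr$B, seed = pr$seed,
                                null_mean = mean(pr$null_distribution)),
                           p, auto_unbox = TRUE, digits = NA))
    emit(paste0("null_", nm, ".csv"), "permutation", function(p)
      utils::write.csv(data.frame(null_statistic = pr$null_distribution), p,
                       row.names = FALSE, quote = FALSE))
  }
  emit("ablation.csv", "ablation", function(p)
    utils::write.csv(bundle$ablation, p, row.names = FALSE, quote = FALSE))
  emit("gender_conditions.csv", "gender", function(p)
    utils::write.csv(bundle$gender$table, p, row.names = FALSE, quote = FALSE))
  emit("gender_paired_tests.csv", "gender", function(p)
    utils::write.csv(bundle$gender$paired, p, row.names = FALSE, quote = FALSE))
  mf <- do.call(rbind, manifest)
  mf$seed <- bundle$seed
  utils::write.csv(mf, file.path(out_dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  mf
}
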