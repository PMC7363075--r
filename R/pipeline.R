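# Pipeline orchestration: three-stage training with split hygiene,
# end-to-end inference, configuration and reports.

#' Pipeline configuration
#'
#' Collects per-stage model configurations, preprocessing toggles, patch
#' and component parameters, evaluation settings and the global seed.  The
#' default experiment crops around the cranial cavity but leaves pixel-wise
#' cavity masking off; both are exposed as flags.  All randomness flows
#' from `seed` via named per-stage sub-seeds.
#'
#' @param seed Global integer seed.
#' @param desk Use desk-scale presets in every stage (CPU-sized models).
#' @param cavity,proposal,patch Stage configs (defaults built with `desk`).
#' @param pixelwise_masking Zero intensities outside the cavity before
#'   stage 2 (default off, matching the better reference configuration).
#' @param align Estimate and apply midline alignment after cavity
#'   segmentation.
#' @param crop_margin In-plane crop margin (voxels).
#' @param band_px,hu_max Boundary-refinement band half-width (pixels) and
#'   HU bound.
#' @param min_cm3 Proposal component-volume bound (cm^3).
#' @param n_per_lesion Border positions per lesion at inference (70).
#' @param n_per_lesion_train Border positions per lesion when building the
#'   training patch set.
#' @param threshold Subject-score operating point for confusion matrices.
#' @param bootstrap_reps,bootstrap_m Bootstrap repetitions and resample
#'   size.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, desk = FALSE,
                            cavity = cavity_config(desk = desk),
                            proposal = proposal_config(desk = desk),
                            patch = patch_config(desk = desk),
                            pixelwise_masking = FALSE, align = TRUE,
                            crop_margin = 2L, band_px = if (desk) 3 else 11,
                            hu_max = 50,
                            min_cm3 = 0.2, n_per_lesion = 70L,
                            n_per_lesion_train = if (desk) 20L else 70L,
                            threshold = 0.3, bootstrap_reps = 1000L,
                            bootstrap_m = 100L) {
  structure(list(seed = as.integer(seed), desk = isTRUE(desk),
                 cavity = cavity, proposal = proposal, patch = patch,
                 pixelwise_masking = isTRUE(pixelwise_masking),
                 align = isTRUE(align), crop_margin = as.integer(crop_margin),
                 band_px = band_px, hu_max = hu_max, min_cm3 = min_cm3,
                 n_per_lesion = as.integer(n_per_lesion),
                 n_per_lesion_train = as.integer(n_per_lesion_train),
                 threshold = threshold,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 bootstrap_m = as.integer(bootstrap_m)),
            class = "pipeline_config")
}

#' Check split hygiene of a cohort table
#'
#' Every subject id must carry exactly one split tag; violations fail hard
#' with the offending subject ids.
#'
#' @param cohort Data.frame with `subject_id` and `split` columns.
#' @return `TRUE`, invisibly.
#' @export
check_split_hygiene <- function(cohort) {
  tab <- tapply(cohort$split, cohort$subject_id,
                function(s) length(unique(s)))
  bad <- names(tab)[tab > 1]
  if (length(bad) > 0)
    stop("split leakage: subject(s) in multiple splits: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

split_samples <- function(samples, cohort, tag) {
  ids <- cohort$subject_id[cohort$split == tag]
  samples[vapply(samples, function(s) s$record$subject_id %in% ids,
                 logical(1))]
}

# Shared preprocessing: window, predicted cavity + refinement, optional
# midline alignment, crop; extra masks ride along through the identical
# transforms.
preprocess_volume <- function(cavity_model, volume, config, masks = list()) {
  nv <- clip_normalize(volume)
  cav <- segment_cavity(cavity_model, nv)
  cav <- refine_boundary(cav, volume, config$band_px, config$hu_max)
  if (sum(cav$voxels) == 0)
    stop("cavity segmentation produced an empty mask for ",
         volume$subject_id)
  angle <- 0
  if (config$align) {
    al <- align_midline(volume, cav)
    volume <- al$volume
    cav <- al$cavity
    angle <- al$angle
    masks <- lapply(masks, function(m) {
      m$voxels <- array(as.integer(
        rotate_volume_inplane(m$voxels, angle, bilinear = FALSE) != 0),
        dim(m$voxels))
      m
    })
  }
  cr <- crop_background(volume, cav, masks, margin = config$crop_margin)
  nv <- clip_normalize(cr$volume)
  if (config$pixelwise_masking)
    nv$voxels <- nv$voxels * cr$cavity$voxels
  list(volume = cr$volume, nvol = nv, cavity = cr$cavity,
       masks = cr$masks, offset = cr$offset, angle = angle)
}

#' Train the three-stage pipeline
#'
#' Stage 1 (cavity) trains on all training subjects; stage 2 (proposals)
#' on the lesion-bearing slices of preprocessed stroke training subjects;
#' stage 3 on ground-truth lesion-border patches of stroke training
#' subjects versus hard negatives mined from healthy training subjects.
#' Split hygiene is asserted before any training.
#'
#' @param samples List of `phantom_sample`-like objects.
#' @param cohort Cohort data.frame (subject_id, label, split, ...).
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory for model checkpoints (RDS) and
#'   training-curve CSVs.
#' @return List of class `pipeline_models` with `cavity`, `proposal`,
#'   `patch` models and the config.
#' @export
run_training <- function(samples, cohort, config = pipeline_config(),
                         out_dir = NULL) {
  check_split_hygiene(cohort)
  seed <- config$seed
  train <- split_samples(samples, cohort, "train")
  val <- split_samples(samples, cohort, "val")
  if (length(train) == 0 || length(val) == 0)
    stop("cohort must contain train and val subjects")
  is_stroke <- function(s) s$record$label == 1

  # stage 1: cranial cavity
  cav_model <- build_cavity_model(config$cavity, seed = sub_seed(seed, "cav"))
  cav_model <- train_cavity(cav_model, train, val,
                            seed = sub_seed(seed, "cav_train"))

  # stage 2: region proposals, on preprocessed stroke subjects
  pp_train <- lapply(Filter(is_stroke, train), function(s)
    preprocessed_sample(cav_model, s, config))
  pp_val <- lapply(Filter(is_stroke, val), function(s)
    preprocessed_sample(cav_model, s, config))
  if (length(pp_train) == 0) stop("no stroke subjects in the training split")
  prop_model <- build_proposal_model(config$proposal,
                                     seed = sub_seed(seed, "prop"))
  prop_model <- train_region_proposal(prop_model, pp_train,
                                      if (length(pp_val)) pp_val else
                                        pp_train[1],
                                      seed = sub_seed(seed, "prop_train"))

  # stage 3: positives from ground truth, negatives mined from healthy
  healthy_train <- Filter(Negate(is_stroke), train)
  pp_healthy <- lapply(healthy_train, function(s)
    preprocessed_sample(cav_model, s, config))
  pos <- extract_positive_patches(pp_train, config$n_per_lesion_train,
                                  seed = sub_seed(seed, "pos"))
  neg <- mine_hard_negatives(pp_healthy, prop_model,
                             n_per_lesion = config$n_per_lesion_train,
                             min_cm3 = config$min_cm3,
                             seed = sub_seed(seed, "neg"))
  if (length(neg) == 0)
    stop("hard-negative mining produced no patches; proposal model too",
         " conservative for stage-3 training")
  ds <- build_patch_dataset(pos, neg, seed = sub_seed(seed, "ds"))
  # validation patches from the val split; fall back to a held-out slice of
  # the training set when a val class is empty
  vpos <- extract_positive_patches(pp_val, config$n_per_lesion_train,
                                   seed = sub_seed(seed, "vpos"))
  pp_hval <- lapply(Filter(Negate(is_stroke), val), function(s)
    preprocessed_sample(cav_model, s, config))
  vneg <- mine_hard_negatives(pp_hval, prop_model,
                              n_per_lesion = config$n_per_lesion_train,
                              min_cm3 = config$min_cm3,
                              seed = sub_seed(seed, "vneg"))
  vds <- if (length(vpos) > 0 && length(vneg) > 0)
    build_patch_dataset(vpos, vneg, seed = sub_seed(seed, "vds"))
  else {
    nval <- max(2, round(0.1 * length(ds$patches)))
    list(patches = ds$patches[seq_len(nval)], label = ds$label[seq_len(nval)])
  }
  patch_model <- build_patch_classifier(config$patch,
                                        seed = sub_seed(seed, "patch"))
  patch_model <- train_patch_classifier(patch_model, ds, vds,
                                        seed = sub_seed(seed, "patch_train"))

  models <- structure(list(cavity = cav_model, proposal = prop_model,
                           patch = patch_model, config = config),
                      class = "pipeline_models")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(cav_model, file.path(out_dir, "cavity_model.rds"))
    saveRDS(prop_model, file.path(out_dir, "proposal_model.rds"))
    saveRDS(patch_model, file.path(out_dir, "patch_model.rds"))
    utils::write.csv(cav_model$history,
                     file.path(out_dir, "cavity_history.csv"),
                     row.names = FALSE)
    utils::write.csv(prop_model$history,
                     file.path(out_dir, "proposal_history.csv"),
                     row.names = FALSE)
    utils::write.csv(patch_model$history,
                     file.path(out_dir, "patch_history.csv"),
                     row.names = FALSE)
  }
  models
}

# preprocess a phantom-like sample, carrying its lesion ground truth through
preprocessed_sample <- function(cavity_model, s, config) {
  pp <- preprocess_volume(cavity_model, s$volume, config,
                          masks = list(lesions = s$lesions))
  list(volume = pp$volume, nvol = pp$nvol, cavity = pp$cavity,
       lesions = pp$masks$lesions, record = s$record)
}

#' Run end-to-end inference on one volume
#'
#' Preprocess, segment the cavity, propose regions, filter small
#' components, score 70 border patches per lesion, average to lesion
#' scores, and take the subject maximum.
#'
#' @param models A `pipeline_models` bundle (all three stages trained).
#' @param volume A `ct_volume` in HU.
#' @param report_path Optional path for a JSON per-subject report.
#' @return List: `subject_id`, `score`, `lesions` (data.frame id,
#'   volume_cm3, score), `proposals` (`seg_mask`, cropped grid), `offset`,
#'   `angle`.
#' @export
run_inference <- function(models, volume, report_path = NULL) {
  for (st in c("cavity", "proposal", "patch"))
    if (is.null(models[[st]]))
      stop("missing trained model for stage: ", st)
  config <- models$config
  pp <- preprocess_volume(models$cavity, volume, config)
  prop <- propose_regions(models$proposal, pp$nvol)
  prop <- filter_small_components(prop, config$min_cm3)
  lesions <- label_lesions(prop, subject_id = volume$subject_id)
  les_scores <- numeric(0)
  les_df <- data.frame(id = integer(), volume_cm3 = numeric(),
                       score = numeric())
  for (les in lesions) {
    border <- lesion_border(les, dim(prop$voxels))
    if (is.null(border)) next
    pos <- sample_border_positions(border, config$n_per_lesion,
                                   seed = sub_seed(config$seed, paste0(
                                     volume$subject_id, "_inf_", les$id)))
    patches <- lapply(seq_len(nrow(pos)), function(j)
      extract_dual_patch(pp$nvol, pos[j, ]))
    probs <- classify_patches(models$patch, patches)
    sc <- lesion_score(probs)
    les_scores <- c(les_scores, sc)
    les_df <- rbind(les_df, data.frame(id = les$id,
                                       volume_cm3 = les$volume_cm3,
                                       score = sc))
  }
  res <- list(subject_id = volume$subject_id,
              score = subject_score(les_scores), lesions = les_df,
              proposals = prop, offset = pp$offset, angle = pp$angle)
  if (!is.null(report_path))
    save_report(list(subject_id = res$subject_id, score = res$score,
                     angle = res$angle, offset = res$offset,
                     lesions = les_df), report_path)
  res
}

#' Score a test cohort and evaluate
#'
#' Runs inference on every sample, then computes ROC/AUC, a bootstrap CI
#' and the confusion matrix at the configured threshold.  With
#' `proposal_only = TRUE`, stage 3 is bypassed and the subject score is the
#' any-surviving-proposal indicator.
#'
#' @param models A `pipeline_models` bundle.
#' @param samples Test samples.
#' @param proposal_only Bypass the stage-3 classifier.
#' @return List: `predictions` (data.frame subject_id, score, label),
#'   `auc`, `ci`, `confusion`.
#' @export
evaluate_cohort <- function(models, samples, proposal_only = FALSE) {
  config <- models$config
  preds <- do.call(rbind, lapply(samples, function(s) {
    if (proposal_only) {
      pp <- preprocess_volume(models$cavity, s$volume, config)
      prop <- filter_small_components(
        propose_regions(models$proposal, pp$nvol), config$min_cm3)
      sc <- as.numeric(sum(prop$voxels) > 0)
      nles <- length(label_lesions(prop))
    } else {
      res <- run_inference(models, s$volume)
      sc <- res$score
      nles <- nrow(res$lesions)
    }
    data.frame(subject_id = s$record$subject_id, score = sc,
               label = s$record$label, n_lesions = nles)
  }))
  ev <- roc_auc(preds$score, preds$label)
  ci <- bootstrap_auc_ci(preds$score, preds$label,
                         reps = config$bootstrap_reps,
                         m = min(config$bootstrap_m, nrow(preds)),
                         seed = sub_seed(config$seed, "boot"))
  conf <- confusion_at_threshold(preds$score, preds$label, config$threshold)
  list(predictions = preds, auc = ev$auc, roc = ev$roc, ci = ci,
       confusion = conf)
}

#' Lesion-level proposal sensitivity
#'
#' Fraction of ground-truth lesions (over the given stroke samples) that
#' overlap at least one surviving stage-2 proposal component, after the
#' standard preprocessing.  High sensitivity is the stage-2 design goal;
#' the false positives it tolerates are removed by stage 3.
#'
#' @param models A `pipeline_models` bundle (stages 1 and 2 trained).
#' @param samples Stroke samples with `volume` and `lesions` elements.
#' @return List with `sensitivity`, `n_lesions`, `n_hit`.
#' @export
proposal_sensitivity <- function(models, samples) {
  config <- models$config
  n_les <- 0L; n_hit <- 0L
  for (s in samples) {
    pp <- preprocessed_sample(models$cavity, s, config)
    prop <- filter_small_components(
      propose_regions(models$proposal, pp$nvol), config$min_cm3)
    for (les in label_lesions(pp$lesions)) {
      n_les <- n_les + 1L
      if (any(prop$voxels[les$coords] == 1)) n_hit <- n_hit + 1L
    }
  }
  list(sensitivity = if (n_les > 0) n_hit / n_les else NA_real_,
       n_lesions = n_les, n_hit = n_hit)
}

# Config files and reports ------------------------------------------------

pipeline_config_fields <- function() {
  c("seed", "desk", "pixelwise_masking", "align", "crop_margin", "band_px",
    "hu_max", "min_cm3", "n_per_lesion", "n_per_lesion_train", "threshold",
    "bootstrap_reps", "bootstrap_m", "cavity", "proposal", "patch")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown fields are rejected with their path; missing fields take the
#' defaults of `pipeline_config()`.  Stage sub-configs accept the
#' corresponding constructor arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- pipeline_config_fields()
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (is.null(raw$seed)) stop("missing required config field: seed")
  desk <- isTRUE(raw$desk)
  args <- raw
  args$desk <- desk
  for (st in c("cavity", "proposal", "patch")) {
    if (!is.null(raw[[st]])) {
      ctor <- switch(st, cavity = cavity_config, proposal = proposal_config,
                     patch = patch_config)
      vals <- raw[[st]]
      # drop derived fields a round-tripped config carries
      vals <- vals[setdiff(names(vals),
                           c("kernel", "bn_momentum", "bn_eps", "desk"))]
      ok <- names(formals(ctor))
      bad <- setdiff(names(vals), ok)
      if (length(bad) > 0)
        stop("unknown config field(s): ",
             paste(paste0(st, ".", bad), collapse = ", "))
      args[[st]] <- do.call(ctor, c(vals, list(desk = desk)))
    }
  }
  do.call(pipeline_config, args)
}

#' Save a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  for (st in c("cavity", "proposal", "patch")) x[[st]] <- unclass(x[[st]])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Save a JSON report
#'
#' @param report Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
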