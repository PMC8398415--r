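#' Detect feeding events for one animal
#'
#' Convenience wrapper over the fusion steps: feeding clusters from the
#' prediction stream, GPS clusters from the fixes, temporal matching with
#' centroid merging and boundary correction, and the pre-event high-ACC
#' scan.
#'
#' @param preds Prediction set for one animal (time-sorted).
#' @param fixes The animal's GPS fixes (time-sorted).
#' @param fix_interval_min The animal's active GPS schedule in minutes.
#' @param cfg A [detection_config()].
#' @return A list with `events` (including `high_acc_before`),
#'   `unmatched`, `feeding_clusters` and `gps_clusters`.
#' @export
detect_feeding_events <- function(preds, fixes, fix_interval_min,
                                  cfg = detection_config()) {
  fcl <- find_feeding_clusters(preds, cfg)
  gcl <- find_gps_clusters(fixes, cfg)
  m <- match_feeding_to_gps(fcl, gcl, fixes, fix_interval_min, cfg)
  ev <- m$events
  if (nrow(ev) > 0) {
    ev$high_acc_before <- vapply(seq_len(nrow(ev)), function(i) {
      suppressWarnings(scan_high_acc_before(preds, ev$start[i], cfg))
    }, logical(1))
    ev$gps_schedule_min <- fix_interval_min
  } else {
    ev$high_acc_before <- logical(0)
    ev$gps_schedule_min <- numeric(0)
  }
  list(events = ev, unmatched = m$unmatched, feeding_clusters = fcl,
       gps_clusters = gcl)
}

#' Write the events report CSV
#'
#' One row per detected feeding event: animal, date, start/end (UTC),
#' duration in whole minutes, the GPS schedule, the matched GPS cluster
#' span and duration, whether high-ACC bursts preceded the event, and the
#' match status.
#'
#' @param events Event tibble from [detect_feeding_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- data.frame(
    animal_id = events$animal_id,
    date = format(events$start, "%Y-%m-%d", tz = "UTC"),
    start = format_utc(events$start),
    end = format_utc(events$end),
    duration_min = events$duration_min,
    gps_schedule_min = events$gps_schedule_min,
    gps_cluster_start = format_utc(events$gps_start),
    gps_cluster_end = format_utc(events$gps_end),
    gps_cluster_duration_min = events$gps_duration_min,
    high_acc_before = ifelse(events$high_acc_before, "yes", "no"),
    match_status = events$match_status,
    stringsAsFactors = FALSE
  )
  fwrite(df, path, sep = ",", eol = "\n", quote = FALSE)
  invisible(path)
}

#' Run the full pipeline on synthetic data
#'
#' simulate -> ingest -> features -> train -> validate -> predict ->
#' detect, writing every stage's output plus a manifest under `out_dir`.
#' The captive scenario supplies the ground-truthed training stream; the
#' free-ranging study scenario supplies the stream to which the model is
#' applied. Rerunning with the same arguments reproduces the outputs
#' byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for both scenarios and all fits.
#' @param threshold Probability threshold (default 0.5).
#' @param train_bursts_per_class Captive bursts per behaviour per animal.
#' @param n_train_animals Number of captive animals.
#' @param validate One of `"none"`, `"pacv"`, `"loocv"`: the
#'   cross-validation run on the captive set (LOOCV refits per burst and
#'   is the slow option).
#' @param cfg A [detection_config()].
#' @param config A [classifier_config()].
#' @param include_rest_walk Also compute the (re-designed) resting/walking
#'   clusters; off by default.
#' @param captive,study Optional scenario overrides ([scenario_config()]);
#'   by default the canonical captive and free-ranging study scenarios are
#'   built from `seed`.
#' @return Invisibly, a list with the stage outputs (`model`, `events`,
#'   `unmatched`, `validation`, paths, and the two scenarios).
#' @export
run_pipeline <- function(out_dir, seed = 1, threshold = 0.5,
                         train_bursts_per_class = 30, n_train_animals = 5,
                         validate = c("pacv", "loocv", "none"),
                         cfg = detection_config(),
                         config = classifier_config(),
                         include_rest_walk = FALSE,
                         captive = NULL, study = NULL) {
  validate <- match.arg(validate)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log_stage <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }

  # simulate
  captive <- captive %||% make_captive_scenario(
    seed = seed, n_animals = n_train_animals,
    bursts_per_class = train_bursts_per_class)
  study <- study %||% make_study_scenario(seed = seed)
  cap_sim <- generate_bursts(captive)
  study_sim <- generate_bursts(study)
  track <- generate_track(study)
  paths$acc_captive <- file.path(out_dir, "acc_captive.csv")
  paths$acc_study <- file.path(out_dir, "acc_study.csv")
  paths$gps_study <- file.path(out_dir, "gps_study.csv")
  paths$ground_truth <- file.path(out_dir, "ground_truth.csv")
  write_bursts(cap_sim$bursts, paths$acc_captive)
  write_bursts(study_sim$bursts, paths$acc_study)
  write_gps(track$fixes, paths$gps_study)
  write_ground_truth(study$episodes, paths$ground_truth)
  log_stage("simulate", "%d captive and %d study bursts, %d fixes",
            nrow(cap_sim$bursts), nrow(study_sim$bursts), nrow(track$fixes))

  # ingest (read back the canonical files: the same path field data takes)
  cap_in <- read_bursts(paths$acc_captive, captive$animals[[1]]$config)
  study_in <- read_bursts(paths$acc_study, study$animals[[1]]$config)
  gps_in <- read_gps(paths$gps_study)
  stopifnot(nrow(cap_in$rejected) == 0, nrow(study_in$rejected) == 0,
            nrow(gps_in$rejected) == 0)
  log_stage("ingest", "%d + %d bursts, %d fixes, 0 rejected",
            nrow(cap_in$bursts), nrow(study_in$bursts), nrow(gps_in$fixes))

  # features
  cap_f <- filter_single_behaviour(cap_in$bursts)
  feats_train <- feature_table(cap_f$kept)
  feats_study <- feature_table(study_in$bursts)
  paths$features_train <- file.path(out_dir, "features_captive.csv")
  paths$features_study <- file.path(out_dir, "features_study.csv")
  write_features(feats_train, paths$features_train)
  write_features(feats_study, paths$features_study)
  log_stage("features", "%d training rows (%d mixed discarded), %d study rows",
            nrow(feats_train), cap_f$discarded_count, nrow(feats_study))

  # train
  model <- train_behaviour_model(feats_train, seed = seed, config = config)
  log_stage("train", "6 classifiers on %d bursts, %d animals",
            model$n_train, length(model$animals))

  # validate
  validation <- NULL
  if (validate != "none") {
    validation <- if (validate == "loocv") {
      loocv(feats_train, threshold = threshold, seed = seed, config = config)
    } else {
      pacv(feats_train, threshold = threshold, seed = seed, config = config)
    }
    paths$validation <- file.path(out_dir, paste0("validation_", validate, ".csv"))
    rep <- if (validate == "loocv") validation$report else
      dplyr::bind_rows(lapply(names(validation), function(a)
        dplyr::mutate(validation[[a]]$report, animal_id = a, .before = 1)))
    fwrite(rep, paths$validation, sep = ",", eol = "\n", quote = FALSE)
    log_stage("validate", "%s report written", validate)
  }

  # predict
  preds <- predict_bursts(model, feats_study, threshold = threshold)
  paths$predictions <- file.path(out_dir, "predictions.csv")
  pred_df <- as.data.frame(preds)
  pred_df$start_time <- format_utc(pred_df$start_time)
  fwrite(pred_df, paths$predictions, sep = ",", eol = "\n", quote = FALSE)
  log_stage("predict", "%d bursts at threshold %.2f", nrow(preds), threshold)

  # detect, per animal
  all_events <- list()
  all_unmatched <- list()
  rest_walk <- list()
  for (a in names(study$animals)) {
    p_a <- preds[preds$animal_id == a, ]
    f_a <- gps_in$fixes[gps_in$fixes$animal_id == a, ]
    det <- detect_feeding_events(p_a, f_a,
                                 study$animals[[a]]$gps_active_min, cfg)
    all_events[[a]] <- det$events
    all_unmatched[[a]] <- det$unmatched
    if (include_rest_walk) {
      rest_walk[[a]] <- dplyr::mutate(
        resting_walking_clusters(p_a, f_a, det$events, cfg),
        animal_id = a, .before = 1)
    }
  }
  events <- dplyr::bind_rows(all_events)
  unmatched <- dplyr::bind_rows(all_unmatched)
  paths$events <- file.path(out_dir, "events.csv")
  write_events(events, paths$events)
  shared <- suggest_shared_sites(events, cfg)
  log_stage("detect", "%d events, %d unmatched, %d shared-site suggestions",
            nrow(events), nrow(unmatched), nrow(shared))

  # manifest
  manifest <- list(
    seed = seed, threshold = threshold,
    train_bursts_per_class = train_bursts_per_class,
    n_train_animals = n_train_animals,
    validate = validate,
    detection_config = unclass(cfg),
    classifier_config = unclass(config)[setdiff(names(unclass(config)), "")],
    stages = c("simulate", "ingest", "features", "train", "validate",
               "predict", "detect"),
    outputs = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(model = model, events = events, unmatched = unmatched,
                 shared_sites = shared, validation = validation,
                 rest_walk = if (include_rest_walk) dplyr::bind_rows(rest_walk),
                 paths = paths, captive = captive, study = study,
                 predictions = preds))
}
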