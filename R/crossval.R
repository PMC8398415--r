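#' Confusion matrix with an abstention column
#'
#' Rows are true behaviours (D, F, G, R, T, W), columns are predicted
#' behaviours plus NOT_CONCLUSIVE.
#'
#' @param true Character vector of true labels (among the six behaviours).
#' @param predicted Character vector of predicted labels (behaviours or
#'   NOT_CONCLUSIVE).
#' @return A 6 x 7 integer matrix.
#' @export
confusion_matrix <- function(true, predicted) {
  stopifnot(length(true) == length(predicted))
  t_ <- factor(true, levels = BEHAVIOURS)
  p_ <- factor(predicted, levels = c(BEHAVIOURS, NOT_CONCLUSIVE))
  unclass(table(true = t_, predicted = p_))
}

#' Per-behaviour precision and recall (percent)
#'
#' PR = 100 * TP / (TP + FP) where FP counts every other behaviour
#' predicted as `behaviour`; RE = 100 * TP / (TP + FN) where FN counts
#' every misprediction of a true `behaviour` burst, including abstentions
#' (NOT_CONCLUSIVE). Both are 0 by convention when their denominator is 0.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @param behaviour One of the six behaviour codes.
#' @return Named numeric vector `c(PR = , RE = )` in percent.
#' @export
precision_recall <- function(cm, behaviour) {
  stopifnot(behaviour %in% BEHAVIOURS)
  tp <- cm[behaviour, behaviour]
  fp <- sum(cm[, behaviour]) - tp
  fn <- sum(cm[behaviour, ]) - tp
  c(PR = if (tp + fp > 0) 100 * tp / (tp + fp) else 0,
    RE = if (tp + fn > 0) 100 * tp / (tp + fn) else 0)
}

# Overall (micro-averaged) precision: correct conclusive predictions over
# all conclusive predictions. Overall recall: correct conclusive
# predictions over all bursts. Under abstention this pair naturally gives
# PR >= RE. A macro-averaged alternative is available.
overall_pr_re <- function(cm, aggregate = c("micro", "macro")) {
  aggregate <- match.arg(aggregate)
  if (aggregate == "macro") {
    pr <- vapply(BEHAVIOURS, function(b) precision_recall(cm, b), numeric(2))
    present <- rowSums(cm) > 0
    return(c(PR = mean(pr["PR", present]), RE = mean(pr["RE", present])))
  }
  tp <- sum(diag(cm[, BEHAVIOURS]))
  conclusive <- sum(cm[, BEHAVIOURS])
  total <- sum(cm)
  c(PR = if (conclusive > 0) 100 * tp / conclusive else 0,
    RE = if (total > 0) 100 * tp / total else 0)
}

#' Performance report from per-method confusion matrices
#'
#' @param cms Named list of confusion matrices (one per method).
#' @param aggregate `"micro"` (default) or `"macro"` overall aggregation.
#' @return A tibble: `method`, `behaviour` (`"overall"` or a class code),
#'   `PR`, `RE` (percent), `nc_fraction` (fraction of bursts labelled
#'   NOT_CONCLUSIVE, repeated per method).
#' @export
performance_report <- function(cms, aggregate = "micro") {
  rows <- list()
  for (m in names(cms)) {
    cm <- cms[[m]]
    ov <- overall_pr_re(cm, aggregate)
    nc <- if (sum(cm) > 0) sum(cm[, NOT_CONCLUSIVE]) / sum(cm) else 0
    rows[[length(rows) + 1L]] <- tibble(
      method = m, behaviour = "overall",
      PR = unname(ov["PR"]), RE = unname(ov["RE"]),
      nc_fraction = nc
    )
    for (b in BEHAVIOURS) {
      pr <- precision_recall(cm, b)
      rows[[length(rows) + 1L]] <- tibble(
        method = m, behaviour = b,
        PR = unname(pr["PR"]), RE = unname(pr["RE"]),
        nc_fraction = nc
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Build per-method confusion matrices from cached probabilities at a
# threshold. `cache` is the list returned by loocv()/predict_cached.
cache_confusions <- function(cache, threshold, majority_on = "thresholded") {
  preds <- rethreshold_predictions(cache$probs, cache$key, threshold,
                                   majority_on = majority_on)
  cms <- list()
  for (a in ALGORITHMS) {
    cms[[toupper(a)]] <- confusion_matrix(cache$true, preds[[paste0(a, "_label")]])
  }
  cms$Mean <- confusion_matrix(cache$true, preds$mean_label)
  cms$Majority <- confusion_matrix(cache$true, preds$majority_label)
  cms
}

#' Leave-one-out cross-validation of the classifier bank
#'
#' Every burst is predicted by a model trained on all other bursts. The
#' per-algorithm class probabilities of the n held-out predictions are
#' cached so any probability threshold can be re-applied without
#' refitting (see [threshold_sweep()]).
#'
#' @param features Labelled feature table with at least two classes.
#' @param threshold Probability threshold for the report.
#' @param seed Integer seed (used identically for every fold fit).
#' @param config A [classifier_config()].
#' @param aggregate Overall aggregation, `"micro"` or `"macro"`.
#' @return A list with `report` ([performance_report()] tibble),
#'   `confusion` (named list of matrices) and `cache` (held-out
#'   probabilities: `probs`, `key`, `true`).
#' @export
loocv <- function(features, threshold = 0.5, seed = 1,
                  config = classifier_config(), aggregate = "micro") {
  if (length(unique(features$label)) < 2) {
    stop("leave-one-out cross-validation needs at least 2 classes")
  }
  n <- nrow(features)
  k <- length(intersect(BEHAVIOURS, unique(features$label)))
  per_alg <- lapply(ALGORITHMS, function(a) matrix(NA_real_, n, k))
  names(per_alg) <- ALGORITHMS
  for (i in seq_len(n)) {
    model <- train_behaviour_model(features[-i, ], seed = seed,
                                   config = config)
    pp <- predict_probs(model, features[i, ])
    for (a in ALGORITHMS) {
      colnames(per_alg[[a]]) <- model$classes
      per_alg[[a]][i, ] <- pp$probs[[a]][1, ]
    }
  }
  cache <- list(
    probs = per_alg,
    key = tibble(animal_id = features$animal_id,
                 start_time = features$start_time),
    true = features$label,
    majority_on = config$majority_on
  )
  cms <- cache_confusions(cache, threshold, config$majority_on)
  list(report = performance_report(cms, aggregate), confusion = cms,
       cache = cache)
}

#' Per-animal cross-validation
#'
#' For each animal, trains on the complete data of all other animals and
#' evaluates on the held-out animal; the individual-transfer analogue of
#' [loocv()]. Animals with no bursts are skipped with a warning.
#'
#' @inheritParams loocv
#' @return A named list (one entry per evaluated animal), each with
#'   `report` and `confusion`.
#' @export
pacv <- function(features, threshold = 0.5, seed = 1,
                 config = classifier_config(), aggregate = "micro") {
  animals <- unique(features$animal_id)
  animals <- animals[vapply(animals,
                            function(a) sum(features$animal_id == a) > 0,
                            logical(1))]
  if (length(animals) < 2) {
    stop("per-animal cross-validation needs at least 2 animals with data")
  }
  out <- list()
  for (a in animals) {
    test <- features[features$animal_id == a, ]
    train <- features[features$animal_id != a, ]
    model <- train_behaviour_model(train, seed = seed, config = config)
    preds <- predict_bursts(model, test, threshold = threshold)
    probs <- attr(preds, "probs")
    cache <- list(probs = probs[ALGORITHMS],
                  key = preds[, c("animal_id", "start_time")],
                  true = test$label, majority_on = config$majority_on)
    cms <- cache_confusions(cache, threshold, config$majority_on)
    out[[a]] <- list(report = performance_report(cms, aggregate),
                     confusion = cms)
  }
  out
}

#' Threshold sweep over cached leave-one-out predictions
#'
#' Runs (or reuses) a single LOOCV pass and re-applies each threshold to
#' the cached probabilities: the fold fits are never repeated. The default
#' grid is 0.3 to 0.8 in steps of 0.1.
#'
#' @param features Labelled feature table (ignored when `cache` is given).
#' @param thresholds Numeric vector of thresholds within `[0, 1]`.
#' @param seed,config Passed to [loocv()] when no cache is supplied.
#' @param cache Optional `cache` element of a previous [loocv()] result.
#' @param aggregate Overall aggregation.
#' @return A tibble with one row per (threshold, method): `threshold`,
#'   `method`, `PR`, `RE` (overall, percent), `nc_fraction`.
#' @export
threshold_sweep <- function(features = NULL,
                            thresholds = seq(0.3, 0.8, by = 0.1),
                            seed = 1, config = classifier_config(),
                            cache = NULL, aggregate = "micro") {
  stopifnot(all(thresholds >= 0), all(thresholds <= 1))
  if (is.null(cache)) {
    cache <- loocv(features, threshold = thresholds[1], seed = seed,
                   config = config)$cache
  }
  rows <- list()
  for (th in thresholds) {
    cms <- cache_confusions(cache, th,
                            cache$majority_on %||% "thresholded")
    rep <- performance_report(cms, aggregate)
    ov <- rep[rep$behaviour == "overall", ]
    rows[[length(rows) + 1L]] <- tibble(
      threshold = th, method = ov$method, PR = ov$PR, RE = ov$RE,
      nc_fraction = ov$nc_fraction
    )
  }
  dplyr::bind_rows(rows)
}

#' Write a performance report as CSV
#'
#' Wide layout: one row per method, PR/RE columns for overall and each
#' behaviour.
#'
#' @param report Tibble from [performance_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  wide <- NULL
  for (m in unique(report$method)) {
    sub <- report[report$method == m, ]
    row <- data.frame(method = m)
    for (b in c("overall", BEHAVIOURS)) {
      row[[paste0(b, "_PR")]] <- round(sub$PR[sub$behaviour == b], 1)
      row[[paste0(b, "_RE")]] <- round(sub$RE[sub$behaviour == b], 1)
    }
    wide <- rbind(wide, row)
  }
  fwrite(wide, path, sep = ",", eol = "\n", quote = FALSE)
  invisible(path)
}
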