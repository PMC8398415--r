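ALGORITHMS <- c("lda", "qda", "knn", "cart", "svm", "rf")
METHODS <- c(ALGORITHMS, "mean", "majority")

#' Classifier-bank configuration
#'
#' Fixed, auditable hyperparameters for the six algorithms. No search is
#' performed: k-nearest neighbours uses neighbour-vote fractions with
#' k = 5; the random forest uses 500 trees with the default feature
#' subsampling; the classification tree is grown with the usual complexity
#' setting and never post-pruned; the support vector machine uses an RBF
#' kernel with the default bandwidth (1/6 for six standardised predictors)
#' and Platt-style probability calibration fitted on the training data.
#' Linear and quadratic discriminant analysis use their native posteriors.
#' Features are z-scored (parameters from the training split only) before
#' the distance- and kernel-based methods (KNN, SVM).
#'
#' @param k Neighbour count for KNN.
#' @param ntree Tree count for the random forest.
#' @param cart_cp Complexity parameter at which tree splits stop.
#' @param cart_minsplit Smallest node the tree may split; 10 keeps the
#'   tree usable on training sets with tens of bursts per class (the
#'   all-purpose default of 20 stops splitting before rare classes
#'   separate).
#' @param majority_on Whether the majority ensemble votes on
#'   `"thresholded"` labels (abstentions excluded; default) or raw
#'   `"argmax"` labels.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(k = 5, ntree = 500, cart_cp = 0.01,
                              cart_minsplit = 10,
                              majority_on = c("thresholded", "argmax")) {
  structure(
    list(k = k, ntree = ntree, cart_cp = cart_cp,
         cart_minsplit = cart_minsplit,
         majority_on = match.arg(majority_on),
         standardize_for = c("knn", "svm")),
    class = "classifier_config"
  )
}

feature_matrix <- function(features) {
  x <- as.matrix(features[, FEATURE_COLS])
  storage.mode(x) <- "double"
  x
}

#' Train the six-classifier behaviour model
#'
#' Fits LDA, QDA, KNN, CART (classification tree), SVM and random forest
#' on the same six predictors and the same rows. All classifiers expose
#' class probabilities so the probability-threshold rule can be applied
#' downstream. Deterministic given `seed`.
#'
#' @param features Labelled feature table ([feature_table()]); labels must
#'   be among the six behaviours, with at least two classes present and at
#'   least 5 rows per present class.
#' @param seed Integer seed controlling all stochastic fits.
#' @param config A [classifier_config()].
#' @return An object of class `behaviour_model`: the six fits,
#'   standardisation parameters, the class set, and training metadata.
#' @export
train_behaviour_model <- function(features, seed = 1,
                                  config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  bad <- setdiff(unique(features$label), BEHAVIOURS)
  if (length(bad) > 0) {
    stop("training labels must be single behaviours; found: ",
         paste(bad, collapse = ", "))
  }
  counts <- table(features$label)
  if (length(counts) < 2) stop("need at least 2 behaviour classes to train")
  small <- names(counts)[counts < 5]
  if (length(small) > 0) {
    stop("too few bursts (< 5) for class(es): ", paste(small, collapse = ", "))
  }

  classes <- intersect(BEHAVIOURS, names(counts))
  x <- feature_matrix(features)
  if (!all(is.finite(x))) stop("non-finite feature values in training data")
  y <- factor(features$label, levels = classes)

  centre <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- scale(x, center = centre, scale = scale_)

  df <- data.frame(label = y, x)

  set.seed(seed)
  fits <- list(
    lda  = MASS::lda(x, grouping = y),
    qda  = MASS::qda(x, grouping = y),
    knn  = caret::knn3(xs, y, k = config$k),
    cart = rpart::rpart(label ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          cp = config$cart_cp,
                          minsplit = config$cart_minsplit,
                          minbucket = max(1, config$cart_minsplit %/% 2),
                          xval = 0)),
    svm  = e1071::svm(xs, y, kernel = "radial", probability = TRUE,
                      scale = FALSE),
    rf   = randomForest::randomForest(x, y, ntree = config$ntree)
  )

  structure(
    list(fits = fits, centre = centre, scale = scale_, classes = classes,
         config = config, seed = seed,
         animals = unique(features$animal_id), n_train = nrow(features)),
    class = "behaviour_model"
  )
}

#' @export
print.behaviour_model <- function(x, ...) {
  cat(sprintf(
    "<behaviour_model> %d classifiers, classes {%s}, %d training bursts, seed %d\n",
    length(x$fits), paste(x$classes, collapse = ","), x$n_train, x$seed
  ))
  invisible(x)
}

#' Per-algorithm class-probability matrices
#'
#' @param model A [train_behaviour_model()] fit.
#' @param features Feature table; rows with non-finite predictors are
#'   excluded and reported (attribute `errors`), with a warning.
#' @return A list with `probs` (named list of one n x K matrix per
#'   algorithm, columns = `model$classes`, rows summing to 1), `key`
#'   (tibble of `animal_id`, `start_time` for the predicted rows), and
#'   `errors` (row report for excluded rows).
#' @export
predict_probs <- function(model, features) {
  stopifnot(inherits(model, "behaviour_model"))
  x <- feature_matrix(features)
  ok <- apply(x, 1, function(r) all(is.finite(r)))
  errors <- tibble(
    row = which(!ok),
    animal_id = features$animal_id[!ok],
    start_time = features$start_time[!ok],
    reason = "non-finite feature value"
  )
  if (any(!ok)) {
    warning(sum(!ok), " feature row(s) with non-finite values excluded")
  }
  x <- x[ok, , drop = FALSE]
  xs <- scale(x, center = model$centre, scale = model$scale)
  k <- length(model$classes)
  n <- nrow(x)

  if (n == 0) {
    empty <- matrix(numeric(0), 0, k, dimnames = list(NULL, model$classes))
    probs <- setNames(rep(list(empty), length(ALGORITHMS)), ALGORITHMS)
  } else {
    newdf <- as.data.frame(x)
    svm_pred <- predict(model$fits$svm, xs, probability = TRUE)
    svm_p <- attr(svm_pred, "probabilities")[, model$classes, drop = FALSE]
    probs <- list(
      lda  = predict(model$fits$lda, x)$posterior,
      qda  = predict(model$fits$qda, x)$posterior,
      knn  = predict(model$fits$knn, xs, type = "prob"),
      cart = predict(model$fits$cart, newdata = newdf, type = "prob"),
      svm  = svm_p,
      rf   = predict(model$fits$rf, x, type = "prob")
    )
    probs <- lapply(probs, function(p) {
      p <- p[, model$classes, drop = FALSE]
      p / rowSums(p)
    })
  }
  list(
    probs = probs,
    key = tibble(animal_id = features$animal_id[ok],
                 start_time = features$start_time[ok]),
    errors = errors
  )
}

#' Threshold a probability matrix into labels
#'
#' A row is labelled with its argmax class when that class's probability
#' meets the threshold, otherwise NOT_CONCLUSIVE. Argmax ties resolve to
#' the alphabetically first class (columns are in alphabetical order).
#'
#' @param p n x K probability matrix, columns named by class.
#' @param threshold Probability in `[0, 1]`.
#' @return Character vector of labels.
#' @export
threshold_labels <- function(p, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (nrow(p) == 0) return(character(0))
  idx <- max.col(p, ties.method = "first")
  maxp <- p[cbind(seq_len(nrow(p)), idx)]
  ifelse(maxp >= threshold, colnames(p)[idx], NOT_CONCLUSIVE)
}

#' Mean-voting ensemble
#'
#' Averages the class-probability vectors of the six algorithms and
#' applies the same threshold rule to the averaged vector.
#'
#' @param prob_list List of the six per-algorithm probability matrices
#'   (identical dimensions and column order).
#' @param threshold Probability threshold.
#' @return A list with `probs` (the mean matrix) and `labels`.
#' @export
ensemble_mean <- function(prob_list, threshold) {
  p <- Reduce(`+`, prob_list) / length(prob_list)
  list(probs = p, labels = threshold_labels(p, threshold))
}

#' Majority-voting ensemble
#'
#' The most frequent concrete label among the per-algorithm votes;
#' NOT_CONCLUSIVE votes are abstentions and never counted. If every vote
#' abstained the ensemble abstains. Ties defer to the mean-ensemble label
#' when it is among the tied classes, otherwise to the alphabetically
#' first tied class.
#'
#' @param label_mat n x 6 character matrix of per-algorithm labels.
#' @param mean_labels Mean-ensemble labels used as tie-breaker.
#' @return Character vector of labels.
#' @export
ensemble_majority <- function(label_mat, mean_labels) {
  n <- nrow(label_mat)
  out <- character(n)
  for (i in seq_len(n)) {
    votes <- label_mat[i, ]
    votes <- votes[votes != NOT_CONCLUSIVE]
    if (length(votes) == 0) {
      out[i] <- NOT_CONCLUSIVE
      next
    }
    tab <- table(votes)
    top <- sort(names(tab)[tab == max(tab)])
    out[i] <- if (length(top) == 1) {
      top
    } else if (mean_labels[i] %in% top) {
      mean_labels[i]
    } else {
      top[1]
    }
  }
  out
}

#' Predict behaviours for a feature table
#'
#' Runs all six classifiers, applies the probability threshold per
#' algorithm, and computes the two ensembles. The returned prediction set
#' carries per-algorithm probability matrices as an attribute so
#' re-thresholding (e.g. a threshold sweep) needs no refitting.
#'
#' @param model A [train_behaviour_model()] fit.
#' @param features Feature table.
#' @param threshold Probability threshold in `[0, 1]` (default 0.5, the
#'   operating point with the best precision/abstention trade-off).
#' @return A tibble (class `prediction_set`) with the burst key, one
#'   `<algorithm>_label` and `<algorithm>_maxp` pair per algorithm,
#'   `mean_label`, `mean_maxp`, and `majority_label`. Attributes: `probs`
#'   (per-algorithm + mean matrices), `classes`, `threshold`, `errors`.
#' @export
predict_bursts <- function(model, features, threshold = 0.5) {
  pp <- predict_probs(model, features)
  out <- rethreshold_predictions(pp$probs, pp$key, threshold,
                                 majority_on = model$config$majority_on)
  attr(out, "errors") <- pp$errors
  out
}

# Assemble a prediction_set tibble from cached probability matrices.
rethreshold_predictions <- function(probs, key, threshold,
                                    majority_on = "thresholded") {
  out <- key
  label_mat <- matrix(NA_character_, nrow(key), length(ALGORITHMS),
                      dimnames = list(NULL, ALGORITHMS))
  for (a in ALGORITHMS) {
    p <- probs[[a]]
    labs <- threshold_labels(p, threshold)
    label_mat[, a] <- labs
    out[[paste0(a, "_label")]] <- labs
    out[[paste0(a, "_maxp")]] <- if (nrow(p) > 0) {
      p[cbind(seq_len(nrow(p)), max.col(p, ties.method = "first"))]
    } else numeric(0)
  }
  mn <- ensemble_mean(probs[ALGORITHMS], threshold)
  out$mean_label <- mn$labels
  out$mean_maxp <- if (nrow(mn$probs) > 0) {
    mn$probs[cbind(seq_len(nrow(mn$probs)),
                   max.col(mn$probs, ties.method = "first"))]
  } else numeric(0)
  vote_mat <- if (majority_on == "argmax") {
    vm <- label_mat
    for (a in ALGORITHMS) vm[, a] <- threshold_labels(probs[[a]], 0)
    vm
  } else label_mat
  out$majority_label <- ensemble_majority(vote_mat, mn$labels)
  attr(out, "probs") <- c(probs[ALGORITHMS], list(mean = mn$probs))
  attr(out, "classes") <- colnames(mn$probs)
  attr(out, "threshold") <- threshold
  class(out) <- c("prediction_set", class(out))
  out
}
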