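test_that("precision and recall follow their confusion-matrix definitions", {
  NC <- not_conclusive_label()
  # perfect classifier: diagonal matrix, no abstention
  true <- rep(behaviour_labels(), each = 5)
  cm <- confusion_matrix(true, true)
  for (b in behaviour_labels()) {
    pr <- precision_recall(cm, b)
    expect_equal(unname(pr["PR"]), 100)
    expect_equal(unname(pr["RE"]), 100)
  }
  ov <- feedscan:::overall_pr_re(cm)
  expect_equal(unname(ov), c(100, 100))

  # worked two-row count: true F = 80 F + 10 R + 10 NC,
  # and 20 non-F bursts predicted F
  true <- c(rep("F", 100), rep("R", 20))
  pred <- c(rep("F", 80), rep("R", 10), rep(NC, 10), rep("F", 20))
  cm <- confusion_matrix(true, pred)
  pr <- precision_recall(cm, "F")
  expect_equal(unname(pr["PR"]), 80)
  expect_equal(unname(pr["RE"]), 80)

  # class never predicted and never true -> 0/0 convention
  pr <- precision_recall(cm, "D")
  expect_equal(unname(pr), c(0, 0))
})

test_that("abstentions count against recall but not precision", {
  NC <- not_conclusive_label()
  true <- rep("F", 10)
  pred <- c(rep("F", 6), rep(NC, 4))
  cm <- confusion_matrix(true, pred)
  pr <- precision_recall(cm, "F")
  expect_equal(unname(pr["PR"]), 100)
  expect_equal(unname(pr["RE"]), 60)
})

test_that("confusion matrices conserve the burst count for every method", {
  ft <- sim_features(seed = 21, n_animals = 1, bursts_per_class = 10)
  cv <- loocv(ft, threshold = 0.5, seed = 1)
  for (m in names(cv$confusion)) {
    expect_equal(sum(cv$confusion[[m]]), nrow(ft))
  }
})

test_that("LOOCV on a separable set is perfect at threshold 0", {
  ft <- blob_features(n_per_class = 10, seed = 31)
  cv <- loocv(ft, threshold = 0, seed = 1)
  ov <- cv$report[cv$report$behaviour == "overall", ]
  expect_equal(ov$PR, rep(100, 8))
  expect_equal(ov$RE, rep(100, 8))
})

test_that("identical feature pairs with opposite labels cap LOOCV accuracy at 50%", {
  set.seed(41)
  base <- matrix(rnorm(10 * 6), ncol = 6)
  mk <- function(label, off) {
    tibble::tibble(
      animal_id = "A1",
      start_time = utc("2017-10-06 04:00:00") + (off + 1:10) * 30,
      n = 40L, mnz = base[, 1], sdz = abs(base[, 2]) + 1, wmz = base[, 3],
      icvz = base[, 4], kz = base[, 5], sz = base[, 6],
      degenerate = FALSE, label = label
    )
  }
  ft <- dplyr::bind_rows(mk("F", 0), mk("R", 10))
  cv <- loocv(ft, threshold = 0, seed = 1)
  # label symmetry bounds every label-symmetric rule at 50%; the SVM is
  # excluded because libsvm's Platt-calibrated probabilities are not
  # label-symmetric on duplicate points and may contradict its own
  # decision rule there
  for (m in setdiff(names(cv$confusion), "SVM")) {
    acc <- sum(diag(cv$confusion[[m]][, behaviour_labels()])) / nrow(ft)
    expect_lte(acc, 0.5)
  }
})

test_that("LOOCV results are reproducible and cached re-thresholding matches", {
  ft <- sim_features(seed = 22, n_animals = 1, bursts_per_class = 8)
  cv1 <- loocv(ft, threshold = 0.5, seed = 3)
  cv2 <- loocv(ft, threshold = 0.5, seed = 3)
  expect_identical(cv1$report, cv2$report)
  # re-thresholding the cache at the same threshold reproduces the matrices
  cms <- feedscan:::cache_confusions(cv1$cache, 0.5)
  expect_identical(cms, cv1$confusion)
})

test_that("abstention fraction grows and recall shrinks with the threshold", {
  ft <- sim_features(seed = 23, n_animals = 1, bursts_per_class = 8)
  cv <- loocv(ft, threshold = 0.5, seed = 1)
  sw <- threshold_sweep(cache = cv$cache, thresholds = c(0, 0.3, 0.5, 0.8, 1.0))
  for (m in unique(sw$method)) {
    s <- sw[sw$method == m, ]
    s <- s[order(s$threshold), ]
    expect_true(all(diff(s$nc_fraction) >= 0))
    expect_true(all(diff(s$RE) <= 1e-9))  # recall is non-increasing
    expect_equal(s$nc_fraction[s$threshold == 0], 0)
  }
})

test_that("the default sweep grid yields six thresholds per method", {
  ft <- sim_features(seed = 24, n_animals = 1, bursts_per_class = 8)
  sw <- threshold_sweep(ft, seed = 1)
  expect_equal(sort(unique(sw$threshold)), seq(0.3, 0.8, by = 0.1))
  for (m in unique(sw$method)) {
    expect_equal(sum(sw$method == m), 6)
  }
})

test_that("PACV transfers across same-distribution animals but degrades under shift", {
  # same distribution: every animal's overall PR in the same range as LOOCV
  ft <- sim_features(seed = 25, n_animals = 3, bursts_per_class = 8)
  pv <- pacv(ft, threshold = 0.5, seed = 1)
  expect_equal(sort(names(pv)), c("C1", "C2", "C3"))
  cv <- loocv(ft, threshold = 0.5, seed = 1)
  loocv_pr <- cv$report$PR[cv$report$method == "Mean" &
                             cv$report$behaviour == "overall"]
  for (a in names(pv)) {
    rep_a <- pv[[a]]$report
    pr_a <- rep_a$PR[rep_a$method == "Mean" & rep_a$behaviour == "overall"]
    expect_lt(abs(pr_a - loocv_pr), 15)
  }

  # one animal with a shifted signal distribution scores lower
  fts <- sim_features(seed = 26, n_animals = 3, bursts_per_class = 10,
                      shifted_animal = "C3")
  pvs <- pacv(fts, threshold = 0.5, seed = 1)
  pr_of <- function(a) {
    r <- pvs[[a]]$report
    r$PR[r$method == "Mean" & r$behaviour == "overall"]
  }
  expect_lt(pr_of("C3"), pr_of("C1"))
  expect_lt(pr_of("C3"), pr_of("C2"))
})

test_that("PACV refuses a single animal", {
  ft <- sim_features(seed = 27, n_animals = 1, bursts_per_class = 6)
  expect_error(pacv(ft, seed = 1), "at least 2 animals")
})

test_that("recall with abstentions counted never exceeds recall ignoring them", {
  NC <- not_conclusive_label()
  set.seed(51)
  for (rep in 1:20) {
    true <- sample(behaviour_labels(), 60, replace = TRUE)
    pred <- sample(c(behaviour_labels(), NC), 60, replace = TRUE)
    cm <- confusion_matrix(true, pred)
    for (b in unique(true)) {
      re_with <- precision_recall(cm, b)["RE"]
      tp <- cm[b, b]
      denom <- sum(cm[b, behaviour_labels()])
      re_without <- if (denom > 0) 100 * tp / denom else 0
      expect_lte(re_with, re_without + 1e-9)
    }
  }
})

test_that("report CSV mirrors the method-by-behaviour layout", {
  ft <- blob_features(n_per_class = 8, seed = 61)
  cv <- loocv(ft, threshold = 0.5, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_report(cv$report, f)
  got <- utils::read.csv(f)
  expect_equal(nrow(got), 8)  # six algorithms + two ensembles
  expect_true(all(c("overall_PR", "overall_RE", "F_PR", "F_RE") %in% names(got)))
  expect_true(all(got$overall_PR >= 0 & got$overall_PR <= 100))
})
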