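make_features <- function(qrs = 0.099, hr = 72, sdnn = 30, rmssd = 25, beats = 100) {
  record_features(qrs_mean_s = qrs, hr_bpm = hr, sdnn_ms = sdnn,
                  rmssd_ms = rmssd, beats = beats)
}

test_that("the QRS-interval rule applies a closed tolerance band", {
  expect_equal(classify_qrs_interval(make_features(qrs = 0.099)), "regular")
  expect_equal(classify_qrs_interval(make_features(qrs = 0.150), tolerance = 0.02),
               "irregular")
  # boundary: deviation exactly equal to the tolerance is still regular
  expect_equal(classify_qrs_interval(make_features(qrs = 0.099 + 0.02),
                                     tolerance = 0.02), "regular")
  expect_error(make_features(qrs = NaN), "finite")
})

test_that("the centroid rule matches a brute-force nearest-centroid loop", {
  set.seed(31)
  train <- c(lapply(1:10, function(i) make_features(qrs = rnorm(1, 0.099, 0.005),
                                                    sdnn = rnorm(1, 20, 3),
                                                    rmssd = rnorm(1, 18, 3))),
             lapply(1:10, function(i) make_features(qrs = rnorm(1, 0.14, 0.01),
                                                    sdnn = rnorm(1, 90, 10),
                                                    rmssd = rnorm(1, 80, 10))))
  labels <- rep(c("regular", "irregular"), each = 10)
  model <- fit_centroids(train, labels)

  expect_equal(classify_qrs_hrv(train[[1]], model), "regular")

  brute <- function(f, model) {
    z <- (c(f$qrs_mean_s, f$hr_bpm, f$sdnn_ms, f$rmssd_ms) - model$center) / model$scale
    dr <- sqrt(sum((z - model$regular)^2))
    di <- sqrt(sum((z - model$irregular)^2))
    if (di < dr) "irregular" else "regular"
  }
  for (k in 1:200) {
    f <- make_features(qrs = runif(1, 0.05, 0.2), hr = runif(1, 40, 140),
                       sdnn = runif(1, 1, 150), rmssd = runif(1, 1, 150))
    expect_identical(classify_qrs_hrv(f, model), brute(f, model))
  }
  # degenerate model: identical centroids warn and fall back to regular
  degen <- model
  degen$irregular <- degen$regular
  expect_warning(out <- classify_qrs_hrv(make_features(), degen), "degenerate")
  expect_equal(out, "regular")
})

test_that("a feature vector at the regular prototype gets fuzzy membership 1", {
  train <- c(lapply(1:5, function(i) make_features(sdnn = 20 + i)),
             lapply(1:5, function(i) make_features(qrs = 0.15, sdnn = 100 + i)))
  model <- fit_centroids(train, rep(c("regular", "irregular"), each = 5))
  cfg <- fuzzy_config(beats_center = 100)
  at_prototype <- make_features(qrs = 0.099, beats = 100)
  out <- classify_fuzzy(at_prototype, cfg, model)
  expect_equal(out$label, "regular")
  expect_equal(unname(out$memberships["regular"]), 1)
  expect_true(all(out$memberships >= 0 & out$memberships <= 1))
})

test_that("fuzzy decisions over a grid equal an independent rule-table evaluation", {
  cfg <- fuzzy_config(beats_center = 100)
  # independent evaluator: recompute memberships and scan the table by hand
  tri <- function(x, a, b, c) {
    if (x <= a || x >= c) 0 else if (x <= b) (x - a) / (b - a) else (c - x) / (c - b)
  }
  shoulder_l <- function(x, a, b) if (x <= a) 1 else if (x >= b) 0 else (b - x) / (b - a)
  shoulder_r <- function(x, a, b) if (x <= a) 0 else if (x >= b) 1 else (x - a) / (b - a)
  oracle <- function(qdev, margin, beats) {
    m <- list(
      qrs = c(low = shoulder_l(qdev, 0.02, 0.05),
              medium = tri(qdev, 0.02, 0.035, 0.05),
              high = shoulder_r(qdev, 0.02, 0.05)),
      margin = c(low = shoulder_l(margin, 0, 1),
                 medium = tri(margin, 0, 0.5, 1),
                 high = shoulder_r(margin, 0, 1)),
      beats = c(low = shoulder_l((beats - 100) / 100, -0.5, 0),
                normal = tri((beats - 100) / 100, -0.5, 0, 0.5),
                high = shoulder_r((beats - 100) / 100, 0, 0.5)))
    agg <- c(regular = 0, irregular = 0)
    fire <- function(label, ...) {
      agg[label] <<- max(agg[label], min(...))
    }
    fire("regular", m$qrs["low"], m$margin["low"])
    fire("regular", m$qrs["low"], m$margin["medium"])
    fire("regular", m$qrs["medium"], m$margin["low"])
    fire("irregular", m$qrs["high"])
    fire("irregular", m$margin["high"])
    fire("regular", m$qrs["medium"], m$margin["medium"], m$beats["normal"])
    fire("irregular", m$qrs["medium"], m$margin["medium"], m$beats["low"])
    fire("irregular", m$qrs["medium"], m$margin["medium"], m$beats["high"])
    if (agg["irregular"] > agg["regular"]) "irregular" else "regular"
  }
  qdevs <- seq(0, 0.08, length.out = 50)
  margins <- seq(-1.5, 2, length.out = 50)
  for (qd in qdevs) {
    for (mg in margins) {
      got <- ecgflow:::fuzzy_decide(cfg, c(qrs = qd, margin = mg, beats = 100))
      expect_true(all(got$memberships >= 0 & got$memberships <= 1))
      expect_identical(got$label, oracle(qd, mg, 100))
    }
  }
  # the beat count tips the intermediate zone
  mid <- c(qrs = 0.035, margin = 0.5, beats = 100)
  expect_identical(ecgflow:::fuzzy_decide(cfg, mid)$label, "regular")
  low_beats <- c(qrs = 0.035, margin = 0.5, beats = 30)
  expect_identical(ecgflow:::fuzzy_decide(cfg, low_beats)$label, "irregular")
})

test_that("fuzzy configs with gaps in coverage are rejected at load", {
  bad_rules <- list(list(qrs = "weird", margin = NA, beats = NA, label = "regular"))
  expect_error(fuzzy_config(rules = bad_rules), "unknown qrs term")
  expect_error(fuzzy_config(qrs_knees = c(0.05, 0.02)), "increasing")
})

test_that("confusion counts partition the records with irregular as positive", {
  pred <- rep(c("irregular", "regular"), c(23, 7))
  cc <- confusion_counts(pred, pred)
  expect_equal(unlist(cc[c("tn", "tp", "fn", "fp")]),
               c(tn = 7, tp = 23, fn = 0, fp = 0))

  actual <- rep(c("irregular", "regular"), c(23, 7))
  pred2 <- c(rep("irregular", 23), rep("irregular", 7))  # all negatives wrong
  cc2 <- confusion_counts(pred2, actual)
  expect_equal(unlist(cc2[c("tn", "tp", "fn", "fp")]),
               c(tn = 0, tp = 23, fn = 0, fp = 7))

  set.seed(41)
  for (k in 1:20) {
    n <- sample(5:50, 1)
    p <- sample(c("regular", "irregular"), n, replace = TRUE)
    a <- sample(c("regular", "irregular"), n, replace = TRUE)
    cc <- confusion_counts(p, a)
    expect_equal(cc$tn + cc$tp + cc$fn + cc$fp, n)
  }
  expect_error(confusion_counts("regular", c("regular", "irregular")), "equally long")
})

test_that("the as-printed metric formulas reproduce their defining examples", {
  m <- classification_metrics(structure(list(tn = 6, tp = 16, fn = 7, fp = 1),
                                        class = "confusion_counts"))
  expect_equal(m$precision, 69.5652, tolerance = 1e-4)
  expect_equal(m$specificity, 69.5652, tolerance = 1e-4)
  expect_equal(m$sensitivity, 72.7273, tolerance = 1e-4)
  expect_equal(m$accuracy, 73.3333, tolerance = 1e-4)

  m2 <- classification_metrics(structure(list(tn = 0, tp = 23, fn = 0, fp = 7),
                                         class = "confusion_counts"))
  expect_equal(m2$precision, 100)
  expect_equal(m2$specificity, 100)
  expect_equal(m2$sensitivity, 100)
  expect_equal(m2$accuracy, 76.667, tolerance = 1e-4)

  m3 <- classification_metrics(structure(list(tn = 0, tp = 12, fn = 0, fp = 0),
                                         class = "confusion_counts"))
  expect_true(all(unlist(m3[c("precision", "specificity", "sensitivity",
                              "accuracy")]) == 100))
})

test_that("perfect agreement yields accuracy 100 and precision always equals specificity", {
  set.seed(43)
  for (k in 1:20) {
    x <- sample(c("regular", "irregular"), sample(3:40, 1), replace = TRUE)
    m <- suppressWarnings(classification_metrics(confusion_counts(x, x)))
    expect_equal(m$accuracy, 100)
  }
  for (k in 1:50) {
    cc <- structure(as.list(setNames(sample(0:30, 4, replace = TRUE),
                                     c("tn", "tp", "fn", "fp"))),
                    class = "confusion_counts")
    if (cc$tn + cc$tp + cc$fn + cc$fp == 0) next
    m <- suppressWarnings(classification_metrics(cc))
    expect_identical(m$precision, m$specificity)
  }
  # standard convention differs and is labelled
  ms <- classification_metrics(
    confusion_counts(c("regular", "irregular", "regular"),
                     c("irregular", "irregular", "regular")),
    convention = "standard")
  expect_equal(ms$sensitivity, 50)  # textbook Tp/(Tp+Fn)
  expect_identical(ms$convention, "standard")
})
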