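#' Per-record features for rhythm classification
#'
#' The feature vector the classification rules consume: mean QRS interval,
#' mean heart rate, SDNN, RMSSD, and the beat count.
#'
#' @param qrs_mean_s mean QRS interval, seconds.
#' @param hr_bpm mean heart rate, bpm.
#' @param sdnn_ms,rmssd_ms time-domain HRV statistics, ms.
#' @param beats number of detected beats, at least 2.
#' @return An object of class `record_features`.
#' @export
record_features <- function(qrs_mean_s, hr_bpm, sdnn_ms, rmssd_ms, beats) {
  vals <- c(qrs_mean_s = qrs_mean_s, hr_bpm = hr_bpm, sdnn_ms = sdnn_ms,
            rmssd_ms = rmssd_ms, beats = beats)
  if (!all(is.finite(vals))) stop("all features must be finite", call. = FALSE)
  if (beats < 2) stop("'beats' must be at least 2", call. = FALSE)
  structure(as.list(vals), class = "record_features")
}

feature_matrix <- function(features_list) {
  do.call(rbind, lapply(features_list, function(f) {
    unlist(f[c("qrs_mean_s", "hr_bpm", "sdnn_ms", "rmssd_ms")])
  }))
}

#' Rule A: classify by mean QRS interval
#'
#' A record is regular when its mean QRS interval lies within `tolerance` of
#' the standard QRS duration (closed interval: a deviation exactly equal to
#' the tolerance is still regular).
#'
#' @param features a [record_features()].
#' @param standard_qrs standard QRS interval, seconds (default 0.099 s).
#' @param tolerance allowed deviation, seconds.
#' @return `"regular"` or `"irregular"`.
#' @export
classify_qrs_interval <- function(features, standard_qrs = 0.099, tolerance = 0.02) {
  stopifnot(inherits(features, "record_features"))
  # closed interval; the epsilon keeps boundary cases like 0.099 + 0.02 regular
  # under floating-point representation
  if (abs(features$qrs_mean_s - standard_qrs) <= tolerance + 1e-12) {
    "regular"
  } else {
    "irregular"
  }
}

#' Fit class centroids for the distance-based rules
#'
#' Standardizes the four-dimensional feature vector (mean QRS, mean HR,
#' SDNN, RMSSD) using the pooled per-feature mean and SD of the training
#' records, then stores each class's centroid in that standardized space.
#'
#' @param features_list list of [record_features()].
#' @param labels character vector of `"regular"`/`"irregular"` labels, one
#'   per record; both classes must be present.
#' @return An object of class `centroid_model`.
#' @export
fit_centroids <- function(features_list, labels) {
  labels <- match.arg(labels, c("regular", "irregular"), several.ok = TRUE)
  X <- feature_matrix(features_list)
  if (nrow(X) != length(labels)) stop("one label per record required", call. = FALSE)
  if (!all(c("regular", "irregular") %in% labels)) {
    stop("training data must contain both classes", call. = FALSE)
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, pop_sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  structure(list(
    center = ctr, scale = scl,
    regular = colMeans(Z[labels == "regular", , drop = FALSE]),
    irregular = colMeans(Z[labels == "irregular", , drop = FALSE])
  ), class = "centroid_model")
}

centroid_distances <- function(features, model) {
  z <- (unlist(features[c("qrs_mean_s", "hr_bpm", "sdnn_ms", "rmssd_ms")]) -
          model$center) / model$scale
  c(regular = sqrt(sum((z - model$regular)^2)),
    irregular = sqrt(sum((z - model$irregular)^2)))
}

#' Rule B: classify by distance to class centroids
#'
#' Assigns the class of the nearer centroid in standardized feature space
#' (Euclidean distance). When the two distances differ by less than
#' `margin_threshold` — including exact ties — the conservative call is
#' `"regular"`.
#'
#' @param features a [record_features()].
#' @param model a [fit_centroids()] model.
#' @param margin_threshold minimum distance margin required to call a record
#'   irregular.
#' @return `"regular"` or `"irregular"`.
#' @export
classify_qrs_hrv <- function(features, model, margin_threshold = 0) {
  stopifnot(inherits(features, "record_features"), inherits(model, "centroid_model"))
  if (isTRUE(all.equal(model$regular, model$irregular))) {
    warning("degenerate centroids (classes coincide); labelling regular")
    return("regular")
  }
  d <- centroid_distances(features, model)
  if (abs(d["regular"] - d["irregular"]) < margin_threshold) return("regular")
  if (d["irregular"] < d["regular"]) "irregular" else "regular"
}

# --- fuzzy rule ------------------------------------------------------------

# piecewise-linear membership: shoulder-left, triangle, shoulder-right
mf_left <- function(x, a, b) ifelse(x <= a, 1, ifelse(x >= b, 0, (b - x) / (b - a)))
mf_right <- function(x, a, b) ifelse(x <= a, 0, ifelse(x >= b, 1, (x - a) / (b - a)))
mf_tri <- function(x, a, b, c) {
  ifelse(x <= a | x >= c, 0, ifelse(x <= b, (x - a) / (b - a), (c - x) / (c - b)))
}

#' Configuration of the fuzzy QRS + HRV rule
#'
#' The fuzzy rule judges three inputs: the absolute deviation of the mean
#' QRS interval from the standard duration (s), the centroid-distance margin
#' `d_regular - d_irregular` in standardized units (positive when the record
#' sits closer to the irregular centroid), and the beat count relative to
#' the cohort. Each input carries low/medium/high terms built from
#' triangular and shoulder memberships; a rule table maps term combinations
#' to the two output labels. The default table calls a record regular when
#' QRS deviation and margin are both small, irregular when either is high,
#' and lets an abnormal beat count tip the balance in the intermediate zone.
#'
#' @param standard_qrs standard QRS interval, seconds.
#' @param qrs_knees `c(low, high)` knees of the QRS-deviation terms, seconds.
#' @param margin_knees `c(low, high)` knees of the margin terms,
#'   standardized units.
#' @param beats_center nominal beat count (e.g. the cohort median).
#' @param beats_spread relative half-width of the "normal" beat-count term.
#' @param rules optional replacement rule table: a list of rules, each a
#'   list with elements `qrs`, `margin`, `beats` (term name or `NA` for
#'   "any") and `label`.
#' @return An object of class `fuzzy_config`.
#' @export
fuzzy_config <- function(standard_qrs = 0.099, qrs_knees = c(0.02, 0.05),
                         margin_knees = c(0, 1), beats_center = NULL,
                         beats_spread = 0.5, rules = NULL) {
  if (length(qrs_knees) != 2L || qrs_knees[1] >= qrs_knees[2]) {
    stop("'qrs_knees' must be increasing c(low, high)", call. = FALSE)
  }
  if (length(margin_knees) != 2L || margin_knees[1] >= margin_knees[2]) {
    stop("'margin_knees' must be increasing c(low, high)", call. = FALSE)
  }
  if (beats_spread <= 0) stop("'beats_spread' must be positive", call. = FALSE)
  if (is.null(rules)) {
    rules <- list(
      list(qrs = "low", margin = "low", beats = NA, label = "regular"),
      list(qrs = "low", margin = "medium", beats = NA, label = "regular"),
      list(qrs = "medium", margin = "low", beats = NA, label = "regular"),
      list(qrs = "high", margin = NA, beats = NA, label = "irregular"),
      list(qrs = NA, margin = "high", beats = NA, label = "irregular"),
      list(qrs = "medium", margin = "medium", beats = "normal", label = "regular"),
      list(qrs = "medium", margin = "medium", beats = "low", label = "irregular"),
      list(qrs = "medium", margin = "medium", beats = "high", label = "irregular")
    )
  }
  terms <- list(qrs = c("low", "medium", "high"),
                margin = c("low", "medium", "high"),
                beats = c("low", "normal", "high"))
  for (r in rules) {
    if (!is.list(r) || !all(c("qrs", "margin", "beats", "label") %in% names(r))) {
      stop("each rule needs elements qrs, margin, beats, label", call. = FALSE)
    }
    for (v in c("qrs", "margin", "beats")) {
      if (!is.na(r[[v]]) && !(r[[v]] %in% terms[[v]])) {
        stop(sprintf("unknown %s term '%s' in rule table", v, r[[v]]), call. = FALSE)
      }
    }
    if (!(r$label %in% c("regular", "irregular"))) {
      stop("rule labels must be 'regular' or 'irregular'", call. = FALSE)
    }
  }
  cfg <- structure(list(standard_qrs = standard_qrs, qrs_knees = qrs_knees,
                        margin_knees = margin_knees, beats_center = beats_center,
                        beats_spread = beats_spread, rules = rules),
                   class = "fuzzy_config")
  # coverage: every point of each input range must activate some term
  probe <- list(qrs = seq(0, 4 * qrs_knees[2], length.out = 101),
                margin = seq(margin_knees[1] - 3, margin_knees[2] + 3, length.out = 101),
                beats = seq(0, 4 * (beats_center %||% 100), length.out = 101))
  for (v in names(probe)) {
    mm <- vapply(probe[[v]], function(x) max(fuzzy_memberships(cfg, v, x)), numeric(1))
    if (any(mm <= 0)) {
      stop(sprintf("membership functions do not cover the %s range", v), call. = FALSE)
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# memberships of one input value for the three terms of variable v
fuzzy_memberships <- function(config, v, x) {
  if (v == "qrs") {
    k <- config$qrs_knees
    c(low = mf_left(x, k[1], k[2]),
      medium = mf_tri(x, k[1], mean(k), k[2]),
      high = mf_right(x, k[1], k[2]))
  } else if (v == "margin") {
    k <- config$margin_knees
    c(low = mf_left(x, k[1], k[2]),
      medium = mf_tri(x, k[1], mean(k), k[2]),
      high = mf_right(x, k[1], k[2]))
  } else {
    ctr <- config$beats_center %||% x  # with no cohort reference, count is nominal
    rel <- if (ctr > 0) (x - ctr) / ctr else 0
    sp <- config$beats_spread
    c(low = mf_left(rel, -sp, 0),
      normal = mf_tri(rel, -sp, 0, sp),
      high = mf_right(rel, 0, sp))
  }
}

#' Rule C: fuzzy QRS + HRV classification
#'
#' Evaluates the rule table of a [fuzzy_config()] with min-conjunction of
#' the antecedent memberships, aggregates rule strengths per output label by
#' max, and returns the label with the larger aggregate membership (ties are
#' called regular).
#'
#' @param features a [record_features()].
#' @param config a [fuzzy_config()].
#' @param model a [fit_centroids()] model used to compute the
#'   centroid-distance margin.
#' @return list with `label` and `memberships` (named numeric, both in
#'   `[0, 1]`).
#' @export
classify_fuzzy <- function(features, config, model) {
  stopifnot(inherits(features, "record_features"), inherits(config, "fuzzy_config"),
            inherits(model, "centroid_model"))
  d <- centroid_distances(features, model)
  inputs <- c(qrs = abs(features$qrs_mean_s - config$standard_qrs),
              margin = unname(d["regular"] - d["irregular"]),
              beats = features$beats)
  fuzzy_decide(config, inputs)
}

# rule-table evaluation on raw input values; shared by classify_fuzzy and
# kept separate so tests can drive the table directly
fuzzy_decide <- function(config, inputs) {
  mem <- lapply(c("qrs", "margin", "beats"),
                function(v) fuzzy_memberships(config, v, inputs[[v]]))
  names(mem) <- c("qrs", "margin", "beats")
  agg <- c(regular = 0, irregular = 0)
  for (r in config$rules) {
    strength <- 1
    for (v in c("qrs", "margin", "beats")) {
      if (!is.na(r[[v]])) strength <- min(strength, mem[[v]][[r[[v]]]])
    }
    agg[r$label] <- max(agg[r$label], strength)
  }
  label <- if (agg["irregular"] > agg["regular"]) "irregular" else "regular"
  list(label = label, memberships = agg)
}

# --- evaluation ------------------------------------------------------------

#' Confusion counts for rhythm classification
#'
#' The irregular class is the positive class. With `Diff` the
#' prediction/truth disagreement indicator: Tp counts agreements on actual
#' irregulars, Tn agreements on actual regulars, Fn disagreements on actual
#' irregulars, Fp disagreements on actual regulars; the four counts
#' partition the records.
#'
#' @param predicted,actual character vectors of `"regular"`/`"irregular"`
#'   labels, equal length, at least 1.
#' @return An object of class `confusion_counts` with fields `tn`, `tp`,
#'   `fn`, `fp`.
#' @export
confusion_counts <- function(predicted, actual) {
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  if (length(predicted) != length(actual) || length(actual) < 1L) {
    stop("'predicted' and 'actual' must be equally long and nonempty", call. = FALSE)
  }
  ok <- c("regular", "irregular")
  if (!all(predicted %in% ok) || !all(actual %in% ok)) {
    stop("labels must be 'regular' or 'irregular'", call. = FALSE)
  }
  agree <- predicted == actual
  pos <- actual == "irregular"
  structure(list(tn = sum(agree & !pos), tp = sum(agree & pos),
                 fn = sum(!agree & pos), fp = sum(!agree & !pos)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> Tn=%d Tp=%d Fn=%d Fp=%d (n=%d)\n",
              x$tn, x$tp, x$fn, x$fp, x$tn + x$tp + x$fn + x$fp))
  invisible(x)
}

#' Percentage metrics from confusion counts
#'
#' The default `"as_printed"` convention implements the evaluation formulas
#' exactly as this pipeline's evaluation protocol defines them — note they
#' are not the textbook definitions:
#' sensitivity `= Tp/(Tp+Tn) * 100`, specificity `= Tp/(Tp+Fn) * 100`,
#' precision `= Tp/(Tp+Fn) * 100` (identical to specificity by
#' construction), accuracy `= (Tp+Tn)/(Tp+Tn+Fn+Fp) * 100`. The
#' `"standard"` convention computes the textbook quantities
#' (sensitivity `= Tp/(Tp+Fn)`, specificity `= Tn/(Tn+Fp)`, precision
#' `= Tp/(Tp+Fp)`) for comparison. A zero denominator yields 0 with a
#' warning.
#'
#' @param counts a [confusion_counts()] with at least one nonzero count.
#' @param convention `"as_printed"` or `"standard"`.
#' @return An object of class `metrics_report`: a list with `precision`,
#'   `specificity`, `sensitivity`, `accuracy` (percent) and `convention`.
#' @examples
#' classification_metrics(confusion_counts(c("regular", "irregular"),
#'                                         c("regular", "irregular")))
#' @export
classification_metrics <- function(counts, convention = c("as_printed", "standard")) {
  convention <- match.arg(convention)
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tn + counts$tp + counts$fn + counts$fp
  if (total == 0L) stop("all counts are zero", call. = FALSE)
  ratio <- function(num, den) {
    if (den == 0) {
      warning("zero denominator in a metric; reporting 0")
      return(0)
    }
    100 * num / den
  }
  out <- if (convention == "as_printed") {
    list(precision = ratio(counts$tp, counts$tp + counts$fn),
         specificity = ratio(counts$tp, counts$tp + counts$fn),
         sensitivity = ratio(counts$tp, counts$tp + counts$tn),
         accuracy = ratio(counts$tp + counts$tn, total))
  } else {
    list(precision = ratio(counts$tp, counts$tp + counts$fp),
         specificity = ratio(counts$tn, counts$tn + counts$fp),
         sensitivity = ratio(counts$tp, counts$tp + counts$fn),
         accuracy = ratio(counts$tp + counts$tn, total))
  }
  structure(c(out, list(convention = convention)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> (%s definitions)\n  precision %.4f | specificity %.4f | sensitivity %.4f | accuracy %.4f\n",
    x$convention, x$precision, x$specificity, x$sensitivity, x$accuracy))
  invisible(x)
}
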