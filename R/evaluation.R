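#' Stratified holdout split
#'
#' Randomly halves each outcome class into training and test sets
#' (mutually exclusive, union = input).  On odd class counts the larger
#' half goes to training, so a 57/177 cohort yields 29/89 training and
#' 28/88 test records.
#'
#' @param data labeled data.frame.
#' @param seed integer seed.
#' @param fraction fraction assigned to training (default 0.5); the
#'   training share of each class is `fraction` rounded half up.
#' @param outcome outcome column name.
#' @return list with `training` and `test` data.frames.
#' @export
holdout_split <- function(data, seed, fraction = 0.5, outcome = "outcome") {
  sp <- stratified_split(data, seed, fraction, outcome)
  list(training = sp$first, test = sp$second)
}

# Shared stratified splitter: `first` receives round-half-up(fraction * n)
# records of each class.  Used by both the holdout protocol and the
# virtual-sample resampling inside marker selection.
stratified_split <- function(data, seed, fraction = 0.5,
                             outcome = "outcome") {
  stopifnot(fraction > 0, fraction < 1 || fraction == 1)
  idx <- class_indices(data, outcome)
  with_seed(seed, {
    pick <- lapply(idx, function(ix) {
      k <- round_half_up(length(ix) * fraction)
      sort(sample(ix, k))
    })
    first <- sort(c(pick$recurrence, pick$nonrecurrence))
    second <- setdiff(seq_len(nrow(data)), first)
    if (!length(second))
      stop("split fraction ", fraction, " leaves no held-out records",
           call. = FALSE)
    list(first = data[first, , drop = FALSE],
         second = data[second, , drop = FALSE])
  })
}

#' Confusion matrix for the two-class problem
#'
#' The positive class is recurrence.  `confusion()` tallies predictions
#' against truths; `confusion_matrix()` builds one from the four cells.
#'
#' @param predicted,truth vectors coercible to the outcome factor.
#' @return an object of class `"confusion_matrix"`: a named integer vector
#'   `(TP, FN, FP, TN)`.
#' @export
confusion <- function(predicted, truth) {
  p <- as_outcome(predicted)
  t <- as_outcome(truth)
  stopifnot(length(p) == length(t))
  confusion_matrix(TP = sum(p == "recurrence" & t == "recurrence"),
                   FN = sum(p == "nonrecurrence" & t == "recurrence"),
                   FP = sum(p == "recurrence" & t == "nonrecurrence"),
                   TN = sum(p == "nonrecurrence" & t == "nonrecurrence"))
}

#' @rdname confusion
#' @param TP,FN,FP,TN nonnegative integer cell counts.
#' @export
confusion_matrix <- function(TP, FN, FP, TN) {
  cells <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  stopifnot(all(cells >= 0), all(cells == as.integer(cells)))
  structure(as.integer(cells), names = names(cells),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(x[c("TP", "FN", "FP", "TN")], 2, 2, byrow = TRUE,
              dimnames = list(truth = c("recurrence", "nonrecurrence"),
                              predicted = c("recurrence", "nonrecurrence")))
  print(m)
  invisible(x)
}

#' Diagnostic metric suite
#'
#' Computes, from a confusion matrix with recurrence as the positive class:
#' sensitivity (recall) TP/(TP+FN), specificity TN/(TN+FP), accuracy,
#' Youden index (sensitivity + specificity - 1), F1 measure
#' (2 * precision * recall / (precision + recall)), and the diagnostic odds
#' ratio (TP*TN)/(FN*FP).  The DOR is `Inf` when `FN*FP = 0` with
#' `TP*TN > 0`, and `NaN` when both products are zero.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `"metric_report"`: named numeric vector with
#'   elements `sensitivity`, `specificity`, `accuracy`, `youden`, `f1`,
#'   `dor` (raw, unrounded; the print method shows two decimals, half-up,
#'   as clinical tables conventionally do).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  TP <- cm[["TP"]]; FN <- cm[["FN"]]; FP <- cm[["FP"]]; TN <- cm[["TN"]]
  if (TP + FN == 0 || TN + FP == 0)
    stop("both classes must be present to compute sensitivity/specificity",
         call. = FALSE)
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  acc <- (TP + TN) / sum(cm)
  prec <- if (TP + FP > 0) TP / (TP + FP) else NaN
  f1 <- if (is.nan(prec) || prec + sens == 0) 0
        else 2 * prec * sens / (prec + sens)
  dor <- if (FN * FP == 0) {
    if (TP * TN > 0) Inf else NaN
  } else (TP * TN) / (FN * FP)
  structure(c(sensitivity = sens, specificity = spec, accuracy = acc,
              youden = sens + spec - 1, f1 = f1, dor = dor),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 2, ...) {
  v <- round_half_up(unclass(x), digits)
  lab <- c(sensitivity = "Sensitivity, recall", specificity = "Specificity",
           accuracy = "Accuracy", youden = "Youden index",
           f1 = "F1 measure", dor = "Diagnostic odds ratio")
  for (k in c("accuracy", "sensitivity", "specificity", "f1", "youden",
              "dor"))
    cat(sprintf("  %-22s %s\n", lab[[k]], format(v[[k]], nsmall = digits)))
  invisible(x)
}

#' Reconstruct a confusion matrix from published sensitivity/specificity
#'
#' Published comparisons often print only an operating point (sensitivity,
#' specificity) and the class sizes; since `TP = sensitivity * n_pos` and
#' `TN = specificity * n_neg` are integers before 2-decimal rounding, the
#' full matrix is recovered by rounding half up.  This lets every derived
#' metric (accuracy, F1, Youden, DOR) of a published system be recomputed
#' and checked.
#'
#' @param sensitivity,specificity published values (typically 2 decimals).
#' @param n_pos,n_neg test-set class sizes (positives = recurrence).
#' @return a [confusion_matrix()].
#' @examples
#' metrics(reconstruct_confusion(0.86, 0.49, 28, 88))
#' @export
reconstruct_confusion <- function(sensitivity, specificity, n_pos, n_neg) {
  TP <- round_half_up(sensitivity * n_pos)
  TN <- round_half_up(specificity * n_neg)
  confusion_matrix(TP = TP, FN = n_pos - TP, FP = n_neg - TN, TN = TN)
}

#' Default nested training-subset schedule
#'
#' Six nested subsets for a training set of `n1` recurrence and `n2`
#' nonrecurrence records.  For the reference 29/89 training set this is
#' (5,15), (6,17), then a linear interpolation to the full set:
#' (12,35), (18,53), (23,71), (29,89).  Other sizes scale the first two
#' steps proportionally.
#'
#' @param n1,n2 training class sizes.
#' @return a two-column integer matrix (recurrence, nonrecurrence), one row
#'   per subset, strictly increasing componentwise.
#' @export
default_subset_schedule <- function(n1, n2) {
  s1 <- c(max(2, round_half_up(n1 * 5 / 29)),
          max(2, round_half_up(n2 * 15 / 89)))
  s2 <- s1 + c(1, 2)
  steps <- vapply(1:4, function(k) {
    c(round_half_up(s2[1] + (n1 - s2[1]) * k / 4),
      round_half_up(s2[2] + (n2 - s2[2]) * k / 4))
  }, numeric(2))
  sched <- rbind(s1, s2, t(steps))
  dimnames(sched) <- list(NULL, c("recurrence", "nonrecurrence"))
  if (any(diff(sched[, 1]) <= 0) || any(diff(sched[, 2]) <= 0))
    stop("training set too small for the default 6-step schedule; ",
         "supply an explicit schedule", call. = FALSE)
  storage.mode(sched) <- "integer"
  sched
}

# One nested chain of per-class training indices for a schedule: permute
# each class once, take prefixes — so S_k is contained in S_{k+1} by
# construction.
draw_nested_chain <- function(idx1, idx2, schedule, seed) {
  with_seed(seed, {
    p1 <- sample(idx1)
    p2 <- sample(idx2)
    lapply(seq_len(nrow(schedule)), function(k) {
      c(p1[seq_len(schedule[k, 1])], p2[seq_len(schedule[k, 2])])
    })
  })
}

#' Learning curve over nested training subsets
#'
#' Measures how test-set sensitivity grows with training-set size.  Each
#' trial draws one nested chain of training subsets (per-class random
#' prefixes, so each subset contains the previous one), fits the discrete
#' Bayes classifier on every subset, and evaluates on the fixed test set;
#' means and confidence intervals are taken across trials.
#'
#' @param training,test labeled data.frames.
#' @param scheme a [cutoff_scheme()].
#' @param markers selected marker names.
#' @param schedule two-column matrix of per-class subset sizes
#'   (default [default_subset_schedule()] for the training set).
#' @param trials number of independent chains (default 30).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @param ci `"normal"` for the normal approximation across trials, or
#'   `"percentile"` for percentile intervals.
#' @param ... passed to [dbayes()] (priors, smoothing, tie-break).
#' @return a data.frame of class `"learning_curve"`: per subset, the class
#'   sizes, total size, mean sensitivity and specificity, and the CI bounds
#'   for sensitivity.
#' @export
learning_curve <- function(training, test, scheme, markers,
                           schedule = NULL, trials = 30, seed,
                           level = 0.95, ci = c("normal", "percentile"),
                           ...) {
  ci <- match.arg(ci)
  idx <- class_indices(training)
  schedule <- schedule %||% default_subset_schedule(length(idx$recurrence),
                                                    length(idx$nonrecurrence))
  if (any(schedule[, 1] > length(idx$recurrence)) ||
      any(schedule[, 2] > length(idx$nonrecurrence)))
    stop("schedule exceeds available training records", call. = FALSE)
  test_div <- discretize(test, scheme, markers)
  truth <- as_outcome(test$outcome)
  seeds <- derive_seeds(seed, trials)
  K <- nrow(schedule)
  sens <- matrix(NA_real_, trials, K)
  spec <- matrix(NA_real_, trials, K)
  for (t in seq_len(trials)) {
    chain <- draw_nested_chain(idx$recurrence, idx$nonrecurrence,
                               schedule, seeds[t])
    for (k in seq_len(K)) {
      fit <- dbayes(training[chain[[k]], , drop = FALSE], scheme,
                    markers = markers, ...)
      cm <- confusion(predict(fit, newdata = test_div, divisions = TRUE),
                      truth)
      m <- metrics(cm)
      sens[t, k] <- m[["sensitivity"]]
      spec[t, k] <- m[["specificity"]]
    }
  }
  alpha <- 1 - level
  bounds <- vapply(seq_len(K), function(k) {
    v <- sens[, k]
    if (ci == "normal") {
      se <- stats::sd(v) / sqrt(trials)
      mean(v) + c(-1, 1) * stats::qnorm(1 - alpha / 2) * se
    } else {
      stats::quantile(v, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    }
  }, numeric(2))
  out <- data.frame(
    n_recurrence = schedule[, 1], n_nonrecurrence = schedule[, 2],
    n_total = rowSums(schedule),
    sensitivity = colMeans(sens), lower = bounds[1, ], upper = bounds[2, ],
    specificity = colMeans(spec))
  class(out) <- c("learning_curve", "data.frame")
  attr(out, "trials") <- trials
  attr(out, "level") <- level
  out
}

#' @export
plot.learning_curve <- function(x, ...) {
  graphics::plot(x$n_total, x$sensitivity, type = "b", pch = 19,
                 ylim = range(c(x$lower, x$upper)),
                 xlab = "Number of training samples",
                 ylab = "Sensitivity", ...)
  graphics::arrows(x$n_total, x$lower, x$n_total, x$upper,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' ROC operating points by marker count
#'
#' The discrete Bayes classifier has no score threshold to sweep; its ROC
#' curve is traced by varying the number of markers.  For each entry of
#' `combos` a classifier is fitted on the full training set and evaluated
#' on the test set, yielding one (1 - specificity, sensitivity) point; the
#' (0,0) and (1,1) anchors are added and points are ordered by
#' false-positive rate.  Coincident points (marker counts with identical
#' performance) are retained.
#'
#' @param training,test labeled data.frames.
#' @param scheme a [cutoff_scheme()].
#' @param combos named list: marker-count label -> character vector of
#'   marker names (e.g. the per-size candidates of [select_markers()]).
#' @param ... passed to [dbayes()].
#' @return a data.frame of class `"roc_points"` with columns `label`,
#'   `fpr`, `sensitivity`, `specificity`, ordered by `fpr` then
#'   sensitivity.
#' @export
roc_points <- function(training, test, scheme, combos, ...) {
  truth <- as_outcome(test$outcome)
  pts <- lapply(names(combos), function(lbl) {
    fit <- dbayes(training, scheme, markers = combos[[lbl]], ...)
    m <- metrics(confusion(predict(fit, newdata = test), truth))
    data.frame(label = lbl, fpr = 1 - m[["specificity"]],
               sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]])
  })
  out <- rbind(
    data.frame(label = "anchor0", fpr = 0, sensitivity = 0, specificity = 1),
    do.call(rbind, pts),
    data.frame(label = "anchor1", fpr = 1, sensitivity = 1, specificity = 0))
  out <- out[order(out$fpr, out$sensitivity), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("roc_points", "data.frame")
  out
}

#' @export
plot.roc_points <- function(x, ...) {
  graphics::plot(x$fpr, x$sensitivity, type = "b", pch = 19,
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Balanced-resampling evaluation
#'
#' Re-evaluates a fitted classifier on class-balanced test sets: each
#' repetition draws `n_per_class` records from each test class without
#' replacement (the whole class when it has exactly `n_per_class` members)
#' and computes the metric suite; means and percentile confidence intervals
#' are reported across repetitions.  With unbalanced test sets this
#' equalizes the class weights that accuracy and F1 place on errors.
#'
#' @param model a fitted [dbayes()] model.
#' @param test labeled data.frame.
#' @param n_per_class records drawn from each class per repetition.
#' @param times repetitions (default 100).
#' @param seed integer seed.
#' @param level confidence level.
#' @return a data.frame with one row per metric: mean, lower, upper.
#' @export
evaluate_balanced <- function(model, test, n_per_class = 28, times = 100,
                              seed, level = 0.95) {
  idx <- class_indices(test)
  if (n_per_class > length(idx$recurrence) ||
      n_per_class > length(idx$nonrecurrence))
    stop("n_per_class exceeds a test class size", call. = FALSE)
  div <- discretize(test, model$counts$scheme, model$markers)
  pred <- predict(model, newdata = div, divisions = TRUE)
  truth <- as_outcome(test$outcome)
  seeds <- derive_seeds(seed, times)
  vals <- vapply(seeds, function(s) {
    pick <- with_seed(s, c(sample(idx$recurrence, n_per_class),
                           sample(idx$nonrecurrence, n_per_class)))
    unclass(metrics(confusion(pred[pick], truth[pick])))
  }, numeric(6))
  alpha <- 1 - level
  data.frame(
    metric = rownames(vals),
    mean = rowMeans(vals),
    lower = apply(vals, 1, stats::quantile, probs = alpha / 2, names = FALSE),
    upper = apply(vals, 1, stats::quantile, probs = 1 - alpha / 2,
                  names = FALSE),
    row.names = NULL)
}
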