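# Independent oracles and fixture builders shared across the test files.
# The oracles are deliberately straightforward, separate implementations of
# the printed formulas; they never call the package's computation paths.

# Direct evaluation of the decision rule on a list of per-marker count
# matrices (divisions x 2 classes): single-division conditionals with the
# pattern-dependent shared denominator, joint by direct product, posterior
# by Bayes' theorem.  Returns NA posteriors when both joints are zero or
# undefined.
oracle_posterior <- function(count_mats, pattern, prior = c(0.5, 0.5),
                             smoothing = 0) {
  d <- length(pattern)
  joint <- vapply(1:2, function(i) {
    cnt <- vapply(seq_len(d),
                  function(j) count_mats[[j]][pattern[j], i],
                  numeric(1)) + smoothing
    denom <- sum(cnt)
    if (denom == 0) return(NaN)
    prod(cnt / denom)
  }, numeric(1))
  num <- ifelse(is.nan(joint), 0, joint) * prior
  if (sum(num) == 0) {
    list(joint = joint, posterior = c(NaN, NaN))
  } else {
    list(joint = joint, posterior = num / sum(num))
  }
}

# Random count table on a scheme-free basis: n_markers matrices with 2-3
# divisions whose columns sum to the class totals.
random_count_table <- function(n_markers = NULL, n1 = NULL, n2 = NULL) {
  n_markers <- n_markers %||% sample(1:4, 1)
  n1 <- n1 %||% sample(1:25, 1)
  n2 <- n2 %||% sample(1:25, 1)
  mats <- lapply(seq_len(n_markers), function(j) {
    R <- sample(2:3, 1)
    cbind(recurrence = as.integer(stats::rmultinom(1, n1, rep(1, R))),
          nonrecurrence = as.integer(stats::rmultinom(1, n2, rep(1, R))))
  })
  names(mats) <- paste0("m", seq_len(n_markers))
  mats <- lapply(mats, function(m) {
    rownames(m) <- paste0("d", seq_len(nrow(m)))
    m
  })
  mats
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap raw count matrices as a fitted model via the package constructors.
model_from_mats <- function(mats, n1, n2, ...) {
  tab <- recurbayes:::new_division_counts(
    mats, n = c(recurrence = as.integer(n1), nonrecurrence = as.integer(n2)))
  dbayes(tab, ...)
}

# Textbook metric formulas, written independently of metrics().
oracle_metrics <- function(TP, FN, FP, TN) {
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  prec <- TP / (TP + FP)
  f1 <- ifelse(is.nan(prec) | (prec + sens) == 0, 0,
               2 * prec * sens / (prec + sens))
  dor <- ifelse(FN * FP == 0, ifelse(TP * TN > 0, Inf, NaN),
                (TP * TN) / (FN * FP))
  cbind(sensitivity = sens, specificity = spec,
        accuracy = (TP + TN) / (TP + FN + FP + TN),
        youden = sens + spec - 1, f1 = f1, dor = dor)
}

# A scheme of M binary threshold markers (values in [0,1], cut at 0.5),
# used for synthetic-cohort experiments.
binary_scheme <- function(M) {
  mk <- lapply(seq_len(M), function(j) {
    nm <- sprintf("m%02d", j)
    marker(nm,
           div_threshold(paste(nm, "> 0.5"), ">", 0.5),
           div_threshold(paste(nm, "<= 0.5"), "<=", 0.5))
  })
  cutoff_scheme(mk, version = "binary-test")
}

# Per-class division-probability lists for binary_scheme cohorts: marker
# `informative` separates the classes, all others are uninformative.
informative_probs <- function(M, informative, p = 0.9) {
  nm <- sprintf("m%02d", informative)
  list(recurrence = stats::setNames(list(c(p, 1 - p)), nm),
       nonrecurrence = stats::setNames(list(c(1 - p, p)), nm))
}

# The published per-size candidate table used for the final-selection rule.
published_candidates <- function() {
  data.frame(
    size = c(3L, 4L, 5L, 6L),
    sensitivity = c(0.79, 0.80, 0.75, 0.74),
    specificity = c(0.50, 0.50, 0.50, 0.51),
    markers = I(list(
      c("tumor_burden", "vp", "liver_damage"),
      c("tumor_burden", "vp", "ICG", "liver_damage"),
      c("ALB", "tumor_burden", "vv", "differentiation", "liver_damage"),
      c("ALB", "tumor_burden", "vp", "ICG", "differentiation",
        "liver_damage"))))
}
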