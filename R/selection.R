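#' Split training data into virtual training and virtual test samples
#'
#' The resampling primitive of marker selection: a stratified random split
#' of the training set, with the larger half of an odd class going to the
#' virtual training side (so 29 + 89 records split 15 + 45 vs 14 + 44 at
#' the default fraction).  Splits are disjoint, cover the input, and are
#' reproducible under the seed.
#'
#' @param training labeled data.frame.
#' @param fraction fraction per class assigned to virtual training
#'   (default 0.5); must leave at least one virtual test record.
#' @param seed integer seed.
#' @param outcome outcome column name.
#' @return list with `virtual_training` and `virtual_test` data.frames.
#' @export
resample_split <- function(training, fraction = 0.5, seed,
                           outcome = "outcome") {
  if (fraction >= 1 || fraction <= 0)
    stop("fraction must be in (0, 1) so the virtual test set is nonempty",
         call. = FALSE)
  sp <- stratified_split(training, seed, fraction, outcome)
  list(virtual_training = sp$first, virtual_test = sp$second)
}

#' Score one marker combination by resampling
#'
#' Estimates a combination's out-of-sample operating point: `N`
#' independent virtual splits of the training set; in each trial the
#' discrete Bayes classifier is fitted on the virtual training samples and
#' every virtual test sample is classified; the per-trial sensitivity and
#' specificity are averaged over the `N` trials.
#'
#' @param training labeled data.frame.
#' @param scheme a [cutoff_scheme()].
#' @param markers character vector of marker names to score.
#' @param N number of resampling trials (default 100).
#' @param fraction virtual-training fraction per class (default 0.5).
#' @param seed integer seed; trial seeds are derived from it, so a fixed
#'   seed fixes all `N` splits.
#' @param ... passed to [dbayes()].
#' @return an object of class `"combination_score"`: list with `markers`,
#'   `sensitivity` and `specificity` (means over trials), and `N`.
#' @export
evaluate_combination <- function(training, scheme, markers, N = 100,
                                 fraction = 0.5, seed, ...) {
  pre <- selection_precompute(training, scheme, markers, N, fraction, seed)
  sc <- score_combo_fast(pre, seq_along(markers), ...)
  structure(list(markers = markers, sensitivity = sc[["sensitivity"]],
                 specificity = sc[["specificity"]], N = N),
            class = "combination_score")
}

#' @export
print.combination_score <- function(x, ...) {
  cat(sprintf("{%s}: mean sensitivity %.3f, mean specificity %.3f (N = %d)\n",
              paste(x$markers, collapse = ", "),
              x$sensitivity, x$specificity, x$N))
  invisible(x)
}

# ---- shared-split machinery -----------------------------------------------
#
# All combinations of a given search size are scored on the SAME N virtual
# splits (common random numbers): the procedure evaluates each
# combination on N independent splits, and sharing the splits across the
# combinations of one size keeps comparisons between combinations free of
# split-to-split noise while leaving each combination's own estimate
# unchanged in distribution.  The precompute stage discretizes once and,
# per trial, stores for every candidate marker the per-class count of each
# virtual-test record's division — after which scoring any subset is a pair
# of column sums.

selection_precompute <- function(training, scheme, markers, N, fraction,
                                 seed) {
  if (fraction >= 1 || fraction <= 0)
    stop("fraction must be in (0, 1) so the virtual test set is nonempty",
         call. = FALSE)
  idx <- class_indices(training)
  div <- discretize(training, scheme, markers)
  n1 <- length(idx$recurrence); n2 <- length(idx$nonrecurrence)
  k1 <- round_half_up(n1 * fraction); k2 <- round_half_up(n2 * fraction)
  if (k1 < 1 || k2 < 1 || k1 >= n1 || k2 >= n2)
    stop("each class needs at least one virtual training and one virtual ",
         "test record", call. = FALSE)
  ndiv <- vapply(markers, function(mn) n_divisions(scheme$markers[[mn]]),
                 integer(1))
  seeds <- derive_seeds(seed, N)
  M <- length(markers)
  nte <- (n1 - k1) + (n2 - k2)
  trials <- lapply(seeds, function(s) {
    pick <- with_seed(s, list(tr1 = sort(sample(idx$recurrence, k1)),
                              tr2 = sort(sample(idx$nonrecurrence, k2))))
    te1 <- setdiff(idx$recurrence, pick$tr1)
    te2 <- setdiff(idx$nonrecurrence, pick$tr2)
    te <- c(te1, te2)  # recurrence test records first
    V1 <- matrix(0, M, nte); V2 <- matrix(0, M, nte)
    for (j in seq_len(M)) {
      c1 <- tabulate(div[pick$tr1, j], nbins = ndiv[j])
      c2 <- tabulate(div[pick$tr2, j], nbins = ndiv[j])
      V1[j, ] <- c1[div[te, j]]
      V2[j, ] <- c2[div[te, j]]
    }
    list(V1 = V1, V2 = V2)
  })
  list(trials = trials, n_te_pos = n1 - k1, n_te_neg = n2 - k2,
       markers = markers, N = N)
}

# Mean sensitivity/specificity of one subset (column indices into the
# precomputed marker set) over the shared trials.
score_combo_fast <- function(pre, subset, prior = c(0.5, 0.5),
                             smoothing = 0,
                             tie_break = c("recurrence", "nonrecurrence")) {
  tie_break <- match.arg(tie_break)
  d <- length(subset)
  lp <- log(prior)
  sens <- numeric(pre$N); spec <- numeric(pre$N)
  pos <- seq_len(pre$n_te_pos)
  neg <- pre$n_te_pos + seq_len(pre$n_te_neg)
  for (t in seq_len(pre$N)) {
    W1 <- pre$trials[[t]]$V1[subset, , drop = FALSE] + smoothing
    W2 <- pre$trials[[t]]$V2[subset, , drop = FALSE] + smoothing
    S1 <- colSums(W1); S2 <- colSums(W2)
    l1 <- colSums(log(W1)) - d * log(S1) + lp[1]
    l2 <- colSums(log(W2)) - d * log(S2) + lp[2]
    l1[S1 == 0] <- -Inf
    l2[S2 == 0] <- -Inf
    pred_rec <- if (tie_break == "recurrence") l1 >= l2 else l1 > l2
    pred_rec[is.na(pred_rec)] <- tie_break == "recurrence"  # both -Inf
    sens[t] <- mean(pred_rec[pos])
    spec[t] <- mean(!pred_rec[neg])
  }
  c(sensitivity = mean(sens), specificity = mean(spec))
}

#' Exhaustive specificity-constrained marker-subset search
#'
#' For each subset size, every combination of the candidate markers is
#' scored by [evaluate_combination()]'s resampling procedure (all
#' combinations of a size share the same `N` virtual splits); among the
#' combinations whose mean specificity meets the constraint, the one with
#' maximal mean sensitivity is that size's candidate (per-size ties go to
#' higher specificity, then lexicographically earlier marker sets).  The
#' overall optimum is the qualifying candidate with maximal mean
#' sensitivity; ties go to fewer markers.
#'
#' @param training labeled data.frame.
#' @param scheme a [cutoff_scheme()].
#' @param candidates candidate marker names (default: all scheme markers).
#' @param sizes subset sizes to search (default `3:(M - 1)` for `M`
#'   candidates, the published search range; any subrange of `1:M` works).
#' @param N resampling trials per size (default 100).
#' @param fraction virtual-training fraction (default 0.5).
#' @param threshold specificity constraint (default 0.5, applied as
#'   `>= threshold - 1e-9` to avoid float boundary artifacts on means that
#'   are exactly 0.50).
#' @param seed integer master seed; the whole search is deterministic given
#'   it.
#' @param ... passed to [dbayes()] (priors, smoothing, tie-break).
#' @return an object of class `"marker_selection"`: list with `candidates`
#'   (data.frame: size, sensitivity, specificity, youden, markers — one row
#'   per size with a qualifying combination), `optimal` (row of
#'   `candidates`), `threshold`, `N`, `seed`, `per_size` (list of
#'   `"combination_score"` or `NULL`).
#' @examples
#' \donttest{
#' cohort <- materialize_exact_counts(hcc_training_counts(), seed = 1)
#' sel <- select_markers(cohort, hcc_marker_scheme(), N = 20, seed = 42,
#'                       sizes = 3:5)
#' sel
#' }
#' @export
select_markers <- function(training, scheme, candidates = NULL,
                           sizes = NULL, N = 100, fraction = 0.5,
                           threshold = 0.5, seed, ...) {
  candidates <- candidates %||% scheme_marker_names(scheme)
  M <- length(candidates)
  sizes <- sizes %||% seq(3L, max(3L, M - 1L))
  if (any(sizes < 1L | sizes > M))
    stop("sizes must lie in 1..", M, call. = FALSE)
  size_seeds <- derive_seeds(seed, length(sizes))
  per_size <- vector("list", length(sizes))
  names(per_size) <- as.character(sizes)
  for (si in seq_along(sizes)) {
    d <- sizes[si]
    pre <- selection_precompute(training, scheme, candidates, N, fraction,
                                size_seeds[si])
    combos <- utils::combn(M, d)
    best <- NULL
    for (ci in seq_len(ncol(combos))) {
      sc <- score_combo_fast(pre, combos[, ci], ...)
      if (sc[["specificity"]] < threshold - 1e-9) next
      if (is.null(best) ||
          sc[["sensitivity"]] > best$sensitivity + 1e-12 ||
          (abs(sc[["sensitivity"]] - best$sensitivity) <= 1e-12 &&
           sc[["specificity"]] > best$specificity + 1e-12)) {
        best <- list(markers = candidates[combos[, ci]],
                     sensitivity = sc[["sensitivity"]],
                     specificity = sc[["specificity"]], N = N)
      }
    }
    if (!is.null(best)) class(best) <- "combination_score"
    per_size[si] <- list(best)  # [[<- NULL would delete the slot
  }
  keep <- !vapply(per_size, is.null, logical(1))
  cand_df <- if (any(keep)) {
    data.frame(
      size = sizes[keep],
      sensitivity = vapply(per_size[keep], `[[`, numeric(1), "sensitivity"),
      specificity = vapply(per_size[keep], `[[`, numeric(1), "specificity"),
      markers = I(lapply(per_size[keep], `[[`, "markers")),
      row.names = NULL)
  } else {
    data.frame(size = integer(), sensitivity = numeric(),
               specificity = numeric(), markers = I(list()))
  }
  cand_df$youden <- cand_df$sensitivity + cand_df$specificity - 1
  optimal <- if (nrow(cand_df)) select_optimal(cand_df, threshold) else NULL
  structure(list(candidates = cand_df, optimal = optimal,
                 threshold = threshold, N = N, seed = seed,
                 sizes = sizes, per_size = per_size),
            class = "marker_selection")
}

#' Pick the overall optimal combination among per-size candidates
#'
#' Applies the final selection rule to a table of per-size candidate
#' combinations (such as [select_markers()] produces, or a table of
#' published candidate rows): among candidates whose mean specificity meets
#' the constraint, the one with maximal mean sensitivity wins; ties go to
#' fewer markers.
#'
#' @param candidates a data.frame with columns `sensitivity`,
#'   `specificity`, and either a list-column `markers` or a `size` column
#'   (when both are present, `size` is taken as given).
#' @param threshold specificity constraint (default 0.5, applied with the
#'   same 1e-9 boundary tolerance as the search).
#' @return the winning row of `candidates` (single-row data.frame), or
#'   `NULL` when no row qualifies.
#' @examples
#' published <- data.frame(
#'   size = c(3, 4, 5, 6),
#'   sensitivity = c(0.79, 0.80, 0.75, 0.74),
#'   specificity = c(0.50, 0.50, 0.50, 0.51))
#' select_optimal(published)  # the size-4 combination
#' @export
select_optimal <- function(candidates, threshold = 0.5) {
  stopifnot(is.data.frame(candidates),
            all(c("sensitivity", "specificity") %in% names(candidates)))
  if (!"size" %in% names(candidates)) {
    if (!"markers" %in% names(candidates))
      stop("candidates need a 'size' or 'markers' column", call. = FALSE)
    candidates$size <- lengths(candidates$markers)
  }
  ok <- candidates$specificity >= threshold - 1e-9
  if (!any(ok)) return(NULL)
  q <- candidates[ok, , drop = FALSE]
  best_sens <- max(q$sensitivity)
  q <- q[q$sensitivity >= best_sens - 1e-12, , drop = FALSE]
  q[order(q$size), , drop = FALSE][1, , drop = FALSE]
}

#' @export
print.marker_selection <- function(x, ...) {
  cat("Marker selection (specificity constraint >= ", x$threshold,
      ", N = ", x$N, " trials per size)\n\n", sep = "")
  cat(sprintf("  %-5s %-12s %-12s %-8s %s\n",
              "Size", "Sensitivity", "Specificity", "Youden",
              "Combination"))
  for (si in seq_along(x$sizes)) {
    b <- x$per_size[[si]]
    if (is.null(b)) {
      cat(sprintf("  %-5d %-12s %-12s %-8s\n", x$sizes[si], "-", "-", "-"))
    } else {
      cat(sprintf("  %-5d %-12.2f %-12.2f %-8.2f %s\n", x$sizes[si],
                  b$sensitivity, b$specificity,
                  b$sensitivity + b$specificity - 1,
                  paste(b$markers, collapse = ", ")))
    }
  }
  if (!is.null(x$optimal)) {
    cat("\n  Optimal: ", paste(x$optimal$markers[[1]], collapse = ", "),
        sprintf("  (sensitivity %.2f, specificity %.2f)\n",
                x$optimal$sensitivity, x$optimal$specificity), sep = "")
  } else {
    cat("\n  No combination met the specificity constraint.\n")
  }
  invisible(x)
}
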