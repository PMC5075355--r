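#' Generate a synthetic two-class cohort
#'
#' Draws labeled patient records whose discretized division per marker is
#' sampled independently, within each class, from a specified categorical
#' distribution — exactly the independence structure the discrete Bayes
#' classifier assumes.  Raw values are emitted (sampled uniformly inside
#' each division's numeric interval, or as the division's category label),
#' so [discretize()] recovers the drawn divisions exactly.
#'
#' @param scheme a [cutoff_scheme()].
#' @param n per-class sizes, a length-2 numeric (recurrence, nonrecurrence);
#'   zero sizes allowed.
#' @param probs per-class, per-marker division probabilities: a list with
#'   elements `recurrence` and `nonrecurrence`, each a named list mapping a
#'   marker name to a probability vector over its divisions (summing to 1
#'   within 1e-9).  Markers absent from `probs` default to the uniform
#'   distribution over their divisions.
#' @param seed integer seed (required).
#' @param markers markers to generate (default: all in the scheme).
#' @return a data.frame with one column per marker plus an `outcome` factor;
#'   recurrence rows first.
#' @examples
#' sch <- hcc_marker_scheme()
#' probs <- list(recurrence = list(ALB = c(0.9, 0.1)),
#'               nonrecurrence = list(ALB = c(0.1, 0.9)))
#' cohort <- generate_cohort(sch, n = c(20, 60), probs = probs, seed = 7)
#' table(cohort$outcome)
#' @export
generate_cohort <- function(scheme, n, probs = NULL, seed, markers = NULL) {
  stopifnot(inherits(scheme, "cutoff_scheme"))
  markers <- markers %||% scheme_marker_names(scheme)
  n <- as.integer(n)
  stopifnot(length(n) == 2L, all(n >= 0))
  probs <- probs %||% list()
  classes <- c("recurrence", "nonrecurrence")
  with_seed(seed, {
    parts <- lapply(seq_along(classes), function(i) {
      ni <- n[i]
      cols <- lapply(markers, function(mn) {
        mk <- scheme$markers[[mn]]
        R <- n_divisions(mk)
        p <- probs[[classes[i]]][[mn]] %||% rep(1 / R, R)
        if (length(p) != R)
          stop("probability vector for marker '", mn, "', class ",
               classes[i], " must have ", R, " entries", call. = FALSE)
        if (abs(sum(p) - 1) > 1e-9)
          stop("probabilities for marker '", mn, "', class ", classes[i],
               " do not sum to 1", call. = FALSE)
        div <- sample.int(R, ni, replace = TRUE, prob = p)
        raw_values_for_divisions(mk, div)
      })
      names(cols) <- markers
      df <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
      if (ni == 0) df <- df[0, , drop = FALSE]
      df$outcome <- factor(rep(classes[i], ni), levels = OUTCOME_LEVELS)
      df
    })
    out <- rbind(parts[[1L]], parts[[2L]])
    rownames(out) <- NULL
    out
  })
}

# Raw values realizing given division indices for one marker (vectorised).
raw_values_for_divisions <- function(mk, div) {
  R <- n_divisions(mk)
  categorical <- mk$divisions[[1L]]$rule$type == "category"
  out <- if (categorical) character(length(div)) else numeric(length(div))
  for (r in seq_len(R)) {
    sel <- div == r
    if (!any(sel)) next
    out[sel] <- rule_sample(mk$divisions[[r]]$rule, sum(sel))
  }
  out
}

#' Materialize a dataset realizing a division-count table exactly
#'
#' Builds a labeled cohort whose [count_divisions()] output reproduces the
#' input table exactly.  Marginal counts carry no joint information, so the
#' per-marker division assignments are shuffled independently across the
#' records of each class: any consistent joint distribution is a valid
#' realization, and the shuffle picks one at random.
#'
#' @param counts a `"division_counts"` table.
#' @param seed integer seed for the within-class shuffles.
#' @param scheme a [cutoff_scheme()]; defaults to the one carried by
#'   `counts`.
#' @return a labeled data.frame of raw marker values; recurrence rows first.
#' @examples
#' cohort <- materialize_exact_counts(hcc_training_counts(), seed = 1)
#' nrow(cohort)  # 118
#' @export
materialize_exact_counts <- function(counts, seed, scheme = NULL) {
  stopifnot(inherits(counts, "division_counts"))
  scheme <- scheme %||% counts$scheme
  if (is.null(scheme))
    stop("no cutoff scheme available to realize raw values", call. = FALSE)
  classes <- c("recurrence", "nonrecurrence")
  with_seed(seed, {
    parts <- lapply(1:2, function(i) {
      ni <- counts$n[i]
      cols <- lapply(counts$markers, function(mn) {
        mk <- scheme$markers[[mn]]
        cv <- counts$counts[[mn]][, i]
        div <- rep.int(seq_along(cv), cv)
        if (length(div) > 1L) div <- sample(div)
        raw_values_for_divisions(mk, div)
      })
      names(cols) <- counts$markers
      df <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
      if (ni == 0) df <- df[0, , drop = FALSE]
      df$outcome <- factor(rep(classes[i], ni), levels = OUTCOME_LEVELS)
      df
    })
    out <- rbind(parts[[1L]], parts[[2L]])
    rownames(out) <- NULL
    out
  })
}
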