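#' Fit a discrete Bayes classifier
#'
#' Fits the two-class discrete Bayes decision rule for early-recurrence
#' prediction.  Fitting is counting: the model state is the per-class
#' division-count table restricted to the selected markers, together with
#' the class priors and an optional additive smoothing constant.
#'
#' For a patient whose discretized values fall in divisions
#' \eqn{r_1, \dots, r_d} of the \eqn{d} selected markers, the
#' class-conditional probability of a single division is
#' \deqn{P(x_{j(r_j)} \mid \omega_i) = \frac{n^i_{j(r_j)}}
#'       {\sum_{k=1}^{d} n^i_{k(r_k)}},}
#' where \eqn{n^i_{j(r_j)}} is the number of class-\eqn{\omega_i} training
#' patients in that division.  Note the denominator: it is the sum of the
#' counts of the divisions *this pattern* falls into across the selected
#' markers, not the per-class total — a pattern-dependent normalization
#' that makes the \eqn{d} single-division conditionals of each class sum to
#' one by construction.  Under the independence assumption the joint
#' conditional is the product over the selected markers, and the posterior
#' follows from Bayes' theorem with the configured priors (equal priors by
#' default, so the posterior is the ratio of joint conditionals).  A
#' pattern is classified into the class with maximal posterior.
#'
#' @param x a `"division_counts"` table (see [count_divisions()] and
#'   [hcc_training_counts()]) or a labeled data.frame of raw patient
#'   records.
#' @param markers character vector of selected marker names, `d >= 1`
#'   (default: all markers available in `x`).
#' @param prior length-2 numeric prior for (recurrence, nonrecurrence);
#'   must sum to 1.  Default `c(0.5, 0.5)` treats the classes equally.
#' @param smoothing nonnegative constant added to every division count
#'   before normalization.  The default 0 uses raw counts, in which case a
#'   zero-count division annihilates its class; a small positive value
#'   (e.g. 0.5) avoids that at the cost of biasing the conditionals.
#' @param tie_break class predicted when the posteriors tie or are both
#'   undefined (every selected count zero in both classes).  The default
#'   `"recurrence"` errs toward not missing a recurrence.
#' @param scheme a [cutoff_scheme()], required when `x` is a data.frame
#'   (ignored otherwise — the counts carry their scheme).
#' @param outcome outcome column name when `x` is a data.frame.
#' @param ... passed between methods.
#' @return an object of class `"dbayes"` with components `counts`
#'   (restricted `division_counts`), `markers`, `prior`, `smoothing`,
#'   `tie_break`, `n`, `call`.
#' @examples
#' fit <- dbayes(hcc_training_counts(), markers = c("ALB", "tumor_burden"))
#' posterior(fit, c(ALB = 1, tumor_burden = 3))
#' @seealso [posterior()], [predict.dbayes()], [select_markers()]
#' @export
dbayes <- function(x, ...) UseMethod("dbayes")

#' @rdname dbayes
#' @export
dbayes.division_counts <- function(x, markers = NULL, prior = c(0.5, 0.5),
                                   smoothing = 0,
                                   tie_break = c("recurrence",
                                                 "nonrecurrence"), ...) {
  markers <- markers %||% x$markers
  tie_break <- match.arg(tie_break)
  unknown <- setdiff(markers, x$markers)
  if (length(unknown))
    stop("selected marker(s) not in count table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (length(markers) < 1L) stop("need at least one marker", call. = FALSE)
  stopifnot(is.numeric(prior), length(prior) == 2L, all(prior >= 0))
  if (abs(sum(prior) - 1) > 1e-9) stop("priors must sum to 1", call. = FALSE)
  stopifnot(is.numeric(smoothing), length(smoothing) == 1L, smoothing >= 0)
  counts <- new_division_counts(x$counts[markers], n = x$n,
                                scheme = x$scheme, markers = markers)
  structure(
    list(counts = counts, markers = markers,
         prior = c(recurrence = prior[1], nonrecurrence = prior[2]),
         smoothing = smoothing, tie_break = tie_break, n = x$n,
         call = match.call()),
    class = "dbayes")
}

#' @rdname dbayes
#' @export
dbayes.data.frame <- function(x, scheme, markers = NULL, prior = c(0.5, 0.5),
                              smoothing = 0,
                              tie_break = c("recurrence", "nonrecurrence"),
                              outcome = "outcome", ...) {
  counts <- count_divisions(x, scheme, markers = markers, outcome = outcome)
  m <- dbayes.division_counts(counts, markers = markers, prior = prior,
                              smoothing = smoothing, tie_break = tie_break)
  m$call <- match.call()
  m
}

#' @export
print.dbayes <- function(x, ...) {
  cat("Discrete Bayes classifier (recurrence vs nonrecurrence)\n")
  cat("  markers (d = ", length(x$markers), "): ",
      paste(x$markers, collapse = ", "), "\n", sep = "")
  cat("  training n: ", x$n[1], " recurrence / ", x$n[2],
      " nonrecurrence\n", sep = "")
  cat("  prior: ", x$prior[1], " / ", x$prior[2],
      "; smoothing: ", x$smoothing,
      "; tie-break: ", x$tie_break, "\n", sep = "")
  invisible(x)
}

#' @export
summary.dbayes <- function(object, ...) {
  print(object)
  cat("\nDivision counts:\n")
  for (mn in object$markers) {
    m <- object$counts$counts[[mn]]
    for (r in seq_len(nrow(m)))
      cat(sprintf("  %-38s %4d %4d\n", rownames(m)[r], m[r, 1], m[r, 2]))
  }
  invisible(object)
}

# Validate a pattern (named division-index vector) against the model and
# return a d x 2 matrix of the pattern's division counts.
pattern_counts <- function(model, pattern) {
  d <- length(model$markers)
  if (is.null(names(pattern))) {
    if (length(pattern) != d)
      stop("unnamed pattern must have one index per selected marker",
           call. = FALSE)
    names(pattern) <- model$markers
  }
  absent <- setdiff(model$markers, names(pattern))
  if (length(absent))
    stop("pattern lacks division index for marker(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  out <- matrix(0, nrow = d, ncol = 2,
                dimnames = list(model$markers,
                                c("recurrence", "nonrecurrence")))
  for (mn in model$markers) {
    m <- model$counts$counts[[mn]]
    r <- pattern[[mn]]
    if (!is.numeric(r) || r < 1 || r > nrow(m) || r != as.integer(r))
      stop("invalid division index ", r, " for marker '", mn, "'",
           call. = FALSE)
    out[mn, ] <- m[r, ]
  }
  out
}

#' Class-conditional probability of a single division
#'
#' Returns \eqn{P(x_{j(r_j)} \mid \omega_i)} under the pattern-dependent
#' normalization: the count of the pattern's division of marker `marker`,
#' divided by the sum over all selected markers of the counts of the
#' divisions the pattern falls into (smoothing added to every count).
#' When the denominator is zero (every selected count of the class is zero
#' and smoothing is 0) the value is `NaN`.
#'
#' @param model a fitted [dbayes()] model.
#' @param pattern named integer vector of division indices covering the
#'   model's selected markers.
#' @param marker marker name.
#' @param class `"recurrence"` or `"nonrecurrence"`.
#' @return a probability (or `NaN` when undefined).
#' @export
division_conditional <- function(model, pattern, marker,
                                 class = c("recurrence", "nonrecurrence")) {
  class <- match.arg(class)
  if (!marker %in% model$markers)
    stop("marker '", marker, "' is not selected in this model", call. = FALSE)
  pc <- pattern_counts(model, pattern)
  cnt <- stats::setNames(pc[, class], rownames(pc)) + model$smoothing
  denom <- sum(cnt)
  if (denom == 0) return(NaN)
  cnt[[marker]] / denom
}

#' Joint class-conditional probability of a pattern
#'
#' The product over the selected markers of [division_conditional()]
#' (independence assumption).  `NaN` when the class's shared denominator is
#' zero.
#'
#' @inheritParams division_conditional
#' @return a probability (or `NaN` when undefined).
#' @export
joint_conditional <- function(model, pattern,
                              class = c("recurrence", "nonrecurrence")) {
  class <- match.arg(class)
  cnt <- pattern_counts(model, pattern)[, class, drop = TRUE] +
    model$smoothing
  denom <- sum(cnt)
  if (denom == 0) return(NaN)
  prod(cnt / denom)
}

# Core: log joint conditionals for a d x 2 matrix of pattern counts.
# Returns c(log P(x|w1), log P(x|w2)); -Inf for a zero product, NaN never
# (zero denominator maps to -Inf, flagged separately by the caller).
log_joint_from_counts <- function(cnt, smoothing) {
  cnt <- cnt + smoothing
  d <- nrow(cnt)
  vapply(1:2, function(i) {
    denom <- sum(cnt[, i])
    if (denom == 0) return(-Inf)
    sum(log(cnt[, i])) - d * log(denom)
  }, numeric(1))
}

#' Posterior class probabilities for a discretized pattern
#'
#' Combines the joint class-conditionals with the model priors by Bayes'
#' theorem.  With the default equal priors the posterior for recurrence is
#' \eqn{P(\mathbf{x}\mid\omega_1) / (P(\mathbf{x}\mid\omega_1) +
#' P(\mathbf{x}\mid\omega_2))}.  Products are evaluated in log space, so
#' large marker counts do not underflow; at small `d` this agrees with the
#' direct product to within 1e-12 relative tolerance.
#'
#' @inheritParams division_conditional
#' @return an object of class `"dbayes_posterior"`: list with `posterior`
#'   (named length-2 numeric), `joint` (named length-2 numeric,
#'   class-conditionals), `class` (predicted), `tie` (logical), and
#'   `degenerate` (`TRUE` when both joint conditionals are zero or
#'   undefined, in which case the posteriors are `NaN` and the prediction
#'   falls back to the model's tie-break class).
#' @examples
#' fit <- dbayes(hcc_training_counts(), markers = c("ALB", "tumor_burden"))
#' posterior(fit, c(ALB = 1, tumor_burden = 3))
#' @export
posterior <- function(model, pattern) {
  stopifnot(inherits(model, "dbayes"))
  cnt <- pattern_counts(model, pattern)
  lj <- log_joint_from_counts(cnt, model$smoothing)
  joint <- exp(lj)
  lw <- lj + log(model$prior)
  degenerate <- all(!is.finite(lw))
  if (degenerate) {
    post <- c(NaN, NaN)
    tie <- TRUE
    cls <- model$tie_break
  } else {
    mx <- max(lw)
    w <- exp(lw - mx)
    post <- unname(w / sum(w))
    tie <- isTRUE(all.equal(post[1], post[2], tolerance = 1e-12))
    cls <- if (tie) model$tie_break
           else c("recurrence", "nonrecurrence")[which.max(post)]
  }
  names(post) <- c("recurrence", "nonrecurrence")
  names(joint) <- c("recurrence", "nonrecurrence")
  structure(list(posterior = post, joint = joint,
                 class = factor(cls, levels = OUTCOME_LEVELS),
                 tie = tie, degenerate = degenerate),
            class = "dbayes_posterior")
}

#' @export
print.dbayes_posterior <- function(x, digits = 4, ...) {
  cat("P(recurrence | x) = ", format(x$posterior[1], digits = digits),
      ",  P(nonrecurrence | x) = ", format(x$posterior[2], digits = digits),
      "\n", sep = "")
  cat("predicted class: ", as.character(x$class),
      if (x$tie) "  (tie)" else "",
      if (x$degenerate) "  (degenerate: no training mass on this pattern)"
      else "", "\n", sep = "")
  invisible(x)
}

#' Predict recurrence for new patients
#'
#' @param object a fitted [dbayes()] model.
#' @param newdata a data.frame of raw marker values (discretized through the
#'   model's scheme) or an integer matrix/data.frame of division indices
#'   with `divisions = TRUE`.
#' @param type `"class"` for predicted classes, `"posterior"` for the n x 2
#'   matrix of posterior probabilities, `"joint"` for the n x 2 matrix of
#'   joint class-conditionals.
#' @param divisions set `TRUE` when `newdata` already holds division
#'   indices.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.dbayes <- function(object, newdata,
                           type = c("class", "posterior", "joint"),
                           divisions = FALSE, ...) {
  type <- match.arg(type)
  div <- if (divisions) {
    m <- as.matrix(newdata)
    storage.mode(m) <- "integer"
    if (is.null(colnames(m))) colnames(m) <- object$markers
    m[, object$markers, drop = FALSE]
  } else {
    if (is.null(object$counts$scheme))
      stop("model carries no cutoff scheme; supply division indices with ",
           "divisions = TRUE", call. = FALSE)
    discretize(newdata, object$counts$scheme, object$markers)
  }
  n <- nrow(div)
  post <- matrix(NA_real_, n, 2,
                 dimnames = list(NULL, c("recurrence", "nonrecurrence")))
  joint <- post
  cls <- character(n)
  for (k in seq_len(n)) {
    p <- posterior(object, div[k, ])
    post[k, ] <- p$posterior
    joint[k, ] <- p$joint
    cls[k] <- as.character(p$class)
  }
  switch(type,
         class = factor(cls, levels = OUTCOME_LEVELS),
         posterior = post,
         joint = joint)
}

#' Serialize a discrete Bayes model to JSON
#'
#' Counts are written as exact integers; `dbayes_from_json()` restores an
#' identical model (minus the cutoff scheme, which is stored separately —
#' attach one via [dbayes()] on the restored counts if raw-value prediction
#' is needed).
#'
#' @param model a fitted [dbayes()] model.
#' @param path output / input file path.
#' @return `dbayes_to_json()` returns `path` invisibly; `dbayes_from_json()`
#'   returns a `"dbayes"` model.
#' @export
dbayes_to_json <- function(model, path) {
  stopifnot(inherits(model, "dbayes"))
  obj <- list(
    markers = model$markers,
    n = as.list(model$n),
    prior = as.list(model$prior),
    smoothing = model$smoothing,
    tie_break = model$tie_break,
    counts = lapply(model$counts$counts, function(m) {
      list(divisions = rownames(m),
           recurrence = as.integer(m[, 1]),
           nonrecurrence = as.integer(m[, 2]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname dbayes_to_json
#' @export
dbayes_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- lapply(obj$counts, function(x) {
    m <- cbind(recurrence = as.integer(x$recurrence),
               nonrecurrence = as.integer(x$nonrecurrence))
    rownames(m) <- x$divisions
    m
  })
  n <- c(recurrence = as.integer(obj$n$recurrence),
         nonrecurrence = as.integer(obj$n$nonrecurrence))
  tab <- new_division_counts(counts, n = n, markers = obj$markers)
  dbayes.division_counts(tab, markers = obj$markers,
                         prior = c(obj$prior$recurrence,
                                   obj$prior$nonrecurrence),
                         smoothing = obj$smoothing,
                         tie_break = obj$tie_break)
}

#' Simulate cohorts from a fitted model
#'
#' Draws synthetic labeled cohorts whose per-class, per-marker division
#' probabilities are the model's empirical training frequencies
#' (count / class total), with divisions drawn independently within each
#' class — the same independence assumption the classifier itself makes.
#' Requires the model to carry a cutoff scheme (raw values are emitted so
#' that discretization round-trips).
#'
#' @param object a fitted [dbayes()] model with an attached scheme.
#' @param nsim number of cohorts.
#' @param seed integer seed (required: all randomness in this package is
#'   explicitly seeded).
#' @param n per-class cohort sizes, named `recurrence`/`nonrecurrence`
#'   (default: the training class sizes).
#' @param ... unused.
#' @return a list of `nsim` data.frames (a single data.frame when
#'   `nsim = 1`).
#' @export
simulate.dbayes <- function(object, nsim = 1, seed, n = NULL, ...) {
  if (is.null(object$counts$scheme))
    stop("model carries no cutoff scheme", call. = FALSE)
  n <- n %||% object$n
  probs <- lapply(c(recurrence = 1L, nonrecurrence = 2L), function(i) {
    lapply(object$counts$counts, function(m) m[, i] / sum(m[, i]))
  })
  seeds <- derive_seeds(seed, nsim)
  sims <- lapply(seeds, function(s) {
    generate_cohort(object$counts$scheme, n = n, probs = probs, seed = s,
                    markers = object$markers)
  })
  if (nsim == 1) sims[[1L]] else sims
}
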