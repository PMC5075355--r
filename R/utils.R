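# Internal helpers shared across the package.

#' Evaluate code under a fixed RNG seed without disturbing global RNG state
#'
#' All stochastic operations in this package take an explicit `seed`; this
#' helper makes them reproducible while leaving the caller's `.Random.seed`
#' untouched.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a vector of sub-seeds from a master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published clinical tables use
#' conventional half-up rounding, so metric printing and confusion-matrix
#' reconstruction use this form.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical outcome levels: the positive class (recurrence within one year)
# always comes first.
OUTCOME_LEVELS <- c("recurrence", "nonrecurrence")

# Normalise an outcome vector to the canonical factor, case-insensitively.
as_outcome <- function(x, allow_na = FALSE) {
  x0 <- tolower(trimws(as.character(x)))
  bad <- !is.na(x0) & !(x0 %in% OUTCOME_LEVELS)
  if (any(bad, na.rm = TRUE)) {
    stop("invalid outcome label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected 'recurrence' or 'nonrecurrence')", call. = FALSE)
  }
  factor(x0, levels = OUTCOME_LEVELS)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
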