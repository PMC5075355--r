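#' Read and write labeled patient tables
#'
#' Patient data are delimited text (CSV or TSV, inferred from the file
#' extension unless `sep` is given): a header row naming the markers, one
#' row per patient, and one outcome column holding the literal strings
#' `"recurrence"` / `"nonrecurrence"` (case-insensitive; the positive class
#' is recurrence within one year).  Unknown columns are preserved on read
#' and ignored by downstream operations; a write/read cycle is the identity
#' on values, labels and row order.
#'
#' @param path file to read or write.
#' @param scheme optional [cutoff_scheme()]; when given, marker columns are
#'   checked to be present and discretizable.
#' @param outcome name of the outcome column (default `"outcome"`).
#' @param sep field separator; `NULL` infers `","` except for `.tsv`/`.txt`
#'   which use tab.
#' @param allow_unknown_outcome keep rows whose outcome is missing (allowed
#'   only at classification time, never for training).
#' @return `read_patients()` returns a data.frame whose `outcome` column is
#'   a factor with levels `recurrence`, `nonrecurrence`.
#' @export
read_patients <- function(path, scheme = NULL, outcome = "outcome",
                          sep = NULL, allow_unknown_outcome = FALSE) {
  sep <- sep %||% (if (grepl("\\.(tsv|txt)$", path)) "\t" else ",")
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = c("NA", "")),
    error = function(e) stop("malformed input '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!outcome %in% names(df))
    stop("outcome column '", outcome, "' not found in ", path, call. = FALSE)
  df[[outcome]] <- as_outcome(df[[outcome]], allow_na = allow_unknown_outcome)
  if (!allow_unknown_outcome && anyNA(df[[outcome]]))
    stop("unknown outcome in row(s) ",
         paste(utils::head(which(is.na(df[[outcome]])), 5L), collapse = ", "),
         call. = FALSE)
  if (!is.null(scheme)) {
    mn <- scheme_marker_names(scheme)
    absent <- setdiff(mn, names(df))
    if (length(absent))
      stop("marker column(s) missing from ", path, ": ",
           paste(absent, collapse = ", "), call. = FALSE)
    for (m in mn) {
      mk <- scheme$markers[[m]]
      numeric_rule <- mk$divisions[[1L]]$rule$type != "category"
      if (numeric_rule && !is.numeric(df[[m]])) {
        v <- suppressWarnings(as.numeric(df[[m]]))
        bad <- which(is.na(v) & !is.na(df[[m]]))
        if (length(bad))
          stop("unparseable numeric value(s) in column '", m, "', line(s) ",
               paste(utils::head(bad + 1L, 5L), collapse = ", "),
               call. = FALSE)
        df[[m]] <- v
      }
    }
  }
  df
}

#' @rdname read_patients
#' @param data data.frame of patient records.
#' @export
write_patients <- function(data, path, sep = NULL) {
  sep <- sep %||% (if (grepl("\\.(tsv|txt)$", path)) "\t" else ",")
  df <- data
  if ("outcome" %in% names(df)) df$outcome <- as.character(df$outcome)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Split a labeled data.frame into per-class row-index lists; errors if a
# class required for training is empty.
class_indices <- function(data, outcome = "outcome", require_both = TRUE) {
  y <- as_outcome(data[[outcome]])
  if (anyNA(y))
    stop("records with unknown outcome cannot be used here", call. = FALSE)
  idx <- list(recurrence = which(y == "recurrence"),
              nonrecurrence = which(y == "nonrecurrence"))
  if (require_both && (!length(idx$recurrence) || !length(idx$nonrecurrence)))
    stop("both outcome classes must be nonempty", call. = FALSE)
  idx
}

#' Tally division counts per class
#'
#' Builds the division-count table that is the discrete Bayes classifier's
#' entire fitted state: for each class, marker and division, the number of
#' training patients whose discretized value falls in that division.  For
#' every marker the per-class division counts sum to that class's total
#' patient count.
#'
#' @param data labeled data.frame (see [read_patients()]); every record must
#'   have a known outcome.  Records with a missing value for a counted
#'   marker are dropped from that fit with a warning.
#' @param scheme a [cutoff_scheme()].
#' @param markers markers to count (default: all in the scheme).
#' @param outcome outcome column name.
#' @return an object of class `"division_counts"`: a list with elements
#'   `counts` (per marker, an integer matrix divisions x 2 classes),
#'   `n` (per-class totals), `scheme`, `markers`.
#' @export
count_divisions <- function(data, scheme, markers = NULL,
                            outcome = "outcome") {
  markers <- markers %||% scheme_marker_names(scheme)
  miss <- rowSums(is.na(data[, markers, drop = FALSE])) > 0
  if (any(miss)) {
    warning(sum(miss), " record(s) with missing marker values excluded ",
            "from counting", call. = FALSE)
    data <- data[!miss, , drop = FALSE]
  }
  idx <- class_indices(data, outcome)
  div <- discretize(data, scheme, markers)
  counts <- lapply(markers, function(mn) {
    R <- n_divisions(scheme$markers[[mn]])
    m <- cbind(
      recurrence    = tabulate(div[idx$recurrence, mn], nbins = R),
      nonrecurrence = tabulate(div[idx$nonrecurrence, mn], nbins = R))
    rownames(m) <- vapply(scheme$markers[[mn]]$divisions, `[[`,
                          character(1), "label")
    m
  })
  names(counts) <- markers
  new_division_counts(counts,
                      n = c(recurrence = length(idx$recurrence),
                            nonrecurrence = length(idx$nonrecurrence)),
                      scheme = scheme, markers = markers)
}

new_division_counts <- function(counts, n, scheme = NULL, markers = NULL) {
  markers <- markers %||% names(counts)
  for (mn in markers) {
    s <- colSums(counts[[mn]])
    if (any(s != n))
      stop("division counts for marker '", mn,
           "' do not sum to the class totals", call. = FALSE)
  }
  structure(list(counts = counts, n = n, scheme = scheme, markers = markers),
            class = "division_counts")
}

#' @export
print.division_counts <- function(x, ...) {
  cat("Division counts: ", length(x$markers), " markers; n = ",
      x$n[1], " recurrence / ", x$n[2], " nonrecurrence\n\n", sep = "")
  for (mn in x$markers) {
    m <- x$counts[[mn]]
    for (r in seq_len(nrow(m))) {
      cat(sprintf("  %-38s %4d %4d\n", rownames(m)[r], m[r, 1], m[r, 2]))
    }
  }
  invisible(x)
}

#' Reference training-cohort division counts
#'
#' The packaged division-count table of the reference hepatocellular-
#' carcinoma training cohort: 29 patients who recurred within one year and
#' 89 who did not, tallied over the ten markers of [hcc_marker_scheme()].
#' This table is sufficient to fit the discrete Bayes classifier — no
#' patient-level data are required.
#'
#' @return a `"division_counts"` object (see [count_divisions()]).
#' @examples
#' fit <- dbayes(hcc_training_counts(), markers = c("ALB", "tumor_burden"))
#' posterior(fit, c(ALB = 1, tumor_burden = 3))
#' @export
hcc_training_counts <- function() {
  sch <- hcc_marker_scheme()
  tab <- list(
    ALB             = c(15, 14,   60, 29),
    tumor_burden    = c( 6, 11, 12,   47, 29, 13),
    vp              = c(10, 19,   18, 71),
    ICG             = c(14, 15,   44, 45),
    vv              = c( 9, 20,   16, 73),
    platelets       = c(16, 13,   70, 19),
    PT              = c(18, 11,   67, 22),
    bilirubin       = c(17, 12,   61, 28),
    differentiation = c(25,  4,   79, 10),
    liver_damage    = c(15, 14,   60, 29)
  )
  counts <- lapply(names(tab), function(mn) {
    R <- n_divisions(sch$markers[[mn]])
    m <- matrix(as.integer(tab[[mn]]), nrow = R,
                dimnames = list(
                  vapply(sch$markers[[mn]]$divisions, `[[`, character(1),
                         "label"),
                  c("recurrence", "nonrecurrence")))
    m
  })
  names(counts) <- names(tab)
  # Joint structure is not recorded here; marginal counts only.  (In the
  # reference cohort 7 recurrence patients fall jointly in ALB > 3.5 and
  # tumor burden > 9 — informational, not part of the fitted state.)
  new_division_counts(counts, n = c(recurrence = 29L, nonrecurrence = 89L),
                      scheme = sch)
}
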