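#' Summed-score clinical staging tables
#'
#' A score table assigns, for each of its markers, integer points according
#' to which condition the patient's raw value satisfies; the per-marker
#' conditions must be mutually exclusive and exhaustive.  A patient's total
#' score is the sum over markers, and the diagnosis compares the total
#' against the table's cutoff (`score >= cutoff` means predicted recurrence
#' under the default direction).
#'
#' @param name system name.
#' @param markers a named list: marker name -> list of conditions, each
#'   condition a list with a `division` rule (see [div_threshold()],
#'   [div_interval()], [div_category()]) and nonnegative integer `points`.
#'   Convenience: a condition may be given as
#'   `list(rule = <division>, points = <int>)`.
#' @param cutoff integer diagnosis cutoff on the total score.
#' @param direction `">="` (default) or `">"`: the comparison under which a
#'   total score means predicted recurrence.
#' @return an object of class `"score_table"`.
#' @seealso [tokyo_score_table()], [total_score()], [diagnose()]
#' @export
score_table <- function(name, markers, cutoff, direction = c(">=", ">")) {
  direction <- match.arg(direction)
  stopifnot(is.list(markers), length(markers) >= 1L,
            !is.null(names(markers)))
  markers <- lapply(markers, function(conds) {
    lapply(conds, function(cond) {
      rule <- cond$rule %||% cond$division
      if (!inherits(rule, "division"))
        stop("each condition needs a 'division' rule", call. = FALSE)
      pts <- cond$points
      if (!is.numeric(pts) || length(pts) != 1L || pts < 0 ||
          pts != as.integer(pts))
        stop("points must be a nonnegative integer", call. = FALSE)
      list(rule = rule, points = as.integer(pts))
    })
  })
  structure(list(name = name, markers = markers,
                 cutoff = as.integer(cutoff), direction = direction),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(x$name, " (diagnose recurrence when total ", x$direction, " ",
      x$cutoff, ")\n", sep = "")
  for (mn in names(x$markers)) {
    for (cond in x$markers[[mn]]) {
      cat(sprintf("  %-12s %-24s %d point(s)\n", mn, cond$rule$label,
                  cond$points))
    }
  }
  invisible(x)
}

#' The Tokyo Score point table
#'
#' The four-marker Tokyo Score for hepatocellular carcinoma: serum albumin
#' (g/dL), serum bilirubin (mg/dL), tumor size (cm), and the number of
#' tumors, each contributing 0-2 points, with diagnosis cutoff 2 on the
#' total.  The worked reference case — albumin 3.0, bilirubin 1.5, tumor
#' size 1.0, four tumors — scores 1 + 1 + 0 + 2 = 4 points and is
#' diagnosed as possible recurrence at cutoff 2.  The table is an ordinary
#' [score_table()] (editable config, not hard-coded truth): only the four
#' markers and the worked case's per-marker points are fixed by the
#' reference; edit or re-serialize it to explore variants.
#'
#' @param cutoff diagnosis cutoff (default 2).
#' @return a `"score_table"`.
#' @examples
#' pt <- list(albumin = 3.0, bilirubin = 1.5, tumor_size = 1.0,
#'            tumor_number = 4)
#' total_score(pt, tokyo_score_table())  # 4
#' @export
tokyo_score_table <- function(cutoff = 2) {
  score_table(
    "Tokyo Score",
    markers = list(
      albumin = list(
        list(rule = div_threshold("albumin > 3.5", ">", 3.5), points = 0),
        list(rule = div_interval("albumin 2.8~3.5", 2.8, 3.5), points = 1),
        list(rule = div_threshold("albumin < 2.8", "<", 2.8), points = 2)),
      bilirubin = list(
        list(rule = div_threshold("bilirubin < 1", "<", 1), points = 0),
        list(rule = div_interval("bilirubin 1~2", 1, 2), points = 1),
        list(rule = div_threshold("bilirubin > 2", ">", 2), points = 2)),
      tumor_size = list(
        list(rule = div_threshold("tumor size < 2", "<", 2), points = 0),
        list(rule = div_interval("tumor size 2~5", 2, 5), points = 1),
        list(rule = div_threshold("tumor size > 5", ">", 5), points = 2)),
      tumor_number = list(
        list(rule = div_threshold("tumor number <= 3", "<=", 3), points = 0),
        list(rule = div_threshold("tumor number > 3", ">", 3), points = 2))
    ),
    cutoff = cutoff)
}

#' Total score of a patient under a staging table
#'
#' Sums the per-marker points of the conditions the patient's raw values
#' satisfy.  Staging systems require every one of their markers: a missing
#' value (or absent column) is an error naming the marker — unlike the
#' discrete Bayes classifier, a score table cannot fall back to the
#' markers a patient happens to have.
#'
#' @param record a named list or one-row data.frame of raw values.
#' @param table a [score_table()].
#' @return integer total score (for a multi-row data.frame, an integer
#'   vector).
#' @export
total_score <- function(record, table) {
  stopifnot(inherits(table, "score_table"))
  df <- if (is.data.frame(record)) record
        else as.data.frame(record, stringsAsFactors = FALSE, optional = TRUE)
  total <- integer(nrow(df))
  for (mn in names(table$markers)) {
    if (!mn %in% names(df) || anyNA(df[[mn]]))
      stop("marker '", mn, "' required by ", table$name,
           " is missing", call. = FALSE)
    x <- df[[mn]]
    pts <- rep(NA_integer_, nrow(df))
    for (cond in table$markers[[mn]]) {
      sel <- rule_matches(cond$rule$rule, x)
      sel[is.na(sel)] <- FALSE
      conflict <- sel & !is.na(pts)
      if (any(conflict))
        stop("conditions for marker '", mn, "' are not mutually exclusive",
             call. = FALSE)
      pts[sel] <- cond$points
    }
    if (anyNA(pts))
      stop("value '", x[which(is.na(pts))[1]], "' of marker '", mn,
           "' matches no condition of ", table$name, call. = FALSE)
    total <- total + pts
  }
  total
}

#' Diagnose recurrence from a total score
#'
#' @param score integer total score (vectorised).
#' @param table a [score_table()] supplying the cutoff and direction.
#' @return outcome factor: `"recurrence"` when the score meets the cutoff
#'   (`>=` under the default direction), else `"nonrecurrence"`.
#' @examples
#' diagnose(4, tokyo_score_table())  # recurrence
#' @export
diagnose <- function(score, table) {
  stopifnot(inherits(table, "score_table"))
  hit <- if (table$direction == ">=") score >= table$cutoff
         else score > table$cutoff
  factor(ifelse(hit, "recurrence", "nonrecurrence"),
         levels = OUTCOME_LEVELS)
}

#' Score and diagnose a patient table
#'
#' @param data data.frame of raw patient values.
#' @param table a [score_table()].
#' @return `data` with appended `score` and `diagnosis` columns.
#' @export
score_patients <- function(data, table) {
  data$score <- total_score(data, table)
  data$diagnosis <- diagnose(data$score, table)
  data
}

# ---- serialization ---------------------------------------------------------

#' Read or write a score table as YAML
#'
#' @param table a [score_table()].
#' @param path file path.
#' @return `read_score_table()` returns a `"score_table"`;
#'   `write_score_table()` returns `path` invisibly.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  obj <- list(
    name = table$name, cutoff = table$cutoff, direction = table$direction,
    markers = lapply(table$markers, function(conds) {
      lapply(conds, function(cond) {
        c(list(label = cond$rule$label, points = cond$points),
          cond$rule$rule)
      })
    }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  obj <- yaml::read_yaml(path)
  markers <- lapply(obj$markers, function(conds) {
    lapply(conds, function(cond) {
      rule <- cond[setdiff(names(cond), c("label", "points"))]
      div <- switch(rule$type,
        threshold = div_threshold(cond$label, rule$op, rule$value),
        interval  = div_interval(cond$label, rule$lower, rule$upper,
                                 isTRUE(rule$incl_lower),
                                 isTRUE(rule$incl_upper)),
        category  = div_category(cond$label, unlist(rule$values)),
        stop("unknown rule type in score table: ", rule$type))
      list(rule = div, points = cond$points)
    })
  })
  score_table(obj$name, markers, obj$cutoff, obj$direction)
}
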