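#' Division rules
#'
#' A division is one category of a discretized marker.  Within a marker the
#' division rules must be mutually exclusive and jointly exhaustive over the
#' declared input domain, so every raw value maps to exactly one division.
#' Three rule types are supported:
#'
#' * `div_threshold(label, op, value)` — one-sided cut on a continuous value,
#'   `op` one of `">"`, `">="`, `"<"`, `"<="` (strictness follows the label
#'   as printed on the clinical cutoff sheet);
#' * `div_interval(label, lower, upper, incl_lower, incl_upper)` — a bounded
#'   interval, closed at both ends by default (so a "4~9" band sandwiched
#'   between "< 4" and "> 9" neighbours is \[4, 9\]);
#' * `div_category(label, values)` — exact match against one or more
#'   categorical labels (e.g. vascular-invasion "+" / "-").
#'
#' @param label human-readable division label, e.g. `"ALB > 3.5"`.
#' @param op comparison operator for a threshold rule.
#' @param value numeric threshold.
#' @param lower,upper interval endpoints.
#' @param incl_lower,incl_upper whether each endpoint belongs to the interval.
#' @param values character vector of category labels matched by the rule.
#' @return an object of class `"division"`.
#' @seealso [marker()], [cutoff_scheme()]
#' @export
div_threshold <- function(label, op, value) {
  op <- match.arg(op, c(">", ">=", "<", "<="))
  stopifnot(is.numeric(value), length(value) == 1L)
  new_division(label, list(type = "threshold", op = op, value = value))
}

#' @rdname div_threshold
#' @export
div_interval <- function(label, lower, upper, incl_lower = TRUE,
                         incl_upper = TRUE) {
  stopifnot(is.numeric(lower), is.numeric(upper), lower <= upper)
  new_division(label, list(type = "interval", lower = lower, upper = upper,
                           incl_lower = incl_lower, incl_upper = incl_upper))
}

#' @rdname div_threshold
#' @export
div_category <- function(label, values) {
  stopifnot(is.character(values), length(values) >= 1L)
  new_division(label, list(type = "category", values = values))
}

new_division <- function(label, rule) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  structure(list(label = label, rule = rule), class = "division")
}

# Does raw value x satisfy a division rule?  Vectorised over x.
rule_matches <- function(rule, x) {
  switch(rule$type,
    threshold = {
      v <- suppressWarnings(as.numeric(x))
      switch(rule$op,
        ">"  = v >  rule$value,
        ">=" = v >= rule$value,
        "<"  = v <  rule$value,
        "<=" = v <= rule$value)
    },
    interval = {
      v <- suppressWarnings(as.numeric(x))
      lo <- if (rule$incl_lower) v >= rule$lower else v > rule$lower
      hi <- if (rule$incl_upper) v <= rule$upper else v < rule$upper
      lo & hi
    },
    category = as.character(x) %in% rule$values,
    stop("unknown rule type: ", rule$type)
  )
}

# A representative raw value inside a division, used when synthesising
# records that must discretize back into that division.
rule_representative <- function(rule) {
  switch(rule$type,
    threshold = switch(rule$op,
      ">"  = rule$value + rule_span(rule$value) / 2,
      ">=" = rule$value,
      "<"  = rule$value - rule_span(rule$value) / 2,
      "<=" = rule$value),
    interval = (rule$lower + rule$upper) / 2,
    category = rule$values[[1L]]
  )
}

# An open sampling interval (a, b) whose interior lies inside the division;
# for one-sided rules the unbounded side is capped at a scale-dependent span.
rule_span <- function(value) max(1, abs(value))

rule_interval <- function(rule) {
  switch(rule$type,
    threshold = switch(rule$op,
      ">"  = c(rule$value, rule$value + rule_span(rule$value)),
      ">=" = c(rule$value, rule$value + rule_span(rule$value)),
      "<"  = c(rule$value - rule_span(rule$value), rule$value),
      "<=" = c(rule$value - rule_span(rule$value), rule$value)),
    interval = c(rule$lower, rule$upper),
    category = NULL
  )
}

# Sample n raw values uniformly within a division.  For one-sided and
# interval rules draws land in the interior of the division almost surely;
# ">=", "<=" boundaries are honoured by a closed endpoint being the
# representative fallback for zero-width intervals.
rule_sample <- function(rule, n) {
  if (rule$type == "category") {
    return(sample(rule$values, n, replace = TRUE))
  }
  iv <- rule_interval(rule)
  if (iv[1] == iv[2]) return(rep(iv[1], n))
  stats::runif(n, iv[1], iv[2])
}

#' Define a marker and its divisions
#'
#' A marker is a laboratory or pathology feature whose range is partitioned
#' into at least two ordered divisions.  Division indices are 1-based and
#' follow the order given here.
#'
#' @param name marker name, used as the column name in patient tables.
#' @param ... two or more `"division"` objects, in index order.
#' @param id optional small-integer marker id (defaults to assignment order
#'   within the scheme).
#' @return an object of class `"marker"`.
#' @export
marker <- function(name, ..., id = NA_integer_) {
  divisions <- list(...)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(divisions) < 2L)
    stop("marker '", name, "' needs at least 2 divisions", call. = FALSE)
  ok <- vapply(divisions, inherits, logical(1), "division")
  if (!all(ok)) stop("all divisions must be 'division' objects", call. = FALSE)
  labels <- vapply(divisions, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate division labels in marker '", name, "'", call. = FALSE)
  structure(list(name = name, id = as.integer(id), divisions = divisions),
            class = "marker")
}

#' Assemble a cutoff scheme
#'
#' A cutoff scheme is the ordered collection of markers (with their division
#' rules) that defines how raw patient values are discretized.  Marker ids
#' are assigned from position when not given explicitly.
#'
#' @param ... `"marker"` objects.
#' @param version free-form version tag stored with the scheme.
#' @return an object of class `"cutoff_scheme"`.
#' @examples
#' sch <- cutoff_scheme(
#'   marker("ALB",
#'     div_threshold("ALB > 3.5", ">", 3.5),
#'     div_threshold("ALB <= 3.5", "<=", 3.5)))
#' discretize(data.frame(ALB = c(3.6, 3.5)), sch)
#' @export
cutoff_scheme <- function(..., version = "1") {
  markers <- list(...)
  if (length(markers) == 1L && is.list(markers[[1L]]) &&
      !inherits(markers[[1L]], "marker")) {
    markers <- markers[[1L]]
  }
  ok <- vapply(markers, inherits, logical(1), "marker")
  if (!length(markers) || !all(ok))
    stop("cutoff_scheme() expects one or more 'marker' objects", call. = FALSE)
  names <- vapply(markers, `[[`, character(1), "name")
  if (anyDuplicated(names))
    stop("duplicate marker names in scheme", call. = FALSE)
  for (k in seq_along(markers)) {
    if (is.na(markers[[k]]$id)) markers[[k]]$id <- k
  }
  names(markers) <- names
  structure(list(markers = markers, version = as.character(version)),
            class = "cutoff_scheme")
}

#' @export
print.cutoff_scheme <- function(x, ...) {
  cat("Cutoff scheme (version ", x$version, "), ",
      length(x$markers), " markers\n", sep = "")
  for (m in x$markers) {
    labs <- vapply(m$divisions, `[[`, character(1), "label")
    cat(sprintf("  x%-2d %-28s [%s]\n", m$id, m$name,
                paste(labs, collapse = " | ")))
  }
  invisible(x)
}

scheme_marker_names <- function(scheme) {
  unname(vapply(scheme$markers, `[[`, character(1), "name"))
}

n_divisions <- function(marker) length(marker$divisions)

#' Discretize raw marker values into division indices
#'
#' Maps each raw value to the 1-based index of the unique division whose rule
#' it satisfies.  This is the conversion of quantitative laboratory data into
#' the categorical pattern vector consumed by the discrete Bayes classifier.
#'
#' @param data a data.frame of raw patient values (one row per patient) with
#'   marker-named columns, or a single named list/one-row data.frame.
#' @param scheme a [cutoff_scheme()].
#' @param markers character vector of marker names to discretize (defaults to
#'   every marker in the scheme).  Output column order follows this list.
#' @return an integer matrix (rows = patients, columns = requested markers)
#'   of division indices.
#' @details A missing raw value for a requested marker is an error naming the
#'   marker; so is a raw value matching no division (possible only for a
#'   scheme that does not cover its declared domain, or a category label
#'   outside the declared set).
#' @export
discretize <- function(data, scheme, markers = NULL) {
  stopifnot(inherits(scheme, "cutoff_scheme"))
  if (!is.data.frame(data)) data <- as.data.frame(data, stringsAsFactors = FALSE)
  markers <- markers %||% scheme_marker_names(scheme)
  unknown <- setdiff(markers, scheme_marker_names(scheme))
  if (length(unknown))
    stop("marker(s) not in scheme: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(markers, names(data))
  if (length(absent))
    stop("missing marker column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  out <- matrix(NA_integer_, nrow = nrow(data), ncol = length(markers),
                dimnames = list(NULL, markers))
  for (mn in markers) {
    m <- scheme$markers[[mn]]
    x <- data[[mn]]
    if (anyNA(x)) {
      stop("missing value for marker '", mn, "' in record(s) ",
           paste(utils::head(which(is.na(x)), 5L), collapse = ", "),
           call. = FALSE)
    }
    idx <- rep(NA_integer_, length(x))
    hits <- integer(length(x))
    for (r in seq_along(m$divisions)) {
      sel <- rule_matches(m$divisions[[r]]$rule, x)
      sel[is.na(sel)] <- FALSE
      hits <- hits + sel
      idx[sel & is.na(idx)] <- r
    }
    if (any(hits == 0L)) {
      bad <- which(hits == 0L)[1L]
      stop("value '", x[bad], "' of marker '", mn,
           "' matches no division", call. = FALSE)
    }
    if (any(hits > 1L)) {
      bad <- which(hits > 1L)[1L]
      stop("value '", x[bad], "' of marker '", mn,
           "' matches more than one division (rules not mutually exclusive)",
           call. = FALSE)
    }
    out[, mn] <- idx
  }
  out
}

# ---- serialization ---------------------------------------------------------

scheme_to_list <- function(scheme) {
  list(
    version = scheme$version,
    markers = lapply(unname(scheme$markers), function(m) {
      list(
        id = m$id,
        name = m$name,
        divisions = lapply(m$divisions, function(d) {
          c(list(label = d$label), d$rule)
        })
      )
    })
  )
}

scheme_from_list <- function(x) {
  markers <- lapply(x$markers, function(m) {
    divisions <- lapply(m$divisions, function(d) {
      rule <- d[setdiff(names(d), "label")]
      switch(rule$type,
        threshold = div_threshold(d$label, rule$op, rule$value),
        interval  = div_interval(d$label, rule$lower, rule$upper,
                                 isTRUE(rule$incl_lower),
                                 isTRUE(rule$incl_upper)),
        category  = div_category(d$label, unlist(rule$values)),
        stop("unknown rule type in scheme file: ", rule$type))
    })
    do.call(marker, c(list(m$name), divisions, list(id = m$id %||% NA_integer_)))
  })
  cutoff_scheme(markers, version = x$version %||% "1")
}

#' Read or write a cutoff scheme as YAML
#'
#' The serialized form round-trips without loss: labels, rule types,
#' operators, endpoints and marker ids are preserved exactly.
#'
#' @param scheme a [cutoff_scheme()].
#' @param path file path (`.yaml`).
#' @return `read_scheme()` returns a `cutoff_scheme`; `write_scheme()`
#'   returns `path` invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "cutoff_scheme"))
  yaml::write_yaml(scheme_to_list(scheme), path)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  scheme_from_list(yaml::read_yaml(path))
}

#' The reference liver-marker cutoff scheme
#'
#' The ten-marker cutoff scheme used throughout the package examples:
#' serum albumin (ALB, g/dL), tumor burden (tumor number times tumor size),
#' portal vein invasion (vp), indocyanine green retention (ICG, %), hepatic
#' vein invasion (vv), platelet count, prothrombin time (PT, %), serum
#' bilirubin, histological differentiation (poorly differentiated "por" vs
#' other), and clinical liver-damage grade (A/B).  Cutoff values are the
#' physician-determined divisions of the reference cohort; threshold
#' strictness follows the printed labels (e.g. "ALB > 3.5" is strict, so a
#' value of exactly 3.5 falls in "ALB <= 3.5"), and the tumor-burden band
#' "4~9" is the closed interval \[4, 9\] because its neighbours are "< 4"
#' and "> 9".  Marker units are stored implicitly in the labels; values are
#' treated as unitless numbers.
#'
#' @return a [cutoff_scheme()] with 10 markers.
#' @export
hcc_marker_scheme <- function() {
  cutoff_scheme(
    marker("ALB",
      div_threshold("ALB > 3.5", ">", 3.5),
      div_threshold("ALB <= 3.5", "<=", 3.5)),
    marker("tumor_burden",
      div_threshold("Tumor number x tumor size < 4", "<", 4),
      div_interval("Tumor number x tumor size 4~9", 4, 9),
      div_threshold("Tumor number x tumor size > 9", ">", 9)),
    marker("vp",
      div_category("vp+", "+"),
      div_category("vp-", "-")),
    marker("ICG",
      div_threshold("ICG < 15", "<", 15),
      div_threshold("ICG >= 15", ">=", 15)),
    marker("vv",
      div_category("vv+", "+"),
      div_category("vv-", "-")),
    marker("platelets",
      div_threshold("Number of platelets >= 10", ">=", 10),
      div_threshold("Number of platelets < 10", "<", 10)),
    marker("PT",
      div_threshold("PT >= 80", ">=", 80),
      div_threshold("PT < 80", "<", 80)),
    marker("bilirubin",
      div_threshold("Bilirubin < 1", "<", 1),
      div_threshold("Bilirubin >= 1", ">=", 1)),
    marker("differentiation",
      div_category("Degree of differentiation non-por", "non-por"),
      div_category("Degree of differentiation por", "por")),
    marker("liver_damage",
      div_category("Liver damage A", "A"),
      div_category("Liver damage B", "B")),
    version = "hcc-reference-1"
  )
}
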