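#' Crash-record variable schema
#'
#' A schema is an ordered list of variable specifications describing the
#' categorical predictors a dispatch decision tree may split on: the MPDS
#' dispatch code plus the crash characteristics a bystander can report over
#' the phone (rollover, trapped occupants, atmosphere, ...). Each variable is
#' dichotomous, nominal, ordinal or continuous; ordinals carry their category
#' order and continuous variables carry an equal-frequency binning rule that
#' must be applied before tree growth.
#'
#' @name schema
NULL

#' Reserved label for a missing value
#'
#' Missing feature values are represented by a single reserved category
#' label. During tree growth the missing category "floats": it may merge
#' with any other category group, including non-adjacent groups of an
#' ordinal variable.
#'
#' @export
MISSING_LABEL <- "__missing__"

#' Construct a variable specification
#'
#' @param name variable name (unique within a schema)
#' @param kind one of \code{"dichotomous"}, \code{"nominal"},
#'   \code{"ordinal"}, \code{"continuous"}
#' @param categories character vector of category labels; for ordinals the
#'   order is the category order; ignored for continuous variables until they
#'   are binned
#' @param n_bins number of equal-frequency bins for a continuous variable
#' @return an object of class \code{variable_spec}
#' @export
variable_spec <- function(name, kind = c("dichotomous", "nominal", "ordinal",
                                         "continuous"),
                          categories = character(), n_bins = 10L) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  categories <- as.character(categories)
  if (anyDuplicated(categories))
    stop("duplicate category labels in variable '", name, "'")
  if (MISSING_LABEL %in% categories)
    stop("'", MISSING_LABEL, "' is reserved and cannot be a declared category")
  if (kind != "continuous" && length(categories) < 1L)
    stop("variable '", name, "' declares no categories")
  if (kind == "dichotomous" && length(categories) != 2L)
    stop("dichotomous variable '", name, "' must declare exactly 2 categories")
  structure(list(name = name, kind = kind, categories = categories,
                 n_bins = as.integer(n_bins), missing_label = MISSING_LABEL),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat("<variable_spec> ", x$name, " (", x$kind, "): ",
      if (x$kind == "continuous" && length(x$categories) == 0L)
        paste0("unbinned, ", x$n_bins, " equal-frequency bins at load")
      else paste(x$categories, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Build a schema from variable specifications
#'
#' @param ... \code{variable_spec} objects, in declared order. The declared
#'   order is the deterministic tie-break when two candidate splits have
#'   identical adjusted p-values.
#' @return an object of class \code{mvc_schema} (named list of specs)
#' @export
mvc_schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) &&
      !inherits(specs[[1]], "variable_spec"))
    specs <- specs[[1]]
  if (!all(vapply(specs, inherits, logical(1), "variable_spec")))
    stop("all arguments must be variable_spec objects")
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate variable names in schema")
  structure(stats::setNames(specs, nms), class = "mvc_schema")
}

#' @export
print.mvc_schema <- function(x, ...) {
  cat("<mvc_schema> with", length(x), "variables:\n")
  for (v in x)
    cat(sprintf("  %-22s %-12s %d categories\n", v$name, v$kind,
                length(v$categories)))
  invisible(x)
}

#' The default crash-record schema
#'
#' The full variable set of the dispatch-triage analysis: the Protocol-29
#' MPDS dispatch code (52 codes) and 21 crash characteristics. Sixteen
#' characteristics carry the embedded reference marginals; the remaining five
#' (raining, speed limit, time of day, traffic control, intersection type)
#' are declared per the study's variable dictionary but have no printed
#' marginal distribution, so the generator uses illustrative defaults for
#' them.
#'
#' @param n_time_bins equal-frequency bins for the continuous time-of-day
#'   variable
#' @return an \code{mvc_schema}
#' @export
default_schema <- function(n_time_bins = 10L) {
  t2 <- .table2_raw()
  t3 <- .table3_raw()
  cats <- function(v) t3$category[t3$variable == v]
  dich <- function(v) variable_spec(v, "dichotomous", cats(v))
  mvc_schema(
    variable_spec("mpds_code", "nominal", t2$code),
    dich("anyone_trapped"),
    dich("vulnerable_road_user"),
    dich("anyone_not_ambulant"),
    dich("anyone_ejected"),
    dich("rollover"),
    dich("airbag_deployed"),
    dich("older"),
    dich("child"),
    dich("single_v_multi"),
    dich("accident_type"),
    dich("road_alignment"),
    dich("road_surface"),
    variable_spec("road_grade", "nominal", cats("road_grade")),
    variable_spec("atmosphere", "nominal", cats("atmosphere")),
    variable_spec("lighting", "nominal", cats("lighting")),
    variable_spec("day_of_week", "nominal", cats("day_of_week")),
    variable_spec("raining", "dichotomous", c("Raining", "Clear")),
    variable_spec("speed_limit", "ordinal",
                  c("40", "50", "60", "70", "80", "90", "100", "110")),
    variable_spec("time_of_day", "continuous", n_bins = n_time_bins),
    variable_spec("traffic_control", "nominal",
                  c("Traffic lights", "Stop sign", "Give way sign",
                    "Zebra crossing", "Railway crossing", "School crossing",
                    "No signal or control")),
    variable_spec("intersection_type", "nominal",
                  c("4-way", "3-way (T-junction)", "Roundabout", "Bridge",
                    "Rail crossing", "Driveway"))
  )
}

#' Crash characteristic variables (everything except the MPDS code)
#' @param schema an \code{mvc_schema}
#' @return character vector of variable names
#' @export
characteristic_variables <- function(schema) {
  setdiff(names(schema), "mpds_code")
}

#' Read or write a schema as JSON
#'
#' @param path file path
#' @return \code{read_schema}: an \code{mvc_schema}
#' @export
read_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(seq_len(nrow(raw$variables)), function(i) {
    r <- raw$variables[i, ]
    variable_spec(r$name, r$kind, unlist(r$categories),
                  n_bins = if (is.null(r$n_bins) || is.na(r$n_bins)) 10L
                           else r$n_bins)
  })
  mvc_schema(specs)
}

#' @rdname read_schema
#' @param schema an \code{mvc_schema}
#' @export
write_schema <- function(schema, path) {
  vars <- data.frame(
    name = names(schema),
    kind = vapply(schema, `[[`, character(1), "kind"),
    n_bins = vapply(schema, `[[`, integer(1), "n_bins"),
    stringsAsFactors = FALSE)
  vars$categories <- unname(lapply(schema, `[[`, "categories"))
  jsonlite::write_json(list(variables = vars), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
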