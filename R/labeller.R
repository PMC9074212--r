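#' Outcome labelling: did this crash need a lights-and-sirens response?
#'
#' The binary outcome is reconstructed retrospectively from clinical fields
#' by a composite disjunction — a record is labelled L&S-needed when any of
#' the following holds:
#' \enumerate{
#'   \item the ambulance left the scene for an emergency department under
#'     L&S;
#'   \item anyone was dead on scene or in transit;
#'   \item anyone met at least one L&S dispatch indicator (an
#'     intervention / medication / observation predicate).
#' }
#' Indicators are evaluated per incident ("anyone"), not per patient. There
#' is no authoritative public indicator list; the package ships an
#' illustrative default rule set (see
#' \code{system.file("extdata", "default_indicator_rules.json", package =
#' "dispatchtriage")}) that users should replace with their service's own
#' clinical governance rules.
#'
#' @name outcome_labeller
NULL

#' Build an indicator rule set
#'
#' Each rule is a named predicate over one clinical field:
#' \code{list(name, field, operator, threshold)} with operator one of
#' \code{"lt"}, \code{"le"}, \code{"gt"}, \code{"ge"}, \code{"eq"},
#' \code{"is_true"}. An empty rule set is allowed — labelling then reduces
#' to the first two clauses.
#'
#' @param rules list of rule lists
#' @return an object of class \code{indicator_rule_set}
#' @export
indicator_rule_set <- function(rules = list()) {
  nms <- vapply(rules, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate indicator names")
  ops <- c("lt", "le", "gt", "ge", "eq", "is_true")
  for (r in rules) {
    stopifnot(all(c("name", "field", "operator") %in% names(r)))
    if (!r$operator %in% ops)
      stop("unknown operator '", r$operator, "' in indicator '", r$name, "'")
    if (r$operator != "is_true" && is.null(r$threshold))
      stop("indicator '", r$name, "' needs a threshold")
  }
  structure(list(rules = rules), class = "indicator_rule_set")
}

#' Read an indicator rule set from JSON
#'
#' @param path JSON file: an array of \code{{name, field, operator,
#'   threshold}} objects
#' @return an \code{indicator_rule_set}
#' @export
read_indicator_rules <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  indicator_rule_set(raw)
}

#' The illustrative default indicator rule set
#'
#' Four physiologically motivated example indicators (reduced consciousness,
#' hypotension, intubation, adrenaline administration). Not a clinical
#' authority — replace with service-defined rules for real use.
#'
#' @return an \code{indicator_rule_set}
#' @export
default_indicator_rules <- function() {
  read_indicator_rules(system.file("extdata",
                                   "default_indicator_rules.json",
                                   package = "dispatchtriage"))
}

# Evaluate one rule against a clinical data frame -> logical vector.
.eval_rule <- function(rule, clinical) {
  if (!rule$field %in% names(clinical))
    stop("clinical field '", rule$field, "' required by indicator '",
         rule$name, "' is absent")
  x <- clinical[[rule$field]]
  if (anyNA(x))
    stop("clinical field '", rule$field, "' has missing values; ",
         "labelling requires complete clinical fields")
  switch(rule$operator,
         lt = as.numeric(x) < rule$threshold,
         le = as.numeric(x) <= rule$threshold,
         gt = as.numeric(x) > rule$threshold,
         ge = as.numeric(x) >= rule$threshold,
         eq = x == rule$threshold,
         is_true = as.logical(x))
}

#' Label records from clinical profiles
#'
#' @param clinical data frame with logical columns
#'   \code{from_scene_priority_ls} and \code{any_death}, plus whatever
#'   fields the rule set references; every referenced field must be complete
#'   (labelling never silently defaults to "no")
#' @param rules an \code{indicator_rule_set}
#' @return integer vector of labels (1 = L&S needed)
#' @export
label_records <- function(clinical, rules = indicator_rule_set()) {
  need <- c("from_scene_priority_ls", "any_death")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop("clinical profile lacks field(s): ", paste(miss, collapse = ", "))
  base <- lapply(need, function(f) {
    x <- clinical[[f]]
    if (anyNA(x)) stop("clinical field '", f, "' has missing values")
    as.logical(x)
  })
  hit <- base[[1]] | base[[2]]
  for (r in rules$rules) hit <- hit | .eval_rule(r, clinical)
  as.integer(hit)
}

#' Label a dataset
#'
#' Records that already carry a label pass through unchanged; unlabelled
#' records must have complete clinical fields in the record table, from
#' which the composite rule computes their label.
#'
#' @param data an \code{mvc_dataset} whose records hold clinical columns
#'   for any unlabelled record
#' @param rules an \code{indicator_rule_set}
#' @return the dataset, fully labelled
#' @export
label_dataset <- function(data, rules = indicator_rule_set()) {
  rec <- data$records
  if (!"label" %in% names(rec)) rec$label <- NA_integer_
  todo <- which(is.na(rec$label))
  if (length(todo)) {
    if (!all(c("from_scene_priority_ls", "any_death") %in% names(rec)))
      stop(length(todo), " record(s) have neither a label nor a clinical ",
           "profile")
    rec$label[todo] <- label_records(rec[todo, , drop = FALSE], rules)
  }
  data$records <- rec
  data
}
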