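#' Crash datasets
#'
#' An \code{mvc_dataset} couples a schema with a data frame of crash records.
#' Feature columns hold category labels (character), with missing values
#' stored as the reserved label. Two optional column groups ride along:
#' a binary outcome column \code{label} (1 = L&S response needed) and
#' clinical columns used by the outcome labeller.
#'
#' @name dataset
NULL

#' Construct a crash dataset
#'
#' @param records data frame with one column per schema variable (character
#'   category labels; \code{NA} or \code{""} are converted to the missing
#'   label), an optional integer/logical \code{label} column and any clinical
#'   columns
#' @param schema an \code{mvc_schema}
#' @param unknown how to handle undeclared category values: \code{"error"}
#'   or \code{"missing"} (coerce to the missing label)
#' @return an object of class \code{mvc_dataset}
#' @export
mvc_dataset <- function(records, schema, unknown = c("error", "missing")) {
  unknown <- match.arg(unknown)
  stopifnot(is.data.frame(records), inherits(schema, "mvc_schema"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(schema), names(records))
  if (length(missing_cols))
    stop("records lack schema column(s): ", paste(missing_cols, collapse = ", "))
  for (v in names(schema)) {
    x <- as.character(records[[v]])
    x[is.na(x) | x == ""] <- MISSING_LABEL
    spec <- schema[[v]]
    if (spec$kind != "continuous" || length(spec$categories)) {
      bad <- !(x %in% c(spec$categories, MISSING_LABEL))
      if (any(bad)) {
        if (unknown == "error") {
          stop("undeclared value(s) for variable '", v, "' in row(s) ",
               paste(utils::head(which(bad), 5L), collapse = ", "),
               ": ", paste(utils::head(unique(x[bad]), 5L), collapse = ", "),
               "; declared categories: ",
               paste(spec$categories, collapse = ", "))
        }
        x[bad] <- MISSING_LABEL
      }
    }
    records[[v]] <- x
  }
  if ("label" %in% names(records)) {
    lab <- records$label
    if (is.logical(lab)) lab <- as.integer(lab)
    if (!all(is.na(lab) | lab %in% c(0L, 1L)))
      stop("label column must be binary (0/1)")
    records$label <- as.integer(lab)
  }
  structure(list(schema = schema, records = records), class = "mvc_dataset")
}

#' @export
print.mvc_dataset <- function(x, ...) {
  n <- nrow(x$records)
  cat("<mvc_dataset> ", n, " records, ", length(x$schema), " schema variables\n",
      sep = "")
  if ("label" %in% names(x$records)) {
    lab <- x$records$label
    if (anyNA(lab)) {
      cat("  outcome: ", sum(is.na(lab)), " unlabelled\n", sep = "")
    } else {
      cat(sprintf("  outcome: %d L&S (%.1f%%), %d not L&S\n",
                  sum(lab == 1L), 100 * mean(lab == 1L), sum(lab == 0L)))
    }
  } else cat("  outcome: absent\n")
  invisible(x)
}

#' Number of records in a dataset
#' @param data an \code{mvc_dataset}
#' @export
n_records <- function(data) nrow(data$records)

#' Is every record labelled?
#' @param data an \code{mvc_dataset}
#' @export
is_labelled <- function(data) {
  "label" %in% names(data$records) && !anyNA(data$records$label)
}

#' Read a crash dataset from CSV
#'
#' Expects a header row naming at least every schema variable; extra columns
#' (label, clinical fields) are carried through. Blank cells become the
#' missing label.
#'
#' @param path CSV file path (UTF-8, header row, one record per row)
#' @inheritParams mvc_dataset
#' @return an \code{mvc_dataset}
#' @export
read_dataset <- function(path, schema, unknown = c("error", "missing")) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols))
    stop("CSV header lacks schema column(s): ",
         paste(missing_cols, collapse = ", "))
  if ("label" %in% names(raw)) {
    suppressWarnings(lab <- as.integer(raw$label))
    bad <- which(!is.na(raw$label) & raw$label != "" & is.na(lab))
    if (length(bad))
      stop("malformed row ", bad[1], ", column 'label': '",
           raw$label[bad[1]], "' is not binary")
    lab[!is.na(raw$label) & raw$label == ""] <- NA_integer_
    raw$label <- lab
  }
  mvc_dataset(raw, schema, unknown = match.arg(unknown))
}

#' Write a crash dataset to CSV
#'
#' Missing labels are written as empty cells so that a write/read cycle is an
#' identity.
#'
#' @param data an \code{mvc_dataset}
#' @param path output CSV path
#' @export
write_dataset <- function(data, path) {
  out <- data$records
  for (v in names(data$schema))
    out[[v]][out[[v]] == MISSING_LABEL] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Bin continuous variables into equal-frequency ordinal categories
#'
#' CHAID splits categorical predictors only, so continuous variables (here,
#' time of day as \code{"hh:mm"}) are discretised before growth into
#' equal-frequency bins; the binned variable is treated as ordinal. Bin
#' boundaries are sample quantiles of the observed values; bins are labelled
#' \code{"B01"}, \code{"B02"}, ... in increasing order. Missing values stay
#' missing.
#'
#' @param data an \code{mvc_dataset}
#' @return the dataset with each continuous variable replaced by its binned
#'   ordinal version (schema updated in step)
#' @export
bin_continuous <- function(data) {
  schema <- data$schema
  for (v in names(schema)) {
    spec <- schema[[v]]
    if (spec$kind != "continuous") next
    x <- data$records[[v]]
    obs <- x != MISSING_LABEL
    minutes <- .parse_hhmm(x[obs])
    k <- max(2L, spec$n_bins)
    brk <- unique(stats::quantile(minutes, probs = seq(0, 1, length.out = k + 1),
                                  type = 1, names = FALSE))
    if (length(brk) < 3L) brk <- c(min(minutes) - 1, max(minutes))
    bins <- cut(minutes, breaks = brk, include.lowest = TRUE, labels = FALSE)
    labels <- sprintf("B%02d", seq_len(length(brk) - 1L))
    out <- rep(MISSING_LABEL, length(x))
    out[obs] <- labels[bins]
    data$records[[v]] <- out
    schema[[v]] <- variable_spec(v, "ordinal", labels)
  }
  data$schema <- schema
  data
}

# "hh:mm" -> minutes since midnight
.parse_hhmm <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("malformed time-of-day value(s): ",
         paste(utils::head(x[bad], 3L), collapse = ", "))
  h <- as.integer(vapply(m, `[`, character(1), 2L))
  mi <- as.integer(vapply(m, `[`, character(1), 3L))
  if (any(h > 23L | mi > 59L)) stop("time-of-day out of range")
  h * 60L + mi
}

#' Require a dataset ready for tree growth
#' @keywords internal
.assert_growable <- function(data) {
  if (!is_labelled(data))
    stop("dataset must be fully labelled before tree growth/evaluation; ",
         "run label_dataset() or supply a label column")
  for (v in names(data$schema))
    if (data$schema[[v]]$kind == "continuous")
      stop("continuous variable '", v, "' must be binned (bin_continuous) ",
           "before tree growth")
  invisible(data)
}
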