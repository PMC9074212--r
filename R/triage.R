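#' Confusion matrix for dispatch predictions
#'
#' Positive = L&S needed / predicted. Counts are laid out as \code{tp}
#' (dispatched L&S, needed), \code{fp} (dispatched L&S, not needed),
#' \code{tn}, \code{fn}.
#'
#' @param predictions binary vector of predicted labels
#' @param truth binary vector of true labels, same length
#' @return an object of class \code{confusion_matrix}
#' @export
confusion <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("predictions and truth differ in length")
  p <- as.integer(predictions); t <- as.integer(truth)
  if (!all(p %in% 0:1) || !all(t %in% 0:1))
    stop("labels must be binary 0/1")
  structure(list(tp = sum(p == 1L & t == 1L), fp = sum(p == 1L & t == 0L),
                 tn = sum(p == 0L & t == 0L), fn = sum(p == 0L & t == 1L)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("L&S", "not L&S"),
                              predicted = c("L&S", "not L&S")))
  print(m)
  invisible(x)
}

#' Over- and under-triage rates
#'
#' Over triage is the share of dispatched-L&S incidents that did not need
#' L&S, \eqn{100 \cdot fp / (fp + tp)} — one minus the positive predictive
#' value. Under triage is the share of not-dispatched incidents that did
#' need L&S, \eqn{100 \cdot fn / (fn + tn)} — one minus the negative
#' predictive value. An empty denominator yields 0 by convention (an
#' all-L&S dispatch policy has under triage 0%).
#'
#' @param m a \code{confusion_matrix}
#' @return percentage in [0, 100]
#' @export
over_triage <- function(m) {
  d <- m$fp + m$tp
  if (d == 0L) 0 else 100 * m$fp / d
}

#' @rdname over_triage
#' @export
under_triage <- function(m) {
  d <- m$fn + m$tn
  if (d == 0L) 0 else 100 * m$fn / d
}

#' @rdname over_triage
#' @return \code{triage_rates}: list with \code{over_triage_pct},
#'   \code{under_triage_pct} and the matrix
#' @export
triage_rates <- function(m) {
  structure(list(over_triage_pct = over_triage(m),
                 under_triage_pct = under_triage(m), matrix = m),
            class = "triage_rates")
}

#' @export
print.triage_rates <- function(x, ...) {
  cat(sprintf("over triage %.1f%% | under triage %.1f%%\n",
              x$over_triage_pct, x$under_triage_pct))
  invisible(x)
}

#' Trauma-triage benchmark criteria
#'
#' The ACS COT field-triage benchmark: under triage at or below 5% and over
#' triage between 25% and 35%. Bounds are configurable for services with a
#' different risk appetite.
#'
#' @param max_under_pct maximum acceptable under triage (default 5)
#' @param over_range_pct acceptable over-triage interval (default c(25, 35))
#' @return an object of class \code{acs_cot_criteria}
#' @export
acs_cot_criteria <- function(max_under_pct = 5, over_range_pct = c(25, 35)) {
  stopifnot(length(over_range_pct) == 2L,
            over_range_pct[1] <= over_range_pct[2])
  structure(list(max_under_pct = max_under_pct,
                 over_range_pct = over_range_pct),
            class = "acs_cot_criteria")
}

#' Select the best dispatch model from evaluated sweep rows
#'
#' Rows are candidate (model family, cost ratio) fits with their triage
#' rates. Each row gets a compliance flag: does it meet the full benchmark
#' (under within the cap AND over inside the interval)? Selection is
#' "front-loaded": degenerate all-positive rows (no predicted negatives,
#' i.e. \code{fn + tn = 0}) are excluded, then among rows with under triage
#' within the cap the minimum under triage wins, ties broken by minimum over
#' triage, then by row order. Returns \code{NULL} selection when no row
#' qualifies.
#'
#' @param rows data frame of evaluation rows with numeric columns
#'   \code{over_pct}, \code{under_pct} and logical \code{degenerate}
#'   (see [chaid_sweep()]); extra columns are carried through
#' @param criteria an \code{acs_cot_criteria}
#' @return list with \code{selected} (a one-row data frame or \code{NULL})
#'   and \code{rows} (input plus a \code{compliant} flag column)
#' @export
select_model <- function(rows, criteria = acs_cot_criteria()) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L,
            all(c("over_pct", "under_pct") %in% names(rows)))
  if (is.null(rows$degenerate)) rows$degenerate <- FALSE
  rows$compliant <- rows$under_pct <= criteria$max_under_pct &
    rows$over_pct >= criteria$over_range_pct[1] &
    rows$over_pct <= criteria$over_range_pct[2]
  eligible <- which(!rows$degenerate &
                      rows$under_pct <= criteria$max_under_pct)
  if (!length(eligible)) return(list(selected = NULL, rows = rows))
  ord <- eligible[order(rows$under_pct[eligible], rows$over_pct[eligible])]
  list(selected = rows[ord[1L], , drop = FALSE], rows = rows)
}
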