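#' Dispatch model families
#'
#' The five tree families compared in the analysis differ only in their
#' candidate variables, whether the MPDS dispatch code is forced as the
#' root split, and the depth limit:
#' \itemize{
#'   \item A — MPDS dispatch code only (necessarily depth 1)
#'   \item B — MPDS code forced first, crash characteristics below, depth 3
#'   \item C — crash characteristics only, depth 3
#'   \item D — MPDS code forced first, crash characteristics below,
#'     unlimited depth
#'   \item E — crash characteristics only, unlimited depth
#' }
#'
#' @param id single letter "A".."E"
#' @param variables candidate variable names
#' @param forced_first forced root variable or \code{NULL}
#' @param max_depth depth limit (\code{Inf} for unlimited)
#' @return an object of class \code{model_family}
#' @export
model_family <- function(id, variables, forced_first = NULL,
                         max_depth = Inf) {
  stopifnot(is.character(id), length(id) == 1L, length(variables) >= 1L)
  structure(list(id = id, variables = variables,
                 forced_first = forced_first, max_depth = max_depth),
            class = "model_family")
}

#' @rdname model_family
#' @param schema an \code{mvc_schema} (the MPDS code variable must be named
#'   \code{"mpds_code"})
#' @return \code{model_families}: named list of the five standard families
#' @export
model_families <- function(schema) {
  chars <- characteristic_variables(schema)
  all_vars <- c("mpds_code", chars)
  list(
    A = model_family("A", "mpds_code", forced_first = "mpds_code",
                     max_depth = 1),
    B = model_family("B", all_vars, forced_first = "mpds_code",
                     max_depth = 3),
    C = model_family("C", chars, max_depth = 3),
    D = model_family("D", all_vars, forced_first = "mpds_code",
                     max_depth = Inf),
    E = model_family("E", chars, max_depth = Inf)
  )
}

# Merge a family's constraints into a base growth configuration.
.family_config <- function(family, config) {
  chaid_config(alpha_merge = config$alpha_merge,
               alpha_split = config$alpha_split,
               max_depth = family$max_depth,
               min_parent = config$min_parent,
               min_child = config$min_child,
               forced_first_variable = family$forced_first,
               candidate_variables = family$variables)
}

#' Sweep misclassification cost ratios for one model family
#'
#' Grows the family's tree once (costs do not shape growth), then evaluates
#' cost ratios 1:1, 1:2, ... — each ratio re-classifies every record and
#' yields a confusion matrix and over/under-triage rates. Raising the
#' false-negative cost can only flip whole leaves from not-L&S to L&S, in
#' decreasing order of their L&S proportion, so under triage is
#' non-increasing and over triage non-decreasing across the sweep. The sweep
#' stops at the first ratio with 0% under triage — the point where the tree
#' dispatches L&S to every incident that needs it — or at \code{max_ratio},
#' in which case the result is flagged as capped.
#'
#' @param family a \code{model_family}
#' @param data a labelled \code{mvc_dataset} (training and evaluation data;
#'   apparent rates, as no holdout is used)
#' @param config a \code{chaid_config} supplying alpha levels and node-size
#'   floors (depth/variables come from the family)
#' @param max_ratio cap on the swept ratio (default 100)
#' @return an object of class \code{sweep_result}: list with \code{family},
#'   \code{tree}, \code{rows} (data frame: \code{family}, \code{depth},
#'   \code{ratio}, \code{over_pct}, \code{under_pct}, \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}, \code{degenerate}), \code{terminated_at},
#'   \code{capped}
#' @export
chaid_sweep <- function(family, data, config = chaid_config(),
                        max_ratio = 100L) {
  stopifnot(inherits(family, "model_family"), max_ratio >= 1L)
  .assert_growable(data)
  tree <- chaid_grow(data, .family_config(family, config))
  res <- sweep_grown_tree(tree, data, max_ratio = max_ratio,
                          family_id = family$id)
  res$family <- family
  res
}

#' @rdname chaid_sweep
#' @param tree an already-grown \code{chaid_tree}
#' @param family_id label used in the output rows
#' @export
sweep_grown_tree <- function(tree, data, max_ratio = 100L,
                             family_id = "tree") {
  .assert_growable(data)
  assign <- route_records(tree, data)
  y <- data$records$label
  ids <- sort(unique(assign))
  m1 <- vapply(ids, function(i) sum(y[assign == i] == 1L), integer(1))
  m0 <- vapply(ids, function(i) sum(y[assign == i] == 0L), integer(1))
  p_hat <- vapply(tree$nodes, `[[`, numeric(1), "p_hat")[ids]
  depth <- tree_depth(tree)

  rows <- NULL
  terminated_at <- NA_integer_
  for (k in seq_len(max_ratio)) {
    pos <- .node_decisions(p_hat, cost_ratio(k)) == 1L
    tp <- sum(m1[pos]); fp <- sum(m0[pos])
    fn <- sum(m1[!pos]); tn <- sum(m0[!pos])
    m <- structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
                   class = "confusion_matrix")
    rows <- rbind(rows, data.frame(
      family = family_id, depth = depth, ratio = k,
      over_pct = over_triage(m), under_pct = under_triage(m),
      tp = tp, fp = fp, tn = tn, fn = fn,
      degenerate = (fn + tn) == 0L, stringsAsFactors = FALSE))
    if (fn == 0L) { terminated_at <- k; break }
  }
  capped <- is.na(terminated_at)
  if (capped)
    warning("sweep for family ", family_id, " reached max_ratio = ",
            max_ratio, " without a 0% under-triage row")
  structure(list(family = family_id, tree = tree, rows = rows,
                 terminated_at = terminated_at, capped = capped),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  fid <- if (inherits(x$family, "model_family")) x$family$id else x$family
  cat("<sweep_result> family ", fid, ": ", nrow(x$rows), " ratios",
      if (x$capped) " (capped!)" else
        paste0(", terminated at 1:", x$terminated_at),
      "\n", sep = "")
  print(collapse_ratio_ranges(x$rows))
  invisible(x)
}

#' Collapse consecutive equal-rate ratios into ranges
#'
#' Consecutive ratios within a family whose over/under rates agree to one
#' decimal place are reported as a single row with a ratio range
#' ("1:13 to 1:18"), the reporting convention of the sweep table.
#'
#' @param rows sweep rows (see [chaid_sweep()])
#' @return data frame with columns \code{depth}, \code{family},
#'   \code{costs}, \code{over_pct}, \code{under_pct}
#' @export
collapse_ratio_ranges <- function(rows) {
  out <- NULL
  for (fid in unique(rows$family)) {
    rf <- rows[rows$family == fid, ]
    rf <- rf[order(rf$ratio), ]
    key <- paste(sprintf("%.1f", rf$over_pct), sprintf("%.1f", rf$under_pct))
    run <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
    for (g in unique(run)) {
      rg <- rf[run == g, ]
      costs <- if (nrow(rg) == 1L) sprintf("1:%d", rg$ratio[1]) else
        sprintf("1:%d to 1:%d", min(rg$ratio), max(rg$ratio))
      out <- rbind(out, data.frame(
        depth = rg$depth[1], family = fid, costs = costs,
        over_pct = round(rg$over_pct[1], 1),
        under_pct = round(rg$under_pct[1], 1), stringsAsFactors = FALSE))
    }
  }
  out
}

#' Run the full family sweep and select a model
#'
#' Grows and sweeps every family (A–E by default), assembles the combined
#' report table and the over-vs-under scatter data, and applies the
#' benchmark selection rule.
#'
#' @inheritParams chaid_sweep
#' @param families list of \code{model_family} (default
#'   \code{model_families(data$schema)})
#' @param criteria an \code{acs_cot_criteria}
#' @return list with \code{results} (named list of \code{sweep_result}),
#'   \code{report} (collapsed table), \code{scatter} (one point per
#'   family/ratio: \code{family}, \code{ratio}, \code{over_pct},
#'   \code{under_pct}), \code{selection} (see [select_model()])
#' @export
run_all_families <- function(data, config = chaid_config(),
                             families = NULL,
                             criteria = acs_cot_criteria(),
                             max_ratio = 100L) {
  .assert_growable(data)
  if (is.null(families)) families <- model_families(data$schema)
  results <- lapply(families, chaid_sweep, data = data, config = config,
                    max_ratio = max_ratio)
  all_rows <- do.call(rbind, lapply(results, `[[`, "rows"))
  rownames(all_rows) <- NULL
  selection <- select_model(all_rows, criteria)
  list(results = results,
       report = collapse_ratio_ranges(all_rows),
       scatter = all_rows[, c("family", "ratio", "over_pct", "under_pct")],
       selection = selection)
}
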