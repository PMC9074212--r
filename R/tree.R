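#' CHAID growth configuration
#'
#' Controls tree growth: significance levels for the merge and split tests,
#' depth limit, node-size floors, the optional forced first split variable
#' (used to pin the MPDS dispatch code at the root, mirroring dispatch
#' practice), and the candidate variable list.
#'
#' @param alpha_merge significance level for category merging (default 0.05)
#' @param alpha_split significance level a Bonferroni-adjusted split p-value
#'   must reach (default 0.05)
#' @param max_depth maximum tree depth (root = depth 0); \code{Inf} for
#'   unlimited
#' @param min_parent minimum node size to attempt a split (default 100)
#' @param min_child minimum size of every child a split would create
#'   (default 50)
#' @param forced_first_variable variable name forced as the root split, or
#'   \code{NULL}
#' @param candidate_variables variables the tree may split on, in tie-break
#'   order; \code{NULL} means every schema variable in declared order
#' @return an object of class \code{chaid_config}
#' @export
chaid_config <- function(alpha_merge = 0.05, alpha_split = 0.05,
                         max_depth = Inf, min_parent = 100L, min_child = 50L,
                         forced_first_variable = NULL,
                         candidate_variables = NULL) {
  stopifnot(alpha_merge > 0, alpha_merge <= 1, alpha_split > 0,
            alpha_split <= 1, max_depth >= 1, min_parent >= 1,
            min_child >= 1, min_child <= min_parent)
  structure(list(alpha_merge = alpha_merge, alpha_split = alpha_split,
                 max_depth = max_depth, min_parent = as.integer(min_parent),
                 min_child = as.integer(min_child),
                 forced_first_variable = forced_first_variable,
                 candidate_variables = candidate_variables),
            class = "chaid_config")
}

#' @export
print.chaid_config <- function(x, ...) {
  cat("<chaid_config> alpha_merge =", x$alpha_merge,
      "| alpha_split =", x$alpha_split,
      "| max_depth =", x$max_depth,
      "| min_parent =", x$min_parent, "| min_child =", x$min_child, "\n")
  if (!is.null(x$forced_first_variable))
    cat("  forced first split:", x$forced_first_variable, "\n")
  invisible(x)
}

# Per-variable integer encodings of the records, computed once per growth.
# Category index space: declared categories in order, missing label last.
.encode_dataset <- function(data, vars) {
  schema <- data$schema
  enc <- list()
  for (v in vars) {
    levels <- c(schema[[v]]$categories, MISSING_LABEL)
    code <- match(data$records[[v]], levels)
    if (anyNA(code))
      stop("record value outside declared categories for '", v, "'")
    enc[[v]] <- list(code = code, levels = levels,
                     kind = schema[[v]]$kind)
  }
  enc
}

# category x outcome counts at a node, observed categories only
.node_var_counts <- function(enc_v, idx, y) {
  nl <- length(enc_v$levels)
  code <- enc_v$code[idx]
  cnt <- tabulate(code + nl * y[idx], nbins = 2L * nl)
  m <- cbind(cnt[seq_len(nl)], cnt[nl + seq_len(nl)])
  rownames(m) <- enc_v$levels
  m[rowSums(m) > 0L, , drop = FALSE]
}

#' Find the best Bonferroni-adjusted split at a node
#'
#' For each candidate variable, merge its observed categories at the node
#' (see [merge_categories()]), test the merged r x 2 table with the Pearson
#' chi-square, and multiply the raw p-value by the Bonferroni multiplier for
#' the number of ways the categories could have been grouped. The candidate
#' with the smallest adjusted p-value is returned provided it is significant
#' at \code{alpha_split} and every child it creates holds at least
#' \code{min_child} records; otherwise \code{NULL} (the node stays a leaf).
#' Ties on the adjusted p-value go to the earlier variable in candidate
#' order.
#'
#' @param data a labelled \code{mvc_dataset}
#' @param idx integer row indices defining the node
#' @param config a \code{chaid_config}
#' @param variables candidate variable names for this node
#' @return \code{NULL}, or a list with \code{variable}, \code{groups},
#'   \code{statistic}, \code{df}, \code{raw_p}, \code{bonferroni},
#'   \code{adjusted_p}, \code{child_sizes}
#' @export
best_split <- function(data, idx, config, variables = NULL) {
  .assert_growable(data)
  if (is.null(variables))
    variables <- config$candidate_variables %||% names(data$schema)
  enc <- .encode_dataset(data, variables)
  y <- data$records$label
  .best_split_encoded(enc, y, idx, config, variables)
}

.best_split_encoded <- function(enc, y, idx, config, variables) {
  best <- NULL
  for (v in variables) {
    m <- .node_var_counts(enc[[v]], idx, y)
    if (nrow(m) < 2L) next
    kind <- enc[[v]]$kind
    groups <- merge_categories(m, kind, config$alpha_merge,
                               min_size = config$min_child)
    r <- length(groups)
    if (r < 2L) next
    gm <- t(vapply(groups, function(g)
      colSums(m[g, , drop = FALSE]), numeric(2)))
    ct <- pearson_chi_square(gm)
    B <- bonferroni_multiplier(nrow(m), r,
                               if (kind == "ordinal") "ordinal" else "nominal")
    adj <- min(1, B * ct$p_value)
    if (is.null(best) || adj < best$adjusted_p - 1e-12) {
      best <- list(variable = v, groups = groups, statistic = ct$statistic,
                   df = ct$df, raw_p = ct$p_value, bonferroni = B,
                   adjusted_p = adj, child_sizes = as.integer(rowSums(gm)))
    }
  }
  if (is.null(best)) return(NULL)
  if (best$adjusted_p > config$alpha_split) return(NULL)
  if (any(best$child_sizes < config$min_child)) return(NULL)
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grow a CHAID dispatch decision tree
#'
#' Recursive multi-way partitioning of a labelled crash dataset: at each
#' node large enough to split (\code{min_parent}) and above the depth limit,
#' the best Bonferroni-adjusted chi-square split (see [best_split()]) is
#' applied; children are created per merged category group. When
#' \code{forced_first_variable} is set it is the only candidate at the root,
#' reflecting a dispatch system that always has the MPDS code first.
#' Misclassification costs play no role in growth — they enter at
#' classification time — so one grown tree serves a whole cost-ratio sweep.
#'
#' @param data a labelled \code{mvc_dataset} with no unbinned continuous
#'   variables
#' @param config a \code{chaid_config}
#' @return an object of class \code{chaid_tree}
#' @export
chaid_grow <- function(data, config = chaid_config()) {
  .assert_growable(data)
  vars <- config$candidate_variables %||% names(data$schema)
  unknown <- setdiff(vars, names(data$schema))
  if (length(unknown))
    stop("candidate variable(s) not in schema: ",
         paste(unknown, collapse = ", "))
  if (!is.null(config$forced_first_variable) &&
      !(config$forced_first_variable %in% vars))
    stop("forced first variable '", config$forced_first_variable,
         "' is not a candidate variable")
  enc <- .encode_dataset(data, vars)
  y <- data$records$label
  n <- length(y)

  nodes <- list()
  new_node <- function(parent, depth, idx) {
    id <- length(nodes) + 1L
    cnt <- c(sum(y[idx] == 0L), sum(y[idx] == 1L))
    nodes[[id]] <<- list(id = id, parent = parent, depth = depth,
                         counts = cnt, size = length(idx),
                         p_hat = cnt[2] / sum(cnt),
                         is_leaf = TRUE, split = NULL, children = integer())
    id
  }
  root <- new_node(0L, 0L, seq_len(n))
  queue <- list(list(id = root, idx = seq_len(n)))
  while (length(queue)) {
    item <- queue[[1]]; queue <- queue[-1]
    nd <- nodes[[item$id]]
    if (nd$size < config$min_parent || nd$depth >= config$max_depth) next
    if (nd$counts[1] == 0L || nd$counts[2] == 0L) next   # pure node
    cand <- if (nd$depth == 0L && !is.null(config$forced_first_variable))
      config$forced_first_variable else vars
    sp <- .best_split_encoded(enc, y, item$idx, config, cand)
    if (is.null(sp)) next
    enc_v <- enc[[sp$variable]]
    glab <- vapply(sp$groups, function(g) paste(g, collapse = "; "),
                   character(1))
    code <- enc_v$code[item$idx]
    group_of_level <- integer(length(enc_v$levels))
    for (k in seq_along(sp$groups))
      group_of_level[match(sp$groups[[k]], enc_v$levels)] <- k
    assignment <- group_of_level[code]
    kids <- integer(length(sp$groups))
    for (k in seq_along(sp$groups)) {
      child_idx <- item$idx[assignment == k]
      kids[k] <- new_node(item$id, nd$depth + 1L, child_idx)
      queue[[length(queue) + 1L]] <- list(id = kids[k], idx = child_idx)
    }
    nodes[[item$id]]$is_leaf <- FALSE
    nodes[[item$id]]$split <- sp[c("variable", "groups", "statistic", "df",
                                   "raw_p", "bonferroni", "adjusted_p")]
    nodes[[item$id]]$children <- kids
    nodes[[item$id]]$group_labels <- glab
  }
  structure(list(nodes = nodes, config = config,
                 variables = vars, n_train = n),
            class = "chaid_tree")
}

#' @export
print.chaid_tree <- function(x, max_nodes = 50L, ...) {
  nl <- vapply(x$nodes, `[[`, logical(1), "is_leaf")
  cat("<chaid_tree> ", length(x$nodes), " nodes (", sum(nl),
      " terminal), depth ", tree_depth(x), ", trained on ", x$n_train,
      " records\n", sep = "")
  shown <- 0L
  for (nd in x$nodes) {
    if (shown >= max_nodes) { cat("  ...\n"); break }
    pad <- strrep("  ", nd$depth + 1L)
    edge <- ""
    if (nd$parent > 0L) {
      par <- x$nodes[[nd$parent]]
      edge <- paste0("[", par$split$variable, " in {",
                     par$group_labels[match(nd$id, par$children)], "}] ")
    }
    cat(pad, edge, "node ", nd$id, ": n=", nd$size,
        sprintf(" p(L&S)=%.3f", nd$p_hat),
        if (!nd$is_leaf)
          sprintf("  split %s (adj p=%.3g)", nd$split$variable,
                  nd$split$adjusted_p),
        "\n", sep = "")
    shown <- shown + 1L
  }
  invisible(x)
}

#' Tree size helpers
#'
#' @param tree a \code{chaid_tree}
#' @return \code{tree_depth}: maximum node depth; \code{n_nodes}: total node
#'   count; \code{n_leaves}: terminal node count
#' @export
tree_depth <- function(tree) max(vapply(tree$nodes, `[[`, integer(1), "depth"))

#' @rdname tree_depth
#' @export
n_nodes <- function(tree) length(tree$nodes)

#' @rdname tree_depth
#' @export
n_leaves <- function(tree)
  sum(vapply(tree$nodes, `[[`, logical(1), "is_leaf"))
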