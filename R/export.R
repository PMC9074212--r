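#' Serialise a CHAID tree
#'
#' \code{tree_to_json} writes a lossless JSON document (node ids, depths,
#' class counts, split variables, merged category groups) from which
#' \code{tree_from_json} rebuilds a tree that classifies identically.
#' \code{tree_to_dot} renders the tree in Graphviz DOT, one box per node
#' with its class counts and L&S proportion, edges labelled by merged
#' category group.
#'
#' @param tree a \code{chaid_tree}
#' @param path output file path, or \code{NULL} to return the text
#' @return the file path (invisibly) or, with \code{path = NULL}, the
#'   serialised text
#' @export
tree_to_json <- function(tree, path = NULL) {
  nodes <- lapply(tree$nodes, function(nd) {
    out <- list(id = nd$id, parent = nd$parent, depth = nd$depth,
                counts = as.integer(nd$counts), is_leaf = nd$is_leaf)
    if (!nd$is_leaf) {
      out$split <- list(variable = nd$split$variable,
                        groups = nd$split$groups,
                        statistic = nd$split$statistic, df = nd$split$df,
                        raw_p = nd$split$raw_p,
                        bonferroni = nd$split$bonferroni,
                        adjusted_p = nd$split$adjusted_p)
      out$children <- nd$children
    }
    out
  })
  doc <- list(format = "chaid_tree", version = 1L,
              n_train = tree$n_train, variables = tree$variables,
              config = unclass(tree$config), nodes = nodes)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname tree_to_json
#' @param x JSON text or a file path produced by \code{tree_to_json}
#' @export
tree_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (!identical(doc$format, "chaid_tree"))
    stop("not a chaid_tree JSON document")
  cfg <- doc$config
  cfg$max_depth <- cfg$max_depth %||% Inf
  if (is.character(cfg$max_depth)) cfg$max_depth <- Inf  # "Inf" round-trip
  config <- chaid_config(cfg$alpha_merge, cfg$alpha_split, cfg$max_depth,
                         cfg$min_parent, cfg$min_child,
                         cfg$forced_first_variable,
                         if (!is.null(cfg$candidate_variables))
                           unlist(cfg$candidate_variables))
  nodes <- lapply(doc$nodes, function(nd) {
    cnt <- as.integer(unlist(nd$counts))
    out <- list(id = nd$id, parent = nd$parent, depth = nd$depth,
                counts = cnt, size = sum(cnt),
                p_hat = cnt[2] / sum(cnt),
                is_leaf = isTRUE(nd$is_leaf),
                split = NULL, children = integer())
    if (!out$is_leaf) {
      out$split <- list(variable = nd$split$variable,
                        groups = lapply(nd$split$groups,
                                        function(g) unlist(g)),
                        statistic = nd$split$statistic, df = nd$split$df,
                        raw_p = nd$split$raw_p,
                        bonferroni = nd$split$bonferroni,
                        adjusted_p = nd$split$adjusted_p)
      out$children <- as.integer(unlist(nd$children))
      out$group_labels <- vapply(out$split$groups,
                                 function(g) paste(g, collapse = "; "),
                                 character(1))
    }
    out
  })
  structure(list(nodes = nodes, config = config,
                 variables = unlist(doc$variables),
                 n_train = doc$n_train),
            class = "chaid_tree")
}

#' @rdname tree_to_json
#' @export
tree_to_dot <- function(tree, path = NULL) {
  esc <- function(s) gsub("\"", "\\\\\"", s)
  lines <- c("digraph chaid_tree {", "  node [shape=box, fontsize=10];")
  for (nd in tree$nodes) {
    lab <- sprintf("node %d\\nn=%d (not L&S %d / L&S %d)\\np(L&S)=%.3f",
                   nd$id, nd$size, nd$counts[1], nd$counts[2], nd$p_hat)
    if (!nd$is_leaf)
      lab <- paste0(lab, "\\nsplit: ", esc(nd$split$variable))
    lines <- c(lines, sprintf("  n%d [label=\"%s\"];", nd$id, lab))
    if (!nd$is_leaf)
      for (k in seq_along(nd$children))
        lines <- c(lines, sprintf("  n%d -> n%d [label=\"%s\"];", nd$id,
                                  nd$children[k], esc(nd$group_labels[k])))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Export a grown tree
#'
#' Dispatch wrapper over [tree_to_json()] and [tree_to_dot()].
#'
#' @inheritParams tree_to_json
#' @param format \code{"json"} or \code{"dot"}
#' @export
export_tree <- function(tree, format = c("json", "dot"), path = NULL) {
  format <- match.arg(format)
  switch(format, json = tree_to_json(tree, path),
         dot = tree_to_dot(tree, path))
}
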