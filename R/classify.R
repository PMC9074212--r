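#' Misclassification cost matrix
#'
#' Costs penalise the two dispatch errors asymmetrically: \code{c_fp} is the
#' cost of sending lights-and-sirens when it was not needed (over triage per
#' case) and \code{c_fn} the cost of withholding it when it was needed
#' (under triage per case — the clinically dangerous error). The study's
#' "1:k" ratio notation means \code{c_fp = 1, c_fn = k}.
#'
#' @param c_fp cost of a false positive (> 0)
#' @param c_fn cost of a false negative (> 0)
#' @return an object of class \code{cost_matrix}
#' @export
cost_matrix <- function(c_fp = 1, c_fn = 1) {
  stopifnot(c_fp > 0, c_fn > 0)
  structure(list(c_fp = c_fp, c_fn = c_fn), class = "cost_matrix")
}

#' @rdname cost_matrix
#' @param k the ratio's right-hand side: costs 1:k
#' @export
cost_ratio <- function(k) cost_matrix(1, k)

#' @export
print.cost_matrix <- function(x, ...) {
  cat("<cost_matrix> FP:FN = ", x$c_fp, ":", x$c_fn, "\n", sep = "")
  invisible(x)
}

#' Route records to tree nodes
#'
#' Sends each record down the tree. At an internal node the record follows
#' the child whose merged category group contains its value. A value absent
#' from every group (an unseen category, or a missing value at a node whose
#' groups never saw one) falls back to the missing rule: take the child
#' whose group contains the missing label; if no such child exists the
#' record stops and is classified by the current node's own class
#' distribution.
#'
#' @param tree a \code{chaid_tree}
#' @param data an \code{mvc_dataset} conforming to the training schema
#' @return integer vector of node ids, one per record (usually terminal
#'   nodes; an internal node id marks a stopped record)
#' @export
route_records <- function(tree, data) {
  nrec <- n_records(data)
  assign <- rep.int(1L, nrec)
  settled <- rep.int(FALSE, nrec)
  for (nd in tree$nodes) {
    if (nd$is_leaf) next
    here <- which(assign == nd$id & !settled)
    if (!length(here)) next
    x <- data$records[[nd$split$variable]][here]
    map_cat <- unlist(nd$split$groups, use.names = FALSE)
    map_child <- rep(nd$children, lengths(nd$split$groups))
    child <- map_child[match(x, map_cat)]
    if (anyNA(child)) {
      miss_child <- map_child[match(MISSING_LABEL, map_cat)]
      lost <- is.na(child)
      if (!is.na(miss_child)) {
        child[lost] <- miss_child
      } else {
        settled[here[lost]] <- TRUE
        child[lost] <- nd$id
      }
    }
    assign[here] <- child
  }
  assign
}

#' Cost-sensitive classification with a grown tree
#'
#' Each record is routed to a node (see [route_records()]) and predicted
#' L&S when the expected cost of withholding L&S is at least that of sending
#' it: with node L&S proportion \eqn{\hat p}, predict L&S iff
#' \eqn{\hat p \, c_{fn} \ge (1 - \hat p) \, c_{fp}}. The tie predicts L&S
#' (the safety-first direction). A node that saw no L&S cases in training
#' has \eqn{\hat p = 0} and predicts not-L&S at any finite cost ratio.
#'
#' @inheritParams route_records
#' @param costs a \code{cost_matrix}
#' @param type \code{"label"} (0/1 prediction), \code{"prob"} (node L&S
#'   proportion) or \code{"node"} (assigned node id)
#' @return integer, numeric or integer vector per \code{type}
#' @export
chaid_classify <- function(tree, data, costs = cost_matrix(), type = "label") {
  type <- match.arg(type, c("label", "prob", "node"))
  assign <- route_records(tree, data)
  if (type == "node") return(assign)
  p_hat <- vapply(tree$nodes, `[[`, numeric(1), "p_hat")[assign]
  if (type == "prob") return(p_hat)
  as.integer(p_hat * costs$c_fn >= (1 - p_hat) * costs$c_fp)
}

#' Per-node leaf decision at a given cost matrix
#' @keywords internal
.node_decisions <- function(p_hat, costs) {
  as.integer(p_hat * costs$c_fn >= (1 - p_hat) * costs$c_fp)
}
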