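#' Greedy chi-square merging of predictor categories
#'
#' The CHAID reduction step: starting from one group per observed category,
#' repeatedly find the allowable pair of groups whose 2 x 2 subtable (the two
#' groups against the binary outcome) has the largest raw chi-square p-value
#' and merge it, as long as that p-value exceeds \code{alpha_merge}. Merging
#' stops when every allowable pair is significantly heterogeneous or a single
#' group remains.
#'
#' Allowable pairs: any pair for nominal (and dichotomous) variables;
#' adjacent groups only for ordinals, where each group must remain a
#' contiguous run of the declared category order. A group consisting solely
#' of the missing category "floats" and may pair with any group, ordinal
#' adjacency notwithstanding; once absorbed, the combined group obeys the
#' adjacency of its non-missing members. Ties on the p-value are broken by
#' the first allowable pair in scan order (groups indexed by their leading
#' category), which keeps growth deterministic.
#'
#' After the significance-driven phase, any group holding fewer than
#' \code{min_size} records is folded into its most similar allowable
#' neighbour (again the largest raw p-value), smallest group first, until
#' every group is large enough or one group remains. This keeps rare
#' categories — e.g. dispatch codes seen a handful of times in three years —
#' from vetoing a split through the minimum-child-size rule, the standard
#' small-category handling of CHAID implementations.
#'
#' @param counts integer matrix, one row per observed category (rownames are
#'   the category labels; for ordinals rows must be in category order, with
#'   an optional missing-label row in any position), two outcome columns
#' @param kind \code{"nominal"}, \code{"dichotomous"} or \code{"ordinal"}
#' @param alpha_merge significance level below which groups stay apart
#' @param min_size force-merge groups smaller than this (0 disables)
#' @return list of character vectors: the merged grouping, each group the
#'   categories it contains (ordinal groups in run order)
#' @export
merge_categories <- function(counts, kind, alpha_merge = 0.05,
                             min_size = 0L) {
  counts <- as.matrix(counts)
  cats <- rownames(counts)
  if (is.null(cats)) stop("counts must carry category rownames")
  stopifnot(ncol(counts) == 2L)
  is_missing <- cats == MISSING_LABEL
  ord_pos <- cumsum(!is_missing)        # position among non-missing cats
  groups <- lapply(seq_along(cats), function(i) {
    list(cats = cats[i], counts = counts[i, ],
         lo = if (is_missing[i]) NA_integer_ else ord_pos[i],
         hi = if (is_missing[i]) NA_integer_ else ord_pos[i])
  })
  ordinal <- identical(kind, "ordinal")

  allowable <- function(a, b) {
    if (!ordinal) return(TRUE)
    if (is.na(a$lo) || is.na(b$lo)) return(TRUE)      # floating missing group
    a$hi + 1L == b$lo || b$hi + 1L == a$lo
  }

  repeat {
    if (length(groups) <= 1L) break
    best_p <- -1; best_pair <- NULL
    for (i in seq_len(length(groups) - 1L)) {
      for (j in (i + 1L):length(groups)) {
        if (!allowable(groups[[i]], groups[[j]])) next
        tab <- rbind(groups[[i]]$counts, groups[[j]]$counts)
        p <- pearson_chi_square(tab)$p_value
        if (p > best_p + 1e-12) { best_p <- p; best_pair <- c(i, j) }
      }
    }
    if (is.null(best_pair) || best_p <= alpha_merge) break
    i <- best_pair[1]; j <- best_pair[2]
    a <- groups[[i]]; b <- groups[[j]]
    merged <- list(
      cats = c(a$cats, b$cats),
      counts = a$counts + b$counts,
      lo = suppressWarnings(min(a$lo, b$lo, na.rm = TRUE)),
      hi = suppressWarnings(max(a$hi, b$hi, na.rm = TRUE)))
    if (is.infinite(merged$lo)) { merged$lo <- NA_integer_; merged$hi <- NA_integer_ }
    groups[[i]] <- merged
    groups[[j]] <- NULL
  }

  # fold undersized groups into their most similar allowable neighbour
  merge_pair <- function(i, j) {
    a <- groups[[i]]; b <- groups[[j]]
    merged <- list(
      cats = c(a$cats, b$cats),
      counts = a$counts + b$counts,
      lo = suppressWarnings(min(a$lo, b$lo, na.rm = TRUE)),
      hi = suppressWarnings(max(a$hi, b$hi, na.rm = TRUE)))
    if (is.infinite(merged$lo)) { merged$lo <- NA_integer_; merged$hi <- NA_integer_ }
    groups[[i]] <<- merged
    groups[[j]] <<- NULL
  }
  if (min_size > 0L) {
    repeat {
      if (length(groups) <= 1L) break
      sizes <- vapply(groups, function(g) sum(g$counts), numeric(1))
      small <- which(sizes < min_size)
      if (!length(small)) break
      i <- small[which.min(sizes[small])]
      best_p <- -1; best_j <- NA_integer_
      for (j in seq_along(groups)) {
        if (j == i || !allowable(groups[[i]], groups[[j]])) next
        p <- pearson_chi_square(rbind(groups[[i]]$counts,
                                      groups[[j]]$counts))$p_value
        if (p > best_p + 1e-12) { best_p <- p; best_j <- j }
      }
      if (is.na(best_j)) break    # isolated group (cannot happen for r > 1)
      merge_pair(min(i, best_j), max(i, best_j))
    }
  }
  lapply(groups, `[[`, "cats")
}
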