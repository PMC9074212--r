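#' Pearson chi-square test of independence for an r x 2 table
#'
#' The association measure driving CHAID: the Pearson statistic
#' \eqn{X^2 = \sum (O - E)^2 / E} over cells with positive expected count,
#' with \eqn{df = (r - 1)} for an \eqn{r \times 2} table, and the upper-tail
#' chi-square probability. A table whose outcome column is all zero (or with
#' a single row) carries no association: statistic 0, p-value 1.
#'
#' @param counts numeric matrix with r rows and 2 columns
#'   (column 1 = not-L&S, column 2 = L&S), non-negative, grand total > 0
#' @return list with \code{statistic}, \code{df}, \code{p_value}
#' @export
#' @examples
#' pearson_chi_square(rbind(c(30, 10), c(10, 30)))  # X^2 = 20, df = 1
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L || nrow(counts) < 1L)
    stop("empty contingency table")
  if (ncol(counts) != 2L) stop("table must have exactly 2 outcome columns")
  if (any(counts < 0)) stop("negative counts")
  n <- sum(counts)
  if (n <= 0) stop("contingency table has grand total 0")
  rs <- rowSums(counts)
  cs <- colSums(counts)
  df <- (nrow(counts) - 1L) * 1L
  if (df == 0L || any(cs == 0))
    return(list(statistic = 0, df = max(df, 0L), p_value = 1))
  expected <- outer(rs, cs) / n
  ok <- expected > 0
  stat <- sum((counts[ok] - expected[ok])^2 / expected[ok])
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Bonferroni multiplier for a merged grouping
#'
#' CHAID adjusts each candidate split's p-value for the number of ways the
#' variable's \code{c} observed categories could have been reduced to
#' \code{r} groups. For a nominal (free) variable this is the Stirling number
#' of the second kind \eqn{S(c, r)}; for an ordinal variable, where groups
#' must be contiguous runs, it is \eqn{\binom{c-1}{r-1}}.
#'
#' @param c number of observed categories (>= 1)
#' @param r number of merged groups, \code{1 <= r <= c}
#' @param kind \code{"nominal"} or \code{"ordinal"} (a dichotomous variable
#'   is nominal with c = 2)
#' @return the multiplier B (>= 1)
#' @export
#' @examples
#' bonferroni_multiplier(3, 2, "nominal")  # S(3,2) = 3
#' bonferroni_multiplier(4, 2, "ordinal")  # choose(3,1) = 3
bonferroni_multiplier <- function(c, r, kind = c("nominal", "ordinal")) {
  kind <- match.arg(kind)
  c <- as.integer(c); r <- as.integer(r)
  if (r < 1L || c < 1L) stop("c and r must be positive")
  if (r > c) stop("cannot partition ", c, " categories into ", r, " groups")
  if (kind == "ordinal") return(choose(c - 1L, r - 1L))
  # Stirling number of the second kind, S(c, r)
  i <- 0:(r - 1L)
  B <- sum((-1)^i * (r - i)^c / (factorial(i) * factorial(r - i)))
  max(1, round(B))
}
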