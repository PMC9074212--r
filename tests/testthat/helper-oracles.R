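# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: partitions are enumerated by brute force and
# p-values come from stats::chisq.test.

# Count set partitions of n items into exactly r non-empty blocks by
# exhaustive enumeration (restricted-growth strings).
count_set_partitions <- function(n, r) {
  count <- 0L
  recurse <- function(i, assignment, nblocks) {
    if (i > n) {
      if (nblocks == r) count <<- count + 1L
      return(invisible())
    }
    for (b in seq_len(nblocks + 1L)) {
      assignment[i] <- b
      recurse(i + 1L, assignment, max(nblocks, b))
    }
  }
  recurse(1L, integer(n), 0L)
  count
}

# Count partitions of an ordered sequence of n items into r contiguous runs
# by enumerating cut-point subsets.
count_contiguous_partitions <- function(n, r) {
  if (r == 1L) return(1L)
  if (n == 1L) return(0L)
  nrow(t(utils::combn(n - 1L, r - 1L)))
}

# Step-by-step re-execution of the documented greedy merge rule for a
# nominal variable, coded independently (chisq.test p-values, plain lists).
oracle_merge_nominal <- function(counts, alpha) {
  groups <- lapply(seq_len(nrow(counts)), function(i)
    list(cats = rownames(counts)[i], counts = counts[i, ]))
  repeat {
    if (length(groups) <= 1L) break
    best <- list(p = -1)
    for (i in seq_len(length(groups) - 1L)) {
      for (j in (i + 1L):length(groups)) {
        tab <- rbind(groups[[i]]$counts, groups[[j]]$counts)
        p <- if (any(colSums(tab) == 0)) 1 else
          suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
        if (is.na(p)) p <- 1
        if (p > best$p + 1e-12) best <- list(p = p, i = i, j = j)
      }
    }
    if (best$p <= alpha) break
    groups[[best$i]] <- list(
      cats = c(groups[[best$i]]$cats, groups[[best$j]]$cats),
      counts = groups[[best$i]]$counts + groups[[best$j]]$counts)
    groups[[best$j]] <- NULL
  }
  lapply(groups, `[[`, "cats")
}

# Canonical form of a grouping for order-free comparison.
canonical_grouping <- function(groups) {
  sorted <- lapply(groups, sort)
  sorted[order(vapply(sorted, `[`, character(1), 1L))]
}

# A small labelled dataset over a toy schema, for unit tests.
toy_schema <- function() {
  mvc_schema(
    variable_spec("mpds_code", "nominal", c("29B1", "29B4", "29D2", "29D4")),
    variable_spec("trapped", "dichotomous", c("yes", "no")),
    variable_spec("speed", "ordinal", c("50", "60", "70"))
  )
}

toy_dataset <- function(n = 400L, seed = 42L) {
  withr::with_seed(seed, {
    code <- sample(c("29B1", "29B4", "29D2", "29D4"), n, replace = TRUE,
                   prob = c(0.4, 0.3, 0.2, 0.1))
    trapped <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.2, 0.8))
    speed <- sample(c("50", "60", "70"), n, replace = TRUE)
    p <- ifelse(trapped == "yes", 0.7, 0.1) +
      ifelse(code %in% c("29D2", "29D4"), 0.15, 0)
    label <- stats::rbinom(n, 1L, pmin(p, 1))
  })
  mvc_dataset(data.frame(mpds_code = code, trapped = trapped, speed = speed,
                         label = label, stringsAsFactors = FALSE),
              toy_schema())
}
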