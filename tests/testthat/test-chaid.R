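test_that("Pearson chi-square matches hand-derived values and conventions", {
  r <- pearson_chi_square(rbind(c(10, 10), c(10, 10)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- pearson_chi_square(rbind(c(30, 10), c(10, 30)))  # expecteds all 20
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1L)
  expect_equal(r$p_value, stats::pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # degenerate inputs
  expect_equal(pearson_chi_square(rbind(c(5, 0), c(9, 0)))$p_value, 1)
  expect_equal(pearson_chi_square(matrix(c(3, 4), 1))$statistic, 0)
  expect_error(pearson_chi_square(matrix(numeric(), 0, 2)), "empty")
})

test_that("chi-square p-values agree with the independent routine on random tables", {
  withr::with_seed(101, {
    for (i in 1:200) {
      r <- sample(2:6, 1)
      tab <- matrix(rpois(2 * r, lambda = sample(c(3, 20, 80), 1)), r, 2)
      tab[1, ] <- tab[1, ] + 1   # keep the grand total positive
      # the grower only ever tests observed categories
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      if (nrow(tab) < 2) next
      mine <- pearson_chi_square(tab)
      if (any(colSums(tab) == 0)) {
        expect_equal(mine$p_value, 1)
        next
      }
      ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)
    }
  })
})

test_that("Bonferroni multipliers equal brute-force partition counts", {
  expect_equal(bonferroni_multiplier(3, 2, "nominal"), 3)   # S(3,2)
  expect_equal(bonferroni_multiplier(4, 2, "ordinal"), 3)   # C(3,1)
  expect_equal(bonferroni_multiplier(5, 3, "nominal"), 25)  # S(5,3)
  for (c in 1:7) {
    for (r in 1:c) {
      expect_equal(bonferroni_multiplier(c, r, "nominal"),
                   count_set_partitions(c, r),
                   info = sprintf("nominal c=%d r=%d", c, r))
      expect_equal(bonferroni_multiplier(c, r, "ordinal"),
                   count_contiguous_partitions(c, r),
                   info = sprintf("ordinal c=%d r=%d", c, r))
    }
  }
  expect_error(bonferroni_multiplier(3, 4, "nominal"), "partition")
})

test_that("categories with identical outcome proportions merge", {
  m <- rbind(a = c(50, 10), b = c(100, 20), c = c(10, 40))
  g <- merge_categories(m, "nominal", 0.05)
  g <- canonical_grouping(g)
  expect_length(g, 2L)
  expect_true(any(vapply(g, function(x) setequal(x, c("a", "b")), logical(1))))
})

test_that("ordinal merging respects adjacency; the missing category floats", {
  # 50 and 70 share a profile but 60 differs: without adjacency they would
  # merge; with it, they cannot pair directly
  m <- rbind("50" = c(50, 50), "60" = c(95, 5), "70" = c(50, 50))
  g <- canonical_grouping(merge_categories(m, "ordinal", 0.05))
  expect_false(any(vapply(g, function(x)
    setequal(x, c("50", "70")), logical(1))))
  # a missing-only group may join a non-adjacent partner
  m2 <- rbind("50" = c(50, 50), "60" = c(95, 5), "70" = c(90, 10))
  m2 <- rbind(m2, "__missing__" = c(49, 51))
  g2 <- canonical_grouping(merge_categories(m2, "ordinal", 0.05))
  has_float <- vapply(g2, function(x)
    ("__missing__" %in% x) && ("50" %in% x), logical(1))
  expect_true(any(has_float))
})

test_that("greedy merging reproduces an independent step-by-step oracle", {
  withr::with_seed(202, {
    for (i in 1:30) {
      r <- sample(3:6, 1)
      m <- matrix(rpois(2 * r, 25) + 1, r, 2)
      rownames(m) <- letters[seq_len(r)]
      mine <- canonical_grouping(merge_categories(m, "nominal", 0.05))
      ref <- canonical_grouping(oracle_merge_nominal(m, 0.05))
      expect_identical(mine, ref, info = paste("table", i))
    }
  })
})

test_that("undersized groups are folded into their most similar neighbour", {
  # category 'tiny' is significantly different but far below min_size
  m <- rbind(a = c(500, 50), b = c(480, 60), tiny = c(2, 8))
  g <- merge_categories(m, "nominal", 0.05, min_size = 50)
  expect_true(all(vapply(g, function(x)
    sum(m[x, ]) >= 50, logical(1))))
  expect_length(unlist(g), 3L)
})

test_that("best_split prefers the smaller adjusted p-value and honours guards", {
  d <- toy_dataset(600)
  cfg <- chaid_config(min_parent = 20, min_child = 10)
  sp <- best_split(d, seq_len(n_records(d)), cfg)
  expect_equal(sp$variable, "trapped")   # the strong planted effect
  expect_gte(sp$adjusted_p, sp$raw_p)
  expect_lte(sp$adjusted_p, 0.05)
  # pure node: no variable can split
  pure <- d
  pure$records$label <- 1L
  expect_null(best_split(pure, seq_len(n_records(d)), cfg))
  # forced variable restricts the candidate set
  spf <- best_split(d, seq_len(n_records(d)), cfg, variables = "mpds_code")
  expect_equal(spf$variable, "mpds_code")
})

test_that("growth conserves counts, respects depth limits and is deterministic", {
  d <- toy_dataset(800)
  cfg <- chaid_config(min_parent = 40, min_child = 15, max_depth = 2)
  tr <- chaid_grow(d, cfg)
  expect_lte(tree_depth(tr), 2L)
  for (nd in tr$nodes) {
    expect_gte(nd$split$adjusted_p %||% 1, nd$split$raw_p %||% 0)
    if (!nd$is_leaf) {
      kid_counts <- Reduce(`+`, lapply(tr$nodes[nd$children], `[[`, "counts"))
      expect_equal(kid_counts, nd$counts)
    }
  }
  tr2 <- chaid_grow(d, cfg)
  expect_identical(tree_to_json(tr), tree_to_json(tr2))
  # pure-outcome data grows a single node
  d$records$label <- 0L
  expect_equal(n_nodes(chaid_grow(d, cfg)), 1L)
})

test_that("unlabelled data cannot be grown", {
  d <- toy_dataset(100)
  d$records$label <- NULL
  expect_error(chaid_grow(d), "labelled")
})

test_that("cost-sensitive leaf decisions follow the expected-cost threshold", {
  leaf_tree <- function(n0, n1) {
    d <- mvc_dataset(data.frame(
      mpds_code = "29B1", trapped = "no", speed = "50",
      label = rep(c(0L, 1L), c(n0, n1)), stringsAsFactors = FALSE),
      toy_schema())
    list(tree = chaid_grow(d, chaid_config(alpha_split = 1e-9)), data = d)
  }
  # p = 0.10 at 1:21 -> dispatch L&S (2.1 > 0.9)
  lt <- leaf_tree(90, 10)
  expect_equal(unique(chaid_classify(lt$tree, lt$data, cost_ratio(21))), 1L)
  # p = 0.04 at 1:21 -> do not (0.84 < 0.96)
  lt <- leaf_tree(96, 4)
  expect_equal(unique(chaid_classify(lt$tree, lt$data, cost_ratio(21))), 0L)
  # p = 1/22 at 1:21 is the exact tie -> safety-first L&S
  lt <- leaf_tree(21, 1)
  expect_equal(unique(chaid_classify(lt$tree, lt$data, cost_ratio(21))), 1L)
  # a zero-L&S node predicts not-L&S at any finite ratio
  lt <- leaf_tree(50, 0)
  expect_equal(unique(chaid_classify(lt$tree, lt$data, cost_ratio(1000))), 0L)
})

test_that("raising the cost ratio never shrinks the positive leaf set", {
  d <- toy_dataset(900, seed = 77)
  tr <- chaid_grow(d, chaid_config(min_parent = 40, min_child = 15))
  prev <- rep(FALSE, n_records(d))
  for (k in c(1, 2, 5, 10, 50)) {
    pos <- chaid_classify(tr, d, cost_ratio(k)) == 1L
    expect_true(all(pos[prev]))
    prev <- pos
  }
})

test_that("JSON export round-trips to identical predictions; DOT renders nodes", {
  d <- toy_dataset(500, seed = 5)
  tr <- chaid_grow(d, chaid_config(min_parent = 30, min_child = 10))
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tr, path)
  tr2 <- tree_from_json(path)
  probe <- toy_dataset(100, seed = 6)
  for (k in c(1, 7, 30))
    expect_identical(chaid_classify(tr, probe, cost_ratio(k)),
                     chaid_classify(tr2, probe, cost_ratio(k)))
  dot <- tree_to_dot(tr)
  expect_equal(length(gregexpr("label=\"node", dot)[[1]]), n_nodes(tr))
  # a single-node tree renders one DOT node and no edges
  d1 <- d; d1$records$label <- 0L
  dot1 <- tree_to_dot(chaid_grow(d1))
  expect_false(grepl("->", dot1))
  expect_error(export_tree(tr, "svg"), "arg")
})

test_that("routing falls back to the missing rule for unseen categories", {
  d <- toy_dataset(600, seed = 8)
  tr <- chaid_grow(d, chaid_config(min_parent = 30, min_child = 10))
  probe <- toy_dataset(50, seed = 9)
  probe$records$trapped <- MISSING_LABEL   # unseen at the trapped split
  ids <- route_records(tr, probe)
  expect_true(all(ids %in% seq_len(n_nodes(tr))))
  p <- chaid_classify(tr, probe, type = "prob")
  expect_true(all(p >= 0 & p <= 1))
})
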