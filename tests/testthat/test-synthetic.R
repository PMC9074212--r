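test_that("the fixture-faithful cohort reproduces the dispatch-code joint counts", {
  d <- sample_fixture_faithful(seed = 13)
  expect_equal(n_records(d), 11971L)
  expect_equal(sum(d$records$label == 1L), 1771L)
  expect_equal(sum(d$records$label == 0L), 10200L)
  expect_equal(sum(d$records$mpds_code == "29D2p"), 444L)
  joint <- table(d$records$mpds_code, d$records$label)
  fx <- load_table2_fixture()$rows
  expect_equal(as.integer(joint[fx$category, "0"]), fx$not_ls)
  expect_equal(as.integer(joint[fx$category, "1"]), fx$ls)
})

test_that("fixture-faithful generation is seed-deterministic, order aside", {
  a <- sample_fixture_faithful(seed = 5)
  b <- sample_fixture_faithful(seed = 5)
  expect_identical(a$records, b$records)
  c <- sample_fixture_faithful(seed = 6)
  expect_false(identical(a$records, c$records))
  # joint counts never depend on the seed
  expect_equal(table(c$records$mpds_code, c$records$label),
               table(a$records$mpds_code, a$records$label))
})

test_that("characteristic draws follow the per-class marginals with their deficits", {
  d <- sample_fixture_faithful(seed = 17)
  rec <- d$records
  t3 <- load_table3_fixture()$rows
  # rollover among not-L&S records: expected 9823/10200 'No vehicle rolled'
  p_exp <- 9823 / 10200
  n0 <- sum(rec$label == 0L)
  p_obs <- mean(rec$rollover[rec$label == 0L] == "No vehicle rolled")
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n0))
  # accident type missingness approximates the block deficit (~33%)
  miss_exp <- 1 - 7982 / 11971
  miss_obs <- mean(rec$accident_type == MISSING_LABEL)
  expect_lt(abs(miss_obs - miss_exp), 0.02)
})

test_that("planted leaves generate outcomes at their probabilities", {
  spec <- default_planted_spec()
  cfg <- generator_config(n = 100000L, seed = 29, mode = "planted_tree")
  d <- sample_planted(spec, cfg)
  rec <- d$records
  leaf_rate <- function(sel, p) {
    n <- sum(sel)
    expect_lt(abs(mean(rec$label[sel]) - p), 3 * sqrt(p * (1 - p) / n))
  }
  trapped <- rec$anyone_trapped == "Anyone trapped"
  bad_air <- rec$atmosphere %in% c("Raining", "Fog/Mist", "Fog/smoke/dust",
                                   "Dust/Smoke")
  rolled <- rec$rollover == "Any vehicle rolled"
  leaf_rate(trapped & bad_air, 0.85)
  leaf_rate(trapped & !bad_air, 0.45)
  leaf_rate(!trapped & rolled, 0.40)
  leaf_rate(!trapped & !rolled, 0.05)
  # feature marginal within 1% of the reference share
  p_roll <- 377 / 10200
  expect_lt(abs(mean(rolled) - p_roll), 0.01)
  # degenerate probabilities make labels a deterministic feature function
  det <- planted_node("rollover", list(
    list(categories = c("Any vehicle rolled", MISSING_LABEL),
         child = planted_leaf(1)),
    list(categories = "No vehicle rolled", child = planted_leaf(0))))
  dd <- sample_planted(det, generator_config(n = 2000L, seed = 31,
                                             mode = "planted_tree"))
  expect_identical(dd$records$label,
                   as.integer(dd$records$rollover != "No vehicle rolled"))
})

test_that("planted specs must partition the variable's categories", {
  bad <- planted_node("rollover", list(
    list(categories = "Any vehicle rolled", child = planted_leaf(1)),
    list(categories = "No vehicle rolled", child = planted_leaf(0))))
  expect_error(sample_planted(bad, generator_config(n = 10, seed = 1,
                                                    mode = "planted_tree")),
               "partition")
  ghost <- planted_node("not_a_variable", list(
    list(categories = "x", child = planted_leaf(1)),
    list(categories = "y", child = planted_leaf(0))))
  expect_error(sample_planted(ghost, generator_config(n = 10, seed = 1,
                                                      mode = "planted_tree")),
               "unknown variable")
})

test_that("apply_missingness blanks features at the configured rates only", {
  d <- toy_dataset(4000, seed = 37)
  same <- apply_missingness(d, c(trapped = 0), seed = 1)
  expect_identical(same$records, d$records)
  all_miss <- apply_missingness(d, c(trapped = 1), seed = 1)
  expect_true(all(all_miss$records$trapped == MISSING_LABEL))
  expect_identical(all_miss$records$label, d$records$label)
  part <- apply_missingness(d, c(speed = 0.3), seed = 2)
  obs <- mean(part$records$speed == MISSING_LABEL)
  expect_lt(abs(obs - 0.3), 3 * sqrt(0.3 * 0.7 / 4000))
})

test_that("the null generator carries no feature-outcome association", {
  d <- sample_marginal_independent(generator_config(n = 30000L, seed = 41,
                                                    mode = "marginal_independent"))
  expect_lt(abs(mean(d$records$label) - 1771 / 11971), 0.01)
  # no planted signal: the trapped/untrapped L&S rates agree closely
  rec <- d$records
  trapped <- rec$anyone_trapped == "Anyone trapped"
  expect_lt(abs(mean(rec$label[trapped]) - mean(rec$label[!trapped])), 0.03)
})
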