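test_that("dataset CSV write/read round-trips records exactly", {
  d <- toy_dataset(50)
  d$records$trapped[3] <- MISSING_LABEL
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  d2 <- read_dataset(path, toy_schema())
  expect_identical(d2$records[names(d$records)], d$records)
})

test_that("blank cells load as the reserved missing label", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mpds_code,trapped,speed,label",
               "29B1,,60,0",
               "29D2,yes,,1"), path)
  d <- read_dataset(path, toy_schema())
  expect_equal(d$records$trapped[1], MISSING_LABEL)
  expect_equal(d$records$speed[2], MISSING_LABEL)
  expect_equal(d$records$label, c(0L, 1L))
})

test_that("undeclared categories error with the declared list, or map to missing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mpds_code,trapped,speed,label", "29Z9,yes,60,1"), path)
  expect_error(read_dataset(path, toy_schema()), "29Z9")
  expect_error(read_dataset(path, toy_schema()), "29B1")   # lists valid codes
  d <- read_dataset(path, toy_schema(), unknown = "missing")
  expect_equal(d$records$mpds_code[1], MISSING_LABEL)
})

test_that("schema declarations are validated", {
  expect_error(variable_spec("x", "nominal", c("a", "a")), "duplicate")
  expect_error(variable_spec("x", "dichotomous", c("a", "b", "c")),
               "exactly 2")
  expect_error(variable_spec("x", "nominal", c("a", MISSING_LABEL)),
               "reserved")
  expect_error(mvc_schema(variable_spec("x", "nominal", "a"),
                          variable_spec("x", "nominal", "b")), "duplicate")
})

test_that("schema JSON round-trips", {
  sch <- default_schema()
  path <- withr::local_tempfile(fileext = ".json")
  write_schema(sch, path)
  sch2 <- read_schema(path)
  expect_identical(names(sch2), names(sch))
  for (v in names(sch)) {
    expect_identical(sch2[[v]]$kind, sch[[v]]$kind)
    expect_identical(sch2[[v]]$categories, sch[[v]]$categories)
  }
})

test_that("dispatch-code fixture matches the printed cohort", {
  fx <- load_table2_fixture()
  rows <- fx$rows
  expect_equal(nrow(rows), 52L)
  expect_equal(unname(fx$totals), c(10200L, 1771L, 11971L))
  expect_equal(sum(rows$not_ls), 10200L)
  expect_equal(sum(rows$ls), 1771L)
  pick <- function(code) unlist(rows[rows$category == code, c("not_ls", "ls")])
  expect_equal(unname(pick("29B1")), c(2098L, 237L))
  expect_equal(unname(pick("29O1")), c(116L, 6L))
  expect_equal(sum(pick("29D2p")), 444L)
  # printed column shares
  share <- function(code) round(100 * sum(pick(code)) / 11971, 1)
  expect_equal(share("29B1"), 19.5)
  expect_equal(share("29B4"), 18.7)
  expect_equal(share("29D2l"), 9.6)
})

test_that("characteristic fixture blocks are conserved within the cohort total", {
  fx <- load_table3_fixture()
  rows <- fx$rows
  pick <- function(v, cat)
    unlist(rows[rows$variable == v & rows$category == cat,
                c("not_ls", "ls")])
  expect_equal(unname(pick("rollover", "No vehicle rolled")),
               c(9823L, 1704L))
  # ejected block covers everyone; no-one-ejected share is 99.0%
  ej <- rows[rows$variable == "anyone_ejected", ]
  expect_equal(sum(ej$not_ls) + sum(ej$ls), 11971L)
  expect_equal(round(100 * sum(pick("anyone_ejected", "No one ejected")) /
                       11971, 1), 99.0)
  # surface block has missingness: sums short of the total
  surf <- rows[rows$variable == "road_surface", ]
  expect_lt(sum(surf$not_ls) + sum(surf$ls), 11971L)
  # every block is bounded by the per-class totals
  for (v in unique(rows$variable)) {
    blk <- rows[rows$variable == v, ]
    expect_lte(sum(blk$not_ls), 10200L)
    expect_lte(sum(blk$ls), 1771L)
  }
})

test_that("time of day bins into equal-frequency ordinal categories", {
  n <- 1000L
  withr::with_seed(9, {
    times <- sprintf("%02d:%02d", sample(0:23, n, TRUE), sample(0:59, n, TRUE))
  })
  sch <- mvc_schema(variable_spec("mpds_code", "nominal", "29B1"),
                    variable_spec("time_of_day", "continuous", n_bins = 4L))
  d <- mvc_dataset(data.frame(mpds_code = "29B1", time_of_day = times,
                              stringsAsFactors = FALSE), sch)
  b <- bin_continuous(d)
  expect_equal(b$schema$time_of_day$kind, "ordinal")
  tab <- table(b$records$time_of_day)
  expect_true(max(tab) - min(tab) <= n / 4)   # near-equal occupancy
  expect_error(bin_continuous(
    mvc_dataset(data.frame(mpds_code = "29B1", time_of_day = "25:99",
                           stringsAsFactors = FALSE), sch)))
})
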