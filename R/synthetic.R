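#' Synthetic crash-cohort generator
#'
#' The analysis cohort itself is not distributable, but its marginal
#' structure is embedded in the package (see [load_table2_fixture()],
#' [load_table3_fixture()]). The generator produces labelled datasets in
#' three modes:
#' \describe{
#'   \item{fixture-faithful}{exactly 11,971 records whose (MPDS code,
#'     outcome) joint counts equal the embedded dispatch-code table;
#'     characteristics drawn from the characteristic marginals conditional
#'     on the outcome, with item-level missingness equal to each block's
#'     deficit. Only record order depends on the seed.}
#'   \item{planted-tree}{features drawn independently from the overall
#'     marginals; the outcome drawn from a per-record leaf probability given
#'     by a planted decision tree — a recoverable ground truth for the CHAID
#'     grower.}
#'   \item{marginal-independent}{features from the overall marginals and an
#'     outcome independent of them at the cohort prevalence (a null
#'     dataset).}
#' }
#' Characteristics are conditionally independent given the outcome (the
#' cohort's true inter-feature correlations are unknown), so joint-feature
#' structure beyond the planted tree is absent by design.
#'
#' @name synthetic
NULL

#' Generator configuration
#'
#' @param n number of records (ignored in fixture-faithful mode, which is
#'   pinned to the cohort size 11,971)
#' @param seed integer seed; every sampling step derives from it
#' @param mode one of \code{"fixture_faithful"}, \code{"planted_tree"},
#'   \code{"marginal_independent"}
#' @param missingness named per-variable missing rates in [0, 1]; defaults
#'   to [default_missingness_rates()]
#' @return an object of class \code{generator_config}
#' @export
generator_config <- function(n = 11971L, seed = 1L,
                             mode = c("fixture_faithful", "planted_tree",
                                      "marginal_independent"),
                             missingness = NULL) {
  mode <- match.arg(mode)
  stopifnot(n > 0, is.numeric(seed))
  if (!is.null(missingness))
    stopifnot(all(missingness >= 0), all(missingness <= 1))
  structure(list(n = as.integer(n), seed = as.integer(seed), mode = mode,
                 missingness = missingness),
            class = "generator_config")
}

#' Default per-variable missing rates
#'
#' Derived from each characteristic block's deficit against the cohort total
#' of 11,971 (e.g. the accident-type block sums to 7,982, a 33.3% deficit).
#' Variables without an embedded block get the typical crash-record deficit
#' of 35% if they originate from the crash report, 0 if from the ambulance
#' call log (time of day).
#'
#' @return named numeric vector of rates in [0, 1]
#' @export
default_missingness_rates <- function() {
  t3 <- .table3_raw()
  tot <- .fixture_totals()[["n"]]
  blocks <- tapply(t3$not_ls + t3$ls, t3$variable, sum)
  rates <- 1 - as.numeric(blocks) / tot
  names(rates) <- names(blocks)
  extra <- c(raining = 0.35, speed_limit = 0.35, traffic_control = 0.35,
             intersection_type = 0.35, time_of_day = 0)
  c(rates, extra)
}

# Per-class category probabilities (including a missing share) for every
# schema variable. Fixture-backed variables use the embedded per-class
# counts; the rest use the illustrative marginals below, identical in both
# classes (no outcome signal).
.class_conditional_probs <- function(schema) {
  t3 <- .table3_raw()
  tot <- .fixture_totals()
  ill <- .illustrative_marginals()
  miss <- default_missingness_rates()
  out <- list()
  for (v in characteristic_variables(schema)) {
    if (schema[[v]]$kind == "continuous") next
    if (v %in% t3$variable) {
      blk <- t3[t3$variable == v, ]
      probs <- lapply(c(not_ls = "not_ls", ls = "ls"), function(cl) {
        cnt <- stats::setNames(blk[[cl]], blk$category)
        class_n <- tot[[cl]]
        p <- c(cnt, stats::setNames(class_n - sum(cnt), MISSING_LABEL))
        p / class_n
      })
    } else {
      base <- ill[[v]]
      mr <- unname(miss[v])
      p <- c(base * (1 - mr), stats::setNames(mr, MISSING_LABEL))
      probs <- list(not_ls = p, ls = p)
    }
    out[[v]] <- probs
  }
  out
}

# Marginals for variables the embedded tables do not cover; illustrative
# urban-road values, identical across outcome classes.
.illustrative_marginals <- function() {
  list(
    raining = c("Raining" = 0.12, "Clear" = 0.88),
    speed_limit = c("40" = 0.05, "50" = 0.25, "60" = 0.30, "70" = 0.15,
                    "80" = 0.12, "90" = 0.05, "100" = 0.05, "110" = 0.03),
    traffic_control = c("Traffic lights" = 0.25, "Stop sign" = 0.05,
                        "Give way sign" = 0.10, "Zebra crossing" = 0.02,
                        "Railway crossing" = 0.01, "School crossing" = 0.02,
                        "No signal or control" = 0.55),
    intersection_type = c("4-way" = 0.35, "3-way (T-junction)" = 0.40,
                          "Roundabout" = 0.15, "Bridge" = 0.02,
                          "Rail crossing" = 0.01, "Driveway" = 0.07)
  )
}

# Commuter-peaked hourly weights for time-of-day sampling.
.hour_weights <- function() {
  w <- c(2, 1.5, 1, 1, 1, 2, 4, 7, 8, 6, 5.5, 5.5,
         6, 6, 6.5, 8, 9, 9.5, 7, 5, 4, 3.5, 3, 2.5)
  w / sum(w)
}

.sample_time_of_day <- function(n) {
  h <- sample(0:23, n, replace = TRUE, prob = .hour_weights())
  sprintf("%02d:%02d", h, sample(0:59, n, replace = TRUE))
}

.sample_characteristics <- function(schema, label, conditional = TRUE) {
  probs <- .class_conditional_probs(schema)
  n <- length(label)
  w <- .fixture_totals()
  rec <- list()
  for (v in characteristic_variables(schema)) {
    if (schema[[v]]$kind == "continuous") {
      rec[[v]] <- .sample_time_of_day(n)
      next
    }
    p <- probs[[v]]
    x <- character(n)
    if (conditional) {
      for (cl in c(0L, 1L)) {
        pv <- if (cl == 0L) p$not_ls else p$ls
        who <- which(label == cl)
        x[who] <- sample(names(pv), length(who), replace = TRUE, prob = pv)
      }
    } else {
      # overall marginal: per-class probabilities pooled at the class weights
      pv <- (p$not_ls * w[["not_ls"]] + p$ls * w[["ls"]]) / w[["n"]]
      x <- sample(names(pv), n, replace = TRUE, prob = pv)
    }
    rec[[v]] <- x
  }
  rec
}

#' Generate the fixture-faithful cohort
#'
#' Exactly 11,971 records whose (MPDS dispatch code, outcome) joint counts
#' equal the embedded dispatch-code table — 1,771 records needing L&S,
#' 10,200 not — with crash characteristics drawn from the characteristic
#' marginals conditional on the outcome (missingness built in as each
#' block's deficit). Counts are deterministic; the seed only shuffles record
#' order and drives the characteristic draws.
#'
#' @param seed integer seed
#' @param schema schema to generate under (default [default_schema()])
#' @return a labelled \code{mvc_dataset} of 11,971 records
#' @export
sample_fixture_faithful <- function(seed = 1L, schema = default_schema()) {
  t2 <- .table2_raw()
  code <- c(rep(t2$code, t2$not_ls), rep(t2$code, t2$ls))
  label <- c(rep(0L, sum(t2$not_ls)), rep(1L, sum(t2$ls)))
  withr::with_seed(as.integer(seed), {
    rec <- .sample_characteristics(schema, label)
    rec$mpds_code <- code
    rec$label <- label
    df <- as.data.frame(rec, stringsAsFactors = FALSE,
                        check.names = FALSE)
    df <- df[sample.int(nrow(df)), , drop = FALSE]
  })
  rownames(df) <- NULL
  mvc_dataset(df, schema)
}

#' Declare a planted ground-truth tree
#'
#' A planted tree is a nested rule: an internal node names a schema variable
#' and partitions its full category set (missing label included) into
#' groups, each leading to a child; a leaf carries the L&S probability of
#' every record that reaches it. [sample_planted()] draws outcomes from it,
#' giving the CHAID grower a recoverable truth.
#'
#' @param variable schema variable name split at this node
#' @param groups list of lists, each \code{list(categories = <chr>,
#'   child = <planted_node or planted_leaf>)}; the categories must partition
#'   the variable's declared categories plus the missing label
#' @return a \code{planted_node}
#' @export
planted_node <- function(variable, groups) {
  stopifnot(is.character(variable), length(groups) >= 2L)
  structure(list(variable = variable, groups = groups),
            class = "planted_node")
}

#' @rdname planted_node
#' @param p L&S probability in [0, 1]
#' @export
planted_leaf <- function(p) {
  stopifnot(p >= 0, p <= 1)
  structure(list(p = p), class = "planted_leaf")
}

# Validate a planted spec against a schema: groups partition categories.
.validate_planted <- function(node, schema) {
  if (inherits(node, "planted_leaf")) return(invisible(TRUE))
  v <- node$variable
  if (!v %in% names(schema))
    stop("planted tree references unknown variable '", v, "'")
  full <- c(schema[[v]]$categories, MISSING_LABEL)
  got <- sort(unlist(lapply(node$groups, `[[`, "categories")))
  if (!identical(got, sort(full)))
    stop("planted groups for '", v, "' do not partition its categories")
  for (g in node$groups) .validate_planted(g$child, schema)
  invisible(TRUE)
}

# Leaf probability per record (vectorised recursive descent).
.planted_leaf_p <- function(node, records, idx = seq_len(nrow(records))) {
  p <- numeric(nrow(records))
  descend <- function(node, idx) {
    if (!length(idx)) return()
    if (inherits(node, "planted_leaf")) { p[idx] <<- node$p; return() }
    x <- records[[node$variable]][idx]
    for (g in node$groups)
      descend(g$child, idx[x %in% g$categories])
  }
  descend(node, idx)
  p
}

#' Sample a dataset from a planted tree
#'
#' Features are drawn independently from the overall marginals (without
#' missingness — add it afterwards with [apply_missingness()] if wanted,
#' though note blanking a planted variable changes the labels' generative
#' tree); each record's outcome is Bernoulli with its planted leaf
#' probability.
#'
#' @param spec a \code{planted_node}
#' @param config a \code{generator_config} (mode \code{"planted_tree"})
#' @param schema schema to generate under
#' @return a labelled \code{mvc_dataset} of \code{config$n} records
#' @export
sample_planted <- function(spec, config, schema = default_schema()) {
  .validate_planted(spec, schema)
  n <- config$n
  withr::with_seed(config$seed, {
    rec <- .sample_characteristics(schema, rep(0L, n), conditional = FALSE)
    t2 <- .table2_raw()
    tot <- t2$not_ls + t2$ls
    rec$mpds_code <- sample(t2$code, n, replace = TRUE, prob = tot / sum(tot))
    df <- as.data.frame(rec, stringsAsFactors = FALSE, check.names = FALSE)
    p <- .planted_leaf_p(spec, df)
    df$label <- stats::rbinom(n, 1L, p)
  })
  mvc_dataset(df, schema)
}

#' Sample a null dataset (outcome independent of features)
#'
#' @inheritParams sample_planted
#' @param prevalence L&S probability (default the cohort prevalence
#'   1771/11971)
#' @export
sample_marginal_independent <- function(config, schema = default_schema(),
                                        prevalence = 1771 / 11971) {
  n <- config$n
  withr::with_seed(config$seed, {
    label <- stats::rbinom(n, 1L, prevalence)
    rec <- .sample_characteristics(schema, label, conditional = FALSE)
    t2 <- .table2_raw()
    tot <- t2$not_ls + t2$ls
    rec$mpds_code <- sample(t2$code, n, replace = TRUE, prob = tot / sum(tot))
    rec$label <- label
    df <- as.data.frame(rec, stringsAsFactors = FALSE, check.names = FALSE)
  })
  mvc_dataset(df, schema)
}

#' Blank features at configured missing rates
#'
#' Independently replaces each feature value by the missing label at its
#' per-variable rate. Labels are never blanked.
#'
#' @param data an \code{mvc_dataset}
#' @param rates named per-variable rates (variables absent from the vector
#'   are left untouched)
#' @param seed integer seed
#' @return the dataset with missingness applied
#' @export
apply_missingness <- function(data, rates = default_missingness_rates(),
                              seed = 1L) {
  n <- n_records(data)
  withr::with_seed(as.integer(seed), {
    for (v in intersect(names(rates), names(data$schema))) {
      r <- rates[[v]]
      if (r <= 0) next
      hit <- stats::runif(n) < r
      data$records[[v]][hit] <- MISSING_LABEL
    }
  })
  data
}

#' Generate a dataset per a generator configuration
#'
#' Mode dispatcher used by the command-line layer.
#'
#' @param config a \code{generator_config}
#' @param schema schema to generate under
#' @param spec planted tree (required for mode \code{"planted_tree"};
#'   default [default_planted_spec()])
#' @return a labelled \code{mvc_dataset}
#' @export
generate_dataset <- function(config, schema = default_schema(), spec = NULL) {
  switch(config$mode,
    fixture_faithful = sample_fixture_faithful(config$seed, schema),
    planted_tree = sample_planted(spec %||% default_planted_spec(schema),
                                  config, schema),
    marginal_independent = sample_marginal_independent(config, schema))
}

#' A two-level planted tree with strong effects
#'
#' Root split on trapped occupants; the trapped branch splits on atmosphere,
#' the non-trapped branch on rollover. Leaf L&S probabilities span 0.05 to
#' 0.85, i.e. well-separated effects a tree grower should recover.
#'
#' @param schema schema the planted tree must conform to
#' @return a \code{planted_node}
#' @export
default_planted_spec <- function(schema = default_schema()) {
  atmos <- c(schema[["atmosphere"]]$categories, MISSING_LABEL)
  bad_air <- c("Raining", "Fog/Mist", "Fog/smoke/dust", "Dust/Smoke")
  planted_node("anyone_trapped", list(
    list(categories = c("Anyone trapped", MISSING_LABEL),
         child = planted_node("atmosphere", list(
           list(categories = setdiff(atmos, bad_air),
                child = planted_leaf(0.45)),
           list(categories = bad_air, child = planted_leaf(0.85))
         ))),
    list(categories = "No one trapped",
         child = planted_node("rollover", list(
           list(categories = c("Any vehicle rolled", MISSING_LABEL),
                child = planted_leaf(0.40)),
           list(categories = "No vehicle rolled",
                child = planted_leaf(0.05))
         )))
  ))
}
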