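#' Embedded reference marginal tables
#'
#' The package ships the marginal tables of a three-year metropolitan
#' ambulance motor-vehicle-crash cohort (n = 11,971 incidents; 1,771 needed a
#' lights-and-sirens (L&S) response, 10,200 did not). Two tables are embedded:
#' the joint distribution of Protocol-29 MPDS dispatch code by outcome, and
#' per-characteristic category-by-outcome blocks. They drive the synthetic
#' data generator and the fixed baseline checks.
#'
#' @name fixtures
#' @keywords internal
NULL

# MPDS Protocol 29 dispatch code x outcome counts.
# Columns: code, descriptor, not_ls, ls.
.table2_raw <- function() {
  txt <- "
29D1|Major incident|7|1
29D1V|Major incident, multiple patients|2|0
29D1b|Major incident - bus|5|1
29D1d|Major incident - train|1|2
29D1f|Major incident - multiple vehicle pile-up|4|0
29D2|High mechanism|257|78
29D2k|High mechanism - all-terrain/snowmobile|2|0
29D2l|High mechanism - vehicle v. bicycle/motorcycle|905|247
29D2m|High mechanism - vehicle v. pedestrian|672|169
29D2n|High mechanism - ejection|80|34
29D2p|High mechanism - rollovers|377|67
29D2r|High mechanism - possible death at scene|0|1
29D3|HAZMAT|67|10
29D3U|HAZMAT, unknown number of patients|3|1
29D3V|HAZMAT, multiple patients|19|3
29D3X|HAZMAT, unknown patients, additional response|1|0
29D3Y|HAZMAT, multiple patients, additional response|3|0
29D4|Trapped victim|338|126
29D4U|Trapped victim, unknown number of patients|59|23
29D4V|Trapped victim, multiple patients|124|64
29D4X|Trapped victim, unknown patients, additional response|3|2
29D4Y|Trapped victim, multiple patients, additional response|28|21
29D4n|Trapped victim, ejection|3|0
29D5|Not alert|325|153
29D5U|Not alert, unknown number of patients|5|2
29D5V|Not alert, multiple patients|47|21
29D5X|Not alert, unknown patients, additional response|0|1
29D5Y|Not alert, multiple patients, additional response|3|2
29D5m|Not alert, vehicle v. pedestrian|0|2
29D5n|Not alert, ejection|2|4
29B1|Injuries|2098|237
29B1U|Injuries, unknown number of patients|41|8
29B1V|Injuries, multiple patients|470|56
29B1X|Injuries, unknown patients, additional response|6|1
29B1Y|Injuries, multiple patients, additional response|57|5
29B2|Serious haemorrhage|126|31
29B2V|Serious haemorrhage, multiple patients|23|3
29B2X|Serious haemorrhage, unknown patients, additional response|1|0
29B2Y|Serious haemorrhage, multiple patients, additional response|5|3
29B3|Other hazards|589|76
29B3U|Other hazards, unknown number of patients|71|8
29B3V|Other hazards, multiple patients|214|29
29B3X|Other hazards, unknown patients, additional response|6|2
29B3Y|Other hazards, multiple patients, additional response|33|4
29B4|Unknown status/Other codes not applicable|2054|185
29B4U|Unknown status, unknown number of patients|429|36
29B4V|Unknown status, multiple patients|442|37
29B4X|Unknown status, unknown patients, additional response|29|4
29B4Y|Unknown status, multiple patients, additional response|31|5
29A1|1st party caller, injury to not dangerous body area|16|0
29A1V|1st party caller, not dangerous body area, multiple patients|1|0
29O1|No injuries (confirmed)|116|6"
  df <- utils::read.table(text = txt, sep = "|", quote = "",
                          col.names = c("code", "descriptor", "not_ls", "ls"),
                          stringsAsFactors = FALSE, strip.white = TRUE)
  df
}

# Crash characteristic blocks: variable, category, not_ls, ls.
# Blocks whose counts sum short of 11,971 carry item-level missingness.
.table3_raw <- function() {
  txt <- "
accident_type|Intersection|4230|653
accident_type|Midblock|2513|586
airbag_deployed|Any airbag deployed|3280|571
airbag_deployed|No airbag deployed|6920|1200
road_alignment|Curve|861|206
road_alignment|Straight|4669|850
atmosphere|Clear|3207|694
atmosphere|Dust/Smoke|5|1
atmosphere|Fog/Mist|12|3
atmosphere|Fog/smoke/dust|0|1
atmosphere|Overcast|277|90
atmosphere|Raining|358|55
day_of_week|Monday|1384|189
day_of_week|Tuesday|1481|261
day_of_week|Wednesday|1537|234
day_of_week|Thursday|1552|271
day_of_week|Friday|1683|297
day_of_week|Saturday|1360|258
day_of_week|Sunday|1203|261
anyone_ejected|Anyone ejected|63|62
anyone_ejected|No one ejected|10137|1709
road_grade|Crest of hill|78|18
road_grade|Level|3321|668
road_grade|Slope|666|186
lighting|Daylight|4867|824
lighting|Dawn/Dusk|479|75
lighting|Dark - street lights on|1095|257
lighting|Dark - street lights off|19|6
lighting|Dark - street lights not provided|69|46
anyone_not_ambulant|Anyone not ambulant|140|116
anyone_not_ambulant|Everyone ambulant|10060|1655
older|Any aged >= 75 years|739|120
older|Everyone aged <= 74 years|9461|1651
single_v_multi|2 or more vehicles|5314|689
single_v_multi|Single vehicle|1423|326
road_surface|Sealed|3321|668
road_surface|Unsealed|78|18
rollover|Any vehicle rolled|377|67
rollover|No vehicle rolled|9823|1704
anyone_trapped|Anyone trapped|444|303
anyone_trapped|No one trapped|9756|1468
child|Anyone <= 12 years|455|92
child|Everyone >= 13 years|9745|1679
vulnerable_road_user|Motor vehicle occupant|6866|854
vulnerable_road_user|Vulnerable|1943|536"
  df <- utils::read.table(text = txt, sep = "|", quote = "",
                          col.names = c("variable", "category", "not_ls", "ls"),
                          stringsAsFactors = FALSE, strip.white = TRUE)
  df
}

.fixture_totals <- function() c(not_ls = 10200L, ls = 1771L, n = 11971L)

#' Load the dispatch-code marginal fixture
#'
#' Returns the embedded joint distribution of Protocol-29 MPDS dispatch codes
#' by lights-and-sirens outcome. The code counts sum exactly to the cohort
#' totals (10,200 not-L&S, 1,771 L&S, 11,971 incidents).
#'
#' @return An object of class \code{marginal_fixture}: a list with
#'   \code{rows} (data frame \code{variable}, \code{category},
#'   \code{not_ls}, \code{ls}) and \code{totals} (named integer vector
#'   \code{not_ls}, \code{ls}, \code{n}).
#' @seealso [load_table3_fixture()]
#' @export
#' @examples
#' fx <- load_table2_fixture()
#' subset(fx$rows, category == "29B1")
load_table2_fixture <- function() {
  raw <- .table2_raw()
  rows <- data.frame(variable = "mpds_code", category = raw$code,
                     not_ls = as.integer(raw$not_ls), ls = as.integer(raw$ls),
                     stringsAsFactors = FALSE)
  fx <- structure(list(rows = rows, totals = .fixture_totals(),
                       descriptors = stats::setNames(raw$descriptor, raw$code)),
                  class = "marginal_fixture")
  validate_marginal_fixture(fx, exact = TRUE)
  fx
}

#' Load the crash-characteristic marginal fixture
#'
#' Returns the embedded per-characteristic category-by-outcome blocks. Blocks
#' may sum to fewer than 11,971 incidents; the deficit is item-level
#' missingness and is what the generator's default missingness rates are
#' derived from.
#'
#' @inherit load_table2_fixture return
#' @seealso [load_table2_fixture()], [default_missingness_rates()]
#' @export
load_table3_fixture <- function() {
  rows <- .table3_raw()
  rows$not_ls <- as.integer(rows$not_ls)
  rows$ls <- as.integer(rows$ls)
  fx <- structure(list(rows = rows, totals = .fixture_totals()),
                  class = "marginal_fixture")
  validate_marginal_fixture(fx, exact = FALSE)
  fx
}

#' @rdname fixtures
#' @param x a \code{marginal_fixture}
#' @param exact require every block to sum exactly to the totals
#' @keywords internal
validate_marginal_fixture <- function(x, exact = FALSE) {
  stopifnot(is.list(x), all(c("rows", "totals") %in% names(x)))
  rows <- x$rows
  if (any(rows$not_ls < 0) || any(rows$ls < 0))
    stop("fixture counts must be non-negative")
  tot <- x$totals
  for (v in unique(rows$variable)) {
    blk <- rows[rows$variable == v, ]
    if (anyDuplicated(blk$category))
      stop("duplicate category in fixture block ", v)
    s <- c(sum(blk$not_ls), sum(blk$ls))
    if (exact) {
      if (s[1] != tot["not_ls"] || s[2] != tot["ls"])
        stop("fixture block ", v, " does not sum to the cohort totals")
    } else {
      if (s[1] > tot["not_ls"] || s[2] > tot["ls"])
        stop("fixture block ", v, " exceeds the cohort totals")
    }
  }
  invisible(x)
}

#' @export
print.marginal_fixture <- function(x, ...) {
  nv <- length(unique(x$rows$variable))
  cat("Marginal fixture:", nrow(x$rows), "category rows across", nv,
      if (nv == 1L) "variable\n" else "variables\n")
  cat("Cohort totals: ", x$totals["not_ls"], " not-L&S + ", x$totals["ls"],
      " L&S = ", x$totals["n"], " incidents\n", sep = "")
  invisible(x)
}
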