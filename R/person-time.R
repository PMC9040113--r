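# Person-time (Lexis) splitting on the time-since-diagnosis scale and
# tabulation into stratum x band cells.

#' Time-since-diagnosis band scheme
#'
#' An ordered set of contiguous half-open intervals `[a, b)` covering
#' follow-up, each with midpoint `(a + b) / 2` at which predicted rates are
#' plotted and interpolated. The default is the seven survivorship bands
#' 1-<2, 2-<3, 3-<4, 4-<5, 5-<10, 10-<15 and 15-25 years since diagnosis,
#' with midpoints 1.5, 2.5, 3.5, 4.5, 7.5, 12.5 and 20.
#'
#' @param breaks strictly increasing band boundaries in years since
#'   diagnosis; band `i` is `[breaks[i], breaks[i+1])`.
#' @return a `band_scheme` data frame with columns `band`, `lo`, `hi`,
#'   `midpoint`, `label`.
#' @export
band_scheme <- function(breaks = c(1, 2, 3, 4, 5, 10, 15, 25)) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 2L || any(diff(breaks) <= 0)) {
    stop("band_scheme: breaks must be strictly increasing")
  }
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1L]
  out <- data.frame(
    band = seq_along(lo), lo = lo, hi = hi,
    midpoint = (lo + hi) / 2,
    label = sprintf("%g-<%g", lo, hi),
    stringsAsFactors = FALSE
  )
  class(out) <- c("band_scheme", "data.frame")
  out
}

scheme_breaks <- function(scheme) c(scheme$lo, scheme$hi[nrow(scheme)])

#' Split follow-up into time-since-diagnosis bands
#'
#' Distributes each person's follow-up `[entry, exit)` over the bands of a
#' scheme: the person-years in a band are the overlap length, and the death
#' (if any) is attached to the band containing the exit time under the
#' half-open convention — an exit at an interior boundary contributes no
#' time to the right-hand band, but a death at that instant belongs to it.
#' A death at the terminal boundary belongs to the last band (closed top).
#' Banded person-years re-sum to `exit - entry` exactly (up to additive
#' float rounding below 1e-9 years).
#'
#' @param records a cohort data frame (one or many rows).
#' @param scheme a [band_scheme()]; its coverage must contain all follow-up.
#' @return a `data.frame` with one row per person-band with positive
#'   person-years (plus the death band even when it receives zero time):
#'   `person_id`, `band`, `py`, `death` (logical).
#' @examples
#' rec <- data.frame(person_id = 1L, site = "lung", sex = "male",
#'                   age_group = "60-79", entry_years = 1, exit_years = 6.2,
#'                   died = TRUE, underlying_cause = "cvd",
#'                   immediate_cause = "cvd")
#' split_followup(rec)
#' @export
split_followup <- function(records, scheme = band_scheme()) {
  stopifnot(inherits(scheme, "band_scheme"))
  brk <- scheme_breaks(scheme)
  entry <- records$entry_years
  exit <- records$exit_years
  if (any(entry < brk[1L] - 1e-12)) {
    stop("split_followup: entry before the first band start (", brk[1L], ")")
  }
  if (any(exit > brk[length(brk)] + 1e-12)) {
    stop("split_followup: exit beyond band coverage (horizon ",
         brk[length(brk)], " years)")
  }
  nb <- nrow(scheme)
  n <- nrow(records)
  died <- as.logical(records$died)
  # band containing the exit; terminal boundary closed
  k_exit <- findInterval(exit, brk)
  k_exit[k_exit > nb] <- nb

  pieces <- vector("list", nb)
  for (k in seq_len(nb)) {
    py <- pmax(0, pmin(exit, scheme$hi[k]) - pmax(entry, scheme$lo[k]))
    keep <- py > 0 | (died & k_exit == k)
    if (any(keep)) {
      pieces[[k]] <- data.frame(
        person_id = records$person_id[keep],
        band = k, py = py[keep],
        death = died[keep] & k_exit[keep] == k
      )
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$person_id, out$band), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabulate person-years and cause-specific deaths
#'
#' Aggregates split follow-up into cells keyed by (site, age group, sex,
#' band): person-years, number of persons contributing any follow-up, and
#' death counts for the cardiovascular, primary-cancer, other-cancer,
#' any-cancer (primary plus other) and remaining-cause categories. Because
#' follow-up is censored at all-cause death, each person contributes at
#' most one death across the whole table, in the band containing the exit.
#' Cells are completed over every band for each stratum present, so bands
#' with no follow-up appear with zero person-years (their rates are later
#' flagged undefined, never silently zero).
#'
#' @param records a cohort data frame.
#' @param scheme a [band_scheme()].
#' @param cause_field attribute deaths by the `"underlying"` (default) or
#'   `"immediate"` recorded cause — the latter is the death-certificate
#'   sensitivity analysis.
#' @param stratify_sex if `TRUE`, cells for each sex are appended to the
#'   pooled (`sex = "all"`) cells.
#' @return a `person_time_table` data frame with columns `site`,
#'   `age_group`, `sex`, `band`, `lo`, `hi`, `midpoint`, `py`, `n_persons`,
#'   `d_cvd`, `d_primary_cancer`, `d_other_cancer`, `d_any_cancer`,
#'   `d_other`.
#' @export
tabulate_person_time <- function(records, scheme = band_scheme(),
                                 cause_field = c("underlying", "immediate"),
                                 stratify_sex = FALSE) {
  cause_field <- match.arg(cause_field)
  ccol <- paste0(cause_field, "_cause")
  unknown <- records$died & !(records[[ccol]] %in% mortcross_causes)
  if (any(unknown)) {
    stop("tabulate_person_time: unknown ", cause_field,
         " cause for person_id ",
         paste(records$person_id[unknown], collapse = ", "))
  }
  validate_cohort(records, horizon = max(scheme_breaks(scheme)))
  sp <- data.table::as.data.table(split_followup(records, scheme))
  meta <- data.table::as.data.table(
    records[, c("person_id", "site", "sex", "age_group")])
  meta[, cause := records[[ccol]]]
  sp <- meta[sp, on = "person_id"]

  agg_one <- function(dt, sex_label) {
    cells <- dt[, .(
      py = sum(py),
      n_persons = data.table::uniqueN(person_id),
      d_cvd = sum(death & cause == "cvd"),
      d_primary_cancer = sum(death & cause == "primary_cancer"),
      d_other_cancer = sum(death & cause == "other_cancer"),
      d_other = sum(death & cause == "other")
    ), by = .(site, age_group, band)]
    full <- data.table::CJ(site = unique(dt$site),
                           age_group = unique(dt$age_group),
                           band = scheme$band, unique = TRUE)
    # keep only strata that actually occur
    strata <- unique(dt[, .(site, age_group)])
    full <- full[strata, on = c("site", "age_group")]
    cells <- cells[full, on = c("site", "age_group", "band")]
    for (col in c("py", "n_persons", "d_cvd", "d_primary_cancer",
                  "d_other_cancer", "d_other")) {
      data.table::set(cells, which(is.na(cells[[col]])), col, 0)
    }
    cells[, sex := sex_label]
    cells
  }

  out <- agg_one(sp, "all")
  if (stratify_sex) {
    for (sx in sort(unique(records$sex))) {
      out <- rbind(out, agg_one(sp[sex == sx], sx))
    }
  }
  out[, d_any_cancer := d_primary_cancer + d_other_cancer]
  out <- merge(out, scheme[, c("band", "lo", "hi", "midpoint")], by = "band")
  data.table::setcolorder(out, c("site", "age_group", "sex", "band", "lo",
                                 "hi", "midpoint", "py", "n_persons",
                                 "d_cvd", "d_primary_cancer",
                                 "d_other_cancer", "d_any_cancer", "d_other"))
  data.table::setorder(out, site, age_group, sex, band)
  res <- as.data.frame(out)
  attr(res, "scheme") <- scheme
  attr(res, "cause_field") <- cause_field
  class(res) <- c("person_time_table", "data.frame")
  res
}

#' Cohort margins by site and age group
#'
#' Denominator-and-outcome margins in the layout of the shipped study
#' population fixture: individuals, females, and deaths from cardiovascular
#' disease, the primary cancer and any cancer, per site x age-group cell.
#'
#' @param records a cohort data frame.
#' @param cause_field `"underlying"` or `"immediate"`.
#' @return a data frame with columns `site`, `age_group`, `individuals`,
#'   `female`, `cvd_deaths`, `primary_cancer_deaths`, `all_cancer_deaths`.
#' @export
cohort_margins <- function(records, cause_field = c("underlying", "immediate")) {
  cause_field <- match.arg(cause_field)
  ccol <- paste0(cause_field, "_cause")
  dt <- data.table::as.data.table(records)
  dt[, cause := dt[[ccol]]]
  out <- dt[, .(
    individuals = .N,
    female = sum(sex == "female"),
    cvd_deaths = sum(died & cause == "cvd"),
    primary_cancer_deaths = sum(died & cause == "primary_cancer"),
    all_cancer_deaths = sum(died & cause %in% c("primary_cancer", "other_cancer"))
  ), by = .(site, age_group)]
  data.table::setorder(out, site, age_group)
  as.data.frame(out)
}

#' Check margins against expected counts
#'
#' Compares observed against expected count margins cell by cell and margin
#' by margin, and (when `totals` are supplied) the study-level totals.
#' Used to confirm that a tabulation — or the shipped transcription of the
#' study-population denominator table — reproduces its printed totals.
#'
#' @param observed a margins data frame (`site`, `age_group`, count
#'   columns), e.g. from [cohort_margins()] or [fixture_table1()].
#' @param expected a data frame with `site`, `age_group` and any subset of
#'   the observed count columns; zero rows give a vacuous pass.
#' @param totals optional named list/vector of expected totals for count
#'   columns, checked against column sums of `observed`.
#' @return a `margin_report` data frame with one row per checked margin:
#'   `site`, `age_group` (`"(total)"` rows for totals), `margin`,
#'   `observed`, `expected`, `pass`. Attribute `"pass"` gives the overall
#'   verdict.
#' @export
validate_margins <- function(observed, expected, totals = NULL) {
  keys <- c("site", "age_group")
  count_cols <- setdiff(intersect(names(observed), names(expected)), keys)
  rows <- list()
  if (nrow(expected) > 0 && length(count_cols) > 0) {
    m <- merge(expected[, c(keys, count_cols)], observed,
               by = keys, all.x = TRUE, suffixes = c(".exp", ".obs"))
    for (col in count_cols) {
      rows[[length(rows) + 1L]] <- data.frame(
        site = m$site, age_group = m$age_group, margin = col,
        observed = m[[paste0(col, ".obs")]],
        expected = m[[paste0(col, ".exp")]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(totals)) {
    for (col in intersect(names(totals), names(observed))) {
      rows[[length(rows) + 1L]] <- data.frame(
        site = "(total)", age_group = "(total)", margin = col,
        observed = sum(observed[[col]]),
        expected = as.numeric(totals[[col]]),
        stringsAsFactors = FALSE
      )
    }
  }
  rep <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(site = character(), age_group = character(),
               margin = character(), observed = numeric(),
               expected = numeric(), stringsAsFactors = FALSE)
  }
  rep$pass <- !is.na(rep$observed) & rep$observed == rep$expected
  attr(rep, "pass") <- all(rep$pass)  # vacuously TRUE on empty expectations
  class(rep) <- c("margin_report", "data.frame")
  rep
}

#' @export
print.margin_report <- function(x, ...) {
  n_fail <- sum(!x$pass)
  cat(sprintf("<margin_report> %d margins checked, %d failed — %s\n",
              nrow(x), n_fail, if (attr(x, "pass")) "PASS" else "FAIL"))
  if (n_fail > 0) print.data.frame(x[!x$pass, ])
  invisible(x)
}
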