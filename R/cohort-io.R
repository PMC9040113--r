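# Delimited-text cohort files. Fixed header, comma-separated, times in
# decimal years since diagnosis, empty cause fields for survivors.

cohort_columns <- c("person_id", "site", "sex", "age_group",
                    "entry_years", "exit_years", "died",
                    "underlying_cause", "immediate_cause")

#' Validate a cohort table
#'
#' Checks the record invariants: exit strictly after entry, exit within the
#' administrative horizon, death flag consistent with cause labels (causes
#' present iff died), and cause labels drawn from [mortcross_causes].
#'
#' @param records a cohort data frame (see [simulate_cohort()] for the
#'   schema).
#' @param horizon administrative horizon in years since diagnosis.
#' @param lines optional file line numbers used to report offending rows
#'   (used by [read_cohort()]); defaults to row indices.
#' @return the records, invisibly; errors describe every offending row.
#' @export
validate_cohort <- function(records, horizon = 25, lines = NULL) {
  miss <- setdiff(cohort_columns, names(records))
  if (length(miss)) {
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(lines)) lines <- seq_len(nrow(records))
  where <- if (is.null(attr(lines, "unit"))) "row" else attr(lines, "unit")
  bad <- function(cond, what) {
    if (any(cond)) {
      stop("invalid cohort: ", what, " on ", where, " ",
           paste(lines[which(cond)], collapse = ", "), call. = FALSE)
    }
  }
  died <- records$died
  bad(!is.finite(records$entry_years) | !is.finite(records$exit_years),
      "non-numeric entry/exit time")
  bad(records$exit_years <= records$entry_years, "exit_years <= entry_years")
  bad(records$exit_years > horizon + 1e-9,
      paste0("exit_years beyond the ", horizon, "-year horizon"))
  no_cause <- is.na(records$underlying_cause) | records$underlying_cause == ""
  bad(died & no_cause, "death without an underlying cause")
  bad(!died & !no_cause, "underlying cause recorded for a survivor")
  known <- no_cause | records$underlying_cause %in% mortcross_causes
  bad(!known, "unknown underlying cause label")
  no_ic <- is.na(records$immediate_cause) | records$immediate_cause == ""
  bad(died & no_ic, "death without an immediate cause")
  bad(!no_ic & !(records$immediate_cause %in% mortcross_causes | no_ic),
      "unknown immediate cause label")
  invisible(records)
}

#' Write / read a cohort as delimited text
#'
#' `write_cohort()` writes one row per person with the fixed header
#' `person_id, site, sex, age_group, entry_years, exit_years, died,
#' underlying_cause, immediate_cause`; survivors carry empty cause fields.
#' `read_cohort()` reads the same format back, validating every record and
#' reporting offending file line numbers (header is line 1). The round trip
#' is the identity.
#'
#' @param records a cohort data frame.
#' @param path file path.
#' @return `read_cohort()` returns a validated `cohort` data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(records, path) {
  validate_cohort(records)
  out <- data.table::as.data.table(records[, cohort_columns])
  out[, `:=`(underlying_cause = ifelse(is.na(underlying_cause), "", underlying_cause),
             immediate_cause  = ifelse(is.na(immediate_cause), "", immediate_cause))]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("read_cohort: no such file: ", path)
  dt <- data.table::fread(path, colClasses = list(
    character = c("site", "sex", "age_group", "underlying_cause", "immediate_cause")
  ), na.strings = NULL)
  miss <- setdiff(cohort_columns, names(dt))
  if (length(miss)) {
    stop("read_cohort: ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  }
  res <- as.data.frame(dt)[, cohort_columns]
  res$died <- as.logical(res$died)
  res$underlying_cause[res$underlying_cause == ""] <- NA_character_
  res$immediate_cause[res$immediate_cause == ""] <- NA_character_
  lines <- seq_len(nrow(res)) + 1L  # header is file line 1
  attr(lines, "unit") <- "line"
  validate_cohort(res, lines = lines)
  class(res) <- c("cohort", "data.frame")
  res
}
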