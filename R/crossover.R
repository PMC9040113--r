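# Crossover-point estimation: the time since diagnosis at which the
# cardiovascular rate curve overtakes a cancer rate curve, by linear
# interpolation between band midpoints, with percentile-bootstrap CIs from
# resampled individuals.

new_crossover_estimate <- function(site = NA, age_group = NA, sex = NA,
                                   comparison = NA, time = NA_real_,
                                   status, ci_lower = NA_real_,
                                   ci_upper = NA_real_, n_boot = NA_integer_,
                                   n_not_crossed = NA_integer_,
                                   unstable = NA, seed = NA_integer_,
                                   horizon = NA_real_) {
  structure(
    list(site = site, age_group = age_group, sex = sex,
         comparison = comparison, time = time, status = status,
         ci_lower = ci_lower, ci_upper = ci_upper, n_boot = n_boot,
         n_not_crossed = n_not_crossed, unstable = unstable,
         seed = seed, horizon = horizon),
    class = "crossover_estimate"
  )
}

#' @export
print.crossover_estimate <- function(x, ...) {
  cat(sprintf("<crossover_estimate> %s / %s / cvd vs %s\n",
              x$site, x$age_group, x$comparison))
  if (x$status == "crossed") {
    ci <- if (!is.na(x$ci_lower)) {
      sprintf(" (95%% CI %.2f-%.2f, B = %d, %d replicate(s) not crossed%s)",
              x$ci_lower, x$ci_upper, x$n_boot, x$n_not_crossed,
              if (isTRUE(x$unstable)) ", UNSTABLE" else "")
    } else ""
    cat(sprintf("  crossover at %.2f years since diagnosis%s\n", x$time, ci))
  } else {
    cat("  status:", x$status, "\n")
  }
  invisible(x)
}

# Core scan over band midpoints. m must be increasing; cvd/cancer are rate
# vectors; undefined entries NA. scale = "log" interpolates the log-rates
# (non-positive rates become undefined there). Returns list(time, status).
crossover_scan <- function(m, cvd, cancer, horizon, scale = "rate") {
  if (scale == "log") {
    cvd <- ifelse(cvd > 0, log(cvd), NA_real_)
    cancer <- ifelse(cancer > 0, log(cancer), NA_real_)
  }
  keep <- !is.na(cvd) & !is.na(cancer)
  if (!any(keep)) return(list(time = NA_real_, status = "undefined_cells"))
  m <- m[keep]; a <- cvd[keep]; b <- cancer[keep]
  d <- a - b
  if (d[1L] > 0) {
    return(list(time = NA_real_, status = "already_overtaken_at_first_midpoint"))
  }
  if (d[1L] == 0) {
    # equal at the first usable midpoint: a crossover there only if the
    # cardiovascular curve is above at the next one
    if (length(d) > 1L && d[2L] > 0) {
      st <- if (m[1L] <= horizon) "crossed" else "never_within_horizon"
      return(list(time = if (st == "crossed") m[1L] else NA_real_, status = st))
    }
    return(list(time = NA_real_, status = "already_overtaken_at_first_midpoint"))
  }
  if (length(d) > 1L) {
    for (i in seq_len(length(d) - 1L)) {
      if (d[i] < 0 && d[i + 1L] >= 0) {
        gap_i <- b[i] - a[i]                 # > 0
        gap_j <- a[i + 1L] - b[i + 1L]       # >= 0
        t_star <- m[i] + (m[i + 1L] - m[i]) * gap_i / (gap_i + gap_j)
        if (t_star > horizon) {
          return(list(time = NA_real_, status = "never_within_horizon"))
        }
        return(list(time = t_star, status = "crossed"))
      }
    }
  }
  list(time = NA_real_, status = "never_within_horizon")
}

#' Estimate the crossover point of two rate curves
#'
#' Scans consecutive pairs of band midpoints at which both curves are
#' defined for the first change of sign of (cardiovascular minus cancer)
#' from negative to non-negative, and solves for the intersection of the
#' two straight lines joining the pair on the natural rate scale:
#' \deqn{t^* = m_i + (m_{i+1} - m_i)\,\frac{c_i - v_i}{(c_i - v_i) + (v_{i+1} - c_{i+1})}}
#' with \eqn{v} the cardiovascular and \eqn{c} the cancer rate. Exact
#' equality at a midpoint yields that midpoint. A crossover beyond the
#' reporting horizon, or none at all, gives status `never_within_horizon`;
#' a cardiovascular rate already at or above the cancer rate at the first
#' usable midpoint gives `already_overtaken_at_first_midpoint` (no numeric
#' time); no usable midpoints gives `undefined_cells`. Later re-crossings
#' are ignored.
#'
#' @param cvd,cancer [fit_rates()] curves for a single stratum (same site,
#'   age group and sex, identical midpoints); `cvd` is the cardiovascular
#'   curve.
#' @param horizon reporting horizon in years since diagnosis (default 20:
#'   crossovers later than this are not reported even though follow-up
#'   extends to 25 years).
#' @param scale interpolate on the natural `"rate"` scale (default, the
#'   plainest reading of interpolating between plotted points) or on the
#'   `"log"` rate scale (sensitivity variant; zero rates are undefined
#'   there). The two agree on which bands bracket the crossing — a
#'   monotone transform preserves ordering — but place `t*` slightly
#'   differently within the bracket.
#' @return a `crossover_estimate` (no bootstrap CI; see
#'   [bootstrap_crossover()]).
#' @export
find_crossover <- function(cvd, cancer, horizon = 20,
                           scale = c("rate", "log")) {
  scale <- match.arg(scale)
  stopifnot(inherits(cvd, "data.frame"), inherits(cancer, "data.frame"))
  for (col in c("site", "age_group", "sex")) {
    if (length(unique(cvd[[col]])) > 1L || length(unique(cancer[[col]])) > 1L) {
      stop("find_crossover: curves must cover a single stratum (column '",
           col, "' varies); subset the fit_rates() output first")
    }
    if (!identical(unique(cvd[[col]]), unique(cancer[[col]]))) {
      stop("find_crossover: curves are on different strata ('", col, "')")
    }
  }
  cvd <- cvd[order(cvd$midpoint), ]
  cancer <- cancer[order(cancer$midpoint), ]
  if (!isTRUE(all.equal(cvd$midpoint, cancer$midpoint))) {
    stop("find_crossover: curves have mismatched band midpoints")
  }
  r_v <- ifelse(cvd$defined, cvd$rate, NA_real_)
  r_c <- ifelse(cancer$defined, cancer$rate, NA_real_)
  sc <- crossover_scan(cvd$midpoint, r_v, r_c, horizon, scale = scale)
  new_crossover_estimate(
    site = cvd$site[1L], age_group = cvd$age_group[1L], sex = cvd$sex[1L],
    comparison = cancer$cause[1L], time = sc$time, status = sc$status,
    horizon = horizon
  )
}

# person x band contribution table for fast bootstrap re-tabulation
boot_contributions <- function(records, scheme, cause_field) {
  ccol <- paste0(cause_field, "_cause")
  sp <- data.table::as.data.table(split_followup(records, scheme))
  meta <- data.table::data.table(
    person_id = records$person_id,
    idx = seq_len(nrow(records)),
    age_group = records$age_group,
    cause = records[[ccol]]
  )
  sp <- meta[sp, on = "person_id"]
  sp[, `:=`(
    d_cvd = as.numeric(death & cause == "cvd"),
    d_primary_cancer = as.numeric(death & cause == "primary_cancer"),
    d_any_cancer = as.numeric(death & cause %in% c("primary_cancer", "other_cancer")),
    d_other_cancer = as.numeric(death & cause == "other_cancer"),
    d_other = as.numeric(death & cause == "other")
  )]
  sp
}

#' Percentile-bootstrap confidence interval for a crossover point
#'
#' Resamples individuals (not person-time cells) with replacement from one
#' site's cohort, preserving its size, and reruns the whole estimation
#' pipeline — person-time splitting, tabulation, age-stratified Poisson
#' fit, interpolation — on every replicate. The point estimate comes from
#' the original sample; the CI takes the 2.5th and 97.5th percentiles
#' (quantile type 7, linear interpolation between order statistics, so
#' endpoints are reproducible bit for bit at a fixed seed) of the
#' replicate crossover times among replicates that crossed. Replicates
#' that do not cross are excluded from the percentiles but always counted
#' and reported; if more than 5% of replicates fail to cross, the CI is
#' flagged unstable.
#'
#' @param records cohort data frame (may contain several sites; resampling
#'   is restricted to `site`).
#' @param scheme a [band_scheme()].
#' @param site cancer site.
#' @param age_group age stratum whose curves are compared.
#' @param comparison cancer outcome compared against the cardiovascular
#'   rate: `"primary_cancer"` or `"any_cancer"`.
#' @param B number of bootstrap replicates (>= 2; 200 for reported CIs).
#' @param seed integer seed for the resampling.
#' @param horizon reporting horizon, years since diagnosis.
#' @param cause_field `"underlying"` or `"immediate"`.
#' @param stratify_age if `TRUE`, resampling preserves age-group sizes
#'   within the site (recorded in the estimate's metadata via attribute
#'   `"stratified"`); default resamples the site cohort as a whole.
#' @return a `crossover_estimate` with bootstrap fields filled in. If the
#'   point estimate itself did not cross, the CI is skipped and the
#'   point-estimate status is propagated.
#' @export
bootstrap_crossover <- function(records, scheme = band_scheme(), site,
                                age_group, comparison = c("primary_cancer",
                                                          "any_cancer"),
                                B = 200, seed = NULL, horizon = 20,
                                cause_field = c("underlying", "immediate"),
                                stratify_age = FALSE) {
  comparison <- match.arg(comparison)
  cause_field <- match.arg(cause_field)
  if (B < 2) stop("bootstrap_crossover: B must be >= 2")
  records <- records[records$site == site, , drop = FALSE]
  if (nrow(records) == 0L) stop("bootstrap_crossover: no records for site '",
                                site, "'")
  if (!any(records$age_group == age_group)) {
    stop("bootstrap_crossover: no records for age group '", age_group,
         "' in site '", site, "'")
  }
  validate_cohort(records, horizon = max(scheme_breaks(scheme)))
  dcol <- death_column(comparison)
  pb <- boot_contributions(records, scheme, cause_field)
  target_age <- age_group
  pb_age <- pb[pb$age_group == target_age]

  cell_rates <- function(w) {
    cells <- pb_age[, .(py = sum(py * w[idx]),
                        dv = sum(d_cvd * w[idx]),
                        dc = sum(.SD[[1L]] * w[idx])),
                    by = band, .SDcols = dcol]
    cells <- cells[match(scheme$band, band)]
    def <- !is.na(cells$py) & cells$py > 0
    list(cvd = ifelse(def, cells$dv / cells$py * 1000, NA_real_),
         cancer = ifelse(def, cells$dc / cells$py * 1000, NA_real_))
  }

  n <- nrow(records)
  w1 <- rep(1, n)
  r0 <- cell_rates(w1)
  point <- crossover_scan(scheme$midpoint, r0$cvd, r0$cancer, horizon)
  est <- new_crossover_estimate(
    site = site, age_group = age_group, sex = "all",
    comparison = comparison, time = point$time, status = point$status,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    horizon = horizon
  )
  attr(est, "stratified") <- stratify_age
  if (point$status != "crossed") return(est)

  if (!is.null(seed)) set.seed(seed)
  age_idx <- if (stratify_age) split(seq_len(n), records$age_group) else NULL
  times <- rep(NA_real_, B)
  crossed <- logical(B)
  for (b in seq_len(B)) {
    idx <- if (stratify_age) {
      unlist(lapply(age_idx, function(ii) ii[sample.int(length(ii),
                                                        length(ii),
                                                        replace = TRUE)]),
             use.names = FALSE)
    } else {
      sample.int(n, n, replace = TRUE)
    }
    w <- tabulate(idx, nbins = n)
    rb <- cell_rates(w)
    sc <- crossover_scan(scheme$midpoint, rb$cvd, rb$cancer, horizon)
    crossed[b] <- sc$status == "crossed"
    times[b] <- sc$time
  }
  est$n_boot <- as.integer(B)
  est$n_not_crossed <- as.integer(sum(!crossed))
  est$unstable <- est$n_not_crossed > 0.05 * B
  if (any(crossed)) {
    q <- quantile(times[crossed], probs = c(0.025, 0.975), type = 7,
                  names = FALSE)
    est$ci_lower <- q[1L]
    est$ci_upper <- q[2L]
  }
  est
}

#' Crossover table across sites, age groups and comparisons
#'
#' Applies [find_crossover()] (and, when `B >= 2`, [bootstrap_crossover()])
#' to every combination of site, age group and comparison present in the
#' cohort, producing the site x age-group crossover summary table. Strata
#' whose estimation fails are reported with status `"error"` rather than
#' aborting the run.
#'
#' @inheritParams bootstrap_crossover
#' @param comparisons cancer outcomes to compare against the cardiovascular
#'   rate.
#' @param B bootstrap replicates; `0` skips the CI (point estimates only).
#' @param sex sex stratum: `"all"` (default) pools both sexes; a sex label
#'   restricts the cohort (and any bootstrap resampling) to that sex before
#'   estimation, giving the sex-specific secondary analysis.
#' @return data frame with one row per site x age group x comparison:
#'   crossover time, CI, status, replicate diagnostics.
#' @export
crossover_table <- function(records, scheme = band_scheme(),
                            comparisons = c("primary_cancer", "any_cancer"),
                            B = 0, seed = NULL, horizon = 20,
                            cause_field = c("underlying", "immediate"),
                            stratify_age = FALSE, sex = "all") {
  cause_field <- match.arg(cause_field)
  if (!identical(sex, "all")) {
    records <- records[records$sex == sex, , drop = FALSE]
    if (nrow(records) == 0L) stop("crossover_table: no records for sex '",
                                  sex, "'")
  }
  sites <- sort(unique(records$site))
  tab <- tabulate_person_time(records, scheme, cause_field = cause_field)
  rows <- list()
  i <- 0L
  for (st in sites) {
    ages <- sort(unique(records$age_group[records$site == st]))
    for (ag in ages) {
      for (cmp in comparisons) {
        i <- i + 1L
        est <- tryCatch({
          if (B >= 2) {
            bootstrap_crossover(records, scheme, site = st, age_group = ag,
                                comparison = cmp, B = B,
                                seed = if (is.null(seed)) NULL else seed + i,
                                horizon = horizon, cause_field = cause_field,
                                stratify_age = stratify_age)
          } else {
            cv <- fit_rates(tab, st, "cvd")
            cc <- fit_rates(tab, st, cmp)
            find_crossover(cv[cv$age_group == ag, ],
                           cc[cc$age_group == ag, ], horizon = horizon)
          }
        }, error = function(e) {
          est <- new_crossover_estimate(site = st, age_group = ag, sex = sex,
                                        comparison = cmp, status = "error",
                                        horizon = horizon)
          attr(est, "message") <- conditionMessage(e)
          est
        })
        rows[[i]] <- data.frame(
          site = st, age_group = ag, sex = sex, comparison = cmp,
          time = est$time, ci_lower = est$ci_lower, ci_upper = est$ci_upper,
          status = est$status,
          n_boot = est$n_boot, n_not_crossed = est$n_not_crossed,
          unstable = est$unstable, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
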