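# Cause-specific Poisson rate models over categorical time-since-diagnosis
# bands, predictions at band midpoints per 1,000 person-years, and the
# figure precision-truncation rule.

#' Confidence interval for a crude event rate
#'
#' Log-rate Wald interval for a Poisson count over person-time:
#' `rate * exp(+/- z / sqrt(d))` per 1,000 person-years for `d >= 1`
#' events. With zero events the point and lower bound are 0 and the upper
#' bound is the exact Poisson limit `-log(alpha/2) / PY * 1000` (the
#' largest mean under which zero events retains probability `alpha/2`).
#'
#' @param deaths event count(s), non-negative integers.
#' @param person_years person-time denominator(s), strictly positive.
#' @param level confidence level (default 0.95).
#' @return data frame with `lower` and `upper`, per 1,000 person-years.
#' @examples
#' rate_ci(100, 1000)   # about (82.2, 121.7)
#' @export
rate_ci <- function(deaths, person_years, level = 0.95) {
  if (any(person_years <= 0)) stop("rate_ci: person_years must be > 0")
  if (any(deaths < 0)) stop("rate_ci: deaths must be >= 0")
  stopifnot(level > 0, level < 1)
  n <- max(length(deaths), length(person_years))
  deaths <- rep_len(deaths, n)
  person_years <- rep_len(person_years, n)
  z <- qnorm(1 - (1 - level) / 2)
  rate <- deaths / person_years * 1000
  lower <- ifelse(deaths > 0, rate * exp(-z / sqrt(deaths)), 0)
  upper <- ifelse(deaths > 0, rate * exp(z / sqrt(deaths)),
                  -log((1 - level) / 2) / person_years * 1000)
  data.frame(lower = lower, upper = upper)
}

death_column <- function(cause) {
  cause <- match.arg(cause, c("cvd", "primary_cancer", "any_cancer",
                              "other_cancer", "other"))
  paste0("d_", cause)
}

#' Fit cause-specific rate curves over time-since-diagnosis bands
#'
#' Fits a log-linear Poisson model for one cancer site and one
#' cause-of-death outcome over the cells of a person-time table, with
#' categorical band and age-group effects, and predicts rates per 1,000
#' person-years at the band midpoints.
#'
#' With `age_interaction = TRUE` (default) the model is saturated within
#' each age stratum — one parameter per age x band cell — so the
#' maximum-likelihood prediction is the closed-form crude rate
#' `deaths / person-years`; this is the age-stratified prediction used for
#' crossover estimation. With `age_interaction = FALSE` a main-effects
#' model (`~ band + age_group`, log person-years offset) is fitted by
#' iteratively reweighted least squares via [stats::glm()] (convergence at
#' relative deviance change 1e-10 within 100 iterations, non-convergence
#' is an error), and an age stratum's predictions combine the shared band
#' effects with that stratum's age effect.
#'
#' Cells with zero person-years are flagged `defined = FALSE` and carry
#' `NA` rates — never zero, which would corrupt crossover detection.
#'
#' @param table a [tabulate_person_time()] result.
#' @param site cancer site to fit (must be present in the table).
#' @param cause outcome: `"cvd"`, `"primary_cancer"`, `"any_cancer"`,
#'   `"other_cancer"` or `"other"`.
#' @param age_interaction saturated-in-age fits (default) versus shared
#'   band effects across age groups.
#' @param level confidence level for the per-band intervals (saturated fit:
#'   [rate_ci()]; main-effects fit: Wald interval on the linear predictor).
#' @param sex which sex stratum of the table to use (default `"all"`).
#' @return a `rate_curve` data frame, one row per age group x band:
#'   `site`, `age_group`, `sex`, `cause`, `band`, `midpoint`, `deaths`,
#'   `py`, `rate`, `lower`, `upper`, `defined`.
#' @export
fit_rates <- function(table, site, cause, age_interaction = TRUE,
                      level = 0.95, sex = "all") {
  stopifnot(inherits(table, "person_time_table"))
  dcol <- death_column(cause)
  sub <- table[table$site == site & table$sex == sex, , drop = FALSE]
  if (nrow(sub) == 0L) stop("fit_rates: site '", site, "' (sex '", sex,
                            "') not present in the person-time table")
  if (all(sub$py <= 0)) {
    stop("fit_rates: zero person-years in every band for site '", site, "'")
  }
  sub <- sub[order(sub$age_group, sub$band), , drop = FALSE]
  d <- sub[[dcol]]
  py <- sub$py
  defined <- py > 0

  rate <- lower <- upper <- rep(NA_real_, nrow(sub))
  if (age_interaction) {
    # saturated in age x band: MLE prediction is the crude rate d / PY
    rate[defined] <- d[defined] / py[defined] * 1000
    ci <- rate_ci(d[defined], py[defined], level)
    lower[defined] <- ci$lower
    upper[defined] <- ci$upper
  } else {
    fit_dat <- data.frame(
      d = d[defined], py = py[defined],
      band = factor(sub$band[defined]),
      age_group = factor(sub$age_group[defined])
    )
    fit <- glm(d ~ band + age_group + offset(log(py)),
               family = poisson(), data = fit_dat,
               control = list(epsilon = 1e-10, maxit = 100))
    if (!fit$converged) {
      stop("fit_rates: IRLS did not converge for site '", site,
           "', cause '", cause, "'")
    }
    nd <- data.frame(band = factor(sub$band[defined]),
                     age_group = factor(sub$age_group[defined]),
                     py = 1000)  # rate per 1,000 person-years
    pr <- predict(fit, newdata = nd, type = "link", se.fit = TRUE)
    z <- qnorm(1 - (1 - level) / 2)
    rate[defined] <- exp(pr$fit)
    lower[defined] <- exp(pr$fit - z * pr$se.fit)
    upper[defined] <- exp(pr$fit + z * pr$se.fit)
  }

  out <- data.frame(
    site = site, age_group = sub$age_group, sex = sex, cause = cause,
    band = sub$band, midpoint = sub$midpoint,
    deaths = d, py = py, rate = rate, lower = lower, upper = upper,
    defined = defined, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("rate_curve", "data.frame")
  attr(out, "level") <- level
  attr(out, "age_interaction") <- age_interaction
  out
}

#' Apply the precision-truncation rule to a rate curve
#'
#' Mirrors the figure convention of suppressing imprecise tails: from the
#' earliest band whose confidence-interval width (upper minus lower)
#' exceeds `max_ci_width` per 1,000 person-years onward, all bands are
#' marked suppressed — including later bands whose own intervals are
#' narrow. Bands with undefined rates (zero person-years) or zero deaths
#' are treated as exceeding any threshold.
#'
#' @param curve a [fit_rates()] result (possibly several strata).
#' @param max_ci_width width threshold per 1,000 person-years (default 50).
#' @return the curve with a logical `suppressed` column and a
#'   `"truncation_index"` attribute (named by stratum; `NA` when nothing
#'   is suppressed).
#' @export
truncate_curve <- function(curve, max_ci_width = 50) {
  stopifnot(inherits(curve, "rate_curve"))
  if (any(curve$defined & is.na(curve$lower))) {
    stop("truncate_curve: curve has no confidence intervals")
  }
  key <- paste(curve$site, curve$age_group, curve$sex, curve$cause, sep = "|")
  curve$suppressed <- FALSE
  trunc_idx <- setNames(rep(NA_integer_, length(unique(key))), unique(key))
  for (k in unique(key)) {
    rows <- which(key == k)
    rows <- rows[order(curve$midpoint[rows])]
    wide <- !curve$defined[rows] | curve$deaths[rows] == 0 |
      (curve$upper[rows] - curve$lower[rows]) > max_ci_width
    first <- which(wide)[1L]
    if (!is.na(first)) {
      curve$suppressed[rows[first:length(rows)]] <- TRUE
      trunc_idx[k] <- first
    }
  }
  attr(curve, "truncation_index") <- trunc_idx
  curve
}
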