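# Competing-risks cohort simulation by exact inversion of the cumulative
# total hazard. All hazards are piecewise linear on the merged breakpoint
# grid (a step function is the zero-slope special case), so the cumulative
# hazard is piecewise quadratic and inverts in closed form.

stratum_key <- function(site, age_group, sex) paste(site, age_group, sex, sep = "|")

# group a flat list of hazard_spec into strata; every stratum must carry
# all four causes exactly once
group_spec_set <- function(specs) {
  if (length(specs) == 0L) stop("simulate_cohort: empty hazard spec set")
  ok <- vapply(specs, inherits, logical(1L), "hazard_spec")
  if (!all(ok)) stop("simulate_cohort: spec set must contain hazard_spec objects")
  keys <- vapply(specs, function(s) stratum_key(s$site, s$age_group, s$sex), "")
  out <- split(specs, keys)
  for (k in names(out)) {
    causes <- sort(vapply(out[[k]], `[[`, "", "cause"))
    if (!identical(causes, sort(mortcross_causes))) {
      stop("simulate_cohort: stratum [", k, "] must specify each of {",
           paste(mortcross_causes, collapse = ", "), "} exactly once; has {",
           paste(causes, collapse = ", "), "}")
    }
  }
  out
}

# draw event times on [entry, horizon] for one stratum by inversion
# coefs: list per cause of pw_coefs on a shared grid
invert_event_times <- function(n, grid, coefs) {
  lo <- grid[-length(grid)]
  hi <- grid[-1L]
  a0 <- Reduce(`+`, lapply(coefs, `[[`, "a0"))
  a1 <- Reduce(`+`, lapply(coefs, `[[`, "a1"))
  hinc <- a0 * (hi - lo) + a1 / 2 * (hi^2 - lo^2)
  hcum <- c(0, cumsum(hinc))
  e <- rexp(n)
  k <- findInterval(e, hcum)            # ties resolve rightward: flat pieces skipped
  np <- length(lo)
  has_event <- k <= np & e < hcum[np + 1L]
  t <- rep(NA_real_, n)
  if (any(has_event)) {
    ki <- k[has_event]
    s <- lo[ki]
    lam_s <- a0[ki] + a1[ki] * s
    r <- e[has_event] - hcum[ki]
    disc <- pmax(lam_s^2 + 2 * a1[ki] * r, 0)
    den <- lam_s + sqrt(disc)
    u <- ifelse(den > 0, 2 * r / den, 0)
    t[has_event] <- pmin(pmax(s + u, s), hi[ki])
  }
  t
}

#' Simulate a competing-risks cancer-survivor cohort
#'
#' Draws individual follow-up histories under known cause-specific hazards.
#' For each person, a latent all-cause event time on `[entry, horizon]` is
#' sampled by exact inversion of the cumulative total hazard
#' \eqn{\Lambda(t) = \sum_c \Lambda_c(t)} (piecewise quadratic, closed-form
#' roots); the cause of death is then drawn with probability
#' \eqn{\lambda_c(t)/\sum_c \lambda_c(t)} at the realised time. An
#' administrative censoring time is drawn per person (emulating staggered
#' diagnosis dates against a fixed study end); whoever's event time exceeds
#' it exits alive. The recorded immediate cause equals the underlying cause
#' except with probability `p_disagree`, when a random different cause is
#' recorded (emulating death-certificate discordance probed by the
#' immediate-cause sensitivity analysis).
#'
#' @param specs flat list of [hazard_spec()]; every stratum present must be
#'   fully specified (all four causes).
#' @param n_per_stratum persons per stratum: a single count, or a named
#'   vector keyed `"site|age_group|sex"`.
#' @param horizon administrative end of follow-up in years since diagnosis
#'   (at most 25).
#' @param seed integer seed; identical seed and specs give an identical
#'   cohort.
#' @param entry cohort entry in years since diagnosis (default 1: survivors
#'   alive one year after diagnosis).
#' @param cens_window range (years of potential follow-up from entry) of the
#'   per-person uniform administrative censoring draw; a length-1 value
#'   gives fixed censoring, `NULL` censors at the horizon only.
#' @param p_disagree probability that the immediate cause differs from the
#'   underlying cause.
#' @param p_female named probability of female sex by site, used for strata
#'   whose spec sex is `"all"`; unnamed sites default to 0.5 (breast and
#'   uterus to 1, prostate to 0).
#' @return a `cohort` data frame: `person_id, site, sex, age_group,
#'   entry_years, exit_years, died, underlying_cause, immediate_cause`.
#' @examples
#' hz <- linear_crossing_hazards(t_cross = 8)
#' coh <- simulate_cohort(hz$specs, n_per_stratum = 500, seed = 1)
#' table(coh$underlying_cause[coh$died])
#' @export
simulate_cohort <- function(specs, n_per_stratum, horizon = 25, seed = NULL,
                            entry = 1, cens_window = c(5, 24),
                            p_disagree = 0.05, p_female = NULL) {
  if (!(horizon > 1 && horizon <= 25)) {
    stop("simulate_cohort: horizon must lie in (1, 25] years since diagnosis")
  }
  strata <- group_spec_set(specs)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(cens_window)) {
    cens_window <- as.numeric(cens_window)
    if (length(cens_window) == 1L) cens_window <- rep(cens_window, 2L)
    stopifnot(length(cens_window) == 2L, cens_window[1L] <= cens_window[2L],
              cens_window[1L] > 0)
  }
  pf_default <- c(breast = 1, uterus = 1, prostate = 0)
  out <- vector("list", length(strata))
  id0 <- 0L
  for (i in seq_along(strata)) {
    st <- strata[[i]]
    key <- names(strata)[i]
    n <- if (length(n_per_stratum) == 1L && is.null(names(n_per_stratum))) {
      as.integer(n_per_stratum)
    } else {
      if (is.na(match(key, names(n_per_stratum)))) {
        stop("simulate_cohort: n_per_stratum has no entry for stratum [", key, "]")
      }
      as.integer(n_per_stratum[[key]])
    }
    if (n < 1L) stop("simulate_cohort: n_per_stratum must be >= 1 for stratum [", key, "]")
    site <- st[[1L]]$site; age <- st[[1L]]$age_group; sex0 <- st[[1L]]$sex

    grid <- merge_breaks(st, entry, horizon)
    st <- st[order(match(vapply(st, `[[`, "", "cause"), mortcross_causes))]
    coefs <- lapply(st, pw_coefs, grid = grid)
    names(coefs) <- vapply(st, `[[`, "", "cause")

    tev <- invert_event_times(n, grid, coefs)

    cens <- if (is.null(cens_window)) rep(horizon, n) else {
      pmin(entry + runif(n, cens_window[1L], cens_window[2L]), horizon)
    }
    died <- !is.na(tev) & tev <= cens
    exit <- ifelse(died, tev, cens)

    ucause <- rep(NA_character_, n)
    if (any(died)) {
      td <- tev[died]
      k <- findInterval(td, grid, rightmost.closed = TRUE)
      k[k < 1L] <- 1L
      lam <- vapply(coefs, function(pc) pc$a0[k] + pc$a1[k] * td,
                    numeric(sum(died)))
      lam <- matrix(lam, nrow = sum(died))
      tot <- rowSums(lam)
      # degenerate tot == 0 cannot occur at a sampled event time
      r2 <- runif(sum(died)) * tot
      cum <- lam
      for (j in 2:4) cum[, j] <- cum[, j - 1L] + lam[, j]
      ci <- 1L + (r2 > cum[, 1L]) + (r2 > cum[, 2L]) + (r2 > cum[, 3L])
      ucause[died] <- mortcross_causes[ci]
    }
    icause <- ucause
    if (any(died) && p_disagree > 0) {
      flip <- died & runif(n) < p_disagree
      if (any(flip)) {
        icause[flip] <- vapply(ucause[flip], function(cz) {
          sample(setdiff(mortcross_causes, cz), 1L)
        }, "")
      }
    }

    sex <- if (sex0 == "all") {
      pf <- if (!is.null(p_female) && site %in% names(p_female)) {
        p_female[[site]]
      } else if (site %in% names(pf_default)) pf_default[[site]] else 0.5
      ifelse(runif(n) < pf, "female", "male")
    } else rep(sex0, n)

    out[[i]] <- data.frame(
      person_id = id0 + seq_len(n),
      site = site, sex = sex, age_group = age,
      entry_years = entry, exit_years = exit,
      died = died,
      underlying_cause = ucause, immediate_cause = icause,
      stringsAsFactors = FALSE
    )
    id0 <- id0 + n
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cohort", "data.frame")
  res
}

#' Linear cardiovascular/cancer hazards with a known crossover
#'
#' Convenience generator for simulation studies: a stratum where the
#' cardiovascular hazard rises linearly and the primary-cancer hazard falls
#' linearly so that the two are exactly equal at `t_cross` years since
#' diagnosis (the analytic crossover an estimator should recover). The
#' cancer hazard is floored at zero past its zero-crossing, which lies
#' beyond `t_cross` and so never moves the first crossover.
#'
#' @param t_cross target crossover time, years since diagnosis (in (1, 25)).
#' @param rate_at_cross common rate where the curves meet, per 1,000
#'   person-years.
#' @param cvd_at_entry,cancer_at_entry rates at 1 year since diagnosis, per
#'   1,000 person-years; requires `cvd_at_entry < rate_at_cross <
#'   cancer_at_entry`.
#' @param other_cancer_rate,other_rate constant hazards of the two remaining
#'   competing causes, per 1,000 person-years.
#' @param site,age_group,sex stratum labels.
#' @return list with `specs` (the four [hazard_spec()]s) and `t_cross`
#'   (echoed, also recomputed via [true_crossover()] as a guard).
#' @export
linear_crossing_hazards <- function(t_cross, rate_at_cross = 12,
                                    cvd_at_entry = 2, cancer_at_entry = 40,
                                    other_cancer_rate = 1, other_rate = 3,
                                    site = "site1", age_group = "60-79",
                                    sex = "all") {
  stopifnot(t_cross > 1, t_cross < 25,
            cvd_at_entry < rate_at_cross, rate_at_cross < cancer_at_entry)
  s_cvd <- (rate_at_cross - cvd_at_entry) / (t_cross - 1)
  s_can <- (rate_at_cross - cancer_at_entry) / (t_cross - 1)  # negative
  cvd_end <- cvd_at_entry + s_cvd * 24
  t_zero <- t_cross - rate_at_cross / s_can                   # cancer hits 0
  if (t_zero < 25) {
    can_breaks <- c(1, t_zero, 25); can_vals <- c(cancer_at_entry, 0, 0)
  } else {
    can_breaks <- c(1, 25); can_vals <- c(cancer_at_entry, cancer_at_entry + s_can * 24)
  }
  mk <- function(cause, breaks, values, form = "linear") {
    hazard_spec(cause, breaks, values / 1000, form = form,
                site = site, age_group = age_group, sex = sex)
  }
  specs <- list(
    mk("cvd", c(1, 25), c(cvd_at_entry, cvd_end)),
    mk("primary_cancer", can_breaks, can_vals),
    mk("other_cancer", c(1, 25), other_cancer_rate, form = "constant"),
    mk("other", c(1, 25), other_rate, form = "constant")
  )
  tc <- true_crossover(specs[[1L]], specs[[2L]], horizon = 25)
  list(specs = specs, t_cross = tc)
}

#' Hazard presets for a multi-site survivor cohort
#'
#' The `"multisite"` preset covers nine common cancer sites by three
#' age-at-diagnosis strata, with primary-cancer mortality declining over
#' time since diagnosis (steeply for lung, colorectal, bladder and uterus;
#' gently for breast and prostate) and cardiovascular mortality rising with
#' both time and age — low and flat in the 40-59 stratum, strongly rising
#' in the 80+ stratum. Second-cancer and other-cause hazards act as
#' additional competing risks. Stratum sizes default to the shipped
#' population-denominator fixture, scaled by `n_scale`; the female fraction
#' per site is taken from the same fixture. All hazard values are
#' illustrative: they reproduce the qualitative pattern (crossovers within
#' 20 years for most sites in the older strata, none for the young except
#' possibly late), not any site's real rates.
#'
#' @param preset preset name; only `"multisite"`.
#' @param n_scale multiplier applied to the fixture's per-stratum cohort
#'   sizes (minimum 1 person per stratum).
#' @return list with `specs` (flat list of [hazard_spec()]),
#'   `n_per_stratum` (named vector keyed `"site|age_group|all"`), and
#'   `p_female` (named by site).
#' @export
preset_hazards <- function(preset = "multisite", n_scale = 1) {
  preset <- match.arg(preset)
  # per 1,000 person-years at entry (t = 1) and at 25 years
  primary <- list(                       #  start, end
    lung       = c(250, 10), colorectal = c(90, 8), bladder = c(60, 5),
    leukemia   = c(60, 10),  nhl        = c(55, 8), melanoma = c(30, 3),
    uterus     = c(35, 2),   breast     = c(18, 6), prostate = c(14, 6)
  )
  primary_age_mult <- c("40-59" = 0.8, "60-79" = 1.0, "80+" = 1.6)
  cvd <- list("40-59" = c(1, 4), "60-79" = c(6, 30), "80+" = c(25, 110))
  other_cancer <- c("40-59" = 2, "60-79" = 5, "80+" = 8)
  other <- list("40-59" = c(2, 6), "60-79" = c(8, 25), "80+" = c(30, 100))

  fx <- fixture_table1()
  specs <- list()
  n_per <- numeric(0)
  for (site in mortcross_sites) {
    for (age in mortcross_age_groups) {
      pm <- primary[[site]] * primary_age_mult[[age]]
      specs <- c(specs, list(
        hazard_spec("primary_cancer", c(1, 25), pm / 1000,
                    site = site, age_group = age),
        hazard_spec("cvd", c(1, 25), cvd[[age]] / 1000,
                    site = site, age_group = age),
        hazard_spec("other_cancer", c(1, 25), other_cancer[[age]] / 1000,
                    form = "constant", site = site, age_group = age),
        hazard_spec("other", c(1, 25), other[[age]] / 1000,
                    site = site, age_group = age)
      ))
      nrow_fx <- fx$margins[fx$margins$site == site & fx$margins$age_group == age, ]
      n_per[stratum_key(site, age, "all")] <-
        max(1L, as.integer(round(nrow_fx$individuals * n_scale)))
    }
  }
  site_tot <- tapply(fx$margins$individuals, fx$margins$site, sum)
  site_fem <- tapply(fx$margins$female, fx$margins$site, sum)
  p_female <- as.numeric(site_fem / site_tot)
  names(p_female) <- names(site_tot)
  list(specs = specs, n_per_stratum = n_per, p_female = p_female)
}
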