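#' @importFrom stats runif rexp quantile qnorm glm poisson predict coef logLik optim setNames ks.test
#' @importFrom utils packageVersion head tail
NULL

#' Recognised cause-of-death categories
#'
#' The four mutually exclusive underlying-cause categories used throughout:
#' cardiovascular disease, the primary cancer (the person's own site), a
#' second cancer at another site, and everything else (the competing "other"
#' cause). "Any cancer" is a derived outcome: primary plus other cancer.
#'
#' @export
mortcross_causes <- c("cvd", "primary_cancer", "other_cancer", "other")

#' The nine cancer sites of the survivor cohort
#'
#' Site labels used by the simulator presets and the shipped denominator
#' fixture (bladder, breast, colorectal, leukemia, lung, melanoma,
#' non-Hodgkin lymphoma, prostate, uterus).
#'
#' @export
mortcross_sites <- c("bladder", "breast", "colorectal", "leukemia", "lung",
                     "melanoma", "nhl", "prostate", "uterus")

#' Age-at-diagnosis strata
#' @export
mortcross_age_groups <- c("40-59", "60-79", "80+")

#' Define a piecewise cause-specific hazard
#'
#' A hazard specification gives the cause-specific mortality hazard
#' \eqn{\lambda_c(t)} in events per person-year as a function of time since
#' diagnosis, on the interval spanned by `breaks` (within 1 to 25 years).
#' Two forms are supported, both with closed-form cumulative hazards so that
#' event times can be sampled by exact inversion:
#'
#' * `"linear"`: `values` has one entry per breakpoint and the hazard is
#'   linearly interpolated between consecutive breakpoints;
#' * `"constant"`: `values` has one entry per interval between breakpoints
#'   and the hazard is a step function (right-continuous).
#'
#' @param cause one of `mortcross_causes`.
#' @param breaks strictly increasing breakpoints in years since diagnosis,
#'   all within \[1, 25\]; the hazard is defined on `[min(breaks), max(breaks)]`.
#' @param values non-negative hazard values in events per person-year;
#'   length `length(breaks)` for `form = "linear"`, `length(breaks) - 1`
#'   for `form = "constant"`.
#' @param form `"linear"` or `"constant"`.
#' @param site,age_group,sex stratum key labels; `"all"` means the spec is
#'   not restricted on that axis.
#' @return an object of class `hazard_spec`.
#' @examples
#' # CVD hazard rising from 2 to 26 per 1,000 person-years across follow-up
#' hz <- hazard_spec("cvd", breaks = c(1, 25), values = c(2, 26) / 1000)
#' hazard_rate(hz, c(1, 13, 25)) * 1000
#' @export
hazard_spec <- function(cause, breaks, values,
                        form = c("linear", "constant"),
                        site = "all", age_group = "all", sex = "all") {
  form <- match.arg(form)
  cause <- match.arg(cause, mortcross_causes)
  breaks <- as.numeric(breaks)
  values <- as.numeric(values)
  stratum <- sprintf("site=%s/age=%s/sex=%s", site, age_group, sex)
  if (length(breaks) < 2L || any(diff(breaks) <= 0)) {
    stop("hazard_spec [", stratum, ", cause=", cause,
         "]: breaks must be strictly increasing (>= 2 breakpoints)")
  }
  if (breaks[1L] < 1 || breaks[length(breaks)] > 25) {
    stop("hazard_spec [", stratum, ", cause=", cause,
         "]: breaks must lie within [1, 25] years since diagnosis")
  }
  nv <- if (form == "linear") length(breaks) else length(breaks) - 1L
  if (length(values) != nv) {
    stop("hazard_spec [", stratum, ", cause=", cause, "]: expected ",
         nv, " values for form='", form, "', got ", length(values))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("hazard_spec [", stratum, ", cause=", cause,
         "]: hazard values must be finite and non-negative")
  }
  structure(
    list(cause = cause, breaks = breaks, values = values, form = form,
         site = site, age_group = age_group, sex = sex),
    class = "hazard_spec"
  )
}

#' @export
print.hazard_spec <- function(x, ...) {
  cat(sprintf("<hazard_spec> cause=%s form=%s stratum=(%s, %s, %s)\n",
              x$cause, x$form, x$site, x$age_group, x$sex))
  cat("  breaks:", paste(format(x$breaks), collapse = ", "), "\n")
  cat("  values:", paste(format(x$values), collapse = ", "), "(per person-year)\n")
  invisible(x)
}

# Piecewise-linear coefficients of a hazard_spec restricted to a grid.
# `grid` must contain all of spec$breaks and lie within their span.
# Returns a list with lo, hi, a0, a1 vectors: lambda(t) = a0 + a1 * t on
# [lo, hi) (right-continuous; the terminal point takes the last piece).
pw_coefs <- function(spec, grid = spec$breaks) {
  lo <- grid[-length(grid)]
  hi <- grid[-1L]
  # index of the spec piece containing each grid piece (use piece midpoints
  # so boundary fp noise cannot flip the assignment)
  mid <- (lo + hi) / 2
  k <- findInterval(mid, spec$breaks, rightmost.closed = TRUE)
  k[k < 1L] <- 1L
  k[k > length(spec$breaks) - 1L] <- length(spec$breaks) - 1L
  if (spec$form == "constant") {
    a0 <- spec$values[k]
    a1 <- rep(0, length(k))
  } else {
    b0 <- spec$breaks[k]
    b1 <- spec$breaks[k + 1L]
    a1 <- (spec$values[k + 1L] - spec$values[k]) / (b1 - b0)
    a0 <- spec$values[k] - a1 * b0
  }
  list(lo = lo, hi = hi, a0 = a0, a1 = a1)
}

#' Evaluate a piecewise hazard
#'
#' @param spec a [hazard_spec()].
#' @param t times in years since diagnosis (within the spec's break span).
#' @return hazard values in events per person-year. Step-function specs are
#'   right-continuous; the terminal breakpoint takes the last piece's value.
#' @export
hazard_rate <- function(spec, t) {
  stopifnot(inherits(spec, "hazard_spec"))
  if (any(t < spec$breaks[1L] - 1e-12) ||
      any(t > spec$breaks[length(spec$breaks)] + 1e-12)) {
    stop("hazard_rate: t outside the spec's domain [",
         spec$breaks[1L], ", ", spec$breaks[length(spec$breaks)], "]")
  }
  pc <- pw_coefs(spec)
  k <- findInterval(t, spec$breaks, rightmost.closed = TRUE)
  k[k < 1L] <- 1L
  k[k > length(pc$a0)] <- length(pc$a0)
  pc$a0[k] + pc$a1[k] * t
}

# union grid over several specs, clipped to [lo, hi]
merge_breaks <- function(specs, lo = NULL, hi = NULL) {
  g <- sort(unique(unlist(lapply(specs, `[[`, "breaks"))))
  if (!is.null(lo) || !is.null(hi)) {
    lo <- if (is.null(lo)) g[1L] else lo
    hi <- if (is.null(hi)) g[length(g)] else hi
    g <- sort(unique(c(lo, g[g > lo & g < hi], hi)))
  }
  g
}

#' Exact crossover time of two piecewise hazards
#'
#' Finds the earliest time in `[1, horizon]` at which hazard `spec_a` reaches
#' hazard `spec_b` from below and exceeds it immediately afterwards — the
#' analytic ground truth against which the interpolation-based crossover
#' estimator can be judged on simulated cohorts. The difference
#' \eqn{\lambda_a(t) - \lambda_b(t)} is linear on each piece of the merged
#' breakpoint grid, so roots are found in closed form; a jump of the
#' difference from negative (left limit) to non-negative across a breakpoint
#' of a step-function spec counts as a crossover at that breakpoint.
#'
#' @param spec_a,spec_b two [hazard_spec()] objects on the same stratum
#'   (conventionally `spec_a` is the cardiovascular hazard).
#' @param horizon upper end of the search window, years since diagnosis.
#' @return the crossover time in years, or `NA_real_` if `spec_a` never
#'   overtakes `spec_b` within the horizon.
#' @examples
#' # per 1,000 person-years: cvd = 2 + t, cancer = 20 - t, equal at t = 9
#' cvd <- hazard_spec("cvd", c(1, 19), c(3, 21) / 1000)
#' ca  <- hazard_spec("primary_cancer", c(1, 19), c(19, 1) / 1000)
#' true_crossover(cvd, ca)  # 9
#' @export
true_crossover <- function(spec_a, spec_b, horizon = 25) {
  stopifnot(inherits(spec_a, "hazard_spec"), inherits(spec_b, "hazard_spec"))
  if (!identical(c(spec_a$site, spec_a$age_group, spec_a$sex),
                 c(spec_b$site, spec_b$age_group, spec_b$sex))) {
    stop("true_crossover: specs are on different strata")
  }
  lo <- max(spec_a$breaks[1L], spec_b$breaks[1L])
  hi <- min(spec_a$breaks[length(spec_a$breaks)],
            spec_b$breaks[length(spec_b$breaks)], horizon)
  if (hi <= lo) stop("true_crossover: empty overlap of spec domains and horizon")
  grid <- merge_breaks(list(spec_a, spec_b), lo, hi)
  pa <- pw_coefs(spec_a, grid)
  pb <- pw_coefs(spec_b, grid)
  d0 <- pa$a0 - pb$a0
  d1 <- pa$a1 - pb$a1
  np <- length(d0)
  eps <- 1e-12

  # value of the difference just after time t (t in piece k or at its start)
  exceeds_after <- function(k, t) {
    for (j in k:np) {
      s <- max(t, pa$lo[j])
      v <- d0[j] + d1[j] * s
      if (v > eps) return(TRUE)
      if (v < -eps) return(FALSE)
      # v == 0 at s: slope decides within this piece
      if (d1[j] > eps) return(TRUE)
      if (d1[j] < -eps) return(FALSE)
      # identically zero on the piece: look at the next one
    }
    FALSE
  }

  prev_left <- d0[1L] + d1[1L] * grid[1L]  # no jump possible at the start
  for (k in seq_len(np)) {
    s <- pa$lo[k]; e <- pa$hi[k]
    ds <- d0[k] + d1[k] * s
    de <- d0[k] + d1[k] * e
    # jump crossing at the piece boundary s (step-function specs)
    if (prev_left < -eps && ds >= -eps && exceeds_after(k, s)) return(s)
    # equality at s with the hazard rising through it
    if (abs(ds) <= eps && prev_left <= eps && exceeds_after(k, s)) return(s)
    # interior root: difference rises through zero inside (s, e]
    if (ds < -eps && d1[k] > eps) {
      t0 <- -d0[k] / d1[k]
      if (t0 > s && t0 <= e + eps) {
        t0 <- min(t0, e)
        if (exceeds_after(k, t0)) return(t0)
      }
    }
    prev_left <- de
  }
  NA_real_
}
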