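# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data beyond the study-population margins the package ships.

# four constant cause-specific hazards (per person-year) on [1, 25]
const_specs <- function(cvd = 0, primary_cancer = 0, other_cancer = 0,
                        other = 0, site = "site1", age_group = "60-79",
                        sex = "all") {
  vals <- c(cvd = cvd, primary_cancer = primary_cancer,
            other_cancer = other_cancer, other = other)
  lapply(names(vals), function(cz) {
    hazard_spec(cz, c(1, 25), vals[[cz]], form = "constant",
                site = site, age_group = age_group, sex = sex)
  })
}

# random synthetic follow-up records (not from the simulator) for
# splitting/conservation properties
random_records <- function(n, seed = 1, horizon = 25) {
  set.seed(seed)
  entry <- 1
  exit <- entry + runif(n, min = 1e-3, max = horizon - entry)
  died <- runif(n) < 0.5
  cause <- ifelse(died, sample(mortcross_causes, n, replace = TRUE),
                  NA_character_)
  data.frame(
    person_id = seq_len(n),
    site = sample(c("lung", "breast"), n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    age_group = sample(mortcross_age_groups, n, replace = TRUE),
    entry_years = entry, exit_years = exit, died = died,
    underlying_cause = cause, immediate_cause = cause,
    stringsAsFactors = FALSE
  )
}

# hand-built person-time table (single site, sex "all")
make_pt <- function(cells, scheme = band_scheme()) {
  need <- c("site", "age_group", "band", "py", "d_cvd", "d_primary_cancer",
            "d_other_cancer", "d_other")
  for (col in setdiff(need, names(cells))) cells[[col]] <- 0
  cells$sex <- if (is.null(cells$sex)) "all" else cells$sex
  cells$d_any_cancer <- cells$d_primary_cancer + cells$d_other_cancer
  cells$n_persons <- if (is.null(cells$n_persons)) 0 else cells$n_persons
  cells <- merge(cells, scheme[, c("band", "lo", "hi", "midpoint")],
                 by = "band")
  cells <- cells[order(cells$site, cells$age_group, cells$band), ]
  rownames(cells) <- NULL
  attr(cells, "scheme") <- scheme
  attr(cells, "cause_field") <- "underlying"
  class(cells) <- c("person_time_table", "data.frame")
  cells
}

# minimal single-stratum rate curve for find_crossover()
make_curve <- function(midpoint, rate, cause = "cvd", defined = TRUE,
                       site = "site1", age_group = "60-79", sex = "all") {
  data.frame(site = site, age_group = age_group, sex = sex, cause = cause,
             band = seq_along(midpoint), midpoint = midpoint,
             deaths = NA_real_, py = NA_real_, rate = rate,
             lower = NA_real_, upper = NA_real_,
             defined = rep_len(defined, length(midpoint)),
             stringsAsFactors = FALSE)
}

# brute-force crossover of the piecewise-linear interpolants through
# (m, cvd) and (m, cancer): first grid point (step `step`) where the
# difference turns non-negative after being negative
grid_crossover <- function(m, cvd, cancer, horizon = 20, step = 1e-5) {
  d_mid <- cvd - cancer
  if (d_mid[1L] >= 0) return(NA_real_)  # nothing to bracket from below
  i <- which(d_mid[-length(d_mid)] < 0 & d_mid[-1L] >= 0)[1L]
  if (is.na(i)) return(NA_real_)
  tt <- seq(m[i], m[i + 1L], by = step)
  dv <- stats::approx(m, cvd, tt)$y - stats::approx(m, cancer, tt)$y
  j <- which(dv >= 0)[1L]
  if (is.na(j)) return(NA_real_)
  t0 <- tt[j]
  if (t0 > horizon) NA_real_ else t0
}

# fine-grid crossover of two hazard_spec objects (oracle for true_crossover)
grid_hazard_crossover <- function(spec_a, spec_b, horizon = 25, step = 1e-4) {
  lo <- max(spec_a$breaks[1L], spec_b$breaks[1L])
  hi <- min(max(spec_a$breaks), max(spec_b$breaks), horizon)
  tt <- seq(lo, hi, by = step)
  d <- hazard_rate(spec_a, tt) - hazard_rate(spec_b, tt)
  neg_seen <- cumsum(d < -1e-15) > 0
  j <- which(d >= 0 & neg_seen)[1L]
  if (is.na(j)) {
    # equality at the very start counts when the difference rises after
    if (abs(d[1L]) < 1e-15 && length(d) > 1L && d[2L] > 0) return(tt[1L])
    return(NA_real_)
  }
  tt[j]
}
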