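one_record <- function(exit, died = FALSE, cause = NA_character_) {
  data.frame(person_id = 1L, site = "lung", sex = "male", age_group = "60-79",
             entry_years = 1, exit_years = exit, died = died,
             underlying_cause = cause, immediate_cause = cause,
             stringsAsFactors = FALSE)
}

test_that("follow-up splits across bands with the death in the exit band", {
  sp <- split_followup(one_record(6.2, died = TRUE, cause = "cvd"))
  expect_equal(sp$band, 1:5)
  expect_equal(sp$py, c(1, 1, 1, 1, 1.2))
  expect_equal(sp$death, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("band boundaries follow the half-open convention", {
  # censored exactly at a boundary: no time in the right-hand band
  sp <- split_followup(one_record(2.0))
  expect_equal(sp$band, 1L)
  expect_equal(sp$py, 1.0)
  # a death at exactly 2.0 belongs to [2,3) even with zero time there
  spd <- split_followup(one_record(2.0, died = TRUE, cause = "cvd"))
  expect_equal(spd$band, c(1L, 2L))
  expect_equal(spd$py, c(1, 0))
  expect_equal(spd$death, c(FALSE, TRUE))
  # terminal boundary is closed: a death at 25 sits in the last band
  spt <- split_followup(one_record(25, died = TRUE, cause = "cvd"))
  expect_equal(spt$band[spt$death], 7L)
})

test_that("banded person-years re-sum to exit minus entry for random records", {
  rec <- random_records(10000, seed = 31)
  sp <- split_followup(rec)
  tot <- tapply(sp$py, sp$person_id, sum)
  expect_true(all(abs(tot[as.character(rec$person_id)] -
                        (rec$exit_years - rec$entry_years)) <= 1e-9))
  # exactly one death row per dead person
  deaths <- tapply(sp$death, sp$person_id, sum)
  expect_equal(as.vector(deaths[as.character(rec$person_id)]),
               as.integer(rec$died))
})

test_that("splitting rejects follow-up outside the scheme", {
  expect_error(split_followup(one_record(26)), "beyond band coverage")
  rec <- one_record(5); rec$entry_years <- 0.5
  expect_error(split_followup(rec), "entry before")
})

test_that("other-cancer deaths count toward any-cancer but not the primary", {
  rec <- rbind(one_record(7, died = TRUE, cause = "other_cancer"),
               one_record(8))
  rec$person_id <- 1:2
  pt <- tabulate_person_time(rec)
  cell <- pt[pt$band == 5, ]
  expect_equal(cell$d_any_cancer, 1)
  expect_equal(cell$d_primary_cancer, 0)
  expect_equal(cell$d_other_cancer, 1)
})

test_that("a survivor-only cohort has person-years but no deaths", {
  rec <- random_records(200, seed = 8)
  rec$died <- FALSE
  rec$underlying_cause <- rec$immediate_cause <- NA_character_
  pt <- tabulate_person_time(rec)
  expect_true(all(pt[, c("d_cvd", "d_primary_cancer", "d_other_cancer",
                         "d_other")] == 0))
  expect_gt(sum(pt$py), 0)
})

test_that("tabulated cause counts equal direct counts on simulated records", {
  hz <- linear_crossing_hazards(8)
  coh <- simulate_cohort(hz$specs, 1000, seed = 13)
  pt <- tabulate_person_time(coh)
  expect_equal(sum(pt$d_cvd), sum(coh$underlying_cause == "cvd", na.rm = TRUE))
  expect_equal(sum(pt$d_primary_cancer),
               sum(coh$underlying_cause == "primary_cancer", na.rm = TRUE))
  expect_equal(sum(pt$d_cvd + pt$d_any_cancer + pt$d_other), sum(coh$died))
  expect_equal(sum(pt$py), sum(coh$exit_years - coh$entry_years),
               tolerance = 1e-9)
  # every cell respects the containment d_any_cancer >= d_primary_cancer
  expect_true(all(pt$d_any_cancer >= pt$d_primary_cancer))
  # immediate-cause tabulation counts the immediate labels instead
  pti <- tabulate_person_time(coh, cause_field = "immediate")
  expect_equal(sum(pti$d_cvd), sum(coh$immediate_cause == "cvd", na.rm = TRUE))
})

test_that("tabulation is invariant to record order and completes the grid", {
  rec <- random_records(500, seed = 17)
  pt1 <- tabulate_person_time(rec)
  set.seed(1)
  pt2 <- tabulate_person_time(rec[sample.int(nrow(rec)), ])
  expect_equal(pt1, pt2)
  # all 7 bands present for every stratum even when empty
  counts <- table(pt1$site, pt1$age_group)
  expect_true(all(counts == 7))
})

test_that("sex stratification appends per-sex cells consistent with the pool", {
  rec <- random_records(400, seed = 23)
  pt <- tabulate_person_time(rec, stratify_sex = TRUE)
  expect_setequal(unique(pt$sex), c("all", "female", "male"))
  pool <- pt[pt$sex == "all", ]
  bysex <- stats::aggregate(py ~ site + age_group + band,
                            data = pt[pt$sex != "all", ], FUN = sum)
  m <- merge(pool, bysex, by = c("site", "age_group", "band"))
  expect_equal(m$py.x, m$py.y, tolerance = 1e-9)
})

test_that("unknown cause labels abort tabulation with the offending ids", {
  rec <- random_records(20, seed = 2)
  rec$died[3] <- TRUE
  rec$underlying_cause[3] <- "mystery"
  rec$immediate_cause[3] <- "cvd"
  err <- tryCatch(tabulate_person_time(rec), error = conditionMessage)
  expect_match(err, "person_id 3")
})

test_that("margins validate against expected counts and flag perturbations", {
  fx <- fixture_table1()
  rep_ok <- validate_margins(fx$margins, fx$margins,
                             totals = fx$totals[c("individuals", "female",
                                                  "cvd_deaths")])
  expect_true(attr(rep_ok, "pass"))
  bad <- fx$margins
  bad$cvd_deaths[5] <- bad$cvd_deaths[5] + 1
  rep_bad <- validate_margins(fx$margins, bad)
  expect_false(attr(rep_bad, "pass"))
  expect_equal(sum(!rep_bad$pass), 1L)
  # empty expectations pass vacuously
  rep_empty <- validate_margins(fx$margins, fx$margins[0, ])
  expect_true(attr(rep_empty, "pass"))
  expect_equal(nrow(rep_empty), 0L)
})

test_that("cohort margins reproduce direct counts", {
  rec <- random_records(300, seed = 41)
  m <- cohort_margins(rec)
  expect_equal(sum(m$individuals), 300)
  expect_equal(sum(m$female), sum(rec$sex == "female"))
  expect_equal(sum(m$cvd_deaths),
               sum(rec$died & rec$underlying_cause == "cvd", na.rm = TRUE))
  expect_true(all(m$all_cancer_deaths >= m$primary_cancer_deaths))
})
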