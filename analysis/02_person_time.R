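#!/usr/bin/env Rscript
# Step 2 — split follow-up into time-since-diagnosis bands.
#
# Lexis-splits every survivor's follow-up over the seven survivorship
# bands (1-<2, 2-<3, 3-<4, 4-<5, 5-<10, 10-<15, 15-25 years since
# diagnosis) and tabulates person-years and cause-specific death counts
# per site x age x sex x band cell. Deaths sit in the band containing the
# exit; person-years conserve total follow-up exactly.

library(mortcross)

coh <- read_cohort("scratch/cohort.csv")
pt <- tabulate_person_time(coh, stratify_sex = TRUE)
write.csv(pt, "results/person_time.csv", row.names = FALSE)

pool <- pt[pt$sex == "all", ]
cat(sprintf("tabulated %d cells (%d pooled) over %d bands\n",
            nrow(pt), nrow(pool), length(unique(pt$band))))
cat(sprintf("  person-years: %.0f (conservation check vs cohort: %.2e years)\n",
            sum(pool$py),
            abs(sum(pool$py) - sum(coh$exit_years - coh$entry_years))))
by_band <- aggregate(cbind(py, d_cvd, d_primary_cancer) ~ lo + hi,
                     data = pool, FUN = sum)
cat("  pooled person-years and deaths by band:\n")
print(by_band, row.names = FALSE)
cat("wrote results/person_time.csv\n")
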