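#' @import data.table
NULL

# quiet R CMD check about data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", ".N", ".SD", "person_id", "site", "age_group", "band", "py", "death",
  "cause", "sex", "died", "underlying_cause", "immediate_cause",
  "d_cvd", "d_primary_cancer", "d_other_cancer", "d_any_cancer", "d_other",
  "idx", "dv", "dc", "n_persons"
))
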