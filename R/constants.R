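#' Demographic marginals of the modelled coastal-Guinea population
#'
#' Category probabilities are taken from the published agent counts at
#' N = 100,000 (counts, not the rounded percentage column, so each vector
#' sums to exactly 1).
#'
#' @format a list with elements `gender_split` (probability male),
#'   `education_probs`, `wealth_probs`, `age_probs`, and `income` (median,
#'   q25, q75 in GNF per month).
#' @export
table1_marginals <- list(
  gender_split    = 0.5,
  education_probs = c(none = 0.53422, primary = 0.16642, secondary = 0.29936),
  wealth_probs    = c(poorest = 0.20131, poor = 0.19959, middle = 0.19937,
                      rich = 0.20052, richest = 0.19921),
  age_probs       = c(`5-14` = 0.33261, `15-21` = 0.08264,
                      `22-49` = 0.17547, `50+` = 0.40928),
  income          = c(median = 554986, q25 = 341936, q75 = 842990)
)

#' The four surveyed surgical procedures
#' @export
procedure_levels <- c("laparotomy", "cesarean", "goiter", "mandibulectomy")

education_levels <- names(table1_marginals$education_probs)
wealth_levels    <- names(table1_marginals$wealth_probs)
age_levels       <- names(table1_marginals$age_probs)
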