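# Shared fixtures: toy hospital tables and hand-built facility models.

# Write a hospital-survey CSV from a data.frame of character cells.
write_toy_table <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# A minimal two-hospital survey table, fully known, all procedures offered.
toy_table_df <- function() {
  data.frame(hospital_id = c("X", "Y"),
             mds = c("10", "5"), surgeons = c("2", "4"),
             surgical_officers = c("1", "1"), anesthesia_mds = c("1", "0"),
             anesthetic_officers = c("2", "1"), nurses = c("20", "10"),
             ors = c("2", "1"), cases_total = c("100", "50"),
             cases_general_surgery = c("30", "20"), cases_ob = c("40", "20"),
             cases_ent = c("5", "2"),
             cost_laparotomy = c("400000", "300000"),
             cost_cesarean = c("0", "100000"),
             cost_goiter = c("200000", "250000"),
             cost_mandibulectomy = c("350000", "300000"))
}

# Build a facility model directly from matrices, bypassing the CSV layer.
# prices: J x 4 matrix (NA = not offered), Q: length J, coords: J x 2.
toy_facility <- function(prices, Q, coords) {
  J <- length(Q)
  colnames(prices) <- cashdose::procedure_levels
  ids <- LETTERS[seq_len(J)]
  rownames(prices) <- ids
  structure(list(records = data.frame(hospital_id = ids),
                 Q = setNames(Q, ids), prices = prices,
                 offered = !is.na(prices),
                 coords = cbind(x = coords[, 1], y = coords[, 2])),
            class = "facility_model")
}

# A small population spec for fast engine tests.
toy_spec <- function(n = 2000, seed = 1) {
  population_spec(n_agents = n, seed = seed)
}

# Weight model with all randomness switched off.
fixed_weights <- function(g = 0, d = 0, l = 0, a = 0) {
  weight_model(g_mean = g, g_sd = 0, d_mean = d, d_sd = 0,
               l_mean = l, l_sd = 0, a_home_mean = a, a_home_sd = 0)
}

# Assemble a dose_summary object from per-run overall/subgroup rates, for
# subgroup-analysis tests that construct runs by hand.
fake_summary <- function(rates, subgroup_list) {
  runs <- lapply(seq_along(rates), function(i) {
    structure(list(dose = 0, seed = i, no_show_rate = rates[i],
                   subgroups = subgroup_list[[i]]),
              class = "run_result")
  })
  structure(data.frame(dose = 0, mean = mean(rates),
                       ui_low = NA, ui_high = NA, n_runs = length(rates)),
            runs = runs, class = c("dose_summary", "data.frame"))
}
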