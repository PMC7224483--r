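#' Simulation configuration
#'
#' One run draws a fresh batch of agents (population-level stochasticity),
#' draws their preference weights (parameter-level stochasticity), and
#' simulates one care-seeking choice per agent at a fixed cash-transfer
#' dose. A batch summary aggregates `n_runs` such runs.
#'
#' @param spec a [population_spec()]; its `n_agents` is overridden by
#'   `batch_size`.
#' @param fac a [facility_model()].
#' @param wm a [weight_model()].
#' @param dose cash transfer, GNF.
#' @param batch_size agents per run.
#' @param n_runs number of independent runs.
#' @param master_seed seed from which all per-run seeds are spawned.
#' @param money_form see [money_term()].
#' @export
simulation_config <- function(spec = population_spec(), fac = facility_model(),
                              wm = weight_model(), dose = 0,
                              batch_size = 20000L, n_runs = 50L,
                              master_seed = 1L,
                              money_form = "capped_share") {
  if (batch_size <= 0 || n_runs <= 0)
    stop_config("batch_size and n_runs must be positive")
  structure(list(spec = spec, fac = fac, wm = wm, dose = dose,
                 batch_size = as.integer(batch_size),
                 n_runs = as.integer(n_runs),
                 master_seed = as.integer(master_seed),
                 money_form = money_form),
            class = "simulation_config")
}

subgroup_strata <- c(gender = "gender", education = "education",
                     age = "age_band", wealth = "wealth_quintile")

#' Execute one simulation run
#'
#' Generates a fresh seeded batch population, draws preference weights,
#' simulates every agent's choice at the configured dose, and returns the
#' overall and per-stratum no-show rates (fraction choosing to stay home).
#'
#' @param config a [simulation_config()].
#' @param seed seed for this run (population, weights and choices).
#' @return a `run_result` list: `dose`, `seed`, `no_show_rate`,
#'   `subgroups` (per-stratum rate vectors) and `subgroup_n` (stratum
#'   sizes).
#' @export
run_once <- function(config, seed) {
  spec <- config$spec
  spec$n_agents <- config$batch_size
  pop <- generate_population(spec, seed = seed)
  pop <- cbind(pop, draw_weights(nrow(pop), config$wm))
  choice <- simulate_choices(pop, config$fac, config$dose, config$money_form)
  home <- choice == 0L
  subgroups <- lapply(subgroup_strata, function(col)
    tapply(home, pop[[col]], mean))
  structure(list(dose = config$dose, seed = seed,
                 no_show_rate = mean(home), subgroups = subgroups,
                 subgroup_n = lapply(subgroup_strata, function(col)
                   as.vector(table(pop[[col]])))),
            class = "run_result")
}

#' Empirical percentile uncertainty interval
#'
#' The 95% uncertainty interval of a simulation estimate is the empirical
#' 2.5th-97.5th percentile range across independent runs, using the
#' linear-interpolation quantile definition (R type 7).
#'
#' @param values numeric vector of per-run outcomes (>= 2 values).
#' @param level interval level, default 0.95.
#' @return named vector `c(low, high)`.
#' @export
uncertainty_interval <- function(values, level = 0.95) {
  if (length(values) < 2)
    stop("an uncertainty interval requires at least 2 runs")
  a <- (1 - level) / 2
  setNames(quantile(values, c(a, 1 - a), names = FALSE, type = 7),
           c("low", "high"))
}

#' Run a batch of simulations at one dose and summarize
#'
#' Executes `n_runs` independent [run_once()] calls with seeds spawned
#' deterministically from the master seed, and reports the across-run mean
#' no-show rate with its 95% uncertainty interval.
#'
#' @param config a [simulation_config()].
#' @param seeds optional explicit per-run seed vector (used by the dose
#'   sweep to share seeds across doses); defaults to
#'   `spawn_seeds(config$master_seed, config$n_runs)`.
#' @return a `dose_summary` one-row data.frame `dose, mean, ui_low,
#'   ui_high, n_runs`, with the per-run `run_result`s in attribute `runs`.
#' @export
run_batch <- function(config, seeds = NULL) {
  seeds <- seeds %||% spawn_seeds(config$master_seed, config$n_runs)
  stopifnot(length(seeds) == config$n_runs)
  runs <- lapply(seeds, function(s) run_once(config, s))
  rates <- vapply(runs, `[[`, 0, "no_show_rate")
  ui <- uncertainty_interval(rates)
  structure(data.frame(dose = config$dose, mean = mean(rates),
                       ui_low = ui[["low"]], ui_high = ui[["high"]],
                       n_runs = config$n_runs),
            runs = runs, class = c("dose_summary", "data.frame"))
}

#' Per-run no-show rates of a batch
#' @param summary a `dose_summary` from [run_batch()].
#' @export
run_rates <- function(summary) {
  vapply(attr(summary, "runs"), `[[`, 0, "no_show_rate")
}
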