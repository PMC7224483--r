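test_that("plateau detection finds the first dose of a flat suffix", {
  flat <- structure(data.frame(dose = seq(0, 5e5, 1e5), mean = rep(0.3, 6)),
                    class = c("dose_response_curve", "data.frame"))
  expect_equal(detect_plateau(flat, epsilon = 1e-6)$dose, 0)
  # drops by 0.01 per step up to index k, then exactly flat
  k <- 4
  m <- c(0.5 - 0.01 * (0:(k - 1)), rep(0.5 - 0.01 * (k - 1), 4))
  pc <- structure(data.frame(dose = seq(0, by = 1e4,
                                        length.out = length(m)), mean = m),
                  class = c("dose_response_curve", "data.frame"))
  res <- detect_plateau(pc, epsilon = 0.005)
  expect_equal(res$index, k)
  expect_equal(res$dose, pc$dose[k])
  expect_equal(res$rate, m[k])
  # strictly decreasing to the end: no plateau
  dec <- structure(data.frame(dose = 1:5 * 1e4, mean = 0.5 - 0.02 * (1:5)),
                   class = c("dose_response_curve", "data.frame"))
  expect_true(is.na(detect_plateau(dec, epsilon = 0.005)$dose))
})

test_that("monotone check tolerates noise but rejects real upticks", {
  mk <- function(m) structure(data.frame(dose = seq_along(m), mean = m),
                              class = c("dose_response_curve", "data.frame"))
  expect_true(monotone_check(mk(c(0.5, 0.4, 0.3, 0.3)), tol = 1e-9)$monotone)
  expect_true(monotone_check(mk(c(0.5, 0.401, 0.402, 0.3)), tol = 0.005)$monotone)
  expect_false(monotone_check(mk(c(0.5, 0.3, 0.4, 0.3)), tol = 0.005)$monotone)
})

test_that("single-anchor calibration bisects the home offset", {
  cfg <- simulation_config(spec = toy_spec(), batch_size = 1500L,
                           n_runs = 3L, master_seed = 3L)
  cal <- calibrate(data.frame(dose = 0, rate = 0.5), cfg,
                   tolerance = 0.02, cal_runs = 3L, cal_agents = 1500L)
  expect_true(cal$converged)
  expect_lt(abs(cal$achieved - 0.5), 0.02)
  expect_equal(cal$l_mean, cfg$wm$l_mean) # lambda stays fixed
})

test_that("calibration recovers anchors generated from known parameters", {
  cfg <- simulation_config(spec = toy_spec(), batch_size = 2000L,
                           n_runs = 4L, master_seed = 6L)
  truth <- cfg
  truth$wm$a_home_mean <- -0.4
  truth$wm$l_mean <- 2.5
  seeds <- spawn_seeds(1234L, 4)
  gen_rate <- function(dose) {
    c2 <- truth; c2$dose <- dose
    mean(vapply(seeds, function(s) run_once(c2, s)$no_show_rate, 0))
  }
  anchors <- data.frame(dose = c(0, 280000),
                        rate = c(gen_rate(0), gen_rate(280000)))
  # start the search away from the generating values
  cfg$wm$a_home_mean <- 0.5
  cfg$wm$l_mean <- 1.5
  cal <- calibrate(anchors, cfg, tolerance = 0.015,
                   cal_runs = 4L, cal_agents = 2000L, maxit = 120L)
  expect_true(cal$converged)
  expect_true(all(abs(cal$achieved - anchors$rate) <= 0.015))
})

test_that("failed calibration raises a condition carrying the best fit", {
  cfg <- simulation_config(spec = toy_spec(), batch_size = 800L,
                           n_runs = 2L, master_seed = 2L)
  err <- tryCatch(
    calibrate(data.frame(dose = c(0, 280000), rate = c(0.9, 0.1)), cfg,
              tolerance = 0.005, cal_runs = 2L, cal_agents = 800L,
              maxit = 8L),
    cashdose_calibration_error = function(e) e)
  expect_s3_class(err, "cashdose_calibration_error")
  expect_s3_class(err$best, "calibration_result")
  expect_false(err$best$converged)
})

test_that("sweeps share seeds and the plateau sits at the maximum price", {
  for (case_seed in c(21L, 22L)) {
    set.seed(case_seed)
    J <- 3
    # random toy price table on a 50,000-GNF grid, all procedures offered
    prices <- matrix(sample(seq(1e5, 4e5, by = 5e4), J * 4, TRUE), J, 4)
    fac <- toy_facility(prices, Q = runif(J, 0.2, 0.9),
                        coords = matrix(runif(2 * J, 5, 30), J, 2))
    cfg <- simulation_config(spec = toy_spec(), fac = fac,
                             wm = weight_model(l_mean = 2.5,
                                               a_home_mean = -0.5),
                             batch_size = 1200L, n_runs = 4L,
                             master_seed = case_seed)
    grid <- seq(0, max(prices) + 1e5, by = 5e4)
    curve <- dose_sweep(cfg, grid)
    expect_equal(detect_plateau(curve)$dose, max(prices))
    above <- curve$mean[curve$dose >= max(prices)]
    expect_true(all(above == above[1]))
    expect_true(monotone_check(curve)$monotone)
  }
})

test_that("single-dose grids reduce the sweep to a plain batch", {
  cfg <- simulation_config(spec = toy_spec(), batch_size = 1000L,
                           n_runs = 3L, master_seed = 4L)
  curve <- dose_sweep(cfg, 0)
  b <- run_batch(cfg)
  expect_equal(curve$mean, b$mean)
  expect_equal(curve$ui_low, b$ui_low)
  expect_equal(nrow(curve), 1L)
})

test_that("identical strata produce zero differences and no flags", {
  subs <- replicate(5, list(
    gender = c(male = 0.3, female = 0.3),
    education = c(none = 0.3, primary = 0.3, secondary = 0.3),
    age = c(`5-14` = 0.3, `15-21` = 0.3, `22-49` = 0.3, `50+` = 0.3)),
    simplify = FALSE)
  tab <- subgroup_analysis(fake_summary(rep(0.3, 5), subs))
  expect_true(all(tab$diff_vs_ref == 0))
  expect_false(any(tab$significant))
})

test_that("an impoverished stratum is flagged as significantly different", {
  # engineered population: one education stratum has 10x lower income, so
  # under a positive money weight its price share explodes and it shows up
  fac <- facility_model()
  wm <- weight_model(l_mean = 2.7, a_home_mean = -0.43)
  spec <- population_spec(n_agents = 4000)
  seeds <- spawn_seeds(55L, 6)
  runs <- lapply(seeds, function(s) {
    pop <- generate_population(spec, seed = s)
    pop$income[pop$education == "primary"] <-
      pop$income[pop$education == "primary"] / 10
    pop <- cbind(pop, draw_weights(nrow(pop), wm))
    home <- simulate_choices(pop, fac, t = 0) == 0L
    structure(list(dose = 0, seed = s, no_show_rate = mean(home),
                   subgroups = list(education = tapply(home, pop$education,
                                                       mean))),
              class = "run_result")
  })
  summary <- structure(data.frame(dose = 0,
                                  mean = mean(sapply(runs, `[[`,
                                                     "no_show_rate")),
                                  ui_low = NA, ui_high = NA, n_runs = 6),
                       runs = runs,
                       class = c("dose_summary", "data.frame"))
  tab <- subgroup_analysis(summary, strata = "education")
  poor <- tab[tab$stratum == "primary", ]
  rest <- tab[tab$stratum != "primary", ]
  expect_gt(poor$mean, max(rest$mean)) # lower income, higher no-show
  expect_true(poor$significant)
  # the same engineered gap is unmistakable under the stricter rule too
  tab2 <- subgroup_analysis(summary, strata = "education",
                            rule = "difference_ui")
  expect_true(tab2[tab2$stratum == "primary", "significant"])
})

test_that("empty strata are excluded with a warning", {
  subs <- replicate(3, list(gender = c(male = 0.4, female = NA)),
                    simplify = FALSE)
  expect_warning(tab <- subgroup_analysis(fake_summary(rep(0.4, 3), subs),
                                          strata = "gender"),
                 "female")
  expect_equal(nrow(tab), 1L)
})
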