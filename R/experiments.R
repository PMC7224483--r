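#' Mean no-show rate at given doses under common random numbers
#'
#' Shared helper for calibration and the dose sweep: runs the same seed
#' block at each dose, so dose contrasts are evaluated with common random
#' numbers (same agents, weights and choice variates at every dose).
#'
#' @keywords internal
rates_at_doses <- function(config, doses, seeds) {
  vapply(doses, function(d) {
    cfg <- config; cfg$dose <- d
    mean(vapply(seeds, function(s) run_once(cfg, s)$no_show_rate, 0))
  }, 0)
}

#' Calibrate the weight model to no-show anchors
#'
#' The two free parameters of the choice model -- the stay-home offset
#' mean and the money-weight mean -- are fitted so the simulated mean
#' no-show rate reproduces published anchor rates at given doses
#' (typically the status-quo rate at t = 0 and the rate at t = 280,000
#' GNF). The objective (sum of squared anchor errors, in rate units) is
#' smoothed by evaluating every candidate on one fixed seed block (common
#' random numbers) and minimized by derivative-free Nelder-Mead. With a
#' single anchor the money weight stays fixed and the home offset is found
#' by monotone bisection.
#'
#' @param anchors data.frame with columns `dose` (GNF) and `rate`
#'   (target no-show fraction in `[0, 1]`).
#' @param config a [simulation_config()]; `config$wm` supplies the fixed
#'   `g`/`d` means, all SDs, and the starting values of the fitted means.
#' @param tolerance maximum absolute anchor error for convergence, in rate
#'   units (default 0.015 = 1.5 percentage points).
#' @param cal_runs,cal_agents Monte Carlo budget per objective evaluation.
#' @param maxit Nelder-Mead iteration cap.
#' @return a `calibration_result` list: fitted `wm`, `a_home_mean`,
#'   `l_mean`, `achieved` rates at the anchors, `converged`, `iterations`.
#'   If the fit does not reach tolerance an error condition of class
#'   `cashdose_calibration_error` is signalled, carrying the best-found
#'   parameters in its `$best` field.
#' @export
calibrate <- function(anchors, config, tolerance = 0.015,
                      cal_runs = 10L, cal_agents = 5000L, maxit = 150L) {
  stopifnot(all(c("dose", "rate") %in% names(anchors)), nrow(anchors) >= 1,
            all(anchors$rate >= 0 & anchors$rate <= 1))
  cfg <- config
  cfg$batch_size <- as.integer(cal_agents)
  seeds <- spawn_seeds(config$master_seed, cal_runs)
  with_params <- function(a_home, l) {
    c2 <- cfg
    c2$wm$a_home_mean <- a_home
    c2$wm$l_mean <- l
    c2
  }
  evals <- 0L
  achieved_at <- function(a_home, l) {
    evals <<- evals + 1L
    rates_at_doses(with_params(a_home, l), anchors$dose, seeds)
  }
  if (nrow(anchors) == 1L) {
    # no-show rate is monotone increasing in the home offset
    f <- function(a) achieved_at(a, config$wm$l_mean)[1] - anchors$rate[1]
    root <- uniroot(f, c(-15, 15), tol = 1e-3, extendInt = "upX")
    par <- c(root$root, config$wm$l_mean)
  } else {
    obj <- function(p) sum((achieved_at(p[1], p[2]) - anchors$rate)^2)
    fit <- optim(c(config$wm$a_home_mean, config$wm$l_mean), obj,
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-6))
    par <- fit$par
  }
  achieved <- achieved_at(par[1], par[2])
  converged <- all(abs(achieved - anchors$rate) <= tolerance)
  res <- structure(list(wm = with_params(par[1], par[2])$wm,
                        a_home_mean = par[1], l_mean = par[2],
                        anchors = anchors, achieved = achieved,
                        converged = converged, iterations = evals,
                        tolerance = tolerance),
                   class = "calibration_result")
  if (!converged)
    stop(errorCondition(
      sprintf("calibration did not reach tolerance %.3f (worst error %.4f)",
              tolerance, max(abs(achieved - anchors$rate))),
      best = res, class = c("cashdose_calibration_error", "error")))
  res
}

#' Published no-show anchors used for the default calibration
#'
#' Status-quo no-show of 56.6% with no transfer, and 30.0% at a transfer
#' of 280,000 GNF (consistent with the published ~28% no-show when care
#' itself is free but other costs remain).
#' @export
default_anchors <- function() {
  data.frame(dose = c(0, 280000), rate = c(0.566, 0.300))
}

#' Default cash-transfer dose grid
#'
#' 0 to 1,000,000 GNF in increments of 10,000 GNF (101 doses).
#' @export
default_dose_grid <- function() seq(0, 1e6, by = 1e4)

#' Sweep the cash-transfer dose grid
#'
#' Runs a seed-shared batch at every dose of the grid and collects the
#' per-dose mean no-show rate and 95% uncertainty interval. The same
#' per-run seed block is reused at every dose (common random numbers), so
#' the dose-response contrast is not blurred by between-dose Monte Carlo
#' noise and doses at or above the maximum facility price -- where the
#' capped money term makes utilities invariant -- give bit-identical
#' results.
#'
#' @param config a [simulation_config()] with the calibrated weight model.
#' @param dose_grid increasing dose vector, GNF.
#' @return a `dose_response_curve` data.frame (one `dose_summary` row per
#'   dose) with per-run rate matrix in attribute `run_rates`
#'   (runs x doses).
#' @export
dose_sweep <- function(config, dose_grid = default_dose_grid()) {
  stopifnot(length(dose_grid) >= 1, !is.unsorted(dose_grid, strictly = TRUE))
  seeds <- spawn_seeds(config$master_seed, config$n_runs)
  out <- vector("list", length(dose_grid))
  rates <- matrix(NA_real_, config$n_runs, length(dose_grid))
  for (i in seq_along(dose_grid)) {
    cfg <- config; cfg$dose <- dose_grid[i]
    s <- run_batch(cfg, seeds = seeds)
    rates[, i] <- run_rates(s)
    attr(s, "runs") <- NULL
    out[[i]] <- s
  }
  structure(do.call(rbind, out), run_rates = rates,
            class = c("dose_response_curve", "data.frame"))
}

#' Detect the dose-response plateau
#'
#' Returns the smallest grid dose from which the curve stays flat: all
#' subsequent adjacent changes in mean no-show are below `epsilon` in
#' absolute value. Under the default capped money term and shared seeds
#' the curve is exactly constant above the maximum facility price, so the
#' default `epsilon` asks for that exact flatness.
#'
#' @param curve a `dose_response_curve`.
#' @param epsilon flatness threshold on adjacent changes in the mean
#'   no-show rate.
#' @return list `dose` (NA if no plateau), `rate` at the plateau, `index`.
#' @export
detect_plateau <- function(curve, epsilon = 1e-9) {
  m <- curve$mean
  if (length(m) < 2) return(list(dose = curve$dose[1], rate = m[1], index = 1L))
  flat <- abs(diff(m)) < epsilon
  # smallest index whose whole suffix of adjacent changes is flat
  suffix_flat <- rev(cumprod(rev(flat))) == 1
  if (!suffix_flat[length(suffix_flat)])
    return(list(dose = NA_real_, rate = NA_real_, index = NA_integer_))
  i <- which(!suffix_flat)
  i <- if (length(i)) max(i) + 1L else 1L
  list(dose = curve$dose[i], rate = m[i], index = i)
}

#' Check a dose-response curve for monotone non-increase
#'
#' Fits the antitonic (non-increasing) least-squares regression to the
#' per-dose means and reports the largest absolute deviation of the curve
#' from that fit; the curve counts as monotone when the deviation is
#' within `tol` (Monte Carlo noise allowance).
#'
#' @param curve a `dose_response_curve` (or its subset of doses).
#' @param tol allowed deviation; default one standard error of a per-dose
#'   mean, estimated from the per-run rates.
#' @return list `monotone` (logical), `max_deviation`, `tol`.
#' @export
monotone_check <- function(curve, tol = NULL) {
  m <- curve$mean
  if (is.null(tol)) {
    rr <- attr(curve, "run_rates")
    tol <- if (!is.null(rr)) mean(apply(rr, 2, sd)) / sqrt(nrow(rr)) else 1e-6
  }
  fit <- -isoreg(seq_along(m), -m)$yf
  dev <- max(abs(m - fit))
  list(monotone = dev <= tol, max_deviation = dev, tol = tol)
}

#' Subgroup heterogeneity analysis of batched runs
#'
#' Summarizes per-run subgroup no-show rates by stratum (mean and 95%
#' uncertainty interval across runs) and assesses each stratum's pairwise
#' difference against the first stratum of its variable. Consistent with
#' the model's interval-based reporting, the default significance flag is
#' non-overlap of the two strata's 95% uncertainty intervals
#' (`rule = "ui_overlap"`). The across-run distribution of per-run rate
#' differences is also summarized by its own 95% percentile interval
#' (`diff_low`/`diff_high`); `rule = "difference_ui"` instead flags a
#' stratum when that interval excludes zero -- a more sensitive rule that
#' reacts to structural differences of a fraction of a percentage point.
#' Strata empty in any run are excluded with a warning.
#'
#' @param summary a `dose_summary` from [run_batch()] (with runs attached).
#' @param strata which stratifying variables to analyse.
#' @param rule significance rule, `"ui_overlap"` (default) or
#'   `"difference_ui"`.
#' @return a `subgroup_table` data.frame: `variable, stratum, mean,
#'   ui_low, ui_high, diff_vs_ref, diff_low, diff_high, significant`.
#' @export
subgroup_analysis <- function(summary,
                              strata = c("gender", "education", "age"),
                              rule = c("ui_overlap", "difference_ui")) {
  rule <- match.arg(rule)
  runs <- attr(summary, "runs")
  stopifnot(!is.null(runs), length(runs) >= 2)
  strata <- match.arg(strata, names(subgroup_strata), several.ok = TRUE)
  rows <- list()
  for (v in strata) {
    mat <- do.call(rbind, lapply(runs, function(r) r$subgroups[[v]]))
    bad <- colSums(is.na(mat)) > 0
    if (any(bad)) {
      warning("excluding empty stratum(s) of ", v, ": ",
              paste(colnames(mat)[bad], collapse = ", "))
      mat <- mat[, !bad, drop = FALSE]
    }
    ref <- mat[, 1]
    ref_ui <- uncertainty_interval(ref)
    for (k in seq_len(ncol(mat))) {
      ui <- uncertainty_interval(mat[, k])
      d <- mat[, k] - ref
      dui <- uncertainty_interval(d)
      sig <- k > 1 && switch(rule,
        ui_overlap = ui[["low"]] > ref_ui[["high"]] ||
          ui[["high"]] < ref_ui[["low"]],
        difference_ui = dui[["low"]] > 0 || dui[["high"]] < 0)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, stratum = colnames(mat)[k],
        mean = mean(mat[, k]), ui_low = ui[["low"]], ui_high = ui[["high"]],
        diff_vs_ref = mean(d), diff_low = dui[["low"]],
        diff_high = dui[["high"]], significant = sig)
    }
  }
  structure(do.call(rbind, rows),
            class = c("subgroup_table", "data.frame"))
}
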