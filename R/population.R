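#' Fit the quantized income model
#'
#' Monthly income is modelled as a right-skewed two-parameter log-normal
#' distribution fitted to a target median and interquartile range, then
#' partitioned at its own 20/40/60/80% quantiles into five bands aligned
#' with the wealth quintiles ("quantized" income): agents draw income from
#' the band of their quintile, so wealth rank and income are consistent by
#' construction and the pooled draws recover the full fitted distribution.
#'
#' The fit sets `meanlog = log(median)` (the log-normal median is exact) and
#' finds `sdlog` by numerical root-finding on the scale-free quartile ratio
#' `q75/q25` (equivalently, least squares on the log quartiles given the
#' exact median); a two-parameter family cannot match median and both
#' quartiles simultaneously, and this split spreads the residual evenly
#' over the two quartiles.
#'
#' @param median target median income, GNF/month.
#' @param q25,q75 target quartiles, GNF/month.
#' @return an object of class `income_model` with the fitted `meanlog`,
#'   `sdlog` and the five `quintile_band_edges` intervals.
#' @examples
#' m <- fit_income_model()
#' income_quantile(m, 0.5)   # the target median, by construction
#' @export
fit_income_model <- function(median = table1_marginals$income[["median"]],
                             q25 = table1_marginals$income[["q25"]],
                             q75 = table1_marginals$income[["q75"]]) {
  stopifnot(0 < q25, q25 < median, median < q75)
  meanlog <- log(median)
  target_ratio <- q75 / q25
  f <- function(s) qlnorm(0.75, meanlog, s) / qlnorm(0.25, meanlog, s) - target_ratio
  sdlog <- uniroot(f, c(1e-8, 10), tol = 1e-12)$root
  edges <- qlnorm(seq(0.2, 0.8, by = 0.2), meanlog, sdlog)
  m <- structure(
    list(family = "lognormal", meanlog = meanlog, sdlog = sdlog,
         quintile_band_edges = cbind(lower = c(0, edges),
                                     upper = c(edges, Inf)),
         target = c(median = median, q25 = q25, q75 = q75)),
    class = "income_model")
  stopifnot(abs(income_quantile(m, 0.5) - median) / median < 0.005,
            all(diff(edges) > 0))
  m
}

#' Quantile function of a fitted income model
#' @param model an `income_model`.
#' @param p probabilities.
#' @export
income_quantile <- function(model, p) qlnorm(p, model$meanlog, model$sdlog)

#' Draw quantized incomes for given wealth quintiles
#'
#' Each agent draws from the fitted income distribution restricted to their
#' quintile's band (quintile 1 = lowest) by inverse-CDF sampling of a
#' uniform variate on `((k-1)/5, k/5)`, so band membership is exact.
#' Draws consume the current R random number stream.
#'
#' @param wealth_quintile integer vector in 1..5.
#' @param model an `income_model`.
#' @return positive incomes in GNF/month, one per input quintile.
#' @export
sample_income <- function(wealth_quintile, model) {
  stopifnot(all(wealth_quintile %in% 1:5))
  n <- length(wealth_quintile)
  u <- (wealth_quintile - 1 + runif(n)) / 5
  income_quantile(model, u)
}

#' Spatial density model for agent placement
#'
#' A two-component mixture on a square plane: a dense Gaussian cluster
#' standing in for the Conakry peninsula plus a diffuse uniform background.
#' Cluster coordinates are drawn axis-wise from a normal truncated to the
#' square (inverse-CDF), so the x- and y-marginals have a simple closed
#' form.
#'
#' @param width side of the square domain, km.
#' @param cluster_weight probability that a point belongs to the cluster.
#' @param cluster_center cluster centre `c(x, y)` in km.
#' @param cluster_sd isotropic cluster standard deviation, km.
#' @export
density_model <- function(width = 60, cluster_weight = 0.7,
                          cluster_center = c(12, 12), cluster_sd = 6) {
  stopifnot(width > 0, cluster_weight >= 0, cluster_weight <= 1,
            length(cluster_center) == 2,
            all(cluster_center >= 0), all(cluster_center <= width),
            cluster_sd >= 0)
  structure(list(width = width, cluster_weight = cluster_weight,
                 cluster_center = cluster_center, cluster_sd = cluster_sd),
            class = "density_model")
}

# Inverse-CDF draw from N(center, sd) truncated to [0, width].
rtrunc_norm <- function(n, center, sd, width) {
  if (sd <= 0) return(rep(center, n))
  lo <- pnorm(0, center, sd)
  hi <- pnorm(width, center, sd)
  qnorm(lo + runif(n) * (hi - lo), center, sd)
}

#' Place agents on the plane
#'
#' @param n number of points.
#' @param model a [density_model()].
#' @return an `n x 2` matrix of km coordinates inside the square.
#' @export
place_agents <- function(n, model) {
  stopifnot(n > 0)
  in_cluster <- runif(n) < model$cluster_weight
  k <- sum(in_cluster)
  xy <- matrix(0, n, 2, dimnames = list(NULL, c("x", "y")))
  for (d in 1:2) {
    v <- numeric(n)
    v[in_cluster] <- rtrunc_norm(k, model$cluster_center[d], model$cluster_sd,
                                 model$width)
    v[!in_cluster] <- runif(n - k, 0, model$width)
    xy[, d] <- v
  }
  xy
}

#' Specification of a synthetic agent population
#'
#' Bundles the marginal distributions (defaulting to the published coastal
#' Guinea demographics), the income and density models, and a seed. Joint
#' structure beyond income-given-wealth and procedure-given-gender-and-age
#' is not modelled: attributes are sampled independently, the minimal
#' assumption when only marginals are known.
#'
#' @param n_agents number of agents to create.
#' @param gender_split probability that an agent is male.
#' @param education_probs,wealth_probs,age_probs named category probabilities;
#'   each must sum to 1 within 1e-9.
#' @param income_model an [fit_income_model()] result.
#' @param density_model a [density_model()].
#' @param seed integer seed used by [generate_population()].
#' @export
population_spec <- function(n_agents = 100000,
                            gender_split = table1_marginals$gender_split,
                            education_probs = table1_marginals$education_probs,
                            wealth_probs = table1_marginals$wealth_probs,
                            age_probs = table1_marginals$age_probs,
                            income_model = fit_income_model(),
                            density_model = cashdose::density_model(),
                            seed = 1L) {
  check_probs <- function(p, k, what) {
    if (length(p) != k || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop_config(what, " must be ", k,
                  " non-negative probabilities summing to 1")
  }
  if (n_agents <= 0) stop_config("n_agents must be positive")
  if (gender_split < 0 || gender_split > 1)
    stop_config("gender_split must be a probability")
  check_probs(education_probs, 3, "education_probs")
  check_probs(wealth_probs, 5, "wealth_probs")
  check_probs(age_probs, 4, "age_probs")
  structure(list(n_agents = as.integer(n_agents), gender_split = gender_split,
                 education_probs = education_probs,
                 wealth_probs = wealth_probs, age_probs = age_probs,
                 income_model = income_model, density_model = density_model,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic agent population
#'
#' Creates `n_agents` simulated people with location, demographics, monthly
#' income and a needed surgical procedure. Demographic attributes are drawn
#' independently per agent from the spec marginals; income is drawn within
#' the agent's wealth-quintile band; the needed procedure is uniform over
#' the four surveyed operations, except that cesarean section is restricted
#' to women in the 15-21 and 22-49 age bands (ineligible draws are
#' reassigned uniformly to the other three procedures). Deterministic given
#' the seed.
#'
#' @param spec a [population_spec()].
#' @param seed optional override of `spec$seed`.
#' @return a data.frame with one row per agent and columns
#'   `id, x, y, gender, education, wealth_quintile, age_band, income,
#'   procedure` (also the documented CSV column order).
#' @export
generate_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed %||% spec$seed)
  n <- spec$n_agents
  xy <- place_agents(n, spec$density_model)
  gender <- factor(ifelse(runif(n) < spec$gender_split, "male", "female"),
                   levels = c("male", "female"))
  education <- factor(sample(education_levels, n, TRUE, spec$education_probs),
                      levels = education_levels)
  wealth_quintile <- sample.int(5, n, TRUE, spec$wealth_probs)
  age_band <- factor(sample(age_levels, n, TRUE, spec$age_probs),
                     levels = age_levels)
  income <- sample_income(wealth_quintile, spec$income_model)
  procedure <- sample(procedure_levels, n, TRUE)
  ineligible <- procedure == "cesarean" &
    !(gender == "female" & age_band %in% c("15-21", "22-49"))
  if (any(ineligible))
    procedure[ineligible] <- sample(setdiff(procedure_levels, "cesarean"),
                                    sum(ineligible), TRUE)
  data.frame(id = seq_len(n), x = xy[, "x"], y = xy[, "y"], gender = gender,
             education = education, wealth_quintile = wealth_quintile,
             age_band = age_band, income = income,
             procedure = factor(procedure, levels = procedure_levels))
}

#' Write a population to CSV
#'
#' One row per agent, columns in the documented order of
#' [generate_population()].
#'
#' @param population a population data.frame.
#' @param path output file.
#' @export
write_population_csv <- function(population, path) {
  utils::write.csv(population, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
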