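#' Preference-weight model
#'
#' Per-agent preference weights are independent normal draws: `g` scales
#' hospital quality Q, `d` scales (negated) distance in km, `l` scales the
#' money term, and `a_home` is the stay-home alternative-specific offset
#' that absorbs every utility component shared across alternatives (those
#' cancel in the logit, so they are not computed). `a_home` and `l` means
#' are the two free calibration parameters; `g` and `d` means are fixed
#' defaults chosen so quality and distance measurably shift hospital
#' market shares.
#'
#' @param g_mean,g_sd quality weight, unitless.
#' @param d_mean,d_sd distance weight, per km.
#' @param l_mean,l_sd money-term weight, unitless.
#' @param a_home_mean,a_home_sd home offset, unitless.
#' @export
weight_model <- function(g_mean = 1, g_sd = 0.2,
                         d_mean = 0.05, d_sd = 0.01,
                         l_mean = 3, l_sd = 0.5,
                         a_home_mean = 0, a_home_sd = 0.5) {
  w <- list(g_mean = g_mean, g_sd = g_sd, d_mean = d_mean, d_sd = d_sd,
            l_mean = l_mean, l_sd = l_sd,
            a_home_mean = a_home_mean, a_home_sd = a_home_sd)
  if (any(unlist(w[c("g_sd", "d_sd", "l_sd", "a_home_sd")]) < 0))
    stop_config("weight standard deviations must be non-negative")
  structure(w, class = "weight_model")
}

#' Draw stochastic preference weights for a batch of agents
#'
#' @param n number of agents.
#' @param wm a [weight_model()].
#' @return data.frame with columns `w_quality, w_distance, w_money, w_home`.
#' @export
draw_weights <- function(n, wm) {
  data.frame(w_quality  = rnorm(n, wm$g_mean, wm$g_sd),
             w_distance = rnorm(n, wm$d_mean, wm$d_sd),
             w_money    = rnorm(n, wm$l_mean, wm$l_sd),
             w_home     = rnorm(n, wm$a_home_mean, wm$a_home_sd))
}

#' Money term of the utility function
#'
#' The perceived-affordability term `c(Y - P + t)`: income `Y` net of the
#' price of care `P` plus the cash transfer `t`, capped at `Y` and
#' expressed as a share of income,
#' \deqn{c = \min(Y - P + t,\ Y) / Y.}
#' It equals 1 whenever the transfer covers the full price (`t >= P`, and
#' always for the stay-home alternative where `P = 0`), increases with `t`
#' below that, and can be negative when the out-of-pocket remainder
#' exceeds income. The cap is what makes the dose-response curve flatten
#' exactly when the transfer pays for the most expensive surgery. A
#' log-consumption variant `log(max(min(Y - P + t, Y), 0.01 Y) / Y)` is
#' available behind `form`.
#'
#' @param Y income, GNF (> 0).
#' @param P price of care, GNF.
#' @param t cash transfer, GNF.
#' @param form `"capped_share"` (default) or `"log_consumption"`.
#' @return unitless value(s); vectorized over the inputs.
#' @export
money_term <- function(Y, P, t, form = c("capped_share", "log_consumption")) {
  form <- match.arg(form)
  if (any(Y <= 0)) stop("income Y must be strictly positive")
  net <- pmin(Y - P + t, Y)
  switch(form,
         capped_share = net / Y,
         log_consumption = log(pmax(net, 0.01 * Y) / Y))
}

#' Euclidean distance between agents and hospitals
#'
#' Planar km distance on the model's square; the survey region's road
#' network is not modelled.
#'
#' @param ax,ay agent coordinates (vectors, km).
#' @param hx,hy hospital coordinates (vectors, km).
#' @return `length(ax) x length(hx)` matrix of distances.
#' @export
distance_matrix <- function(ax, ay, hx, hy) {
  sqrt(outer(ax, hx, "-")^2 + outer(ay, hy, "-")^2)
}

#' Deterministic utilities for a set of agents over a common choice set
#'
#' Computes the observable part of the random utility
#' `U = a + bX + g Q - d D + l c(Y - P + t) + e` for each alternative.
#' Terms constant across alternatives for one agent (`a + bX`) cancel in
#' the logit and are omitted; the home alternative instead carries the
#' agent's `w_home` offset. Home has Q = 0, D = 0, P = 0, so its money
#' term is always 1. The Gumbel error `e` is not added here: it is
#' realized implicitly by the logit choice probabilities.
#'
#' @param agents data.frame with `income` and weight columns (see
#'   [draw_weights()]).
#' @param Q hospital quality scores (length J).
#' @param D `n x J` distance matrix, km.
#' @param P hospital prices for these agents' procedure (length J).
#' @param t cash transfer, GNF.
#' @param money_form see [money_term()].
#' @return `n x (J + 1)` utility matrix, home in column 1.
#' @export
utility_matrix <- function(agents, Q, D, P, t,
                           money_form = "capped_share") {
  n <- nrow(agents); J <- length(Q)
  stopifnot(ncol(D) == J, length(P) == J)
  cmat <- money_term(agents$income,
                     matrix(P, n, J, byrow = TRUE), t, money_form)
  v_home <- agents$w_home +
    agents$w_money * money_term(agents$income, 0, t, money_form)
  v_hosp <- agents$w_quality * matrix(Q, n, J, byrow = TRUE) -
    agents$w_distance * D + agents$w_money * cmat
  cbind(home = v_home, v_hosp)
}

#' Multinomial-logit choice probabilities
#'
#' Row-wise softmax of the deterministic utilities, the McFadden
#' random-utility choice probabilities under i.i.d. Gumbel errors.
#' Max-shifted for numerical stability; rows sum to 1 within 1e-12.
#'
#' @param V utility matrix (rows = agents, columns = alternatives) or a
#'   single utility vector.
#' @return matrix (or vector) of probabilities in (0, 1).
#' @export
choice_probabilities <- function(V) {
  if (is.null(dim(V))) return(drop(choice_probabilities(matrix(V, 1))))
  e <- exp(V - row_max(V))
  e / rowSums(e)
}

#' Sample one choice per agent from probability rows
#'
#' Categorical draw by inverse CDF on one uniform variate per row
#' (consumes the current RNG stream).
#'
#' @param prob probability matrix, rows summing to 1.
#' @return integer vector of chosen column indices.
#' @export
sample_choice <- function(prob) {
  if (is.null(dim(prob))) prob <- matrix(prob, 1)
  u <- runif(nrow(prob))
  1L + as.integer(rowSums(row_cumsum(prob) < u))
}

#' Simulate the care-seeking choice for a population batch
#'
#' For each agent the choice set is the stay-home alternative plus every
#' hospital offering the agent's needed procedure; utilities, logit
#' probabilities and one sampled choice are computed per agent.
#'
#' @param agents population data.frame with weight columns already drawn.
#' @param fac a [facility_model()].
#' @param t cash transfer, GNF.
#' @param money_form see [money_term()].
#' @return integer vector: 0 = stayed home (no-show), j > 0 = hospital j
#'   in `fac$records` order.
#' @export
simulate_choices <- function(agents, fac, t, money_form = "capped_share") {
  D_all <- distance_matrix(agents$x, agents$y,
                           fac$coords[, "x"], fac$coords[, "y"])
  choice <- integer(nrow(agents))
  for (pr in levels(agents$procedure)) {
    rows <- which(agents$procedure == pr)
    if (!length(rows)) next
    hosp <- which(fac$offered[, pr])
    if (!length(hosp)) { choice[rows] <- 0L; next }
    V <- utility_matrix(agents[rows, ], fac$Q[hosp],
                        D_all[rows, hosp, drop = FALSE],
                        fac$prices[hosp, pr], t, money_form)
    k <- sample_choice(choice_probabilities(V))
    choice[rows] <- ifelse(k == 1L, 0L, hosp[k - 1L])
  }
  choice
}
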