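#' Logistic growth of the resource stock
#'
#' Regrowth added to the stock in one round: `r_g * N * (1 - N / N_max)`.
#' Zero at an empty stock and at carrying capacity, maximal at `N_max / 2`.
#'
#' @param N Resource level(s), in `[0, N_max]`. Vectorised.
#' @param params A [cprg_params()] object.
#' @return Growth in stock units, same length as `N`.
#' @examples
#' resource_growth(500, cprg_params()) # 125
#' @export
resource_growth <- function(N, params = cprg_params()) {
  params <- as_cprg_params(params)
  check_stock(N, params)
  params$r_g * N * (1 - N / params$N_max)
}

#' Cobb-Douglas harvest production
#'
#' Harvest extracted by cumulative effort `X` from a stock `N`:
#' `beta * X^alpha * N^(1 - alpha)`. Effort plays the role of labour and the
#' stock that of capital; the output is never negative, and it is zero
#' whenever either input is zero (the exponent edge cases are resolved to 0).
#'
#' @param X Cumulative effort(s), >= 0. Vectorised; recycled against `N`.
#' @param N Resource level(s), >= 0.
#' @inheritParams resource_growth
#' @return Harvest in stock units.
#' @examples
#' harvest_production(100, 1000, cprg_params()) # about 178.7
#' @export
harvest_production <- function(X, N, params = cprg_params()) {
  params <- as_cprg_params(params)
  if (any(X < 0, na.rm = TRUE)) stop("effort `X` must be >= 0", call. = FALSE)
  if (any(N < 0, na.rm = TRUE)) stop("stock `N` must be >= 0", call. = FALSE)
  out <- params$beta * X^params$alpha * N^(1 - params$alpha)
  # 0^0 = 1 in R; an idle fishery or an empty stock must still yield nothing
  out[X == 0 | N == 0] <- 0
  out
}

#' Cumulative effort of a group
#'
#' @param efforts Numeric vector of per-agent efforts, all >= 0. An empty
#'   vector is an empty group with zero cumulative effort.
#' @return The summed effort.
#' @export
cumulative_effort <- function(efforts) {
  if (length(efforts) && any(efforts < 0, na.rm = TRUE)) {
    stop("all efforts must be >= 0", call. = FALSE)
  }
  if (!length(efforts)) return(0)
  sum(efforts)
}

#' Advance the resource by one round
#'
#' Applies the stock update `N_t = N_{t-1} + G(N_{t-1}) - H(X, N_{t-1})` and
#' clamps the result to `[0, N_max]`. Negative stock is physically
#' meaningless and an empty stock is absorbing (no growth, no harvest). The
#' returned outcome carries the *unclamped* growth, harvest and net growth so
#' that reward signals and diagnostics see the true flows even when the clamp
#' fires.
#'
#' @param N Current resource level, in `[0, N_max]`.
#' @param X Cumulative effort this round, >= 0.
#' @inheritParams resource_growth
#' @return A list with `N` (next, clamped), `G`, `H`, `net_growth`
#'   (`G - H`, unclamped).
#' @examples
#' step_resource(1000, 100, cprg_params()) # N drops by the harvest; G = 0
#' @export
step_resource <- function(N, X, params = cprg_params()) {
  params <- as_cprg_params(params)
  check_stock(N, params)
  G <- params$r_g * N * (1 - N / params$N_max)
  H <- harvest_production(X, N, params)
  net <- G - H
  list(N = min(max(N + net, 0), params$N_max), G = G, H = H, net_growth = net)
}

#' Per-agent payoffs and total payoff
#'
#' Each agent receives a harvest share proportional to its effort and pays a
#' linear effort cost: `pi_i = (x_i / X) * H(X, N) - c * x_i`. The total
#' payoff is `Pi = H - c X` and the individual payoffs always sum to it.
#' When nobody invests anything, all payoffs are zero.
#'
#' @param efforts Per-agent efforts `x_i`, all >= 0.
#' @param N Resource level, >= 0.
#' @inheritParams resource_growth
#' @return A list with `pi` (vector of per-agent payoffs), `Pi` (total),
#'   `H` and `X`.
#' @examples
#' payoffs(rep(20, 10), 500)$Pi
#' @export
payoffs <- function(efforts, N, params = cprg_params()) {
  params <- as_cprg_params(params)
  X <- cumulative_effort(efforts)
  if (X == 0) {
    return(list(pi = rep(0, length(efforts)), Pi = 0, H = 0, X = 0))
  }
  H <- harvest_production(X, N, params)
  pi_i <- efforts / X * H - params$c * efforts
  list(pi = pi_i, Pi = H - params$c * X, H = H, X = X)
}

#' Asset bookkeeping
#'
#' Credits last round's payoff: `A_t = A_{t-1} + pi_{t-1}`. Assets are an
#' abstraction of monetary value and may go negative; there is no bankruptcy
#' rule.
#'
#' @param assets Current asset level(s).
#' @param payoff Payoff(s) earned in the previous round.
#' @return Updated assets.
#' @export
update_assets <- function(assets, payoff) {
  assets + payoff
}

check_stock <- function(N, params) {
  if (any(N < 0 | N > params$N_max, na.rm = TRUE)) {
    stop("resource level `N` must lie in [0, N_max]", call. = FALSE)
  }
  invisible(N)
}
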