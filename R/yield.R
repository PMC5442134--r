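#' Sustainable effort bound
#'
#' The largest cumulative effort whose harvest does not exceed the logistic
#' regrowth at stock level `N`:
#' `(r_g N (1 - N/N_max) / (beta N^(1-alpha)))^(1/alpha)`.
#' Efforts below the bound leave positive net growth, efforts above it shrink
#' the stock. The bound vanishes at `N = 0` and `N = N_max`, where there is
#' no growth to harvest.
#'
#' @param N Resource level(s) in `[0, N_max]`. Vectorised.
#' @param params A [cprg_params()] object.
#' @return Effort bound(s), >= 0.
#' @examples
#' sustainable_effort_bound(500) # about 130.5
#' @export
sustainable_effort_bound <- function(N, params = cprg_params()) {
  params <- as_cprg_params(params)
  check_stock(N, params)
  G <- params$r_g * N * (1 - N / params$N_max)
  out <- (G / (params$beta * N^(1 - params$alpha)))^(1 / params$alpha)
  out[N == 0 | G <= 0] <- 0
  out
}

#' Profitable effort bound
#'
#' The largest cumulative effort for which total profit `H - cX` is
#' non-negative: `(beta N^(1-alpha) / c)^(1/(1-alpha))`, which is linear in
#' `N`. Efforts below the bound are profitable for the group as a whole.
#'
#' @inheritParams sustainable_effort_bound
#' @return Effort bound(s), >= 0. Errors when `c = 0`, where every effort is
#'   profitable and the bound is unbounded.
#' @examples
#' profitable_effort_bound(1000) # about 709.4
#' @export
profitable_effort_bound <- function(N, params = cprg_params()) {
  params <- as_cprg_params(params)
  check_stock(N, params)
  if (params$c == 0) {
    stop("profitability is unbounded when the effort cost `c` is 0",
         call. = FALSE)
  }
  (params$beta / params$c)^(1 / (1 - params$alpha)) * N
}

#' Maximum sustainable yield
#'
#' Maximises the net growth `G(N) - H(X, N)` over the feasible effort range
#' `[X_min, X_max]`. Because the harvest increases strictly with effort, the
#' maximiser is always the minimum feasible effort; the maximum itself may
#' still be negative (at carrying capacity there is no growth to spare). The
#' informative boundary of sustainable effort is
#' [sustainable_effort_bound()].
#'
#' @inheritParams sustainable_effort_bound
#' @param N A single resource level in `[0, N_max]`.
#' @return A list with `X` (argmax effort) and `value` (maximal net growth).
#' @export
msy <- function(N, params = cprg_params()) {
  params <- as_cprg_params(params)
  check_stock(N, params)
  G <- params$r_g * N * (1 - N / params$N_max)
  list(X = params$X_min,
       value = G - harvest_production(params$X_min, N, params))
}

#' Maximum economic yield
#'
#' Maximises the total profit `H(X, N) - cX` over `[X_min, X_max]`. The
#' interior stationary point is `X* = (alpha beta / c)^(1/(1-alpha)) * N`,
#' clipped to the feasible range; with `c = 0` profit increases with effort
#' without bound and the maximiser is `X_max`.
#'
#' @inheritParams msy
#' @return A list with `X` (argmax effort) and `value` (maximal total
#'   profit, possibly negative).
#' @examples
#' mey(1000)$X # about 141.1
#' @export
mey <- function(N, params = cprg_params()) {
  params <- as_cprg_params(params)
  check_stock(N, params)
  if (params$c == 0) {
    X_star <- params$X_max
  } else {
    X_star <- (params$alpha * params$beta / params$c)^(1 / (1 - params$alpha)) * N
    X_star <- min(max(X_star, params$X_min), params$X_max)
  }
  list(X = X_star,
       value = harvest_production(X_star, N, params) - params$c * X_star)
}

#' Best response of a single harvester
#'
#' Maximises an individual's payoff
#' `(x / (x + X_others)) H(x + X_others, N) - c x` over a discrete set of
#' candidate actions, taking the combined effort of the other agents as
#' given. Ties are broken toward the smaller action. With no other effort the
#' problem reduces to the total-profit maximisation of [mey()] restricted to
#' the grid.
#'
#' @param x_grid Candidate actions (efforts), a non-empty numeric vector.
#' @param X_others Combined effort of the other agents, >= 0.
#' @inheritParams msy
#' @return A list with `x` (best action), `payoff` (its payoff) and
#'   `payoffs` (payoff of every candidate, in `x_grid` order).
#' @export
individual_best_response <- function(x_grid, X_others, N,
                                     params = cprg_params()) {
  params <- as_cprg_params(params)
  if (!length(x_grid)) stop("`x_grid` must be non-empty", call. = FALSE)
  if (X_others < 0) stop("`X_others` must be >= 0", call. = FALSE)
  X <- x_grid + X_others
  share <- ifelse(X > 0, x_grid / X, 0)
  pay <- share * harvest_production(X, N, params) - params$c * x_grid
  # ties toward the smaller action: scan in increasing-effort order
  ord <- order(x_grid)
  best <- ord[which.max(pay[ord])]
  list(x = x_grid[best], payoff = pay[best], payoffs = pay)
}

#' Resource-level equilibria of the harvesting game
#'
#' Computes the stock levels at which the feasibility of harvesting changes
#' character:
#' * `E1_sustainable`, `E2_sustainable` — the lowest and highest stock at
#'   which the minimum feasible effort `X_min` is still sustainable (roots of
#'   `sustainable_effort_bound(N) = X_min`, found by bisection). Outside
#'   `[E1, E2]` every feasible effort shrinks the stock.
#' * `E_profitable` — the lowest stock at which the minimum effort turns a
#'   profit; closed form `X_min * (c / beta)^(1/(1-alpha))`.
#' * `E_optimal` — the stock maximising the width of the feasible effort
#'   interval that is both sustainable and profitable (dense scan over `N`;
#'   ties toward the smaller `N`). The "safest" operating point: the most
#'   room for error in either direction.
#'
#' @param params A [cprg_params()] object.
#' @param resolution Scan step for the `E_optimal` search, in stock units.
#' @param tol Bisection tolerance on `N`.
#' @return An object of class `cprg_equilibria`: a list with the four
#'   equilibria, `X_e` (the viable effort interval at `E_optimal`) and the
#'   scan tibble `profile` (columns `N`, `viable_width`).
#' @examples
#' eq <- cprg_equilibria()
#' eq$E_profitable # about 141
#' @export
cprg_equilibria <- function(params = cprg_params(), resolution = 0.5,
                            tol = 1e-6) {
  params <- as_cprg_params(params)
  if (resolution <= 0) stop("`resolution` must be > 0", call. = FALSE)

  f <- function(N) sustainable_effort_bound(N, params) - params$X_min
  N_peak <- stats::optimize(function(N) -f(N), c(0, params$N_max))$minimum
  if (f(N_peak) < 0) {
    E1 <- E2 <- NA_real_
  } else {
    E1 <- stats::uniroot(f, c(0, N_peak), tol = tol)$root
    E2 <- stats::uniroot(f, c(N_peak, params$N_max), tol = tol)$root
  }
  E_prof <- params$X_min * (params$c / params$beta)^(1 / (1 - params$alpha))

  Ns <- seq(resolution / 2, params$N_max - resolution / 2, by = resolution)
  hi <- pmin(sustainable_effort_bound(Ns, params),
             profitable_effort_bound(Ns, params),
             params$X_max)
  width <- pmax(0, hi - params$X_min)
  if (all(width <= 0)) {
    stop("empty viable region: no stock level admits a feasible effort ",
         "that is both sustainable and profitable", call. = FALSE)
  }
  i_opt <- which.max(width) # which.max takes the first, i.e. smallest N
  E_opt <- Ns[i_opt]

  structure(
    list(E1_sustainable = E1, E2_sustainable = E2,
         E_profitable = E_prof, E_optimal = E_opt,
         X_e = c(params$X_min, params$X_min + width[i_opt]),
         profile = tibble::tibble(N = Ns, viable_width = width),
         params = params),
    class = "cprg_equilibria")
}

#' @export
print.cprg_equilibria <- function(x, ...) {
  cat("<cprg_equilibria>\n")
  cat(sprintf("  sustainable between E1 = %.1f and E2 = %.1f\n",
              x$E1_sustainable, x$E2_sustainable))
  cat(sprintf("  profitable above E_profitable = %.1f\n", x$E_profitable))
  cat(sprintf("  widest viable effort interval at E_optimal = %.1f (X_e in [%.1f, %.1f])\n",
              x$E_optimal, x$X_e[1], x$X_e[2]))
  invisible(x)
}

#' Fraction of the action space that is viable
#'
#' Classifies a dense grid over the feasible rectangle
#' `[X_min, X_max] x [0, N_max]` and returns the area fraction where the
#' harvest is simultaneously sustainable (`G - H >= 0`) and profitable
#' (`H - cX >= 0`) — the pool of choices that keep both the resource and the
#' harvesters solvent. Midpoint 2-D integration; the default grid is fine
#' enough that halving the step changes the estimate by well under 0.1
#' percentage points.
#'
#' @inheritParams cprg_equilibria
#' @param n_grid Number of grid cells per axis.
#' @return A single fraction in `[0, 1]`.
#' @examples
#' viable_fraction() # about 0.061
#' @export
viable_fraction <- function(params = cprg_params(), n_grid = 1500) {
  params <- as_cprg_params(params)
  Xs <- seq(params$X_min, params$X_max, length.out = n_grid + 1)
  Xs <- (Xs[-1] + Xs[-length(Xs)]) / 2
  Ns <- seq(0, params$N_max, length.out = n_grid + 1)
  Ns <- (Ns[-1] + Ns[-length(Ns)]) / 2
  # separable: viable iff X <= min(sustainable, profitable) bound at N
  hi <- pmin(sustainable_effort_bound(Ns, params),
             profitable_effort_bound(Ns, params))
  mean(vapply(hi, function(b) mean(Xs <= b), numeric(1)))
}

#' Classify the effort-by-stock action grid
#'
#' Tidy export of the `(X, N)` classification underlying
#' [viable_fraction()], for contour plotting or external analysis.
#'
#' @inheritParams viable_fraction
#' @param n_grid Number of grid cells per axis.
#' @return A tibble with columns `X`, `N`, `net_growth`, `profit`,
#'   `sustainable`, `profitable`, `viable`.
#' @export
classify_actions <- function(params = cprg_params(), n_grid = 100) {
  params <- as_cprg_params(params)
  grid <- tidyr::expand_grid(
    X = seq(params$X_min, params$X_max, length.out = n_grid),
    N = seq(0, params$N_max, length.out = n_grid)
  )
  grid |>
    dplyr::mutate(
      net_growth = resource_growth(.data$N, params) -
        harvest_production(.data$X, .data$N, params),
      profit = harvest_production(.data$X, .data$N, params) -
        params$c * .data$X,
      sustainable = .data$net_growth >= 0,
      profitable = .data$profit >= 0,
      viable = .data$sustainable & .data$profitable
    )
}

#' Full yield analysis of a game parameterisation
#'
#' Samples the sustainable and profitable effort bounds and the MSY/MEY
#' curves on a stock grid, locates the equilibria and computes the viable
#' area fraction. This is the analytical companion to [run_cprg()]: it
#' describes what the action space offers before any learning happens.
#'
#' @inheritParams cprg_equilibria
#' @param n_grid Number of stock levels to sample for the curves.
#' @return An object of class `cprg_yield` with elements `curves` (tibble:
#'   `N`, `X_sustainable_max`, `X_profitable_max`, `msy_X`, `msy_value`,
#'   `mey_X`, `mey_value`), `equilibria` ([cprg_equilibria()] object),
#'   `viable_fraction` and `params`.
#' @examples
#' ya <- yield_analysis()
#' glance(ya)
#' @export
yield_analysis <- function(params = cprg_params(), n_grid = 201) {
  params <- as_cprg_params(params)
  Ns <- seq(0, params$N_max, length.out = n_grid)
  curves <- tibble::tibble(
    N = Ns,
    X_sustainable_max = sustainable_effort_bound(Ns, params),
    X_profitable_max = profitable_effort_bound(Ns, params),
    msy_X = vapply(Ns, function(n) msy(n, params)$X, numeric(1)),
    msy_value = vapply(Ns, function(n) msy(n, params)$value, numeric(1)),
    mey_X = vapply(Ns, function(n) mey(n, params)$X, numeric(1)),
    mey_value = vapply(Ns, function(n) mey(n, params)$value, numeric(1))
  )
  structure(
    list(curves = curves, equilibria = cprg_equilibria(params),
         viable_fraction = viable_fraction(params), params = params),
    class = "cprg_yield")
}

#' @export
print.cprg_yield <- function(x, ...) {
  cat("<cprg_yield>\n")
  print(x$equilibria)
  cat(sprintf("  viable fraction of the action rectangle: %.1f%%\n",
              100 * x$viable_fraction))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a yield analysis
#'
#' @param x A `cprg_yield` object.
#' @param ... Unused.
#' @return The per-stock-level curves tibble.
#' @export
tidy.cprg_yield <- function(x, ...) x$curves

#' One-row summary of a yield analysis
#'
#' @param x A `cprg_yield` object.
#' @param ... Unused.
#' @return A one-row tibble with the equilibria and the viable fraction.
#' @export
glance.cprg_yield <- function(x, ...) {
  eq <- x$equilibria
  tibble::tibble(
    E1_sustainable = eq$E1_sustainable,
    E2_sustainable = eq$E2_sustainable,
    E_profitable = eq$E_profitable,
    E_optimal = eq$E_optimal,
    X_e_lower = eq$X_e[1],
    X_e_upper = eq$X_e[2],
    viable_fraction = x$viable_fraction
  )
}

#' Plot the viable action region
#'
#' Effort bounds over stock level, with the region that is both sustainable
#' and profitable shaded and the equilibria marked.
#'
#' @param object A `cprg_yield` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cprg_yield <- function(object, ...) {
  p <- object$params
  eq <- object$equilibria
  band <- object$curves |>
    dplyr::mutate(
      hi = pmin(.data$X_sustainable_max, .data$X_profitable_max, p$X_max),
      hi = pmax(.data$hi, p$X_min)
    )
  ggplot2::ggplot(object$curves, ggplot2::aes(x = .data$N)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(ymin = p$X_min, ymax = .data$hi),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$X_sustainable_max,
                                    colour = "sustainable bound")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$X_profitable_max,
                                    colour = "profitable bound")) +
    ggplot2::geom_hline(yintercept = c(p$X_min, p$X_max), linetype = 3) +
    ggplot2::geom_vline(xintercept = c(eq$E1_sustainable, eq$E2_sustainable,
                                       eq$E_profitable, eq$E_optimal),
                        linetype = 2, alpha = 0.5) +
    ggplot2::coord_cartesian(ylim = c(0, p$X_max * 1.1)) +
    ggplot2::labs(x = "resource level N", y = "cumulative effort X",
                  colour = NULL,
                  title = "Sustainable and profitable effort bounds") +
    ggplot2::theme_minimal()
}
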