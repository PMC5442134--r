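#' Run the common-pool resource game
#'
#' Couples a group of tabular Q-learning harvesters to the resource for a
#' fixed number of rounds, repeated over independent replicates. Each round:
#' agents observe the binned stock level and pick efforts (epsilon-greedy on
#' their private Q tables), the harvest and payoffs are computed on the
#' observed stock, the stock is stepped, trend rewards are formed from the
#' round's unclamped net growth and the agents' own payoffs, the Q tables
#' are updated, and assets are credited one round in arrears
#' (`A_t = A_{t-1} + pi_{t-1}`).
#'
#' Every source of randomness is seeded from `base_seed`: replicate `r` uses
#' its own set of per-agent RNG substreams derived from
#' `base_seed + r`, so identical calls are bit-identical and adding an agent
#' does not perturb the draws of the others.
#'
#' @param params A [cprg_params()] object.
#' @param n_agents Number of harvesters.
#' @param rounds Rounds per replicate.
#' @param replicates Number of independent replicates.
#' @param base_seed Integer seed for the whole experiment.
#' @param learner A [learner_config()].
#' @param reward A [reward_spec()] (or a bare weight `w`).
#' @param N0 Initial resource level; defaults to the carrying capacity
#'   (a pristine stock).
#' @param initial_assets Initial per-agent endowment.
#' @param record_agents Keep per-agent, per-round records? Disable for large
#'   sweeps where only the round-level series and final assets matter.
#' @return An object of class `cprg_sim` with elements:
#'   * `rounds` — tibble of per-round records: `replicate`, `t`, `N`
#'     (end-of-round stock), `X`, `G`, `H`, `Pi` (all unclamped flows);
#'   * `agents` — tibble of `replicate`, `t`, `agent`, `x`, `pi`, `A`
#'     (assets held during the round, i.e. before that round's payoff is
#'     credited), `R`, or `NULL` if not recorded;
#'   * `final` — tibble of `replicate`, `agent`, `assets` (endowment plus
#'     all payoffs);
#'   * the configuration (`params`, `learner`, `reward`, `n_agents`,
#'     `rounds`, `replicates`, `base_seed`, `N0`, `initial_assets`).
#' @examples
#' sim <- run_cprg(rounds = 50, replicates = 2, n_agents = 3, base_seed = 1)
#' dplyr::count(tidy(sim), replicate)
#' @export
run_cprg <- function(params = cprg_params(), n_agents = 10, rounds = 5000,
                     replicates = 50, base_seed = 1,
                     learner = learner_config(), reward = reward_spec(),
                     N0 = NULL, initial_assets = 1000,
                     record_agents = TRUE) {
  params <- as_cprg_params(params)
  learner <- as_learner_config(learner)
  reward <- as_reward_spec(reward)
  if (rounds < 1 || replicates < 1) {
    stop("`rounds` and `replicates` must be >= 1", call. = FALSE)
  }
  if (is.null(N0)) N0 <- params$N_max
  check_stock(N0, params)

  reps <- lapply(seq_len(replicates), function(r) {
    run_one_replicate(params, n_agents, rounds, learner, reward,
                      N0, initial_assets,
                      rep_seed = base_seed + r, record_agents = record_agents)
  })

  rounds_tbl <- dplyr::bind_rows(lapply(seq_len(replicates), function(r) {
    tibble::tibble(replicate = r, tibble::as_tibble(reps[[r]]$rounds))
  }))
  agents_tbl <- NULL
  if (record_agents) {
    agents_tbl <- dplyr::bind_rows(lapply(seq_len(replicates), function(r) {
      tibble::tibble(replicate = r, reps[[r]]$agents)
    }))
  }
  final_tbl <- dplyr::bind_rows(lapply(seq_len(replicates), function(r) {
    tibble::tibble(replicate = r, agent = seq_len(n_agents),
                   assets = reps[[r]]$assets_final)
  }))

  structure(
    list(rounds = rounds_tbl, agents = agents_tbl, final = final_tbl,
         params = params, learner = learner, reward = reward,
         n_agents = n_agents, rounds_per_replicate = rounds,
         replicates = replicates, base_seed = base_seed,
         N0 = N0, initial_assets = initial_assets),
    class = "cprg_sim")
}

# One replicate of the round loop. The arithmetic here deliberately mirrors
# the dynamics module (an oracle-equivalence test keeps them in lock-step);
# it is inlined because the loop runs hundreds of thousands of times.
run_one_replicate <- function(params, n_agents, rounds, learner, reward,
                              N0, initial_assets, rep_seed, record_agents) {
  acts <- action_grid(learner, params, n_agents)
  nA <- learner$n_actions
  nS <- learner$n_state_bins
  w <- reward$w
  on_profit <- learner$weight_on == "profit"

  # private Q tables and private RNG substreams per agent
  q_tabs <- replicate(n_agents, init_q_table(learner), simplify = FALSE)
  streams <- lapply(seq_len(n_agents), function(i) {
    set.seed((abs(rep_seed) * 1009 + i * 104729) %% 2147483647)
    get(".Random.seed", envir = globalenv())
  })

  N <- N0
  assets <- rep(initial_assets, n_agents)
  eps <- learner$epsilon

  m_rounds <- matrix(NA_real_, nrow = rounds, ncol = 6,
                     dimnames = list(NULL, c("t", "N", "X", "G", "H", "Pi")))
  if (record_agents) {
    m_x <- m_pi <- m_A <- m_R <- matrix(NA_real_, rounds, n_agents)
  }

  for (t in seq_len(rounds)) {
    s <- min(floor(N / params$N_max * nS) + 1L, nS)
    a <- integer(n_agents)
    for (i in seq_len(n_agents)) {
      assign(".Random.seed", streams[[i]], envir = globalenv())
      a[i] <- select_action(q_tabs[[i]], s, eps, learner$tie_break)
      streams[[i]] <- get(".Random.seed", envir = globalenv())
    }
    x <- acts[a]
    X <- sum(x)
    G <- params$r_g * N * (1 - N / params$N_max)
    H <- params$beta * X^params$alpha * N^(1 - params$alpha)
    if (X == 0 || N == 0) H <- 0
    net <- G - H
    pi_i <- if (X > 0) x / X * H - params$c * x else rep(0, n_agents)

    N_next <- min(max(N + net, 0), params$N_max)
    s_next <- min(floor(N_next / params$N_max * nS) + 1L, nS)

    lam <- sign(net)
    xi <- sign(pi_i)
    R <- if (on_profit) w * xi + (1 - w) * lam else w * lam + (1 - w) * xi

    for (i in seq_len(n_agents)) {
      q_tabs[[i]] <- q_update(q_tabs[[i]], s, a[i], R[i], s_next, learner)
    }

    m_rounds[t, ] <- c(t, N_next, X, G, H, H - params$c * X)
    if (record_agents) {
      m_x[t, ] <- x
      m_pi[t, ] <- pi_i
      m_A[t, ] <- assets # held during round t: payoffs credited in arrears
      m_R[t, ] <- R
    }

    assets <- assets + pi_i
    N <- N_next
    eps <- max(eps * learner$epsilon_decay, learner$epsilon_floor)
  }

  agents_tbl <- NULL
  if (record_agents) {
    agents_tbl <- tibble::tibble(
      t = rep(seq_len(rounds), times = n_agents),
      agent = rep(seq_len(n_agents), each = rounds),
      x = as.vector(m_x), pi = as.vector(m_pi),
      A = as.vector(m_A), R = as.vector(m_R)
    )
  }
  list(rounds = m_rounds, agents = agents_tbl, assets_final = assets,
       q_tabs = q_tabs)
}

#' @export
print.cprg_sim <- function(x, ...) {
  cat("<cprg_sim>\n")
  cat(sprintf("  %d agent(s), %d round(s) x %d replicate(s), base seed %d\n",
              x$n_agents, x$rounds_per_replicate, x$replicates, x$base_seed))
  cat(sprintf("  reward weight w = %g on %s; cost c = %g\n",
              x$reward$w, x$learner$weight_on, x$params$c))
  g <- glance(x)
  cat(sprintf("  late-window median N = %.1f; median final per-agent assets = %.1f\n",
              g$median_late_N, g$median_final_assets))
  invisible(x)
}

#' Tidy a simulation
#'
#' @param x A `cprg_sim` object.
#' @param ... Unused.
#' @return The per-round records tibble.
#' @export
tidy.cprg_sim <- function(x, ...) x$rounds

#' One-row summary of a simulation
#'
#' Late-window and final statistics across replicates. The late window is
#' the last `late_window` rounds of each replicate (default: the final fifth
#' of the run, capped at 1000 rounds), the part of the run after the initial
#' learning phase has settled.
#'
#' @param x A `cprg_sim` object.
#' @param late_window Number of trailing rounds to summarise.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.cprg_sim <- function(x, late_window = NULL, ...) {
  lw <- late_window %||% default_late_window(x$rounds_per_replicate)
  per_rep <- x$rounds |>
    dplyr::filter(.data$t > x$rounds_per_replicate - lw) |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(late_N = stats::median(.data$N),
                     late_X = mean(.data$X), .groups = "drop")
  fin <- x$final |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(assets = mean(.data$assets), .groups = "drop")
  tibble::tibble(
    replicates = x$replicates,
    median_late_N = stats::median(per_rep$late_N),
    mean_late_X = mean(per_rep$late_X),
    median_final_assets = stats::median(fin$assets),
    depleted_fraction = mean(per_rep$late_N < 0.01 * x$params$N_max)
  )
}

default_late_window <- function(rounds) max(1L, min(1000L, floor(rounds / 5)))

#' Plot resource trajectories of a simulation
#'
#' One faint line per replicate and the across-replicate mean, with the
#' optimal equilibrium of the yield analysis for reference.
#'
#' @param object A `cprg_sim` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cprg_sim <- function(object, ...) {
  eq <- cprg_equilibria(object$params)
  mean_tbl <- object$rounds |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(N = mean(.data$N), .groups = "drop")
  ggplot2::ggplot(object$rounds,
                  ggplot2::aes(x = .data$t, y = .data$N,
                               group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.2) +
    ggplot2::geom_line(data = mean_tbl, ggplot2::aes(group = NULL),
                       colour = "steelblue", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = eq$E_optimal, linetype = 2) +
    ggplot2::labs(x = "round", y = "resource level N",
                  title = "Resource trajectories",
                  subtitle = "dashed: optimal equilibrium") +
    ggplot2::theme_minimal()
}

#' Group-size experiment
#'
#' Runs the game for each group size in `n_agents` (same seeds, same
#' learner) and summarises the late-window resource level and the final
#' per-agent assets. Also returns the across-replicate mean trajectories of
#' the stock and of per-agent assets, reconstructed from the round records.
#'
#' @inheritParams run_cprg
#' @param n_agents Vector of group sizes to sweep.
#' @return A list of class `cprg_sweep_n` with `summary` (one row per group
#'   size: `n_agents`, `median_late_N`, `median_final_assets`,
#'   `profit_maintained` — whether the median agent ends above the
#'   endowment) and `trajectories` (`n_agents`, `t`, `N_mean`,
#'   `assets_mean`).
#' @export
sweep_group_size <- function(params = cprg_params(), n_agents = 1:15,
                             rounds = 5000, replicates = 50, base_seed = 1,
                             learner = learner_config(),
                             reward = reward_spec(0.5),
                             N0 = NULL, initial_assets = 1000) {
  runs <- lapply(n_agents, function(n) {
    run_cprg(params, n_agents = n, rounds = rounds, replicates = replicates,
             base_seed = base_seed, learner = learner, reward = reward,
             N0 = N0, initial_assets = initial_assets,
             record_agents = FALSE)
  })
  summary <- purrr::map2_dfr(runs, n_agents, function(sim, n) {
    g <- glance(sim)
    tibble::tibble(n_agents = n,
                   median_late_N = g$median_late_N,
                   mean_late_X = g$mean_late_X,
                   median_final_assets = g$median_final_assets,
                   profit_maintained = g$median_final_assets > initial_assets)
  })
  trajectories <- purrr::map2_dfr(runs, n_agents, function(sim, n) {
    sim$rounds |>
      dplyr::group_by(.data$t) |>
      dplyr::summarise(N_mean = mean(.data$N),
                       Pi_mean = mean(.data$Pi), .groups = "drop") |>
      dplyr::mutate(n_agents = n,
                    assets_mean = initial_assets +
                      cumsum(.data$Pi_mean) / n, .before = 1) |>
      dplyr::select("n_agents", "t", "N_mean", "assets_mean")
  })
  structure(list(summary = summary, trajectories = trajectories),
            class = "cprg_sweep_n")
}

#' Cost-by-weight grid experiment
#'
#' Runs the game on the Cartesian grid of effort costs and reward weights
#' and reports the late-window stock and final per-agent assets per cell —
#' the phase diagram of greed versus restraint.
#'
#' @inheritParams run_cprg
#' @param cost_values Sweep of effort costs `c`.
#' @param weight_values Sweep of reward weights `w`.
#' @return A tibble with one row per `(c, w)` cell: `c`, `w`,
#'   `median_late_N`, `median_final_assets`, `depleted_fraction`.
#' @export
sweep_cost_weight <- function(params = cprg_params(),
                              cost_values = seq(0.1, 0.9, by = 0.1),
                              weight_values = seq(0.1, 0.9, by = 0.1),
                              n_agents = 10, rounds = 5000, replicates = 50,
                              base_seed = 1, learner = learner_config(),
                              N0 = NULL, initial_assets = 1000) {
  grid <- tidyr::expand_grid(c = cost_values, w = weight_values)
  purrr::pmap_dfr(grid, function(c, w) {
    p <- params
    p$c <- c
    sim <- run_cprg(validate_params(unclass(p)), n_agents = n_agents,
                    rounds = rounds, replicates = replicates,
                    base_seed = base_seed, learner = learner,
                    reward = reward_spec(w), N0 = N0,
                    initial_assets = initial_assets, record_agents = FALSE)
    g <- glance(sim)
    tibble::tibble(c = c, w = w,
                   median_late_N = g$median_late_N,
                   median_final_assets = g$median_final_assets,
                   depleted_fraction = g$depleted_fraction)
  })
}

#' Harvest-versus-growth phase series
#'
#' The ordered `(G_t, H_t)` pairs of a run, for phase plotting: a population
#' that has learnt to harvest sustainably tracks the diagonal `H = G` near
#' the optimal equilibrium.
#'
#' @param sim A `cprg_sim` object.
#' @return A tibble with `replicate`, `t`, `G`, `H`, `N`.
#' @export
phase_series <- function(sim) {
  stopifnot(inherits(sim, "cprg_sim"))
  sim$rounds |> dplyr::select("replicate", "t", "G", "H", "N")
}

#' Late-window phase statistics
#'
#' The mean absolute harvest-growth gap `|H - G|` and the mean distance of
#' the stock from the optimal equilibrium, early window versus late window.
#' Settling behaviour shows as a late gap below the early one.
#'
#' @param sim A `cprg_sim` object.
#' @param window Number of rounds in each window.
#' @return A tibble with one row per window (`early`, `late`).
#' @export
phase_summary <- function(sim, window = NULL) {
  stopifnot(inherits(sim, "cprg_sim"))
  w <- window %||% default_late_window(sim$rounds_per_replicate)
  eq <- cprg_equilibria(sim$params)
  rounds <- sim$rounds_per_replicate
  sim$rounds |>
    dplyr::mutate(window = dplyr::case_when(
      .data$t <= w ~ "early",
      .data$t > rounds - w ~ "late",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$window)) |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(mean_abs_gap = mean(abs(.data$H - .data$G)),
                     mean_N_offset = mean(.data$N - eq$E_optimal),
                     .groups = "drop")
}
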