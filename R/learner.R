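#' Learner configuration
#'
#' Hyperparameters of the tabular Q-learning harvesters. The learned state
#' is the binned resource level only; the agent's own effort, the group
#' effort and the payoff enter through the reward, which keeps the table
#' small and matches what an agent can observe. Defaults were chosen so
#' that a group of up to ~10 independent learners reliably discovers
#' sustainable play within a few thousand rounds; see the package vignette
#' for the reasoning behind each value.
#'
#' @param n_actions Number of discrete effort levels per agent (>= 2).
#' @param n_state_bins Number of equal-width resource-level bins (>= 1).
#' @param learning_rate Q-update step size, in \[0, 1\]. Zero freezes the
#'   tables, which pins the policy — useful for fixed-policy baselines.
#' @param discount Future-reward discount, in \[0, 1).
#' @param epsilon Initial exploration probability, in \[0, 1\].
#' @param epsilon_decay Multiplicative per-round decay of epsilon.
#' @param epsilon_floor Lower limit of epsilon. Kept well above zero by
#'   default: the environment is never stationary from one agent's point of
#'   view, and sustained exploration is what keeps the social dilemma alive.
#' @param q_init Initial action-value estimate.
#' @param tie_break How greedy selection resolves exactly tied action
#'   values: `"first"` (lowest effort, a cautious prior — the default),
#'   `"last"` (highest effort) or `"random"` (uniform over the tied set).
#' @param weight_on Which trend the reward weight `w` multiplies:
#'   `"profit"` (the individual profit trend; the default) or
#'   `"sustainability"`.
#' @return An object of class `cprg_learner`.
#' @export
learner_config <- function(n_actions = 5, n_state_bins = 10,
                           learning_rate = 0.1, discount = 0.9,
                           epsilon = 0.2, epsilon_decay = 0.999,
                           epsilon_floor = 0.1, q_init = 0,
                           tie_break = c("first", "random", "last"),
                           weight_on = c("profit", "sustainability")) {
  tie_break <- match.arg(tie_break)
  weight_on <- match.arg(weight_on)
  if (n_actions < 2) stop("`n_actions` must be >= 2", call. = FALSE)
  if (n_state_bins < 1) stop("`n_state_bins` must be >= 1", call. = FALSE)
  if (learning_rate < 0 || learning_rate > 1) {
    stop("`learning_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (discount < 0 || discount >= 1) {
    stop("`discount` must lie in [0, 1)", call. = FALSE)
  }
  for (e in c(epsilon, epsilon_decay, epsilon_floor)) {
    if (e < 0 || e > 1) stop("epsilon settings must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_actions = as.integer(n_actions),
                 n_state_bins = as.integer(n_state_bins),
                 learning_rate = learning_rate, discount = discount,
                 epsilon = epsilon, epsilon_decay = epsilon_decay,
                 epsilon_floor = epsilon_floor, q_init = q_init,
                 tie_break = tie_break, weight_on = weight_on),
            class = "cprg_learner")
}

as_learner_config <- function(x) {
  if (inherits(x, "cprg_learner")) return(x)
  if (is.list(x)) return(do.call(learner_config, x))
  stop("cannot interpret `learner`; use learner_config()", call. = FALSE)
}

#' Reward specification
#'
#' The per-round reward is a convex combination of two trend signals,
#' `R = w * xi + (1 - w) * lambda`, where `xi` is the sign of the agent's
#' own payoff (individual wealth motive) and `lambda` the sign of the
#' resource's net growth (collective sustainability norm). Both components
#' are trends only — their magnitudes never enter — so the reward always
#' lies in `[-1, 1]`.
#'
#' @param w Weight on the profit trend, in \[0, 1\]. `w = 1` gives a purely
#'   profit-guided agent, `w = 0` a purely sustainability-guided one.
#'   (The `weight_on` switch in [learner_config()] flips this convention.)
#' @return An object of class `cprg_reward`.
#' @export
reward_spec <- function(w = 0.5) {
  if (!is.numeric(w) || length(w) != 1L || w < 0 || w > 1) {
    stop("`w` must be a single number in [0, 1]", call. = FALSE)
  }
  structure(list(w = w), class = "cprg_reward")
}

as_reward_spec <- function(x) {
  if (inherits(x, "cprg_reward")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(reward_spec(x))
  if (is.list(x)) return(do.call(reward_spec, x))
  stop("cannot interpret `reward`; use reward_spec()", call. = FALSE)
}

#' Sustainability trend signal
#'
#' The sign of the round's net growth: `1` when the stock grew, `0` when it
#' was unchanged, `-1` when it declined. Uses the unclamped net growth of
#' the round in which the action was taken, so the signal is honest even
#' when the stock update was clamped at the boundaries.
#'
#' @param net_growth Net growth `G - H` (stock units). Vectorised.
#' @return Trend(s) in `{-1, 0, 1}`.
#' @export
sustainability_signal <- function(net_growth) sign(net_growth)

#' Profit trend signal
#'
#' The sign of the agent's own payoff: `1` for a profit, `0` for breaking
#' even, `-1` for a loss. Magnitude never enters.
#'
#' @param pi Per-agent payoff(s) (currency). Vectorised.
#' @return Trend(s) in `{-1, 0, 1}`.
#' @export
profit_signal <- function(pi) sign(pi)

#' Weighted trend reward
#'
#' `R = w * xi + (1 - w) * lambda` (with `weight_on = "sustainability"`,
#' the roles of the two trends are swapped).
#'
#' @param xi Profit trend(s) in `{-1, 0, 1}`.
#' @param lambda Sustainability trend(s) in `{-1, 0, 1}`.
#' @param spec A [reward_spec()] (or a bare weight).
#' @param weight_on Which component `w` multiplies.
#' @return Reward(s) in `[-1, 1]`.
#' @examples
#' shaped_reward(1, -1, reward_spec(0.5)) # 0
#' @export
shaped_reward <- function(xi, lambda, spec = reward_spec(),
                          weight_on = c("profit", "sustainability")) {
  spec <- as_reward_spec(spec)
  weight_on <- match.arg(weight_on)
  if (weight_on == "profit") {
    spec$w * xi + (1 - spec$w) * lambda
  } else {
    spec$w * lambda + (1 - spec$w) * xi
  }
}

#' Discretise the resource level into a state bin
#'
#' Equal-width binning of `[0, N_max]`; the right edge (a full stock) falls
#' in the top bin.
#'
#' @param N Resource level(s) in `[0, N_max]`.
#' @param config A [learner_config()].
#' @param params A [cprg_params()].
#' @return Integer bin index(es) in `1..n_state_bins`.
#' @export
discretize_state <- function(N, config = learner_config(),
                             params = cprg_params()) {
  config <- as_learner_config(config)
  params <- as_cprg_params(params)
  check_stock(N, params)
  pmin(floor(N / params$N_max * config$n_state_bins) + 1L,
       config$n_state_bins)
}

#' Per-agent action grid
#'
#' `n_actions` equally spaced effort levels spanning
#' `[X_min / n_agents, X_max / n_agents]`, so that symmetric play spans
#' exactly the feasible cumulative-effort range `[X_min, X_max]`.
#'
#' @param config A [learner_config()].
#' @param params A [cprg_params()].
#' @param n_agents Number of harvesters (>= 1).
#' @return Numeric vector of effort levels, increasing.
#' @examples
#' action_grid(n_agents = 10) # 10, 20, 30, 40, 50
#' @export
action_grid <- function(config = learner_config(), params = cprg_params(),
                        n_agents = 1) {
  config <- as_learner_config(config)
  params <- as_cprg_params(params)
  if (n_agents < 1) stop("`n_agents` must be >= 1", call. = FALSE)
  seq(params$X_min / n_agents, params$X_max / n_agents,
      length.out = config$n_actions)
}

#' Initialise a Q table
#'
#' @param config A [learner_config()].
#' @return A `n_state_bins x n_actions` matrix filled with `q_init`.
#' @export
init_q_table <- function(config = learner_config()) {
  config <- as_learner_config(config)
  matrix(config$q_init, nrow = config$n_state_bins,
         ncol = config$n_actions)
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon`, a uniformly random action; otherwise the
#' action with the highest estimated value in the current state's row. Tied
#' maxima are resolved by the learner's `tie_break` rule. All randomness
#' comes from R's RNG stream, so runs are reproducible under a seed.
#'
#' @param q_table Q matrix (states x actions).
#' @param state_bin Current state index.
#' @param epsilon Exploration probability for this round.
#' @param tie_break Tie rule; see [learner_config()].
#' @return An action index.
#' @export
select_action <- function(q_table, state_bin, epsilon,
                          tie_break = c("first", "random", "last")) {
  tie_break <- match.arg(tie_break)
  n_actions <- ncol(q_table)
  if (stats::runif(1) < epsilon) {
    return(sample.int(n_actions, 1L))
  }
  q <- q_table[state_bin, ]
  if (tie_break == "first") return(which.max(q))
  tied <- which(q == max(q))
  if (length(tied) == 1L) return(tied)
  if (tie_break == "last") return(tied[length(tied)])
  tied[sample.int(length(tied), 1L)]
}

#' One-step Q-learning update
#'
#' The standard Watkins update
#' `Q(s, a) <- Q(s, a) + eta * (R + gamma * max_a' Q(s', a') - Q(s, a))`.
#' Only the visited entry changes.
#'
#' @param q_table Q matrix (states x actions).
#' @param state_bin,action Visited state and action indices.
#' @param reward Observed reward.
#' @param next_state_bin Successor state index.
#' @param config A [learner_config()] supplying `learning_rate` and
#'   `discount`.
#' @return The updated Q matrix.
#' @export
q_update <- function(q_table, state_bin, action, reward, next_state_bin,
                     config = learner_config()) {
  config <- as_learner_config(config)
  target <- reward + config$discount * max(q_table[next_state_bin, ])
  q_table[state_bin, action] <- q_table[state_bin, action] +
    config$learning_rate * (target - q_table[state_bin, action])
  q_table
}
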