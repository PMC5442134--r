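# Independent oracles, kept deliberately separate from the package's own
# arithmetic: harvest in the log domain, and optima / sign boundaries by
# brute-force search on fine grids.

oracle_harvest <- function(X, N, p) {
  if (X == 0 || N == 0) return(0)
  exp(log(p$beta) + p$alpha * log(X) + (1 - p$alpha) * log(N))
}

oracle_growth <- function(N, p) p$r_g * N * (1 - N / p$N_max)

oracle_net_growth <- function(X, N, p) oracle_growth(N, p) - oracle_harvest(X, N, p)

oracle_profit <- function(X, N, p) oracle_harvest(X, N, p) - p$c * X

# largest X on a fine grid with f(X) >= 0 (0 if none)
oracle_sign_bound <- function(f, x_max = 2000, step = 0.01) {
  xs <- seq(step, x_max, by = step)
  ok <- vapply(xs, f, numeric(1)) >= 0
  if (!any(ok)) 0 else xs[max(which(ok))]
}

oracle_grid_argmax <- function(f, lo, hi, n = 20001) {
  xs <- seq(lo, hi, length.out = n)
  ys <- vapply(xs, f, numeric(1))
  list(x = xs[which.max(ys)], value = max(ys))
}

p_ref <- cprg_params()

smoke_sim <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- run_cprg(rounds = 150, replicates = 2, n_agents = 3,
                        base_seed = 11)
    }
    memo
  }
})
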