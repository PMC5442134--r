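test_that("sustainable effort bound separates the sign of net growth", {
  expect_equal(sustainable_effort_bound(0, p_ref), 0)
  expect_equal(sustainable_effort_bound(1000, p_ref), 0)

  # brute-force sign-change oracle at a reference stock
  b500 <- oracle_sign_bound(function(X) oracle_net_growth(X, 500, p_ref))
  expect_equal(sustainable_effort_bound(500, p_ref), b500, tolerance = 1e-3)
  expect_equal(sustainable_effort_bound(500, p_ref), 130.55, tolerance = 1e-3)

  set.seed(3)
  for (k in 1:200) {
    N <- runif(1, 1, 999)
    X <- runif(1, 1, 800)
    bound <- sustainable_effort_bound(N, p_ref)
    gap <- X - bound
    if (abs(oracle_net_growth(X, N, p_ref)) > 1e-9) {
      expect_equal(oracle_net_growth(X, N, p_ref) >= 0, gap <= 1e-9,
                   info = sprintf("N=%.3f X=%.3f", N, X))
    }
  }
})

test_that("profitable effort bound is linear in N and separates profit sign", {
  b1000 <- oracle_sign_bound(function(X) oracle_profit(X, 1000, p_ref))
  expect_equal(profitable_effort_bound(1000, p_ref), b1000, tolerance = 1e-3)
  expect_equal(profitable_effort_bound(1000, p_ref), 709.43, tolerance = 1e-3)
  expect_equal(profitable_effort_bound(500, p_ref),
               profitable_effort_bound(1000, p_ref) / 2, tolerance = 1e-12)
  expect_equal(profitable_effort_bound(2 * 123.4, p_ref),
               2 * profitable_effort_bound(123.4, p_ref), tolerance = 1e-12)

  # monotone decreasing in cost
  costs <- c(0.1, 0.3, 0.5, 0.9)
  bounds <- vapply(costs, function(cc) {
    profitable_effort_bound(600, cprg_params(c = cc))
  }, numeric(1))
  expect_true(all(diff(bounds) < 0))
  expect_error(profitable_effort_bound(600, cprg_params(c = 0)), "unbounded")

  set.seed(4)
  for (k in 1:200) {
    N <- runif(1, 1, 999)
    X <- runif(1, 1, 800)
    gap <- X - profitable_effort_bound(N, p_ref)
    if (abs(oracle_profit(X, N, p_ref)) > 1e-9) {
      expect_equal(oracle_profit(X, N, p_ref) >= 0, gap <= 1e-9)
    }
  }
})

test_that("MSY maximiser is the minimum feasible effort", {
  for (N in c(10, 250, 500, 900, 1000)) {
    m <- msy(N, p_ref)
    g <- oracle_grid_argmax(function(X) oracle_net_growth(X, N, p_ref),
                            p_ref$X_min, p_ref$X_max)
    expect_equal(m$X, g$x, tolerance = 0.05)
    expect_equal(m$value, g$value, tolerance = 1e-6)
  }
  expect_equal(msy(500, p_ref)$value, 11.06, tolerance = 1e-2)
  expect_lt(msy(1000, p_ref)$value, 0) # no growth to spare at capacity
})

test_that("MEY closed form agrees with grid search across random draws", {
  m <- mey(1000, p_ref)
  expect_equal(m$X, 141.08, tolerance = 1e-2)

  set.seed(12)
  for (k in 1:100) {
    p <- cprg_params(alpha = runif(1, 0.05, 0.95), beta = runif(1, 0.1, 1),
                     c = runif(1, 0.05, 1.5))
    N <- runif(1, 1, p$N_max)
    m <- mey(N, p)
    g <- oracle_grid_argmax(function(X) oracle_profit(X, N, p),
                            p$X_min, p$X_max)
    step <- (p$X_max - p$X_min) / 20000
    expect_lte(abs(m$X - g$x), step + 1e-9)
    expect_gte(m$value, g$value - 1e-6)
  }

  # boundary cases: tiny stock clips to X_min; free effort pushes to X_max
  expect_equal(mey(5, p_ref)$X, p_ref$X_min)
  expect_equal(mey(800, cprg_params(c = 0))$X, p_ref$X_max)
})

test_that("individual best response reduces to MEY alone and exceeds the fair share in company", {
  grid <- seq(10, 500, by = 2.5)

  # alone, the individual objective equals total profit
  br <- individual_best_response(grid, 0, 800, p_ref)
  g <- oracle_grid_argmax(function(X) oracle_profit(X, 800, p_ref), 10, 500,
                          n = length(grid))
  expect_equal(br$x, g$x)

  # an empty stock makes every action pure cost: take the smallest
  br0 <- individual_best_response(grid, 90, 0, p_ref)
  expect_equal(br0$x, 10)

  # the commons dilemma: with nine others at the fair share of the optimal
  # equilibrium, the best response overshoots the own fair share
  eq <- cprg_equilibria(p_ref)
  x_fair <- mean(eq$X_e) / 10
  agent_grid <- action_grid(learner_config(), p_ref, n_agents = 10)
  br10 <- individual_best_response(agent_grid, 9 * x_fair, eq$E_optimal, p_ref)
  expect_gt(br10$x, x_fair)

  expect_error(individual_best_response(numeric(0), 0, 500, p_ref), "empty")
})

test_that("equilibria: closed form, bisection and ordering", {
  eq <- cprg_equilibria(p_ref)

  # closed-form profitability equilibrium, and its numeric cross-check
  expect_equal(eq$E_profitable,
               p_ref$X_min * (p_ref$c / p_ref$beta)^(1 / (1 - p_ref$alpha)),
               tolerance = 1e-12)
  expect_equal(eq$E_profitable, 140.96, tolerance = 1e-2)
  root <- uniroot(function(N) profitable_effort_bound(N, p_ref) - p_ref$X_min,
                  c(1, 999), tol = 1e-9)$root
  expect_equal(eq$E_profitable, root, tolerance = 1e-6)

  # sustainability equilibria are the bound's crossings of X_min
  expect_equal(eq$E1_sustainable, 63.82, tolerance = 1e-2)
  expect_equal(eq$E2_sustainable, 563.10, tolerance = 1e-2)
  expect_equal(sustainable_effort_bound(eq$E1_sustainable, p_ref),
               p_ref$X_min, tolerance = 1e-3)
  expect_equal(sustainable_effort_bound(eq$E2_sustainable, p_ref),
               p_ref$X_min, tolerance = 1e-3)

  # ordering and the optimal equilibrium at the bounds' crossing
  expect_lt(eq$E1_sustainable, eq$E_optimal)
  expect_lt(eq$E_optimal, eq$E2_sustainable)
  expect_equal(eq$E_optimal, 290.8, tolerance = 1)
  expect_equal(sustainable_effort_bound(eq$E_optimal, p_ref),
               profitable_effort_bound(eq$E_optimal, p_ref), tolerance = 2)
  expect_equal(eq$X_e[1], p_ref$X_min)

  # no viable region when the cost is prohibitive
  expect_error(cprg_equilibria(cprg_params(c = 10)), "empty viable region")
})

test_that("viable fraction is ~6% of the action rectangle and grid-stable", {
  vf <- viable_fraction(p_ref)
  expect_equal(vf, 0.0614, tolerance = 0.002)
  # refinement stability well under 0.1 percentage points
  expect_lt(abs(viable_fraction(p_ref, n_grid = 3000) - vf), 0.001)

  # low cost: profitable region swallows the sustainable one
  p_low <- cprg_params(c = 0.2)
  sust_only <- local({
    Ns <- seq(0.5, 999.5, by = 1)
    hi <- sustainable_effort_bound(Ns, p_low)
    mean(pmax(0, pmin(hi, 500) - 100)) / 400
  })
  expect_equal(viable_fraction(p_low), sust_only, tolerance = 5e-4)

  # high cost shrinks the viable pool below the reference
  expect_lt(viable_fraction(cprg_params(c = 0.8)), vf)
})

test_that("yield_analysis bundles curves, equilibria and the fraction tidily", {
  ya <- yield_analysis(p_ref, n_grid = 101)
  expect_s3_class(tidy(ya), "tbl_df")
  expect_equal(nrow(tidy(ya)), 101)
  g <- glance(ya)
  expect_equal(g$E_profitable, 140.96, tolerance = 1e-2)
  expect_equal(g$viable_fraction, 0.0614, tolerance = 0.002)
  expect_s3_class(autoplot(ya), "ggplot")

  cls <- classify_actions(p_ref, n_grid = 40)
  expect_equal(nrow(cls), 1600)
  expect_true(all(cls$viable == (cls$sustainable & cls$profitable)))
})
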