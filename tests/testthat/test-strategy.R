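base_es <- endstate_values(econ_params())

test_that("final-stage treatment decision is forced at the belief extremes", {
  v0 <- treat_stage_value(0, base_es)
  expect_equal(v0$p_treat, 0)
  expect_equal(v0$nmb, base_es$nmb[base_es$state == "I"])
  v1 <- treat_stage_value(1, base_es)
  expect_equal(v1$p_treat, 1)
  expect_equal(v1$nmb, base_es$nmb[base_es$state == "IV"])
})

test_that("treatment decision switches exactly at the closed-form threshold", {
  thr <- as.numeric(treatment_threshold(base_es))
  eps <- 1e-6
  expect_equal(treat_stage_value(thr - eps, base_es)$p_treat, 0)
  expect_equal(treat_stage_value(thr + eps, base_es)$p_treat, 1)
})

test_that("information has non-negative value and useless tests are dross", {
  p <- seq(0, 1, by = 0.05)
  treat <- treat_stage_value(p, base_es)
  cont <- function(q) treat_stage_value(q, base_es)
  # zero-cost informative test can never hurt
  free <- test_stage_value(p, fixture_lik_trs, 0, cont, "trs")
  expect_true(all(free$nmb >= treat$nmb - 1e-9))
  # uninformative test at positive cost is worth exactly the cost less
  flat <- likelihood_table("flat", c(-Inf, 0, Inf), c(0.5, 0.5), c(0.5, 0.5))
  dull <- test_stage_value(p, flat, 100, cont, "trs")
  expect_equal(dull$nmb, treat$nmb - 100, tolerance = 1e-9)
  # hence never chosen by the optimized single-test strategy
  pol <- solve_strategy("iii", base_es, lik_trs = flat, lik_grs = NULL,
                        econ_params(cost_trs = 100))
  expect_false(any(pol$grid$action == "trs"))
})

test_that("dynamic program equals exhaustive policy enumeration on toys", {
  set.seed(99)
  priors <- c(0.05, 0.2, 0.6)
  for (rep in 1:6) {
    es <- random_endstates()
    k1 <- sample(2:3, 1); k2 <- sample(2:3, 1)
    lik1 <- random_likelihood(k1, "trs")
    lik2 <- random_likelihood(k2, "grs")
    pars <- econ_params(cost_trs = stats::runif(1, 0, 400),
                        cost_grs = stats::runif(1, 0, 400))
    # one test only (TRS optimized)
    pol3 <- solve_strategy("iii", es, lik1, NULL, pars, grid = priors)
    # two tests in sequence (TRS then optional GRS)
    pol5 <- solve_strategy("v", es, lik1, lik2, pars, grid = priors)
    for (i in seq_along(priors)) {
      o3 <- oracle_enumerate(priors[i], es, lik1, NULL, pars$cost_trs)
      o5 <- oracle_enumerate(priors[i], es, lik1, lik2,
                             pars$cost_trs, pars$cost_grs)
      expect_equal(pol3$grid$nmb[i], o3$best, tolerance = 1e-9)
      expect_equal(pol5$grid$nmb[i], o5$best, tolerance = 1e-9)
    }
  }
})

test_that("classic two-bin toy matches enumeration", {
  es <- random_endstates()
  lik <- likelihood_table("toy", c(-Inf, 0, Inf), c(0.8, 0.2), c(0.2, 0.8))
  pars <- econ_params(cost_trs = 50)
  pol <- solve_strategy("iii", es, lik, NULL, pars, grid = 0.2)
  o <- oracle_enumerate(0.2, es, lik, NULL, 50)
  expect_equal(pol$grid$nmb, o$best, tolerance = 1e-9)
})

test_that("strategy i is linear in the prior and never treats", {
  pol <- solve_strategy("i", base_es, grid = seq(0, 1, 0.01))
  nI <- base_es$nmb[base_es$state == "I"]
  nIII <- base_es$nmb[base_es$state == "III"]
  expect_equal(pol$grid$nmb, pol$grid$prior * nIII + (1 - pol$grid$prior) * nI)
  expect_true(all(pol$grid$p_treat == 0))
  expect_true(all(pol$grid$action == "none"))
})

test_that("perfect free tests attain the oracle upper bound", {
  perfect <- likelihood_table("perfect", c(-Inf, 0, Inf), c(0, 1), c(1, 0))
  pars <- econ_params(cost_trs = 0, cost_grs = 0)
  pol <- solve_strategy("v", base_es, perfect, perfect, pars,
                        grid = seq(0.01, 0.99, 0.07))
  nI <- base_es$nmb[base_es$state == "I"]
  nIV <- base_es$nmb[base_es$state == "IV"]
  bound <- pol$grid$prior * nIV + (1 - pol$grid$prior) * nI
  expect_equal(pol$grid$nmb, bound, tolerance = 1e-9)
})

test_that("embedded options give the strategy-nesting dominance order", {
  set.seed(31)
  for (rep in 1:3) {
    es <- if (rep == 1) base_es else random_endstates()
    lt <- if (rep == 1) fixture_lik_trs else random_likelihood(4, "trs")
    lg <- if (rep == 1) fixture_lik_grs else random_likelihood(3, "grs")
    pars <- econ_params(cost_trs = stats::runif(1, 50, 300),
                        cost_grs = stats::runif(1, 50, 300))
    vals <- sapply(strategy_ids(), function(id)
      evaluate_strategy(solve_strategy(id, es, lt, lg, pars,
                                       grid = fixture_dist$grid),
                        fixture_dist)$nmb)
    tol <- 1e-9
    expect_gte(vals["v"], vals["iii"] - tol)
    expect_gte(vals["iii"], vals["ii"] - tol)
    expect_gte(vals["ii"], vals["i"] - tol)
    expect_gte(vals["vi"], vals["iv"] - tol)
    expect_gte(vals["iv"], vals["ii"] - tol)
    # optimized segments dominate test-everyone references
    expect_gte(vals["iii"], vals["vii"] - tol)
    expect_gte(vals["iv"], vals["viii"] - tol)
    expect_gte(vals["v"], vals["ix"] - tol)
    expect_gte(vals["v"], vals["x"] - tol)
  }
})

test_that("value functions are convex piecewise-linear in the prior", {
  grid <- seq(0, 1, by = 0.01)
  for (id in c("ii", "iii", "v", "vii", "x")) {
    pol <- solve_strategy(id, base_es, fixture_lik_trs, fixture_lik_grs,
                          econ_params(), grid = grid)
    d2 <- diff(diff(pol$grid$nmb))
    expect_true(all(d2 >= -1e-6), info = id)
  }
})

test_that("NMB/cost/QALY accounting identity holds pointwise and aggregated", {
  wtp <- econ_params()$wtp
  for (id in c("ii", "v", "ix")) {
    pol <- solve_strategy(id, base_es, fixture_lik_trs, fixture_lik_grs)
    expect_equal(pol$grid$nmb, pol$grid$qaly * wtp - pol$grid$cost,
                 tolerance = 1e-8)
    ev <- evaluate_strategy(pol, fixture_dist)
    expect_equal(ev$nmb, ev$qaly * wtp - ev$cost, tolerance = 1e-8)
    expect_true(all(c(ev$share_trs, ev$share_grs, ev$share_treated) >= 0))
    expect_true(all(c(ev$share_trs, ev$share_grs, ev$share_treated) <= 1))
  }
})

test_that("population evaluation averages the per-prior values", {
  pol <- solve_strategy("ii", base_es)
  grid <- pol$grid$prior
  # point mass at one grid prior returns that prior's triple
  pm <- build_risk_distribution(point_mass = 0.30)
  ev <- evaluate_strategy(pol, pm)
  i <- which(grid == 0.30)
  expect_equal(ev$nmb, pol$grid$nmb[i])
  expect_equal(ev$qaly, pol$grid$qaly[i])
  # equal mass at two grid points averages the two triples
  w <- numeric(length(grid)); w[c(11, 51)] <- 0.5
  ev2 <- evaluate_strategy(pol, list(grid = grid, weights = w))
  expect_equal(ev2$nmb, mean(pol$grid$nmb[c(11, 51)]))
  # all mass at zero risk under treatment-optimized: nobody treated
  ev0 <- evaluate_strategy(pol, build_risk_distribution(point_mass = 0))
  expect_equal(ev0$share_treated, 0)
  # invalid weights rejected
  expect_error(evaluate_strategy(pol, list(grid = grid,
                                           weights = w * 2)), "sum to 1")
})

test_that("fixed reference strategies force their tests", {
  for (id in c("vii", "ix", "x")) {
    pol <- solve_strategy(id, base_es, fixture_lik_trs, fixture_lik_grs)
    expect_true(all(pol$grid$p_trs >= 1), info = id)
  }
  polx <- solve_strategy("x", base_es, fixture_lik_trs, fixture_lik_grs)
  expect_true(all(polx$grid$p_grs >= 1 - 1e-12))
  # strategy ix performs GRS only within the fixed updated-risk band
  polix <- solve_strategy("ix", base_es, fixture_lik_trs, fixture_lik_grs)
  expect_true(all(polix$grid$p_grs <= 1))
  seg <- polix$segments
  expect_equal(seg$risk_lo[seg$action == "grs"], 0.10)
  expect_equal(seg$risk_hi[seg$action == "grs"], 0.20)
  # a fixed strategy without its likelihood errors
  expect_error(solve_strategy("vii", base_es, NULL, fixture_lik_grs),
               "requires a TRS")
})

test_that("ranking sorts by decreasing NMB", {
  rk <- compare_strategies(base_es, fixture_lik_trs, fixture_lik_grs,
                           fixture_dist, strategies = c("i", "ii", "v"))
  expect_equal(rk$nmb, sort(rk$nmb, decreasing = TRUE))
  expect_equal(nrow(rk), 3)
  expect_error(rank_strategies(list()), "at least one")
})
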