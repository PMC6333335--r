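test_that("PSA parameter draws are centred on the base case", {
  cfg <- psa_config(seed = 77)
  set.seed(77)
  draws <- replicate(4000, {
    p <- sample_psa_parameters(cfg)
    c(p$disutility_event, p$p_death_given_event,
      p$statin_relative_risk_reduction, p$cost_grs,
      p$cost_nonfatal_event, p$cost_fatal_event)
  })
  m <- rowMeans(draws)
  expect_equal(m[1], 52 / 356, tolerance = 0.02)       # ~0.146 disutility
  expect_equal(m[2], 48 / 221, tolerance = 0.02)       # ~0.217 death prob
  expect_equal(m[3], 45 / 166, tolerance = 0.02)       # ~0.271 risk reduction
  expect_equal(m[4], 200, tolerance = 0.02)            # GRS cost
  expect_equal(m[5], 171 * 116, tolerance = 0.01)      # ~19,836 ~ base 19,860
  expect_equal(m[6], 171 * 14, tolerance = 0.01)       # ~2,394 ~ base 2,417
  # unvaried parameters stay at base case
  set.seed(1)
  p <- sample_psa_parameters(cfg)
  expect_equal(p$cost_trs, 173)
  expect_equal(p$qol_chd_free, 0.903)
})

test_that("PSA distributions hit the stated 95% interval widths", {
  set.seed(5)
  d <- default_psa_distributions()
  q <- function(x) unname(stats::quantile(x, c(0.025, 0.975)) / mean(x))
  # event costs: +/-15% band
  g <- stats::rgamma(1e5, shape = d$cost_nonfatal_event$shape,
                     scale = d$cost_nonfatal_event$scale)
  expect_equal(q(g), c(0.85, 1.15), tolerance = 0.012)
  # death probability: +/-25% band
  b <- stats::rbeta(1e5, d$p_death_given_event$shape1,
                    d$p_death_given_event$shape2)
  expect_equal(q(b), c(0.75, 1.25), tolerance = 0.015)
  # GRS cost: +/-50% band (uniform: 2.5/97.5 percentiles at +/-47.5%)
  u <- stats::runif(1e5, d$cost_grs$min, d$cost_grs$max)
  expect_equal(q(u), c(0.525, 1.475), tolerance = 0.01)
})

test_that("seeded PSA runs are reproducible and shares are exact counts", {
  cfg <- psa_config(n_trials = 12, wtp_grid = c(20000, 50000), seed = 42)
  r1 <- run_psa(cfg, fixture_lik_trs, fixture_lik_grs, fixture_dist)
  r2 <- run_psa(cfg, fixture_lik_trs, fixture_lik_grs, fixture_dist)
  expect_identical(r1$shares, r2$shares)
  expect_identical(r1$winners, r2$winners)
  # recount oracle: shares equal the hand-tallied argmax counts
  for (w in cfg$wtp_grid) {
    tally <- table(factor(r1$winners$winner[r1$winners$wtp == w],
                          levels = strategy_ids()))
    sh <- r1$shares[r1$shares$wtp == w, ]
    expect_equal(sh$share[match(names(tally), sh$strategy_id)],
                 as.vector(tally) / cfg$n_trials)
  }
  expect_true(all(r1$shares$share >= 0 & r1$shares$share <= 1))
  expect_equal(as.vector(tapply(r1$shares$share, r1$shares$wtp, sum)),
               rep(1, 2))
  # scatter pairs exist for every trial
  expect_equal(nrow(r1$scatter), 2 * cfg$n_trials)
})

test_that("degenerate point-mass distributions reproduce the base-case ranking", {
  point_dists <- list(
    disutility_event = list(dist = "point", value = 0.147),
    p_death_given_event = list(dist = "point", value = 0.22),
    statin_relative_risk_reduction = list(dist = "point", value = 0.27),
    cost_grs = list(dist = "point", value = 200),
    cost_nonfatal_event = list(dist = "point", value = 19860),
    cost_fatal_event = list(dist = "point", value = 2417)
  )
  cfg <- psa_config(n_trials = 5, wtp_grid = 50000,
                    distributions = point_dists, seed = 1)
  res <- run_psa(cfg, fixture_lik_trs, fixture_lik_grs, fixture_dist)
  base_rank <- compare_strategies(endstate_values(econ_params()),
                                  fixture_lik_trs, fixture_lik_grs,
                                  fixture_dist)
  expect_true(all(res$winners$winner == base_rank$strategy_id[1]))
  # and per-trial best NMB equals the deterministic base-case optimum
  expect_equal(res$winners$nmb, rep(base_rank$nmb[1], 5), tolerance = 1e-9)
})

test_that("restricting the comparison to one strategy gives share one", {
  cfg <- psa_config(n_trials = 4, wtp_grid = 50000, seed = 2)
  res <- run_psa(cfg, fixture_lik_trs, fixture_lik_grs, fixture_dist,
                 strategies = "ii", scatter_strategy = NULL)
  expect_equal(res$shares$share[res$shares$strategy_id == "ii"], 1)
})

test_that("one-way sensitivity is zero at base case with the published signs", {
  ow <- one_way_sensitivity("cost_nonfatal_event",
                            c(19860 * 0.85, 19860, 19860 * 1.15),
                            fixture_lik_trs, fixture_lik_grs, fixture_dist)
  expect_equal(ow$delta_nmb[2], 0)
  expect_gt(ow$delta_nmb[1], 0)   # cheaper events raise the NMB
  expect_lt(ow$delta_nmb[3], 0)   # dearer events lower it
  expect_error(one_way_sensitivity("not_a_param", 1, fixture_lik_trs,
                                   fixture_lik_grs, fixture_dist),
               "unknown parameter")
})

test_that("re-optimization dominates a frozen policy (envelope property)", {
  # toy instance via the enumeration oracle: value of every deterministic
  # policy is affine in a pure cost parameter, so the base-case argmax can
  # only fall behind the re-optimized maximum when the parameter moves
  set.seed(4)
  es <- random_endstates()
  lik <- random_likelihood(3, "trs")
  p <- 0.25
  costs <- c(0, 150, 300)
  vals <- lapply(costs, function(ct) oracle_enumerate(p, es, lik, NULL, ct))
  frozen <- which.max(vals[[2]]$values)
  for (i in seq_along(costs)) {
    expect_gte(vals[[i]]$best, vals[[i]]$values[frozen])
  }
  # affine in the test cost: midpoint value of the frozen policy interpolates
  fv <- vapply(vals, function(v) v$values[frozen], numeric(1))
  expect_equal(fv[2], mean(fv[c(1, 3)]), tolerance = 1e-9)
})

test_that("two-way sensitivity produces a full, downward-closed grid", {
  wtps <- c(10000, 50000, 90000)
  gcosts <- c(0, 150, 400, 1500)
  tw <- two_way_sensitivity(wtps, gcosts, fixture_lik_trs, fixture_lik_grs,
                            fixture_dist)
  expect_equal(nrow(tw), length(wtps) * length(gcosts))
  # free GRS: TRS & GRS optimized weakly dominates TRS optimized
  for (w in wtps) {
    p <- econ_params(cost_grs = 0, wtp = w)
    vals <- chdstrat:::strategy_population_values(p, fixture_lik_trs,
                                                  fixture_lik_grs,
                                                  fixture_dist,
                                                  c("iii", "v"))
    expect_gte(vals$nmb[vals$strategy_id == "v"],
               vals$nmb[vals$strategy_id == "iii"] - 1e-9)
  }
  # the region where GRS is worth using -- the sequential strategy strictly
  # ahead of TRS-only -- is downward-closed in the GRS cost at fixed WTP:
  # the TRS-only value does not depend on the GRS cost while the sequential
  # value is non-increasing in it, so their gap can only shrink as cost rises
  for (w in wtps) {
    gap <- vapply(sort(gcosts), function(gc) {
      p <- econ_params(wtp = w, cost_grs = gc)
      vals <- chdstrat:::strategy_population_values(p, fixture_lik_trs,
                                                    fixture_lik_grs,
                                                    fixture_dist,
                                                    c("iii", "v"))
      vals$nmb[vals$strategy_id == "v"] - vals$nmb[vals$strategy_id == "iii"]
    }, numeric(1))
    expect_true(all(diff(gap) <= 1e-9))
    uses_grs <- gap > 1e-9
    expect_true(all(diff(as.integer(uses_grs)) <= 0))
  }
  expect_error(two_way_sensitivity(numeric(0), gcosts, fixture_lik_trs,
                                   fixture_lik_grs, fixture_dist),
               "non-empty")
})
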