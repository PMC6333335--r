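#' Default probabilistic sensitivity-analysis distributions
#'
#' One distribution per varied parameter, chosen so that the mean equals the
#' base-case value and the 95\% interval spans the stated band (about
#' +/-15\% for event costs, +/-25\% for the event disutility, death
#' probability and statin risk reduction, +/-50\% for the GRS cost):
#' `disutility_event ~ Beta(52, 304)` (drawn as a magnitude, applied as a
#' loss), `p_death_given_event ~ Beta(48, 173)`,
#' `statin_relative_risk_reduction ~ Beta(45, 121)` (magnitude of the
#' relative reduction), `cost_grs ~ Unif(100, 300)`,
#' `cost_nonfatal_event ~ Gamma(shape 171, scale 116)`,
#' `cost_fatal_event ~ Gamma(shape 171, scale 14)`. Gammas are shape--scale
#' so the mean is `shape * scale`. All other parameters stay at base case.
#'
#' @return A named list of distribution specs (`dist` plus its parameters).
#' @export
default_psa_distributions <- function() {
  list(
    disutility_event = list(dist = "beta", shape1 = 52, shape2 = 304),
    p_death_given_event = list(dist = "beta", shape1 = 48, shape2 = 173),
    statin_relative_risk_reduction = list(dist = "beta", shape1 = 45, shape2 = 121),
    cost_grs = list(dist = "unif", min = 100, max = 300),
    cost_nonfatal_event = list(dist = "gamma", shape = 171, scale = 116),
    cost_fatal_event = list(dist = "gamma", shape = 171, scale = 14)
  )
}

#' Probabilistic sensitivity-analysis configuration
#'
#' @param n_trials Monte Carlo trials per WTP value (1,000 at study scale).
#' @param wtp_grid willingness-to-pay grid in Euros/QALY (0, 2,000, ...,
#'   100,000 at study scale).
#' @param distributions per-parameter distribution specs, as
#'   [default_psa_distributions()].
#' @param seed master seed; every (WTP, trial) pair gets its own derived
#'   substream so single trials are re-runnable in isolation.
#' @return A list of class `psa_config`.
#' @export
psa_config <- function(n_trials = 1000,
                       wtp_grid = seq(0, 100000, by = 2000),
                       distributions = default_psa_distributions(),
                       seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (is.unsorted(wtp_grid)) stop("wtp_grid must be ordered")
  structure(list(n_trials = as.integer(n_trials), wtp_grid = wtp_grid,
                 distributions = distributions, seed = as.integer(seed)),
            class = "psa_config")
}

draw_one <- function(spec) {
  switch(spec$dist,
    beta = stats::rbeta(1, spec$shape1, spec$shape2),
    unif = stats::runif(1, spec$min, spec$max),
    gamma = stats::rgamma(1, shape = spec$shape, scale = spec$scale),
    point = spec$value,
    stop("unknown distribution: ", spec$dist))
}

#' Draw one PSA parameter set
#'
#' Samples every varied parameter from its configured distribution (using
#' the current RNG state) and returns an [econ_params()] object with all
#' unvaried parameters at base case.
#'
#' @param config a [psa_config()].
#' @param base base-case parameters to perturb.
#' @return An `econ_params` object.
#' @export
sample_psa_parameters <- function(config, base = econ_params()) {
  draws <- lapply(config$distributions, draw_one)
  do.call(econ_params, utils::modifyList(as.list(unclass(base)), draws))
}

# Deterministic substream seeds, one per (wtp, trial) cell.
psa_substream_seeds <- function(config) {
  set.seed(config$seed)
  matrix(sample.int(.Machine$integer.max - 1L,
                    length(config$wtp_grid) * config$n_trials),
         nrow = length(config$wtp_grid))
}

# Population value of every strategy under one parameter set; fast path
# without segment bookkeeping.
strategy_population_values <- function(params, lik_trs, lik_grs, dist,
                                       strategies = strategy_ids()) {
  es <- endstate_values(params)
  w <- dist$weights
  out <- lapply(strategies, function(id) {
    mach <- strategy_machinery(id, es, lik_trs, lik_grs, params)
    v <- mach$value_fun(dist$grid)
    data.frame(strategy_id = id,
               nmb = sum(w * v$nmb), cost = sum(w * v$cost),
               qaly = sum(w * v$qaly), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the probabilistic sensitivity analysis
#'
#' For every (WTP value, trial) pair: draws a parameter set, re-derives the
#' end-state values, re-solves the optimized strategies and evaluates the
#' fixed reference strategies under the drawn parameters, and records which
#' strategy attains the maximum population expected NMB. Shares are exact
#' ratios of integer counts over trials. Per-trial incremental (QALY, cost)
#' pairs of a chosen strategy against a reference strategy are returned for
#' cost-effectiveness scatter plots.
#'
#' @param config a [psa_config()].
#' @param lik_trs,lik_grs test [likelihood_table()]s.
#' @param dist a [build_risk_distribution()] result.
#' @param base base-case [econ_params()].
#' @param strategies strategy ids entered in the comparison (default all
#'   ten).
#' @param scatter_strategy,scatter_reference strategy ids for the
#'   incremental scatter (defaults `v` vs `i`); set `scatter_strategy =
#'   NULL` to skip.
#' @return A list of class `psa_result`: `shares` (data frame `wtp`,
#'   `strategy_id`, `share`), `winners` (per-trial argmax, data frame `wtp`,
#'   `trial`, `winner`, `nmb`), and `scatter` (data frame `wtp`, `trial`,
#'   `delta_qaly`, `delta_cost`), plus the `config`.
#' @export
run_psa <- function(config, lik_trs, lik_grs, dist, base = econ_params(),
                    strategies = strategy_ids(),
                    scatter_strategy = "v", scatter_reference = "i") {
  if (config$n_trials < 1) stop("n_trials must be >= 1")
  seeds <- psa_substream_seeds(config)
  do_scatter <- !is.null(scatter_strategy) &&
    all(c(scatter_strategy, scatter_reference) %in% strategies)
  winners <- vector("list", length(config$wtp_grid) * config$n_trials)
  scatter <- if (do_scatter) winners else list()
  idx <- 0L
  for (wi in seq_along(config$wtp_grid)) {
    wtp <- config$wtp_grid[wi]
    for (tr in seq_len(config$n_trials)) {
      idx <- idx + 1L
      set.seed(seeds[wi, tr])
      params <- sample_psa_parameters(config, base)
      params$wtp <- wtp
      vals <- strategy_population_values(params, lik_trs, lik_grs, dist,
                                         strategies)
      best <- which.max(vals$nmb)
      winners[[idx]] <- data.frame(wtp = wtp, trial = tr,
                                   winner = vals$strategy_id[best],
                                   nmb = vals$nmb[best])
      if (do_scatter) {
        a <- vals[vals$strategy_id == scatter_strategy, ]
        b <- vals[vals$strategy_id == scatter_reference, ]
        scatter[[idx]] <- data.frame(wtp = wtp, trial = tr,
                                     delta_qaly = a$qaly - b$qaly,
                                     delta_cost = a$cost - b$cost)
      }
    }
  }
  winners <- do.call(rbind, winners)
  shares <- do.call(rbind, lapply(split(winners, winners$wtp), function(d) {
    counts <- table(factor(d$winner, levels = strategies))
    data.frame(wtp = d$wtp[1], strategy_id = names(counts),
               share = as.vector(counts) / nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(shares) <- NULL
  structure(list(shares = shares, winners = winners,
                 scatter = if (do_scatter) do.call(rbind, scatter)
                           else data.frame(),
                 config = config),
            class = "psa_result")
}

#' One-way sensitivity of a strategy's population NMB
#'
#' Re-optimizes the strategy (by default `v`, TRS & GRS optimized) at each
#' alternative value of one parameter and reports the change in population
#' expected NMB relative to the base case.
#'
#' @param param name of an [econ_params()] field.
#' @param values alternative parameter values.
#' @param lik_trs,lik_grs test [likelihood_table()]s.
#' @param dist a [build_risk_distribution()] result.
#' @param base base-case [econ_params()].
#' @param strategy strategy id to re-optimize, default `"v"`.
#' @return A data frame: `param`, `value`, `nmb`, `delta_nmb` (NMB minus the
#'   base-case NMB of the same strategy).
#' @export
one_way_sensitivity <- function(param, values, lik_trs, lik_grs, dist,
                                base = econ_params(), strategy = "v") {
  if (!param %in% names(base)) stop("unknown parameter: ", param)
  base_nmb <- strategy_population_values(base, lik_trs, lik_grs, dist,
                                         strategy)$nmb
  rows <- lapply(values, function(v) {
    p <- base
    p[[param]] <- v
    p <- validate_econ_params(p)
    nmb_v <- strategy_population_values(p, lik_trs, lik_grs, dist,
                                        strategy)$nmb
    data.frame(param = param, value = v, nmb = nmb_v,
               delta_nmb = nmb_v - base_nmb, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-way sensitivity over the WTP threshold and the GRS cost
#'
#' For every (WTP, GRS cost) combination, re-solves all strategies and flags
#' whether the TRS & GRS optimized strategy attains the maximum population
#' expected NMB (ties counted as optimal).
#'
#' @param wtp_values WTP thresholds in Euros/QALY.
#' @param grs_cost_values GRS costs in Euros.
#' @param lik_trs,lik_grs test [likelihood_table()]s.
#' @param dist a [build_risk_distribution()] result.
#' @param base base-case [econ_params()].
#' @param strategies strategy set entered in the comparison.
#' @param target strategy whose optimality is mapped, default `"v"`.
#' @return A long-format data frame: `wtp`, `grs_cost`, `optimal` (logical).
#' @export
two_way_sensitivity <- function(wtp_values, grs_cost_values, lik_trs,
                                lik_grs, dist, base = econ_params(),
                                strategies = strategy_ids(), target = "v") {
  if (!length(wtp_values) || !length(grs_cost_values))
    stop("value grids must be non-empty")
  combos <- expand.grid(wtp = wtp_values, grs_cost = grs_cost_values)
  opt <- vapply(seq_len(nrow(combos)), function(i) {
    p <- base
    p$wtp <- combos$wtp[i]
    p$cost_grs <- combos$grs_cost[i]
    p <- validate_econ_params(p)
    vals <- strategy_population_values(p, lik_trs, lik_grs, dist, strategies)
    vals$nmb[vals$strategy_id == target] >= max(vals$nmb) - 1e-9
  }, logical(1))
  combos$optimal <- opt
  combos
}
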