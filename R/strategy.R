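#' @name strategies
#' @title The ten population testing-and-treatment strategies
#'
#' @description
#' The model compares six optimized strategies and four predetermined
#' reference strategies for targeting TRS/GRS testing and statin treatment:
#'
#' * `i`    no treatment: nobody tested or treated;
#' * `ii`   treatment optimized on prior risk alone;
#' * `iii`  TRS for an optimal segment, then treatment optimized;
#' * `iv`   GRS for an optimal segment, then treatment optimized;
#' * `v`    TRS for an optimal segment, then optionally GRS for an optimal
#'          segment of updated risks;
#' * `vi`   as `v` with the test order reversed;
#' * `vii`  TRS for all;
#' * `viii` GRS for all;
#' * `ix`   TRS for all, then GRS for updated risks in 10--20\%;
#' * `x`    both tests for all.
#'
#' The option to skip testing (and to treat or not on prior risk) is embedded
#' in `iii`--`vi`; skipping the first test of `v`/`vi` forecloses the second.
#' The fixed strategies `vii`--`x` force their tests but still treat
#' optimally at the terminal belief. Belief (current risk estimate) is the
#' only state: every decision rule is a function of risk alone.
NULL

strategy_ids <- function() c("i", "ii", "iii", "iv", "v", "vi",
                             "vii", "viii", "ix", "x")

strategy_labels <- function() {
  c(i = "No treatment", ii = "Treatment optimized", iii = "TRS optimized",
    iv = "GRS optimized", v = "TRS & GRS optimized",
    vi = "GRS & TRS optimized", vii = "TRS for all", viii = "GRS for all",
    ix = "TRS for all & GRS for 10-20%", x = "TRS & GRS for all")
}

# A node value over a belief vector: expected NMB (EUR), cost (positive
# magnitude, EUR), QALYs, and reach-weighted probabilities of treatment and
# of each test being performed in the subtree.
node_value <- function(nmb, cost, qaly, p_treat, p_trs, p_grs) {
  list(nmb = nmb, cost = cost, qaly = qaly,
       p_treat = p_treat, p_trs = p_trs, p_grs = p_grs)
}

#' Value of the final treat/no-treat decision at a belief
#'
#' Treating values the patient as `p * state_IV + (1-p) * state_II`; not
#' treating as `p * state_III + (1-p) * state_I` (componentwise over NMB,
#' cost, QALYs). The NMB-maximizing action is returned; ties go to no
#' treatment.
#'
#' @param p belief vector (risk of a 10-year CHD event), values in `[0,1]`.
#' @param endstates an [endstate_values()] data frame.
#' @param forced `"optimal"` (default), `"never"` (strategy `i`), or
#'   `"always"`.
#' @return A list of vectors `nmb`, `cost` (positive magnitude), `qaly`,
#'   `p_treat`, `p_trs`, `p_grs`, each aligned with `p`.
#' @export
treat_stage_value <- function(p, endstates,
                              forced = c("optimal", "never", "always")) {
  forced <- match.arg(forced)
  v <- split(endstates[c("cost", "qaly", "nmb")], endstates$state)
  cm <- lapply(v, function(s) -s$cost)  # cost magnitudes
  treat_nmb <- p * v$IV$nmb + (1 - p) * v$II$nmb
  none_nmb <- p * v$III$nmb + (1 - p) * v$I$nmb
  treat <- switch(forced,
    optimal = treat_nmb > none_nmb,
    never = rep(FALSE, length(p)),
    always = rep(TRUE, length(p)))
  node_value(
    nmb = ifelse(treat, treat_nmb, none_nmb),
    cost = ifelse(treat, p * cm$IV + (1 - p) * cm$II,
                  p * cm$III + (1 - p) * cm$I),
    qaly = ifelse(treat, p * v$IV$qaly + (1 - p) * v$II$qaly,
                  p * v$III$qaly + (1 - p) * v$I$qaly),
    p_treat = as.numeric(treat),
    p_trs = numeric(length(p)),
    p_grs = numeric(length(p))
  )
}

#' Expected value of performing a test and continuing optimally
#'
#' Takes the expectation of the continuation value over the marginal result
#' distribution at the current belief, with posteriors evaluated exactly (no
#' grid rounding): `sum_bins P(bin | p) * continuation(posterior(p, bin))`,
#' less the test cost (subtracted from NMB, added to expected cost).
#'
#' @param p belief vector.
#' @param lik the test's [likelihood_table()].
#' @param test_cost test cost in Euros.
#' @param continuation function mapping a belief vector to a node-value list,
#'   e.g. a wrapped [treat_stage_value()].
#' @param test `"trs"` or `"grs"`; which test counter to increment.
#' @return A node-value list aligned with `p`.
#' @export
test_stage_value <- function(p, lik, test_cost, continuation,
                             test = c("trs", "grs")) {
  test <- match.arg(test)
  k <- n_bins(lik)
  n <- length(p)
  M <- matrix(marginal_result_prob(p, lik), nrow = n, ncol = k)
  post <- vapply(seq_len(k), function(b) posterior_update(p, b, lik),
                 numeric(n))
  post <- matrix(post, nrow = n, ncol = k)
  cv <- continuation(as.vector(post))
  ex <- function(x) rowSums(M * matrix(x, nrow = n, ncol = k))
  out <- node_value(
    nmb = ex(cv$nmb) - test_cost,
    cost = ex(cv$cost) + test_cost,
    qaly = ex(cv$qaly),
    p_treat = ex(cv$p_treat),
    p_trs = ex(cv$p_trs),
    p_grs = ex(cv$p_grs)
  )
  if (test == "trs") out$p_trs <- out$p_trs + 1 else out$p_grs <- out$p_grs + 1
  out
}

# NMB-maximizing choice between two options; ties prefer `a` (the option
# with fewer tests by construction of every call site).
choose_node <- function(a, b) {
  pick_b <- b$nmb > a$nmb
  out <- lapply(stats::setNames(names(a), names(a)),
                function(f) ifelse(pick_b, b[[f]], a[[f]]))
  out$chose_b <- pick_b
  out
}

# Build the value function and per-stage decision rules of one strategy.
strategy_machinery <- function(strategy_id, endstates, lik_trs, lik_grs,
                               params, grs_interval = c(0.10, 0.20)) {
  id <- match.arg(strategy_id, strategy_ids())
  needs_trs <- id %in% c("iii", "v", "vi", "vii", "ix", "x")
  needs_grs <- id %in% c("iv", "v", "vi", "viii", "ix", "x")
  if (needs_trs && is.null(lik_trs)) stop("strategy ", id, " requires a TRS likelihood table")
  if (needs_grs && is.null(lik_grs)) stop("strategy ", id, " requires a GRS likelihood table")

  treatN <- function(q) treat_stage_value(q, endstates)
  noneN <- function(q) treat_stage_value(q, endstates, forced = "never")
  trsN <- function(q, cont) test_stage_value(q, lik_trs, params$cost_trs, cont, "trs")
  grsN <- function(q, cont) test_stage_value(q, lik_grs, params$cost_grs, cont, "grs")
  eps <- 1e-12
  in_seg <- function(q) q >= grs_interval[1] - eps & q <= grs_interval[2] + eps

  trs_rule_true <- function(q) rep(TRUE, length(q))
  stages <- list()
  value_fun <- switch(id,
    i = noneN,
    ii = treatN,
    iii = {
      stages <- list(list(test = "trs",
                          rule = function(q) trsN(q, treatN)$nmb > treatN(q)$nmb))
      function(q) choose_node(treatN(q), trsN(q, treatN))
    },
    iv = {
      stages <- list(list(test = "grs",
                          rule = function(q) grsN(q, treatN)$nmb > treatN(q)$nmb))
      function(q) choose_node(treatN(q), grsN(q, treatN))
    },
    v = {
      inner <- function(q) choose_node(treatN(q), grsN(q, treatN))
      stages <- list(
        list(test = "trs", rule = function(q) trsN(q, inner)$nmb > treatN(q)$nmb),
        list(test = "grs", rule = function(q) grsN(q, treatN)$nmb > treatN(q)$nmb))
      function(q) choose_node(treatN(q), trsN(q, inner))
    },
    vi = {
      inner <- function(q) choose_node(treatN(q), trsN(q, treatN))
      stages <- list(
        list(test = "grs", rule = function(q) grsN(q, inner)$nmb > treatN(q)$nmb),
        list(test = "trs", rule = function(q) trsN(q, treatN)$nmb > treatN(q)$nmb))
      function(q) choose_node(treatN(q), grsN(q, inner))
    },
    vii = {
      stages <- list(list(test = "trs", rule = trs_rule_true))
      function(q) trsN(q, treatN)
    },
    viii = {
      stages <- list(list(test = "grs", rule = trs_rule_true))
      function(q) grsN(q, treatN)
    },
    ix = {
      seg <- function(q) {
        base <- treatN(q)
        g <- grsN(q, treatN)
        sel <- in_seg(q)
        out <- lapply(stats::setNames(names(base), names(base)),
                      function(f) ifelse(sel, g[[f]], base[[f]]))
        out
      }
      stages <- list(list(test = "trs", rule = trs_rule_true),
                     list(test = "grs", rule = in_seg))
      function(q) trsN(q, seg)
    },
    x = {
      stages <- list(list(test = "trs", rule = trs_rule_true),
                     list(test = "grs", rule = trs_rule_true))
      function(q) trsN(q, function(q2) grsN(q2, treatN))
    })
  treat_rule <- if (id == "i") function(q) rep(FALSE, length(q))
                else function(q) treat_stage_value(q, endstates)$p_treat > 0
  list(id = id, value_fun = value_fun, stages = stages,
       treat_rule = treat_rule)
}

# Contiguous TRUE runs of a logical vector over a risk grid -> intervals.
segments_from_rule <- function(grid, flag) {
  if (!any(flag)) return(data.frame(risk_lo = numeric(0), risk_hi = numeric(0)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(risk_lo = grid[starts[keep]], risk_hi = grid[ends[keep]])
}

#' Solve one strategy by backward induction
#'
#' Backward induction over the strategy's decision tree: the treat/no-treat
#' decision is solved first at every reachable belief, then each preceding
#' test decision by taking the expectation of the continuation value over the
#' marginal result distribution. Posterior beliefs inside the recursion are
#' evaluated exactly; the prior-risk grid (default 0\%, 1\%, ..., 100\%) is
#' used for reporting and population weighting only.
#'
#' @param strategy_id one of `"i"` ... `"x"` (see [strategies]).
#' @param endstates an [endstate_values()] data frame.
#' @param lik_trs,lik_grs [likelihood_table()]s for the tests the strategy
#'   may use (`NULL` allowed when unused).
#' @param params an [econ_params()] object (supplies the test costs).
#' @param grid prior-risk grid, default `seq(0, 1, by = 0.01)`.
#' @param grs_interval updated-risk interval (closed) in which strategy `ix`
#'   forces the GRS, default `c(0.10, 0.20)`.
#' @return An object of class `policy_solution`: list with `strategy_id`,
#'   `grid` (data frame: `prior`, `action` — the optimal first action among
#'   `treat`/`none`/`trs`/`grs` —, `nmb`, `cost`, `qaly`, and reach-weighted
#'   `p_trs`, `p_grs`, `p_treat`), and `segments` (data frame: `stage`,
#'   `action`, `risk_lo`, `risk_hi`; test stages are indexed in strategy
#'   order, the terminal treatment rule has stage `"treat"`).
#' @export
solve_strategy <- function(strategy_id, endstates, lik_trs = NULL,
                           lik_grs = NULL, params = econ_params(),
                           grid = seq(0, 1, by = 0.01),
                           grs_interval = c(0.10, 0.20)) {
  mach <- strategy_machinery(strategy_id, endstates, lik_trs, lik_grs,
                             params, grs_interval)
  val <- mach$value_fun(grid)

  first_test <- if (length(mach$stages)) mach$stages[[1]]$test else NA_character_
  if (!is.na(first_test)) {
    tested_first <- mach$stages[[1]]$rule(grid)
  } else {
    tested_first <- rep(FALSE, length(grid))
  }
  treat_now <- mach$treat_rule(grid)
  action <- ifelse(tested_first, first_test,
                   ifelse(treat_now, "treat", "none"))

  segs <- list()
  for (s in seq_along(mach$stages)) {
    st <- mach$stages[[s]]
    sg <- segments_from_rule(grid, st$rule(grid))
    if (nrow(sg))
      segs[[length(segs) + 1]] <- cbind(stage = as.character(s),
                                        action = st$test, sg)
  }
  tr <- segments_from_rule(grid, treat_now)
  if (nrow(tr))
    segs[[length(segs) + 1]] <- cbind(stage = "treat", action = "treat", tr)
  segments <- if (length(segs)) do.call(rbind, segs)
              else data.frame(stage = character(0), action = character(0),
                              risk_lo = numeric(0), risk_hi = numeric(0))

  structure(
    list(strategy_id = mach$id,
         grid = data.frame(prior = grid, action = action, nmb = val$nmb,
                           cost = val$cost, qaly = val$qaly,
                           p_trs = val$p_trs, p_grs = val$p_grs,
                           p_treat = val$p_treat),
         segments = segments),
    class = "policy_solution"
  )
}

#' Population-weighted evaluation of a solved strategy
#'
#' Averages the per-prior expected NMB, cost, and QALYs over a population
#' risk distribution, and accumulates the population shares tested with each
#' test and treated by propagating the distribution mass through the policy's
#' branch probabilities.
#'
#' @param policy a [solve_strategy()] result.
#' @param dist a risk distribution from [build_risk_distribution()] (list
#'   with `grid` and `weights` on the same prior grid as the policy).
#' @return A one-row data frame: `strategy_id`, `label`, `nmb`, `cost`,
#'   `qaly`, `share_trs`, `share_grs`, `share_treated`.
#' @export
evaluate_strategy <- function(policy, dist) {
  stopifnot(inherits(policy, "policy_solution"))
  w <- dist$weights
  if (length(w) != nrow(policy$grid))
    stop("risk distribution and policy grid differ in length")
  if (any(w < 0)) stop("weights must be >= 0")
  if (abs(sum(w) - 1) > 1e-6) stop("weights must sum to 1")
  g <- policy$grid
  data.frame(
    strategy_id = policy$strategy_id,
    label = unname(strategy_labels()[policy$strategy_id]),
    nmb = sum(w * g$nmb),
    cost = sum(w * g$cost),
    qaly = sum(w * g$qaly),
    share_trs = sum(w * g$p_trs),
    share_grs = sum(w * g$p_grs),
    share_treated = sum(w * g$p_treat),
    stringsAsFactors = FALSE
  )
}

#' Rank strategies by expected net monetary benefit
#'
#' @param evals a list of (or a data frame of row-bound)
#'   [evaluate_strategy()] results.
#' @return The combined data frame sorted in decreasing order of `nmb`.
#' @export
rank_strategies <- function(evals) {
  if (is.data.frame(evals)) df <- evals else df <- do.call(rbind, evals)
  if (is.null(df) || !nrow(df)) stop("need at least one strategy evaluation")
  df[order(-df$nmb), , drop = FALSE]
}

#' Solve and evaluate a set of strategies
#'
#' Convenience wrapper: solves each requested strategy, evaluates it on the
#' population risk distribution, and returns the ranking table.
#'
#' @inheritParams solve_strategy
#' @param dist a [build_risk_distribution()] result.
#' @param strategies character vector of strategy ids, default all ten.
#' @return A data frame as from [rank_strategies()].
#' @export
compare_strategies <- function(endstates, lik_trs, lik_grs, dist,
                               params = econ_params(),
                               strategies = strategy_ids(),
                               grid = dist$grid) {
  evals <- lapply(strategies, function(id) {
    pol <- solve_strategy(id, endstates, lik_trs, lik_grs, params, grid)
    evaluate_strategy(pol, dist)
  })
  rank_strategies(evals)
}
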