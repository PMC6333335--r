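# Shared small fixtures: a synthetic cohort with 5-bin likelihood tables and
# the default population risk distribution. Built once per test run.
fixture_cohort <- generate_cohort(cohort_spec(n_subjects = 6000, seed = 11))
fixture_lik_trs <- estimate_likelihoods(fixture_cohort, "trs", n_bins = 5)
fixture_lik_grs <- estimate_likelihoods(fixture_cohort, "grs", n_bins = 5)
fixture_dist <- build_risk_distribution()

# Published end-state values the base case must reproduce (costs negative).
published_endstates <- data.frame(
  state = c("I", "II", "III", "IV"),
  cost = c(0, -1927, -14629, -12058),
  qaly = c(7.706, 7.689, 6.952, 7.143),
  nmb = c(385296, 382516, 332949, 345093)
)

# Random likelihood table with k bins (both columns strictly positive).
random_likelihood <- function(k, test_name = "toy") {
  l1 <- stats::runif(k, 0.05, 1); l0 <- stats::runif(k, 0.05, 1)
  likelihood_table(test_name, c(-Inf, sort(stats::runif(k - 1)), Inf),
                   l1 / sum(l1), l0 / sum(l0))
}

# Synthetic but internally consistent end-state values: nmb = qaly*wtp + cost
# (cost held negative), with qaly(I) >= qaly(III) and |cost(II)| >= |cost(I)|.
random_endstates <- function(wtp = 50000) {
  qaly <- c(I = stats::runif(1, 7, 8), II = stats::runif(1, 6.8, 7.8),
            III = stats::runif(1, 5.5, 7), IV = stats::runif(1, 6, 7.5))
  qaly["III"] <- min(qaly["III"], qaly["I"])
  cost <- -c(I = 0, II = stats::runif(1, 500, 3000),
             III = stats::runif(1, 5000, 20000),
             IV = stats::runif(1, 3000, 18000))
  out <- data.frame(state = names(qaly), cost = unname(cost),
                    qaly = unname(qaly),
                    nmb = unname(qaly * wtp + cost))
  attr(out, "wtp") <- wtp
  out
}

# ---------------------------------------------------------------------------
# Brute-force policy enumeration oracle for the sequential testing problem:
# root choice among {no treatment, treatment, first test}; after each first-
# test result, choice among {no treatment, treatment, second test (if any)};
# after each second-test result, treat or not. Enumerates every deterministic
# policy with explicit probability accounting -- no dynamic programming, no
# package value functions.
# ---------------------------------------------------------------------------
oracle_enumerate <- function(p, endstates, lik1 = NULL, lik2 = NULL,
                             cost1 = 0, cost2 = 0) {
  nm <- stats::setNames(endstates$nmb, endstates$state)
  term <- function(s, a) {
    if (s == 1) { if (a == 1) nm[["IV"]] else nm[["III"]] }
    else        { if (a == 1) nm[["II"]] else nm[["I"]] }
  }
  vals <- c(
    p * term(1, 0) + (1 - p) * term(0, 0),   # never treat
    p * term(1, 1) + (1 - p) * term(0, 1)    # treat everyone
  )
  if (!is.null(lik1)) {
    B1 <- length(lik1$p_result_given_chd)
    # options available after a first-test result: a=0, a=1, or second test
    # with every possible map from its bins to treat decisions
    second_maps <- if (is.null(lik2)) list() else {
      B2 <- length(lik2$p_result_given_chd)
      g <- expand.grid(rep(list(0:1), B2))
      lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
    }
    opt_value <- function(s, k) {
      if (k == 1) return(term(s, 0))
      if (k == 2) return(term(s, 1))
      map <- second_maps[[k - 2]]
      Ls <- if (s == 1) lik2$p_result_given_chd else lik2$p_result_given_no_chd
      sum(vapply(seq_along(map),
                 function(g) Ls[g] * term(s, map[g]), numeric(1))) - cost2
    }
    nopt <- 2 + length(second_maps)
    assign_grid <- expand.grid(rep(list(seq_len(nopt)), B1))
    pol_vals <- vapply(seq_len(nrow(assign_grid)), function(i) {
      ks <- as.integer(assign_grid[i, ])
      v <- 0
      for (s in 0:1) {
        Ps <- if (s == 1) p else 1 - p
        Lb <- if (s == 1) lik1$p_result_given_chd else lik1$p_result_given_no_chd
        for (b in seq_len(B1)) v <- v + Ps * Lb[b] * opt_value(s, ks[b])
      }
      v - cost1
    }, numeric(1))
    vals <- c(vals, pol_vals)
  }
  list(best = max(vals), values = vals)
}
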