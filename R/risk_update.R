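#' Construct a binned likelihood table for a risk-score test
#'
#' Holds the conditional probabilities of each binned test result given the
#' patient's latent 10-year state (CHD event / no event). These conditionals
#' are the engine of Bayesian risk updating: together with a prior risk they
#' determine the posterior after observing a result bin.
#'
#' @param test_name label, e.g. `"trs"` or `"grs"`.
#' @param bin_edges numeric vector of ordered score cut-points of length
#'   `n_bins + 1` (outer edges may be infinite).
#' @param p_result_given_chd,p_result_given_no_chd per-bin conditional
#'   probabilities; each must sum to 1.
#' @return A list of class `likelihood_table`.
#' @export
likelihood_table <- function(test_name, bin_edges, p_result_given_chd,
                             p_result_given_no_chd) {
  n <- length(p_result_given_chd)
  if (length(p_result_given_no_chd) != n)
    stop("conditional distributions must have equal length")
  if (length(bin_edges) != n + 1)
    stop("bin_edges must have length n_bins + 1")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  for (v in list(p_result_given_chd, p_result_given_no_chd)) {
    if (any(v < 0)) stop("probabilities must be >= 0")
    if (abs(sum(v) - 1) > 1e-9) stop("conditional distribution must sum to 1")
  }
  structure(
    list(test_name = test_name, bin_edges = bin_edges,
         p_result_given_chd = p_result_given_chd,
         p_result_given_no_chd = p_result_given_no_chd),
    class = "likelihood_table"
  )
}

#' Number of result bins of a likelihood table
#' @param lik a [likelihood_table()].
#' @return Integer bin count.
#' @export
n_bins <- function(lik) length(lik$p_result_given_chd)

#' Bayesian posterior risk after one test result
#'
#' Updates the probability of a CHD event within 10 years from a prior `p` to
#' `p L1 / (p L1 + (1 - p) L0)` where `L1` and `L0` are the likelihoods of the
#' observed result bin under the event and no-event states. An uninformative
#' result (`L1 = L0`) returns the prior unchanged; absorbing priors 0 and 1
#' are fixed points.
#'
#' @param prior prior risk(s) in `[0, 1]`; vectorized.
#' @param result_bin observed bin index (scalar, 1-based).
#' @param lik a [likelihood_table()].
#' @return Posterior risk(s), same length as `prior`.
#' @examples
#' lik <- likelihood_table("toy", c(-Inf, 0, Inf), c(0.3, 0.7), c(0.1, 0.9))
#' posterior_update(0.10, 1, lik)  # 0.25, likelihood ratio 3
#' @export
posterior_update <- function(prior, result_bin, lik) {
  if (any(prior < 0 | prior > 1)) stop("prior must be in [0,1]")
  if (result_bin < 1 || result_bin > n_bins(lik)) stop("invalid bin index")
  L1 <- lik$p_result_given_chd[result_bin]
  L0 <- lik$p_result_given_no_chd[result_bin]
  if (L1 == 0 && L0 == 0) stop("impossible result: both likelihoods are zero")
  if (L1 == L0) return(prior)
  num <- prior * L1
  den <- num + (1 - prior) * L0
  post <- ifelse(den == 0, prior, num / den)
  post
}

#' Marginal probability of each test result at a given prior
#'
#' `P(bin) = p L1[bin] + (1 - p) L0[bin]`; the mixture of the two conditional
#' result distributions under the current belief. Sums to 1 over bins.
#'
#' @param prior prior risk in `[0, 1]` (scalar or vector).
#' @param lik a [likelihood_table()].
#' @return If `prior` is scalar, a vector of bin probabilities; otherwise a
#'   matrix with one row per prior and one column per bin.
#' @export
marginal_result_prob <- function(prior, lik) {
  if (any(prior < 0 | prior > 1)) stop("prior must be in [0,1]")
  m <- outer(prior, lik$p_result_given_chd) +
    outer(1 - prior, lik$p_result_given_no_chd)
  if (length(prior) == 1) drop(m) else m
}

#' Estimate a binned likelihood table from a cohort
#'
#' Discretizes a continuous risk score into `n_bins` results at pooled
#' (case + control) quantile cut-points and tabulates conditional result
#' frequencies within cases and controls. Bins receive add-one (Laplace)
#' smoothing so that no result has zero likelihood under either state on a
#' finite cohort; both columns are renormalized after smoothing.
#'
#' @param cohort a data frame with columns `event` (0/1) and
#'   `<test>_score`, e.g. from [generate_cohort()] or [read_cohort()].
#' @param test which score to bin: `"trs"` or `"grs"`.
#' @param n_bins number of result bins (default 10, deciles).
#' @return A [likelihood_table()].
#' @export
estimate_likelihoods <- function(cohort, test = c("trs", "grs"), n_bins = 10) {
  test <- match.arg(test)
  col <- paste0(test, "_score")
  stopifnot(col %in% names(cohort), "event" %in% names(cohort))
  scores <- cohort[[col]]
  event <- as.integer(cohort$event)
  if (!any(event == 1) || !any(event == 0))
    stop("cohort must contain both cases and controls")
  ndistinct <- length(unique(scores))
  if (ndistinct < n_bins) {
    warning("fewer distinct scores (", ndistinct, ") than bins; reducing to ",
            ndistinct)
    n_bins <- ndistinct
  }
  probs <- seq(0, 1, length.out = n_bins + 1)
  edges <- unique(stats::quantile(scores, probs = probs, names = FALSE,
                                  type = 7))
  edges[1] <- -Inf
  edges[length(edges)] <- Inf
  k <- length(edges) - 1
  bin <- cut(scores, breaks = edges, labels = FALSE, include.lowest = TRUE)
  tab1 <- tabulate(bin[event == 1], nbins = k) + 1
  tab0 <- tabulate(bin[event == 0], nbins = k) + 1
  likelihood_table(test, edges, tab1 / sum(tab1), tab0 / sum(tab0))
}

#' Assign scores to the bins of a likelihood table
#'
#' @param scores numeric score vector.
#' @param lik a [likelihood_table()].
#' @return Integer bin indices (1-based).
#' @export
assign_bins <- function(scores, lik) {
  cut(scores, breaks = lik$bin_edges, labels = FALSE, include.lowest = TRUE)
}

#' Write / read a likelihood table as CSV
#'
#' Serialized layout: one row per bin with columns `bin`, `lower_edge`,
#' `upper_edge`, `p_given_chd`, `p_given_no_chd`; the test name travels in the
#' file as a `test_name` column.
#'
#' @param lik a [likelihood_table()].
#' @param path file path.
#' @return `write_likelihoods()` returns `path` invisibly;
#'   `read_likelihoods()` returns a [likelihood_table()].
#' @export
write_likelihoods <- function(lik, path) {
  k <- n_bins(lik)
  df <- data.frame(
    test_name = lik$test_name,
    bin = seq_len(k),
    lower_edge = lik$bin_edges[-(k + 1)],
    upper_edge = lik$bin_edges[-1],
    p_given_chd = lik$p_result_given_chd,
    p_given_no_chd = lik$p_result_given_no_chd
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_likelihoods
#' @export
read_likelihoods <- function(path) {
  df <- utils::read.csv(path)
  likelihood_table(df$test_name[1],
                   c(df$lower_edge, df$upper_edge[nrow(df)]),
                   df$p_given_chd, df$p_given_no_chd)
}
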