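#' Load economic parameters from a YAML config
#'
#' Reads a configuration whose `economic_parameters` block mirrors
#' [econ_params()] field-for-field, with optional `event_costs` (rows of
#' `category`, `acute_cost`, `followup_cost`, `n_events`) and `qol_by_age`
#' blocks. When `cost_nonfatal_event` is absent but an `event_costs` block is
#' present, the non-fatal event cost is derived as the event-count-weighted
#' mean via [weighted_event_cost()]. All invariants are validated on load.
#'
#' @param path YAML file path.
#' @return An `econ_params` object, with any `event_costs` table attached as
#'   attribute `event_cost_table`.
#' @export
econ_params_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$economic_parameters))
    stop("config is missing the 'economic_parameters' block")
  ep <- cfg$economic_parameters
  ect <- NULL
  if (!is.null(cfg$event_costs)) {
    ect <- do.call(rbind, lapply(cfg$event_costs, as.data.frame))
    if (is.null(ep$cost_nonfatal_event))
      ep$cost_nonfatal_event <- weighted_event_cost(ect)$total
  }
  p <- do.call(econ_params, ep)
  attr(p, "event_cost_table") <- ect
  p
}

#' Load a full analysis configuration
#'
#' Parses the blocks an end-to-end run needs: economic parameters, the
#' likelihood source (either `likelihoods: {trs: path, grs: path}` pointing
#' at CSVs, or `cohort:` with either a `path` or a [cohort_spec()] block plus
#' `n_bins`), the risk-distribution block (`beta: {shape1, shape2}` or
#' `point_mass`), the strategy set, and sensitivity-analysis settings.
#' Exactly one likelihood source must be given.
#'
#' @param path YAML file path.
#' @return A list: `params` (`econ_params`), `lik_trs`, `lik_grs`
#'   (likelihood tables), `dist` (`risk_distribution`), `strategies`
#'   (character ids), `seed`, and the raw `config`.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- econ_params_from_yaml(path)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)

  has_lik <- !is.null(cfg$likelihoods)
  has_cohort <- !is.null(cfg$cohort)
  if (has_lik == has_cohort)
    stop("config must name exactly one likelihood source ",
         "('likelihoods' or 'cohort')")
  if (has_lik) {
    for (f in c("trs", "grs"))
      if (!file.exists(cfg$likelihoods[[f]]))
        stop("likelihoods$", f, ": file not found: ", cfg$likelihoods[[f]])
    lik_trs <- read_likelihoods(cfg$likelihoods$trs)
    lik_grs <- read_likelihoods(cfg$likelihoods$grs)
  } else {
    nb <- if (is.null(cfg$cohort$n_bins)) 10 else cfg$cohort$n_bins
    cohort <- if (!is.null(cfg$cohort$path)) {
      if (!file.exists(cfg$cohort$path))
        stop("cohort$path: file not found: ", cfg$cohort$path)
      read_cohort(cfg$cohort$path)
    } else {
      spec_fields <- cfg$cohort[setdiff(names(cfg$cohort), "n_bins")]
      generate_cohort(do.call(cohort_spec, spec_fields))
    }
    lik_trs <- estimate_likelihoods(cohort, "trs", nb)
    lik_grs <- estimate_likelihoods(cohort, "grs", nb)
  }

  rd <- cfg$risk_distribution
  dist <- if (!is.null(rd$point_mass)) {
    build_risk_distribution(point_mass = rd$point_mass)
  } else if (!is.null(rd$beta)) {
    build_risk_distribution(shape1 = rd$beta$shape1, shape2 = rd$beta$shape2)
  } else {
    build_risk_distribution()
  }

  strategies <- if (is.null(cfg$strategies)) strategy_ids()
                else as.character(cfg$strategies)
  bad <- setdiff(strategies, strategy_ids())
  if (length(bad)) stop("unknown strategy id(s): ", paste(bad, collapse = ", "))

  list(params = params, lik_trs = lik_trs, lik_grs = lik_grs, dist = dist,
       strategies = strategies, seed = seed, config = cfg)
}
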