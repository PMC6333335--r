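#' Base-case economic parameters
#'
#' Constructs the validated parameter set that drives the end-state valuation:
#' the 10-year horizon, 3\% discount rate, willingness-to-pay threshold,
#' quality-of-life weights, event probabilities and timing, statin effect, and
#' all unit costs (2015 Euros). Defaults are the base case of the model; any
#' field can be overridden by name.
#'
#' The CHD-free quality of life defaults to 0.903, the population-weighted
#' average of the age-specific 15D estimates (see [qol_by_age_table()]),
#' rather than the rounded 0.90 sometimes quoted; the weighted average is what
#' the discounted QALY arithmetic requires to reproduce the published
#' end-state values.
#'
#' @param ... named overrides of any default field.
#' @return A list of class `econ_params` with fields:
#'   `horizon_years`, `discount_rate`, `wtp`, `qol_chd_free`,
#'   `disutility_event`, `p_death_given_event`, `t_event`,
#'   `statin_relative_risk_reduction`, `statin_annual_disutility`,
#'   `cost_trs`, `cost_grs`, `cost_statin_annual`, `cost_monitoring_annual`,
#'   `cost_secondary_annual`, `cost_nonfatal_event`, `cost_fatal_event`.
#' @examples
#' p <- econ_params()
#' p$wtp
#' econ_params(cost_grs = 100)$cost_grs
#' @export
econ_params <- function(...) {
  p <- list(
    horizon_years = 10,
    discount_rate = 0.03,
    wtp = 50000,
    qol_chd_free = 0.903,
    disutility_event = 0.147,    # QALY loss, applied for 1 year, stored as magnitude
    p_death_given_event = 0.22,
    t_event = 5.75,
    statin_relative_risk_reduction = 0.27,
    statin_annual_disutility = 0.002,
    cost_trs = 173,
    cost_grs = 200,
    cost_statin_annual = 53,
    cost_monitoring_annual = 173,
    cost_secondary_annual = 451,
    cost_nonfatal_event = 19860,
    cost_fatal_event = 2417
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_econ_params(structure(p, class = "econ_params"))
}

validate_econ_params <- function(p) {
  stopifnot(inherits(p, "econ_params"))
  probs <- c("p_death_given_event", "statin_relative_risk_reduction")
  for (f in probs)
    if (p[[f]] < 0 || p[[f]] > 1)
      stop(f, " must be a probability in [0,1]")
  costs <- grep("^cost_", names(p), value = TRUE)
  for (f in costs)
    if (p[[f]] < 0) stop(f, " must be >= 0")
  if (p$discount_rate < 0) stop("discount_rate must be >= 0")
  if (p$wtp < 0) stop("wtp must be >= 0")
  if (p$t_event <= 0 || p$t_event >= p$horizon_years)
    stop("t_event must lie strictly inside (0, horizon_years)")
  if (p$qol_chd_free < 0 || p$qol_chd_free > 1)
    stop("qol_chd_free must be in [0,1]")
  p
}

#' Discount factor at time t
#'
#' @param t time in years (fractional allowed).
#' @param r annual discount rate.
#' @return `(1 + r)^(-t)`.
#' @examples
#' discount_factor(10, 0.03)
#' @export
discount_factor <- function(t, r) {
  if (any(t < 0)) stop("t must be >= 0")
  if (any(r < 0)) stop("r must be >= 0")
  (1 + r)^(-t)
}

#' Discounted annuity factor over a year interval
#'
#' Present value of a unit annual payment stream over `(start, end]`: whole
#' payment years are end-of-year payments, and a fractional terminal year is
#' pro-rated and discounted at its end time. Mid-horizon intervals are valued
#' by complement, `annuity_factor(a, b) = A(0, b) - A(0, a)`, which keeps the
#' factor additive over abutting intervals.
#'
#' @param start,end interval endpoints in years, `0 <= start <= end`.
#' @param r annual discount rate.
#' @return The discounted annuity factor (equals `end - start` when `r = 0`).
#' @examples
#' annuity_factor(0, 10, 0.03)  # canonical 10-year factor, 8.5302
#' annuity_factor(0, 10, 0)     # 10
#' @export
annuity_factor <- function(start, end, r) {
  if (start < 0 || r < 0) stop("start and r must be >= 0")
  if (start > end) stop("start must be <= end")
  a0 <- function(T) {
    if (T == 0) return(0)
    whole <- floor(T)
    v <- if (whole >= 1) sum((1 + r)^(-(seq_len(whole)))) else 0
    v + (T - whole) * (1 + r)^(-T)
  }
  a0(end) - a0(start)
}

#' CHD event cost and frequency table
#'
#' Acute-care and one-year follow-up costs (2015 Euros) with register event
#' counts for the four non-fatal event categories: myocardial infarction,
#' unstable angina pectoris, coronary artery bypass grafting, and percutaneous
#' transluminal coronary angioplasty.
#'
#' @return A data frame with columns `category`, `acute_cost`,
#'   `followup_cost`, `n_events`.
#' @export
event_cost_table <- function() {
  data.frame(
    category = c("MI", "unstable_AP", "CABG", "PTCA"),
    acute_cost = c(8585, 6702, 19483, 7122),
    followup_cost = c(9814, 10147, 23666, 8523),
    n_events = c(11406, 2689, 2493, 7901),
    stringsAsFactors = FALSE
  )
}

#' Quality-of-life weights by age band
#'
#' 15D quality-of-life estimates for the CHD-free state and the disutility of
#' a non-fatal CHD event, by age band, with their population-weighted
#' averages. The model collapses the table to the weighted averages.
#'
#' @return A data frame with columns `age_band`, `qol_chd_free`,
#'   `disutility_event` (disutility as a negative QoL increment; `NA` where an
#'   age band has no estimate for a column).
#' @export
qol_by_age_table <- function() {
  data.frame(
    age_band = c("45-54", "55-64", "65-74", "75-84", "85+", "weighted_average"),
    qol_chd_free = c(0.935, 0.920, 0.900, 0.835, NA, 0.903),
    disutility_event = c(-0.177, -0.177, -0.144, -0.085, -0.012, -0.147),
    stringsAsFactors = FALSE
  )
}

#' Event-count-weighted mean CHD event cost
#'
#' @param table a data frame like [event_cost_table()].
#' @return A list with `acute`, `followup`, and `total` (their sum), each the
#'   event-count-weighted mean cost in Euros.
#' @examples
#' weighted_event_cost(event_cost_table())$total  # ~19,860
#' @export
weighted_event_cost <- function(table = event_cost_table()) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  if (any(table$n_events <= 0)) stop("event counts must be positive")
  n <- sum(table$n_events)
  if (n == 0) stop("zero total events")
  acute <- sum(table$acute_cost * table$n_events) / n
  followup <- sum(table$followup_cost * table$n_events) / n
  list(acute = acute, followup = followup, total = acute + followup)
}

#' Net monetary benefit
#'
#' `NMB = QALYs x lambda - costs`, with cost supplied as a positive magnitude.
#'
#' @param qaly discounted QALYs.
#' @param cost discounted cost in Euros (positive magnitude).
#' @param wtp willingness-to-pay threshold lambda in Euros/QALY.
#' @return Net monetary benefit in Euros.
#' @export
nmb <- function(qaly, cost, wtp) qaly * wtp - cost

#' Value the four end states of the decision tree
#'
#' Computes discounted cost, QALYs, and net monetary benefit for the four
#' terminal states of the testing-and-treatment tree:
#'
#' * `I`  — no CHD event, no treatment (true negative),
#' * `II` — no CHD event, treatment (false positive),
#' * `III`— CHD event, no treatment (false negative),
#' * `IV` — CHD event, treatment (true positive).
#'
#' "CHD event" states mean the patient would suffer an event within the
#' horizon absent treatment; statin therapy averts the event with probability
#' `statin_relative_risk_reduction`, so state IV mixes the treated no-event
#' path (probability 0.27 at base case) with the treated event path. Event
#' branches mix fatal (QoL truncated to zero after the event; fatal event
#' cost) and non-fatal paths (one-year disutility at the event time; acute +
#' follow-up event cost; secondary prevention from the event time to the end
#' of the horizon). Primary prevention (statin + monitoring, with the annual
#' statin disutility) runs the full horizon on no-event paths and stops at the
#' expected event time `t_event` on event paths. Annual flows are end-of-year
#' payments; one-off event flows are discounted at `t_event` exactly.
#'
#' @param params an [econ_params()] object.
#' @return A data frame with one row per state (`state` in `I, II, III, IV`)
#'   and columns `cost` (Euros, reported negative), `qaly`, and `nmb`
#'   (`qaly * wtp + cost`, i.e. QALY value less cost magnitude).
#' @examples
#' endstate_values(econ_params())
#' @export
endstate_values <- function(params = econ_params()) {
  p <- validate_econ_params(params)
  r <- p$discount_rate
  H <- p$horizon_years
  te <- p$t_event
  a_full <- annuity_factor(0, H, r)
  a_pre <- annuity_factor(0, te, r)
  a_post <- annuity_factor(te, H, r)
  d_e <- discount_factor(te, r)
  prim <- p$cost_statin_annual + p$cost_monitoring_annual
  pf <- p$p_death_given_event
  rrr <- p$statin_relative_risk_reduction

  # State I: no event, untreated
  qaly_I <- p$qol_chd_free * a_full
  cost_I <- 0

  # State II: no event, on statin for the whole horizon
  qaly_II <- (p$qol_chd_free - p$statin_annual_disutility) * a_full
  cost_II <- prim * a_full

  # Untreated event paths (state III)
  qaly_fatal <- p$qol_chd_free * a_pre
  qaly_nonfatal <- p$qol_chd_free * a_full - p$disutility_event * d_e
  cost_fatal <- p$cost_fatal_event * d_e
  cost_nonfatal <- p$cost_nonfatal_event * d_e + p$cost_secondary_annual * a_post
  qaly_III <- pf * qaly_fatal + (1 - pf) * qaly_nonfatal
  cost_III <- pf * cost_fatal + (1 - pf) * cost_nonfatal

  # Treated event branch: statin disutility and primary-prevention cost accrue
  # until t_event, then the untreated event paths take over.
  qaly_event_tx <- qaly_III - p$statin_annual_disutility * a_pre
  cost_event_tx <- cost_III + prim * a_pre
  qaly_IV <- rrr * qaly_II + (1 - rrr) * qaly_event_tx
  cost_IV <- rrr * cost_II + (1 - rrr) * cost_event_tx

  cost <- -c(cost_I, cost_II, cost_III, cost_IV)
  qaly <- c(qaly_I, qaly_II, qaly_III, qaly_IV)
  out <- data.frame(
    state = c("I", "II", "III", "IV"),
    cost = cost,
    qaly = qaly,
    nmb = qaly * p$wtp + cost,
    stringsAsFactors = FALSE
  )
  attr(out, "wtp") <- p$wtp
  class(out) <- c("endstate_values", class(out))
  out
}

#' Treatment risk threshold implied by the end-state values
#'
#' Closed form of the final-stage treat/no-treat decision: treating is optimal
#' exactly when the prior event risk p satisfies
#' `p >= (nmb_I - nmb_II) / ((nmb_I - nmb_II) + (nmb_IV - nmb_III))`.
#' The threshold is clipped to 0 (treat everyone) or 1 (treat no one) when one
#' action dominates at all risks.
#'
#' @param endstates an [endstate_values()] data frame.
#' @return The threshold risk in `[0, 1]`, with attribute `indifferent = TRUE`
#'   when the two actions have identical value at every risk.
#' @examples
#' treatment_threshold(endstate_values(econ_params()))  # ~0.186
#' @export
treatment_threshold <- function(endstates) {
  v <- stats::setNames(endstates$nmb, endstates$state)
  a <- v[["I"]] - v[["II"]]   # penalty of treating a no-event patient
  b <- v[["IV"]] - v[["III"]] # benefit of treating an event patient
  if (a + b == 0) {
    return(structure(if (a == 0) 0.5 else if (a > 0) 1 else 0,
                     indifferent = (a == 0)))
  }
  pstar <- a / (a + b)
  if (a <= 0 && b >= 0) pstar <- 0       # treatment weakly dominates
  if (a >= 0 && b <= 0) pstar <- 1       # no-treatment weakly dominates
  structure(min(max(pstar, 0), 1), indifferent = FALSE)
}
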