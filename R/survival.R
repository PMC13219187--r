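#' Survival model parameters
#'
#' Coefficients of the logistic survival model for out-of-hospital cardiac
#' arrest (OHCA). Survival is a decreasing function of the time from collapse
#' to first CPR (`t_cpr`) and of the gap until the ambulance arrives with
#' advanced care (`t_ems - t_cpr`), both in minutes from OHCA onset:
#' \deqn{\phi(t_{CPR}, t_{EMS}) =
#'   \left(1 + e^{\beta_0 + \beta_{CPR} t_{CPR} +
#'   \beta_{gap}(t_{EMS} - t_{CPR})}\right)^{-1}.}
#'
#' The default coefficients (0.04, 0.3 per minute, 0.14 per minute) come from
#' a published model fitted on incidents where both ambulances and volunteers
#' responded and volunteers carried no defibrillator. `onset_to_call` is the
#' assumed delay from collapse to the emergency call (1 minute by default);
#' all simulated times are measured from call arrival and shifted by this
#' amount before entering the survival model.
#'
#' @param beta0 Intercept (dimensionless).
#' @param beta_cpr Coefficient on time to CPR, per minute.
#' @param beta_gap Coefficient on the CPR-to-EMS gap, per minute.
#' @param onset_to_call Minutes from OHCA onset to call initiation; >= 0.
#' @return An object of class `survival_params`.
#' @examples
#' survival_probability(13, 13, survival_params())
#' @export
survival_params <- function(beta0 = 0.04, beta_cpr = 0.3, beta_gap = 0.14,
                            onset_to_call = 1) {
  stopifnot(is.finite(beta0), is.finite(beta_cpr), is.finite(beta_gap),
            is.finite(onset_to_call), onset_to_call >= 0)
  structure(list(beta0 = beta0, beta_cpr = beta_cpr, beta_gap = beta_gap,
                 onset_to_call = onset_to_call),
            class = "survival_params")
}

#' Survival/fatigue trade-off parameters
#'
#' `gamma` is the penalty, in units of survival probability, attached to each
#' redundant volunteer arrival (a proxy for volunteer fatigue). The default
#' 0.01 equates 100 redundant arrivals to one survival.
#'
#' @param gamma Survival probability per redundant volunteer; >= 0.
#' @return An object of class `tradeoff_params`.
#' @export
tradeoff_params <- function(gamma = 0.01) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, is.finite(gamma),
            gamma >= 0)
  structure(list(gamma = gamma), class = "tradeoff_params")
}

#' Logistic survival probability for OHCA
#'
#' @param t_cpr Minutes from OHCA onset to first response (CPR start),
#'   whether by volunteer or ambulance. Vectorised.
#' @param t_ems Minutes from OHCA onset to ambulance arrival. Vectorised.
#' @param params A [survival_params()] object.
#' @return Survival probability in (0, 1).
#' @details Requires `t_cpr <= t_ems`: by definition the first responder
#'   cannot arrive after the ambulance (the ambulance is itself a responder).
#' @examples
#' survival_probability(7.5, 13)
#' @export
survival_probability <- function(t_cpr, t_ems, params = survival_params()) {
  stopifnot(all(is.finite(t_cpr)), all(is.finite(t_ems)),
            all(t_cpr >= 0))
  if (any(t_cpr > t_ems + 1e-12)) {
    stop("t_cpr must not exceed t_ems: the first response cannot occur after ",
         "the ambulance has arrived")
  }
  lin <- params$beta0 + params$beta_cpr * t_cpr +
    params$beta_gap * (t_ems - t_cpr)
  1 / (1 + exp(lin))
}

#' Convert process delays into onset-clock response times
#'
#' Maps the delays observed by the dispatch system (triage delay from call to
#' volunteer-system activation, first CFR response measured from activation,
#' ambulance response measured from the call) onto the common
#' from-OHCA-onset clock used by the survival model. When no volunteer beats
#' the ambulance (`first_response_after_activation` may be `Inf`), the
#' ambulance is the first responder and `t_cpr` is clamped at `t_ems`.
#'
#' @param triage_delay Minutes from call arrival to system activation; >= 0.
#' @param first_response_after_activation Minutes from activation to the
#'   first CFR arrival; `Inf` when no volunteer arrives.
#' @param ems_after_call Minutes from call arrival to ambulance arrival.
#' @param params A [survival_params()] object (supplies `onset_to_call`).
#' @return A list with elements `t_cpr` and `t_ems`, minutes from onset.
#' @examples
#' response_times_from_onset(2, 4.5, 12)   # t_cpr 7.5, t_ems 13
#' response_times_from_onset(2, Inf, 12)   # ambulance first: 13, 13
#' @export
response_times_from_onset <- function(triage_delay,
                                      first_response_after_activation,
                                      ems_after_call,
                                      params = survival_params()) {
  stopifnot(all(triage_delay >= 0), all(ems_after_call >= 0),
            all(first_response_after_activation >= 0))
  t_ems <- params$onset_to_call + ems_after_call
  t_cpr <- pmin(t_ems, params$onset_to_call + triage_delay +
                  first_response_after_activation)
  list(t_cpr = t_cpr, t_ems = t_ems)
}

#' Survival-minus-fatigue objective
#'
#' The scalarised dispatch objective: survival probability minus `gamma`
#' times the (expected) number of redundant volunteer arrivals. May be
#' negative for heavily redundant outcomes.
#'
#' @param survival Survival probability in \[0, 1\]. Vectorised.
#' @param redundant Redundant-arrival count or expected count; >= 0.
#' @param tradeoff A [tradeoff_params()] object.
#' @return Objective value (utility).
#' @examples
#' objective_value(0.0263, 0.1908)  # 0.0244 to 4 d.p.
#' @export
objective_value <- function(survival, redundant,
                            tradeoff = tradeoff_params()) {
  stopifnot(all(survival >= 0), all(survival <= 1), all(redundant >= 0))
  survival - tradeoff$gamma * redundant
}
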