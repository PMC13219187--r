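#' Finite-horizon dispatch MDP configuration
#'
#' Describes one OHCA instance as a discrete-time Markov decision process.
#' Time advances in steps of `step_seconds`; the ambulance arrives `T_steps`
#' after volunteer-system activation, and the `n`-th nearest volunteer needs
#' `travel_steps[n]` steps to reach the patient once they accept. Each
#' alerted, not-yet-responded volunteer independently accepts with per-step
#' probability `p_accept` and rejects with `p_reject` (memoryless view
#' times). Outstanding alerts are void `cancel_steps` after activation
#' (default 180 steps = 15 minutes at 5 s).
#'
#' Only volunteers able to beat the ambulance belong in the model, so
#' `travel_steps` must not exceed `T_steps`.
#'
#' @param T_steps Ambulance arrival, in steps after activation.
#' @param travel_steps Integer vector of volunteer travel times in steps,
#'   sorted ascending (nearest first).
#' @param p_accept,p_reject Per-step response probabilities;
#'   `p_accept + p_reject <= 1`.
#' @param step_seconds Length of one time step, seconds (default 5).
#' @param cancel_steps Steps until outstanding alerts are cancelled
#'   (default 180).
#' @param tradeoff A [tradeoff_params()] object.
#' @param triage_delay Minutes from call to activation, used only inside the
#'   terminal survival times (default 0, so that `T_steps` spans the full
#'   EMS response from the call).
#' @param survival A [survival_params()] object.
#' @param n_cap Largest volunteer count accepted by the exact solver
#'   (default 6; the state space grows exponentially in it).
#' @return An object of class `mdp_config`.
#' @export
mdp_config <- function(T_steps, travel_steps = integer(0),
                       p_accept, p_reject,
                       step_seconds = 5, cancel_steps = 180,
                       tradeoff = tradeoff_params(), triage_delay = 0,
                       survival = survival_params(), n_cap = 6) {
  stopifnot(T_steps >= 1, T_steps == floor(T_steps),
            p_accept >= 0, p_reject >= 0, p_accept + p_reject <= 1,
            step_seconds > 0, cancel_steps >= 0, triage_delay >= 0,
            n_cap >= 0)
  travel_steps <- as.integer(travel_steps)
  if (length(travel_steps)) {
    stopifnot(all(travel_steps >= 0), !is.unsorted(travel_steps),
              all(travel_steps <= T_steps))
  }
  structure(list(T_steps = as.integer(T_steps), travel_steps = travel_steps,
                 p_accept = p_accept, p_reject = p_reject,
                 step_seconds = step_seconds,
                 cancel_steps = as.integer(cancel_steps),
                 tradeoff = tradeoff, triage_delay = triage_delay,
                 survival = survival, n_cap = as.integer(n_cap)),
            class = "mdp_config")
}

#' Convert minutes of travel to MDP steps
#'
#' Uses the ceiling, a conservative convention (a volunteer is never assumed
#' to arrive earlier than their travel time allows).
#'
#' @param minutes Travel time in minutes.
#' @param step_seconds Step length in seconds.
#' @return Integer step counts.
#' @export
minutes_to_steps <- function(minutes, step_seconds = 5) {
  as.integer(ceiling(minutes * 60 / step_seconds))
}

#' MDP state
#'
#' @param t Step index, `0..T`.
#' @param statuses Integer vector over volunteers: 0 unalerted, 1 pending
#'   (alerted, no response yet), 2 accepted, 3 rejected.
#' @param residual Steps until the current fastest responder (volunteer or
#'   ambulance) reaches the patient; 0 marks a terminal state.
#' @return An object of class `mdp_state`.
#' @export
mdp_state <- function(t, statuses, residual) {
  stopifnot(t >= 0, residual >= 0, all(statuses %in% 0:3))
  structure(list(t = as.integer(t), statuses = as.integer(statuses),
                 residual = as.integer(residual)),
            class = "mdp_state")
}

state_key <- function(state) {
  paste0(state$t, "|", paste(state$statuses, collapse = ""), "|",
         state$residual)
}

#' Calibrate per-step response probabilities
#'
#' Inverts the memoryless accept/reject/no-response trichotomy: finds the
#' per-step probabilities such that the chance of having accepted
#' (respectively rejected) within `horizon` steps equals the target
#' cumulative rates. Closed form: the total per-step response probability is
#' `1 - (1 - cum_accept - cum_reject)^(1/horizon)`, split proportionally
#' between acceptance and rejection.
#'
#' @param cum_accept,cum_reject Target cumulative probabilities;
#'   `cum_accept + cum_reject < 1`.
#' @param horizon Number of steps over which the cumulative rates are to be
#'   realised (default 180, the 15-minute cancellation horizon at 5 s).
#' @return A list with `p_accept` and `p_reject`.
#' @examples
#' calibrate_step_probabilities(0.1424, 0.3002, 180)
#' @export
calibrate_step_probabilities <- function(cum_accept, cum_reject,
                                         horizon = 180) {
  stopifnot(cum_accept >= 0, cum_reject >= 0, horizon >= 1)
  if (cum_accept + cum_reject >= 1) {
    stop("cum_accept + cum_reject must be < 1")
  }
  tot <- cum_accept + cum_reject
  if (tot == 0) return(list(p_accept = 0, p_reject = 0))
  p <- 1 - (1 - tot)^(1 / horizon)
  list(p_accept = p * cum_accept / tot, p_reject = p * cum_reject / tot)
}

#' Cumulative response probabilities of the memoryless model
#'
#' Probability that a volunteer alerted at step 0 has accepted
#' (respectively rejected) by step `horizon`, under per-step probabilities
#' `p_accept` / `p_reject`. Inverse of [calibrate_step_probabilities()].
#'
#' @param p_accept,p_reject Per-step probabilities.
#' @param horizon Steps; >= 0.
#' @return A list with `cum_accept` and `cum_reject`.
#' @examples
#' cumulative_response_probabilities(0.00105, 0.00221, 180)
#' @export
cumulative_response_probabilities <- function(p_accept, p_reject, horizon) {
  stopifnot(p_accept >= 0, p_reject >= 0, p_accept + p_reject <= 1,
            horizon >= 0)
  tot <- p_accept + p_reject
  if (tot == 0) return(list(cum_accept = 0, cum_reject = 0))
  mass <- 1 - (1 - tot)^horizon
  list(cum_accept = mass * p_accept / tot, cum_reject = mass * p_reject / tot)
}

valid_actions <- function(state, config) {
  n_unalerted <- sum(state$statuses == 0L)
  if (state$t == 0L) 0:n_unalerted else if (n_unalerted > 0L) 0:1 else 0L
}

#' One-step transition distribution
#'
#' Applies the action (alerting the nearest unalerted volunteers), then lets
#' every pending volunteer independently accept, reject or stay silent
#' during the step. Alerts issued at step `t` can first be answered in the
#' transition to `t + 1`. On acceptance by volunteer `n`, the residual
#' becomes `min(residual - 1, D_n)`; otherwise it decrements.
#'
#' @param state A non-terminal [mdp_state()].
#' @param action At `t = 0` an integer `0..#unalerted`; afterwards 0 or 1.
#' @param config An [mdp_config()].
#' @return A list of `list(state = , prob = )` successor entries whose
#'   probabilities sum to one.
#' @export
transition_distribution <- function(state, action, config) {
  if (state$residual == 0L) stop("state is terminal")
  acts <- valid_actions(state, config)
  if (!(action %in% acts)) {
    stop("invalid action ", action, " at epoch t=", state$t)
  }
  st <- state$statuses
  if (action > 0L) {
    unal <- which(st == 0L)
    st[unal[seq_len(action)]] <- 1L  # nearest-first
  }
  pending <- which(st == 1L)
  m <- length(pending)
  p_a <- config$p_accept
  p_b <- config$p_reject
  q <- 1 - p_a - p_b
  t1 <- state$t + 1L
  if (m == 0L) {
    s1 <- mdp_state(t1, st, state$residual - 1L)
    return(list(list(state = s1, prob = 1)))
  }
  codes <- as.matrix(expand.grid(rep(list(0:2), m)))  # 0 stay, 1 accept, 2 reject
  pr3 <- c(q, p_a, p_b)
  out <- vector("list", nrow(codes))
  for (i in seq_len(nrow(codes))) {
    cd <- codes[i, ]
    st1 <- st
    st1[pending[cd == 1]] <- 2L
    st1[pending[cd == 2]] <- 3L
    res <- state$residual - 1L
    acc <- pending[cd == 1]
    if (length(acc)) {
      res <- min(res, min(config$travel_steps[acc]))
    }
    out[[i]] <- list(state = mdp_state(t1, st1, max(res, 0L)),
                     prob = prod(pr3[cd + 1]))
  }
  out
}

terminal_components <- function(state, config) {
  if (state$residual != 0L) stop("state is not terminal")
  tau <- state$t
  step_min <- config$step_seconds / 60
  rt <- response_times_from_onset(config$triage_delay, tau * step_min,
                                  config$triage_delay +
                                    config$T_steps * step_min,
                                  config$survival)
  f <- survival_probability(rt$t_cpr, rt$t_ems, config$survival)
  n_acc <- sum(state$statuses == 2L)
  n_pend <- sum(state$statuses == 1L)
  # every accepted volunteer other than a strictly-first CFR arrives at or
  # after the first responder and is redundant; ties with the ambulance
  # (tau == T) count as redundant
  g <- if (tau < config$T_steps && n_acc >= 1L) n_acc - 1L else n_acc
  if (n_pend > 0L) {
    horizon <- max(0L, config$cancel_steps - tau)
    cum <- cumulative_response_probabilities(config$p_accept,
                                             config$p_reject, horizon)
    g <- g + n_pend * cum$cum_accept
  }
  c(f = unname(f), g = g)
}

#' Terminal reward on first-responder arrival
#'
#' The MDP grants its only reward on entry into a terminal state (residual
#' time 0): expected survival minus `gamma` times the expected number of
#' redundant volunteers. Redundant volunteers are all accepted volunteers
#' other than a strictly-first CFR (simultaneous arrival with the ambulance
#' counts as redundant), plus, for each still-pending alert, the probability
#' of a future acceptance before the cancellation horizon.
#'
#' @param state A terminal [mdp_state()] entered at step `state$t`.
#' @param config An [mdp_config()].
#' @return Utility (survival units).
#' @export
terminal_reward <- function(state, config) {
  fg <- terminal_components(state, config)
  fg[["f"]] - config$tradeoff$gamma * fg[["g"]]
}

#' Solve the dispatch MDP by backward induction
#'
#' Computes the optimal value and action for every state reachable from the
#' initial state (no volunteer alerted, residual `T_steps`). At activation
#' the action is the size of the initial alert batch (`0..N`); at every
#' later step it is whether to alert the next nearest unalerted volunteer
#' (0/1). Ties between actions are broken toward fewer alerts.
#'
#' @param config An [mdp_config()] with at most `n_cap` volunteers.
#' @return An object of class `mdp_solution` with elements `value0` (optimal
#'   expected objective at activation), `initial`, `config`, and internal
#'   value/action tables accessible through [optimal_action()],
#'   [state_value()] and [solved_states()].
#' @export
solve_backward_induction <- function(config) {
  N <- length(config$travel_steps)
  if (N > config$n_cap) {
    stop("instance has ", N, " volunteers; exact solver capped at n_cap = ",
         config$n_cap)
  }
  val <- new.env(parent = emptyenv())
  act <- new.env(parent = emptyenv())
  sts <- new.env(parent = emptyenv())
  V <- function(state) {
    if (state$residual == 0L) return(0)
    key <- state_key(state)
    v <- val[[key]]
    if (!is.null(v)) return(v)
    best <- -Inf
    best_a <- 0L
    for (a in valid_actions(state, config)) {
      tr <- transition_distribution(state, a, config)
      qv <- 0
      for (s in tr) {
        h <- if (s$state$residual == 0L) terminal_reward(s$state, config)
             else 0
        qv <- qv + s$prob * (h + V(s$state))
      }
      if (qv > best + 1e-14) {
        best <- qv
        best_a <- a
      }
    }
    val[[key]] <- best
    act[[key]] <- best_a
    sts[[key]] <- state
    best
  }
  init <- mdp_state(0L, rep(0L, N), config$T_steps)
  v0 <- V(init)
  structure(list(value0 = v0, initial = init, config = config,
                 .value = val, .action = act, .states = sts),
            class = "mdp_solution")
}

#' @export
print.mdp_solution <- function(x, ...) {
  cat(sprintf(
    "<mdp_solution: N=%d, T=%d steps, optimal value %.6f, action at t=0: %d>\n",
    length(x$config$travel_steps), x$config$T_steps, x$value0,
    optimal_action(x, x$initial)))
  invisible(x)
}

#' Optimal action at a solved state
#' @param solution An `mdp_solution`.
#' @param state An [mdp_state()] reachable under the optimal policy.
#' @return The optimal action (integer).
#' @export
optimal_action <- function(solution, state) {
  a <- solution$.action[[state_key(state)]]
  if (is.null(a)) stop("state was not reached while solving")
  a
}

#' Optimal value of a solved state
#' @inheritParams optimal_action
#' @return Expected future objective from the state.
#' @export
state_value <- function(solution, state) {
  if (state$residual == 0L) return(0)
  v <- solution$.value[[state_key(state)]]
  if (is.null(v)) stop("state was not reached while solving")
  v
}

#' All non-terminal states visited by the solver
#' @inheritParams optimal_action
#' @return A list of [mdp_state()] objects.
#' @export
solved_states <- function(solution) {
  keys <- ls(solution$.states)
  lapply(keys, function(k) solution$.states[[k]])
}

# Map an event-driven policy_spec onto MDP step actions. keep_n_until_t is
# expressed state-wise: top up to n pending alerts (one per step) while no
# acceptance has occurred and the policy clock is within t_stop.
mdp_policy_fn <- function(spec, config) {
  N <- length(config$travel_steps)
  step_min <- config$step_seconds / 60
  function(state) {
    n_unal <- sum(state$statuses == 0L)
    if (state$t == 0L) {
      return(initial_alert_count(spec, N))
    }
    if (spec$kind == "keep_n_until_t") {
      if (any(state$statuses == 2L)) return(0L)
      if (state$t * step_min > spec$t_stop) return(0L)
      if (sum(state$statuses == 1L) < spec$n && n_unal > 0L) return(1L)
      return(0L)
    }
    0L
  }
}

#' Exact evaluation of a fixed policy on the MDP
#'
#' Runs the same backward pass as [solve_backward_induction()] with the
#' action fixed by the policy, tracking expected survival and expected
#' redundant volunteers separately.
#'
#' @param config An [mdp_config()].
#' @param policy A [policy_spec()], a function `state -> action`, or an
#'   `mdp_solution` (whose optimal actions are then replayed).
#' @return A list with `value` (expected objective), `survival` (expected
#'   survival probability) and `redundant` (expected redundant count).
#' @export
evaluate_fixed_policy <- function(config, policy) {
  pol <- if (inherits(policy, "policy_spec")) {
    mdp_policy_fn(policy, config)
  } else if (inherits(policy, "mdp_solution")) {
    sol <- policy
    function(state) optimal_action(sol, state)
  } else if (is.function(policy)) {
    policy
  } else {
    stop("unsupported policy object")
  }
  memo <- new.env(parent = emptyenv())
  FG <- function(state) {
    if (state$residual == 0L) return(c(f = 0, g = 0))
    key <- state_key(state)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    a <- pol(state)
    if (!(a %in% valid_actions(state, config))) {
      stop("policy returned invalid action ", a, " at t=", state$t)
    }
    tr <- transition_distribution(state, a, config)
    fg <- c(f = 0, g = 0)
    for (s in tr) {
      inc <- if (s$state$residual == 0L) terminal_components(s$state, config)
             else FG(s$state)
      fg <- fg + s$prob * inc
    }
    memo[[key]] <- fg
    fg
  }
  N <- length(config$travel_steps)
  fg <- FG(mdp_state(0L, rep(0L, N), config$T_steps))
  list(value = unname(fg[["f"]] - config$tradeoff$gamma * fg[["g"]]),
       survival = unname(fg[["f"]]), redundant = unname(fg[["g"]]))
}

#' Expected benefit and redundancy risk of one marginal volunteer
#'
#' For a single hypothetical volunteer `d` steps from the patient, alerted
#' at step `t`, computes in closed form from the geometric acceptance-time
#' distribution: `s_gain`, the expected increase in survival probability
#' over the ambulance-only baseline, and `r_prob`, the probability that the
#' volunteer accepts (before cancellation) but arrives at or after the
#' ambulance, thereby becoming redundant.
#'
#' @param d Travel time in steps; >= 0.
#' @param t Alert step, `0..T`.
#' @param config An [mdp_config()].
#' @return A list with `s_gain` and `r_prob`.
#' @export
single_volunteer_stats <- function(d, t, config) {
  stopifnot(d >= 0, t >= 0, t <= config$T_steps)
  p_a <- config$p_accept
  p_b <- config$p_reject
  q <- 1 - p_a - p_b
  Tn <- config$T_steps
  cancel <- config$cancel_steps
  step_min <- config$step_seconds / 60
  base_rt <- response_times_from_onset(config$triage_delay, Tn * step_min,
                                       config$triage_delay + Tn * step_min,
                                       config$survival)
  phi_base <- survival_probability(base_rt$t_cpr, base_rt$t_ems,
                                   config$survival)
  # acceptance at step j in (t, cancel]; arrival at j + d
  s_gain <- 0
  j_hi <- min(cancel, Tn - d - 1)
  if (j_hi >= t + 1) {
    j <- (t + 1):j_hi
    w <- p_a * q^(j - t - 1)
    rt <- response_times_from_onset(config$triage_delay, (j + d) * step_min,
                                    config$triage_delay + Tn * step_min,
                                    config$survival)
    phi <- survival_probability(rt$t_cpr, rt$t_ems, config$survival)
    s_gain <- sum(w * (phi - phi_base))
  }
  r_prob <- 0
  j_lo <- max(t + 1, Tn - d)
  if (cancel >= j_lo) {
    j <- j_lo:cancel
    r_prob <- sum(p_a * q^(j - t - 1))
  }
  list(s_gain = s_gain, r_prob = r_prob)
}

#' Distance threshold beyond which alerting is suboptimal
#'
#' The smallest travel distance `d` (in steps) at which the expected
#' survival gain from alerting one more volunteer at step `t` falls below
#' the expected redundancy penalty, `s(d, t) < gamma * r(d, t)`. Volunteers
#' at or beyond the threshold are never alerted by the optimal policy. When
#' no distance in `0..T` satisfies the condition (e.g. `gamma = 0`), the
#' sentinel `T + 1` is returned.
#'
#' @param t Alert step.
#' @param config An [mdp_config()].
#' @return Integer threshold in `0..T+1`.
#' @export
alert_threshold <- function(t, config) {
  gam <- config$tradeoff$gamma
  for (d in 0:config$T_steps) {
    st <- single_volunteer_stats(d, t, config)
    if (st$s_gain < gam * st$r_prob) return(d)
  }
  config$T_steps + 1L
}

#' Read / write MDP instances as JSON
#'
#' The on-disk format is a flat JSON object with keys `step_seconds`,
#' `T_steps`, `travel_steps`, `p_accept`, `p_reject`, `cancel_steps`,
#' `gamma`, `triage_delay_min`.
#'
#' @param path File path.
#' @return For `read_mdp_instance`, an [mdp_config()].
#' @export
read_mdp_instance <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mdp_config(T_steps = x$T_steps, travel_steps = x$travel_steps,
             p_accept = x$p_accept, p_reject = x$p_reject,
             step_seconds = if (is.null(x$step_seconds)) 5 else x$step_seconds,
             cancel_steps = if (is.null(x$cancel_steps)) 180
                            else x$cancel_steps,
             tradeoff = tradeoff_params(if (is.null(x$gamma)) 0.01
                                        else x$gamma),
             triage_delay = if (is.null(x$triage_delay_min)) 0
                            else x$triage_delay_min)
}

#' @rdname read_mdp_instance
#' @param config An [mdp_config()] to serialise.
#' @export
write_mdp_instance <- function(config, path) {
  jsonlite::write_json(
    list(step_seconds = config$step_seconds, T_steps = config$T_steps,
         travel_steps = config$travel_steps, p_accept = config$p_accept,
         p_reject = config$p_reject, cancel_steps = config$cancel_steps,
         gamma = config$tradeoff$gamma,
         triage_delay_min = config$triage_delay),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
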