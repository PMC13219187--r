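# Alert cancellation horizon: outstanding alerts are void this many minutes
# after system activation, and only acceptances within it count anywhere.
CANCEL_MIN <- 15

# fast internal draw: list(outcome=, view=) without data.frame overhead
draw_responses <- function(sampler, k) {
  if (k == 0L) return(list(outcome = character(0), view = numeric(0)))
  if (sampler$mode == "memoryless") {
    p <- sampler$p_accept + sampler$p_reject
    step_min <- sampler$step_seconds / 60
    kk <- stats::rgeom(k, p) + 1L
    acc <- stats::runif(k) < sampler$p_accept / p
    return(list(outcome = ifelse(acc, "accept", "reject"),
                view = kk * step_min))
  }
  if (sampler$mode == "empirical") {
    idx <- sample.int(nrow(sampler$table), k, replace = TRUE)
    return(list(outcome = sampler$table$outcome[idx],
                view = sampler$table$view_delay_min[idx]))
  }
  u <- stats::runif(k)
  outcome <- ifelse(u < sampler$p_accept, "accept",
                    ifelse(u < sampler$p_accept + sampler$p_reject,
                           "reject", "ignore"))
  view <- rep(Inf, k)
  resp <- outcome != "ignore"
  if (any(resp)) {
    ml <- ifelse(outcome[resp] == "accept", sampler$meanlog_accept,
                 sampler$meanlog_reject)
    view[resp] <- stats::rlnorm(sum(resp), ml, sampler$sdlog)
  }
  list(outcome = outcome, view = view)
}

# deterministic substream seed for common random numbers
crn_seed <- function(seed, instance_index, rep) {
  as.integer(((seed %% 100000) * 20011 + instance_index * 131071 + rep) %%
               2147483647L) + 1L
}

#' Simulate one incident under one dispatch policy
#'
#' Event-driven execution of the CFR response process: the initial alert
#' batch goes out at activation (alert delay zero); alerted volunteers
#' accept, reject, or never respond per their pre-drawn (outcome, view
#' delay) pair; policies may issue additional alerts on rejections or batch
#' timers, nearest-unalerted-first, but never after the first acceptance nor
#' after the 15-minute cancellation horizon; an accepting volunteer alerted
#' at time `a` arrives on scene at `a + view_delay + travel_time`; the
#' ambulance arrives `ems_response_from_call - triage_delay` minutes after
#' activation. Only the first-arriving responder contributes to survival.
#'
#' Redundant volunteers are those whose acceptance occurred within 15
#' minutes of activation and who arrive at or after the first responder
#' (the strictly-first CFR itself excluded; a CFR arriving exactly with the
#' ambulance is redundant). The run is fully deterministic given `draws`,
#' which is what enables common-random-number comparisons across policies.
#'
#' @param incident An [incident()] with volunteers sorted nearest-first.
#' @param spec A [policy_spec()].
#' @param draws A `data.frame` (or list) with `outcome` and `view_delay`
#'   aligned to the incident's volunteers; see [sample_response()].
#' @param tradeoff A [tradeoff_params()].
#' @param survival A [survival_params()].
#' @return An object of class `sim_result`: `first_response_after_activation`,
#'   `t_cpr`, `t_ems`, `survival`, `redundant`, `alerts_sent`, `objective`.
#' @export
simulate_incident <- function(incident, spec, draws,
                              tradeoff = tradeoff_params(),
                              survival = survival_params()) {
  travel <- incident$volunteer_travel_times
  k <- length(travel)
  if (is.unsorted(travel)) stop("volunteers must be sorted nearest-first")
  outcome <- if (!is.null(draws$outcome)) draws$outcome else character(0)
  view <- if (!is.null(draws$view_delay)) draws$view_delay else draws$view
  if (length(outcome) != k || length(view) != k) {
    stop("draws must align one-to-one with the incident's volunteers")
  }
  amb_time <- incident$ems_response_from_call - incident$triage_delay

  alert_time <- rep(Inf, k)
  n_alerted <- 0L
  issue <- function(count, time) {
    if (count <= 0L) return()
    take <- seq_len(min(count, k - n_alerted)) + n_alerted
    alert_time[take] <<- time
    n_alerted <<- n_alerted + length(take)
  }
  issue(initial_alert_count(spec, k), 0)

  # response/timer event loop; k is small so we rescan rather than keep a heap
  phased <- spec$kind == "phased_batches"
  interval_min <- spec$batch_interval / 60
  next_timer <- if (phased) interval_min else Inf
  processed <- rep(FALSE, k)
  accepted_yet <- FALSE
  repeat {
    resp_time <- alert_time + view
    cand <- which(!processed & is.finite(resp_time) & resp_time <= CANCEL_MIN)
    ev_resp <- if (length(cand)) cand[which.min(resp_time[cand])] else 0L
    t_resp <- if (ev_resp) resp_time[ev_resp] else Inf
    t_tim <- if (phased && n_alerted < k && !accepted_yet &&
                 next_timer <= CANCEL_MIN) next_timer else Inf
    if (!is.finite(t_resp) && !is.finite(t_tim)) break
    if (t_resp <= t_tim) {  # responses before timers on ties
      processed[ev_resp] <- TRUE
      if (outcome[ev_resp] == "accept") {
        accepted_yet <- TRUE
        break  # no further alerts can ever be issued
      }
      ev <- if (outcome[ev_resp] == "reject") "rejection" else "acceptance"
      if (ev == "rejection") {
        issue(alerts_on_event(spec, "rejection", t_resp, accepted_yet,
                              k - n_alerted), t_resp)
      }
    } else {
      issue(alerts_on_event(spec, "timer", t_tim, accepted_yet,
                            k - n_alerted), t_tim)
      next_timer <- next_timer + interval_min
    }
  }

  resp_time <- alert_time + view
  acc <- which(outcome == "accept" & is.finite(alert_time) &
                 resp_time <= CANCEL_MIN)
  arrivals <- resp_time[acc] + travel[acc]
  first_cfr <- if (length(arrivals)) min(arrivals) else Inf
  n_redundant <- if (length(acc)) {
    length(acc) - as.integer(first_cfr < amb_time)
  } else 0L

  rt <- response_times_from_onset(incident$triage_delay, first_cfr,
                                  incident$ems_response_from_call, survival)
  surv <- survival_probability(rt$t_cpr, rt$t_ems, survival)
  structure(list(
    first_response_after_activation = min(first_cfr, amb_time),
    t_cpr = rt$t_cpr, t_ems = rt$t_ems, survival = surv,
    redundant = n_redundant, alerts_sent = n_alerted,
    objective = objective_value(surv, n_redundant, tradeoff)),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result: t_cpr %.2f, t_ems %.2f, survival %.4f, redundant %d, alerts %d, objective %.4f>\n",
    x$t_cpr, x$t_ems, x$survival, x$redundant, x$alerts_sent, x$objective))
  invisible(x)
}

# Shared replication engine: per-(instance, rep) volunteer draws are derived
# from (seed, instance index, rep) and reused across every policy --- common
# random numbers, so policy comparisons difference out response noise.
policy_outcomes <- function(instances, policy_set, n_reps, seed, sampler,
                            tradeoff = tradeoff_params(),
                            survival = survival_params()) {
  n <- length(instances)
  P <- length(policy_set)
  stopifnot(n >= 1, P >= 1, n_reps >= 1)
  m_obj <- m_sur <- m_red <- m_ale <- matrix(0, n, P)
  s2_obj <- matrix(0, n, P)
  for (i in seq_len(n)) {
    inc <- instances[[i]]
    k <- length(inc$volunteer_travel_times)
    obj <- sur <- red <- ale <- matrix(0, n_reps, P)
    for (r in seq_len(n_reps)) {
      set.seed(crn_seed(seed, i, r))
      draws <- draw_responses(sampler, k)
      for (p in seq_len(P)) {
        res <- simulate_incident(inc, policy_set[[p]], draws, tradeoff,
                                 survival)
        obj[r, p] <- res$objective
        sur[r, p] <- res$survival
        red[r, p] <- res$redundant
        ale[r, p] <- res$alerts_sent
      }
    }
    m_obj[i, ] <- colMeans(obj)
    m_sur[i, ] <- colMeans(sur)
    m_red[i, ] <- colMeans(red)
    m_ale[i, ] <- colMeans(ale)
    s2_obj[i, ] <- apply(obj, 2, stats::var) / n_reps
  }
  list(mean_objective = m_obj, mean_survival = m_sur, mean_redundant = m_red,
       mean_alerts = m_ale, var_mean_objective = s2_obj)
}

#' Replicated evaluation of one policy over an instance set
#'
#' Runs `n_reps` seeded replications of [simulate_incident()] on every
#' instance. Draws are generated once per (instance, replication) pair from
#' `(seed, instance, rep)` and would be identical for any other policy
#' evaluated with the same seed (common random numbers).
#'
#' @param instances List of [incident()] objects.
#' @param spec A [policy_spec()].
#' @param n_reps Replications per instance.
#' @param seed Base RNG seed.
#' @param sampler A `response_sampler`.
#' @param tradeoff,survival Model parameters.
#' @return A list with pooled means (`mean_survival`, `mean_redundant`,
#'   `mean_objective`), their standard errors (over the instance-level
#'   means), and `per_instance`, a `data.frame` of per-instance means.
#' @export
evaluate_policy <- function(instances, spec, n_reps, seed, sampler,
                            tradeoff = tradeoff_params(),
                            survival = survival_params()) {
  if (length(instances) == 0) stop("empty instance list")
  out <- policy_outcomes(instances, list(spec), n_reps, seed, sampler,
                         tradeoff, survival)
  n <- length(instances)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  list(mean_survival = mean(out$mean_survival[, 1]),
       mean_redundant = mean(out$mean_redundant[, 1]),
       mean_objective = mean(out$mean_objective[, 1]),
       se_survival = if (n > 1) se(out$mean_survival[, 1]) else NA_real_,
       se_redundant = if (n > 1) se(out$mean_redundant[, 1]) else NA_real_,
       se_objective = if (n > 1) se(out$mean_objective[, 1])
                      else sqrt(out$var_mean_objective[1, 1]),
       per_instance = data.frame(
         instance = seq_len(n),
         mean_objective = out$mean_objective[, 1],
         mean_survival = out$mean_survival[, 1],
         mean_redundant = out$mean_redundant[, 1],
         mean_alerts = out$mean_alerts[, 1]))
}

#' Write per-replication simulation results to CSV
#'
#' One row per (instance, policy, replication) with the raw [sim_result]
#' fields; the schema is `instance_id, policy_id, rep, t_cpr_min, t_ems_min,
#' survival, redundant, alerts, objective`.
#'
#' @inheritParams evaluate_policy
#' @param policy_set List of [policy_spec()] objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_simulation_results <- function(instances, policy_set, n_reps, seed,
                                     sampler, path,
                                     tradeoff = tradeoff_params(),
                                     survival = survival_params()) {
  rows <- vector("list", length(instances) * length(policy_set) * n_reps)
  z <- 0L
  for (i in seq_along(instances)) {
    inc <- instances[[i]]
    k <- length(inc$volunteer_travel_times)
    for (r in seq_len(n_reps)) {
      set.seed(crn_seed(seed, i, r))
      draws <- draw_responses(sampler, k)
      for (p in seq_along(policy_set)) {
        res <- simulate_incident(inc, policy_set[[p]], draws, tradeoff,
                                 survival)
        z <- z + 1L
        rows[[z]] <- data.frame(
          instance_id = inc$instance_id,
          policy_id = policy_set[[p]]$policy_id, rep = r,
          t_cpr_min = res$t_cpr, t_ems_min = res$t_ems,
          survival = res$survival, redundant = res$redundant,
          alerts = res$alerts_sent, objective = res$objective)
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
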