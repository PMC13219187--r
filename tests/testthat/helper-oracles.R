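# Independent oracles for the dispatch MDP, written from first principles and
# structurally unlike the package implementation: the survival and terminal
# formulas are restated inline, outcome expectations are accumulated by
# conditioning on one pending volunteer at a time (the package enumerates the
# full product distribution), and for a single volunteer there is a fully
# closed-form enumeration over alert plans.

oracle_phi <- function(t_cpr, t_ems, sp = survival_params()) {
  1 / (1 + exp(sp$beta0 + sp$beta_cpr * t_cpr + sp$beta_gap *
                 (t_ems - t_cpr)))
}

oracle_terminal <- function(tau, statuses, cfg) {
  sm <- cfg$step_seconds / 60
  onset <- cfg$survival$onset_to_call
  te <- onset + cfg$triage_delay + cfg$T_steps * sm
  tc <- min(te, onset + cfg$triage_delay + tau * sm)
  f <- oracle_phi(tc, te, cfg$survival)
  n_acc <- sum(statuses == 2)
  g <- if (tau < cfg$T_steps && n_acc > 0) n_acc - 1 else n_acc
  n_pen <- sum(statuses == 1)
  if (n_pen > 0) {
    ptot <- cfg$p_accept + cfg$p_reject
    h <- max(0, cfg$cancel_steps - tau)
    if (ptot > 0) {
      g <- g + n_pen * (cfg$p_accept / ptot) * (1 - (1 - ptot)^h)
    }
  }
  f - cfg$tradeoff$gamma * g
}

# memoised expectation-tree oracle, exact over all reachable states
oracle_value <- function(cfg) {
  memo <- new.env(parent = emptyenv())
  D <- cfg$travel_steps
  pa <- cfg$p_accept
  pb <- cfg$p_reject
  q <- 1 - pa - pb

  # expectation over responses of pending volunteers, one at a time
  expect_over <- function(t, pending, pos, st_next, res_next) {
    if (pos > length(pending)) {
      if (res_next == 0) return(oracle_terminal(t + 1, st_next, cfg))
      return(val(t + 1, st_next, res_next))
    }
    i <- pending[pos]
    s2 <- st_next
    v <- 0
    s2[i] <- 1
    v <- v + q * expect_over(t, pending, pos + 1, s2, res_next)
    s2[i] <- 2
    v <- v + pa * expect_over(t, pending, pos + 1, s2,
                              min(res_next, D[i]))
    s2[i] <- 3
    v <- v + pb * expect_over(t, pending, pos + 1, s2, res_next)
    v
  }

  val <- function(t, statuses, residual) {
    key <- paste(t, paste(statuses, collapse = ""), residual)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    unal <- which(statuses == 0)
    acts <- if (t == 0) 0:length(unal) else if (length(unal)) 0:1 else 0
    best <- -Inf
    for (a in acts) {
      st <- statuses
      if (a > 0) st[unal[seq_len(a)]] <- 1
      v <- expect_over(t, which(st == 1), 1, st, residual - 1)
      best <- max(best, v)
    }
    memo[[key]] <- best
    best
  }
  if (length(D) == 0) {
    return(oracle_terminal(cfg$T_steps, integer(0), cfg))
  }
  val(0, rep(0L, length(D)), cfg$T_steps)
}

# fully closed-form oracle for a single volunteer: enumerate the alert step
# (with one volunteer there is nothing to condition on before the response)
oracle_value_n1 <- function(cfg) {
  stopifnot(length(cfg$travel_steps) == 1)
  D <- cfg$travel_steps[1]
  Tn <- cfg$T_steps
  pa <- cfg$p_accept
  pb <- cfg$p_reject
  q <- 1 - pa - pb
  gam <- cfg$tradeoff$gamma
  sm <- cfg$step_seconds / 60
  onset <- cfg$survival$onset_to_call
  te <- onset + cfg$triage_delay + Tn * sm
  phi <- function(arr) {
    oracle_phi(onset + cfg$triage_delay + arr * sm, te, cfg$survival)
  }
  f_base <- phi(Tn)
  ptot <- pa + pb
  pend_g <- if (ptot > 0) {
    (pa / ptot) * (1 - (1 - ptot)^max(0, cfg$cancel_steps - Tn))
  } else 0
  vals <- f_base  # never alert
  for (a in 0:(Tn - 1)) {
    v <- q^(Tn - a) * (f_base - gam * pend_g)  # silent through the horizon
    for (j in (a + 1):Tn) {
      w <- q^(j - a - 1)
      v <- v + w * pb * f_base
      v <- v + w * pa * if (j + D < Tn) phi(j + D) else f_base - gam
    }
    vals <- c(vals, v)
  }
  max(vals)
}

# brute-force summation for the marginal-volunteer benefit/redundancy pair
oracle_single_stats <- function(d, t, cfg) {
  pa <- cfg$p_accept
  pb <- cfg$p_reject
  q <- 1 - pa - pb
  Tn <- cfg$T_steps
  sm <- cfg$step_seconds / 60
  onset <- cfg$survival$onset_to_call
  te <- onset + cfg$triage_delay + Tn * sm
  phi <- function(arr) {
    oracle_phi(onset + cfg$triage_delay + arr * sm, te, cfg$survival)
  }
  s <- 0
  r <- 0
  if (cfg$cancel_steps >= t + 1) {
    for (j in (t + 1):cfg$cancel_steps) {
      w <- pa * q^(j - t - 1)
      if (j + d < Tn) s <- s + w * (phi(j + d) - phi(Tn)) else r <- r + w
    }
  }
  list(s_gain = s, r_prob = r)
}

# convenience builders used across the suite
tiny_cfg <- function(T_steps = 6, travel = c(2, 4), pa = 0.2, pb = 0.3,
                     gamma = 0.01, cancel = 12, triage = 0) {
  mdp_config(T_steps = T_steps, travel_steps = travel, p_accept = pa,
             p_reject = pb, cancel_steps = cancel,
             tradeoff = tradeoff_params(gamma), triage_delay = triage)
}

test_incident <- function(travel, triage = 2, ems = 12, id = 1L) {
  incident(id, triage, ems, travel)
}

draws_df <- function(outcome, view) {
  data.frame(outcome = outcome, view_delay = view)
}

tree_depth <- function(tree) {
  nodes <- tree$nodes
  walk <- function(id) {
    row <- which(nodes$id == id)
    if (is.na(nodes$feature[row])) return(0L)
    1L + max(walk(nodes$left[row]), walk(nodes$right[row]))
  }
  walk(1L)
}
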