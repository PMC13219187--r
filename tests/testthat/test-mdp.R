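test_that("per-step calibration inverts the cumulative response model", {
  p <- calibrate_step_probabilities(0.1424, 0.3002, 180)
  # printed operational values are 0.00105 / 0.00221; agree within ~1%
  expect_equal(p$p_accept, 0.00105, tolerance = 0.01)
  expect_equal(p$p_reject, 0.00221, tolerance = 0.01)
  # exact round trip
  cum <- cumulative_response_probabilities(p$p_accept, p$p_reject, 180)
  expect_equal(cum$cum_accept, 0.1424, tolerance = 1e-12)
  expect_equal(cum$cum_reject, 0.3002, tolerance = 1e-12)
  expect_equal(calibrate_step_probabilities(0, 0, 50),
               list(p_accept = 0, p_reject = 0))
  expect_error(calibrate_step_probabilities(0.6, 0.5, 10), "< 1")
})

test_that("cumulative response probabilities have the right closed form", {
  cum <- cumulative_response_probabilities(0.00105, 0.00221, 180)
  expect_equal(round(100 * cum$cum_accept), 14)
  expect_equal(cumulative_response_probabilities(0.00105, 0.00221, 0),
               list(cum_accept = 0, cum_reject = 0))
  cum36 <- cumulative_response_probabilities(0.00105, 0.00221, 36)
  expect_equal(cum36$cum_accept, 0.0357, tolerance = 1e-3)
})

test_that("transition kernels enumerate pending responses and sum to one", {
  cfg <- tiny_cfg(T_steps = 6, travel = c(2, 4))
  s0 <- mdp_state(0, c(0, 0), 6)
  # no pending, action 0: deterministic drift
  tr <- transition_distribution(s0, 0, cfg)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$prob, 1)
  expect_equal(tr[[1]]$state$residual, 5)
  # one pending volunteer: accept / reject / silence
  tr <- transition_distribution(s0, 1, cfg)
  expect_length(tr, 3)
  expect_equal(sum(vapply(tr, `[[`, numeric(1), "prob")), 1,
               tolerance = 1e-12)
  probs <- sort(vapply(tr, `[[`, numeric(1), "prob"))
  expect_equal(probs, sort(c(0.2, 0.3, 0.5)))
  # two pending: the full 3x3 product distribution
  tr <- transition_distribution(s0, 2, cfg)
  expect_length(tr, 9)
  expect_equal(sum(vapply(tr, `[[`, numeric(1), "prob")), 1,
               tolerance = 1e-12)
  expect_error(transition_distribution(mdp_state(1, c(0, 0), 5), 2, cfg),
               "invalid action")
})

test_that("acceptance pulls the residual down to the volunteer's travel", {
  cfg <- tiny_cfg(T_steps = 6, travel = c(2, 4))
  tr <- transition_distribution(mdp_state(0, c(0, 0), 6), 2, cfg)
  for (e in tr) {
    st <- e$state$statuses
    expected <- min(5, c(2, 4)[st == 2])
    if (!any(st == 2)) expected <- 5
    expect_equal(e$state$residual, expected)
  }
})

test_that("terminal reward matches the hand formula in each regime", {
  # nobody alerted, ambulance arrives at T
  cfg <- tiny_cfg(T_steps = 144, travel = integer(0), pa = 0.00105,
                  pb = 0.00221, cancel = 180)
  r <- terminal_reward(mdp_state(144, integer(0), 0), cfg)
  expect_equal(r, survival_probability(13, 13), tolerance = 1e-12)
  # one still-pending volunteer at tau = 144 with cancellation at 180:
  # its redundancy contribution is the residual acceptance mass over 36 steps
  cfg2 <- mdp_config(T_steps = 144, travel_steps = 5, p_accept = 0.00105,
                     p_reject = 0.00221, cancel_steps = 180,
                     tradeoff = tradeoff_params(1))  # gamma 1 isolates g
  r2 <- terminal_reward(mdp_state(144, 1L, 0), cfg2)
  g2 <- survival_probability(13, 13) - r2
  expect_equal(g2,
               cumulative_response_probabilities(0.00105, 0.00221,
                                                 36)$cum_accept,
               tolerance = 1e-12)
  # a volunteer arriving exactly with the ambulance is redundant
  r3 <- terminal_reward(mdp_state(144, 2L, 0), cfg2)
  expect_equal(survival_probability(13, 13) - r3, 1, tolerance = 1e-12)
  expect_error(terminal_reward(mdp_state(3, 1L, 2), cfg2), "not terminal")
})

test_that("backward induction equals the exhaustive-enumeration oracle", {
  grid <- list()
  for (Tn in c(3, 5, 6)) {
    travels <- list(integer(0), 1L, Tn - 1L, c(1L, 2L), c(2L, Tn))
    for (tv in travels) {
      if (length(tv) && max(tv) > Tn) next
      for (pp in list(c(0.2, 0.3), c(0.05, 0.1))) {
        for (g in c(0, 0.01, 0.05)) {
          grid[[length(grid) + 1]] <-
            tiny_cfg(Tn, tv, pp[1], pp[2], gamma = g, cancel = Tn + 4)
        }
      }
    }
  }
  for (cfg in grid) {
    sol <- solve_backward_induction(cfg)
    expect_equal(sol$value0, oracle_value(cfg), tolerance = 1e-10)
  }
})

test_that("single-volunteer instances match the closed-form plan oracle", {
  for (D in c(1L, 2L)) {
    for (Tn in c(3L, 6L)) {
      cfg <- tiny_cfg(Tn, D, 0.15, 0.25, gamma = 0.02, cancel = Tn + 6)
      sol <- solve_backward_induction(cfg)
      expect_equal(sol$value0, oracle_value_n1(cfg), tolerance = 1e-10)
    }
  }
})

test_that("degenerate and gamma = 0 instances reduce to known optima", {
  # no volunteers: the value is the ambulance-only survival
  cfg0 <- tiny_cfg(6, integer(0))
  sol0 <- solve_backward_induction(cfg0)
  expect_equal(sol0$value0,
               terminal_reward(mdp_state(6, integer(0), 0), cfg0),
               tolerance = 1e-12)
  # with no fatigue penalty, alerting everyone immediately is optimal
  cfg <- tiny_cfg(6, c(2, 4), gamma = 0)
  sol <- solve_backward_induction(cfg)
  ev <- evaluate_fixed_policy(cfg, policy_spec("send_all"))
  expect_equal(sol$value0, ev$value, tolerance = 1e-10)
})

test_that("the optimal value dominates every predefined policy", {
  cfg <- tiny_cfg(6, c(2, 4), gamma = 0.02)
  sol <- solve_backward_induction(cfg)
  for (spec in build_default_policy_set()) {
    ev <- evaluate_fixed_policy(cfg, spec)
    expect_lte(ev$value, sol$value0 + 1e-12)
  }
  # replaying the stored optimal actions reproduces the optimal value
  ev_opt <- evaluate_fixed_policy(cfg, sol)
  expect_equal(ev_opt$value, sol$value0, tolerance = 1e-12)
  # send-0 is the ambulance-only baseline with zero fatigue
  ev0 <- evaluate_fixed_policy(cfg, policy_spec("send_n", 0))
  expect_equal(ev0$survival,
               survival_probability(1.5, 1.5), tolerance = 1e-12)
  expect_equal(ev0$redundant, 0)
})

test_that("optimal value is monotone in travel time and acceptance rate", {
  vals_D <- vapply(1:5, function(D) {
    solve_backward_induction(tiny_cfg(6, D, gamma = 0))$value0
  }, numeric(1))
  expect_true(all(diff(vals_D) <= 1e-12))
  vals_p <- vapply(c(0.05, 0.1, 0.2, 0.4), function(pa) {
    solve_backward_induction(tiny_cfg(6, 2L, pa = pa, pb = 0.2,
                                      gamma = 0))$value0
  }, numeric(1))
  expect_true(all(diff(vals_p) >= -1e-12))
})

test_that("once someone has accepted, no further alerts are optimal", {
  for (cfg in list(tiny_cfg(6, c(2, 4), gamma = 0.01),
                   tiny_cfg(5, c(1, 3), pa = 0.3, pb = 0.1, gamma = 0.005),
                   tiny_cfg(6, c(2, 3), pa = 0.1, pb = 0.4, gamma = 0.03))) {
    sol <- solve_backward_induction(cfg)
    for (st in solved_states(sol)) {
      if (any(st$statuses == 2L)) {
        expect_identical(optimal_action(sol, st), 0L)
      }
    }
  }
})

test_that("marginal-volunteer statistics match the brute-force summation", {
  cfg <- tiny_cfg(10, 2L, pa = 0.12, pb = 0.2, gamma = 0.01, cancel = 16)
  for (d in c(0, 1, 3, 7, 9, 10)) {
    for (t in c(0, 2, 5, 9)) {
      got <- single_volunteer_stats(d, t, cfg)
      want <- oracle_single_stats(d, t, cfg)
      expect_equal(got$s_gain, want$s_gain, tolerance = 1e-12)
      expect_equal(got$r_prob, want$r_prob, tolerance = 1e-12)
    }
  }
  # too far to beat the ambulance: no benefit, pure redundancy risk
  st <- single_volunteer_stats(10, 3, cfg)
  expect_equal(st$s_gain, 0)
  expect_equal(st$r_prob,
               cumulative_response_probabilities(0.12, 0.2,
                                                 16 - 3)$cum_accept,
               tolerance = 1e-12)
  cfg0 <- tiny_cfg(10, 2L, pa = 0, pb = 0.2)
  st0 <- single_volunteer_stats(3, 0, cfg0)
  expect_equal(st0$s_gain, 0)
  expect_equal(st0$r_prob, 0)
})

test_that("the alert threshold behaves as the benefit/penalty crossover", {
  cfg <- tiny_cfg(10, 2L, pa = 0.12, pb = 0.2, gamma = 0, cancel = 16)
  expect_identical(alert_threshold(0, cfg), cfg$T_steps + 1L)  # never stop
  cfgg <- tiny_cfg(10, 2L, pa = 0.12, pb = 0.2, gamma = 0.02, cancel = 16)
  for (t in c(0, 3, 7)) {
    expect_lte(alert_threshold(t, cfgg), cfgg$T_steps - t)
  }
})

test_that("optimal actions respect the distance threshold", {
  for (cfg in list(tiny_cfg(8, c(2L, 6L), pa = 0.15, pb = 0.25,
                            gamma = 0.02, cancel = 12),
                   tiny_cfg(6, c(1L, 5L), pa = 0.1, pb = 0.3,
                            gamma = 0.05, cancel = 10),
                   tiny_cfg(8, c(3L, 7L), pa = 0.2, pb = 0.2,
                            gamma = 0.01, cancel = 12))) {
    sol <- solve_backward_induction(cfg)
    thr <- vapply(0:cfg$T_steps, alert_threshold, integer(1), config = cfg)
    for (st in solved_states(sol)) {
      a <- optimal_action(sol, st)
      if (a == 0L) next
      unal <- which(st$statuses == 0L)
      alerted_now <- cfg$travel_steps[unal[seq_len(a)]]
      expect_true(all(alerted_now < thr[st$t + 1]))
    }
  }
})

test_that("MDP instances survive a JSON round trip", {
  cfg <- tiny_cfg(8, c(2L, 6L), pa = 0.15, pb = 0.25, gamma = 0.02,
                  cancel = 12, triage = 1.5)
  path <- tempfile(fileext = ".json")
  write_mdp_instance(cfg, path)
  back <- read_mdp_instance(path)
  expect_equal(back$T_steps, cfg$T_steps)
  expect_equal(back$travel_steps, cfg$travel_steps)
  expect_equal(back$p_accept, cfg$p_accept)
  expect_equal(back$tradeoff$gamma, cfg$tradeoff$gamma)
  expect_equal(back$triage_delay, cfg$triage_delay)
  expect_equal(solve_backward_induction(back)$value0,
               solve_backward_induction(cfg)$value0, tolerance = 1e-12)
})
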