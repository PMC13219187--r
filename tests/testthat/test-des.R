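test_that("hand-traced incidents reproduce the expected event sequences", {
  inc <- test_incident(c(4, 6, 8), triage = 2, ems = 12)
  # V1 accepts after 0.5 min, V2 rejects, V3 ignores; send 2
  d <- draws_df(c("accept", "reject", "ignore"), c(0.5, 1, Inf))
  res <- simulate_incident(inc, policy_spec("send_n", 2), d)
  expect_equal(res$first_response_after_activation, 4.5)
  expect_equal(res$t_cpr, 7.5)
  expect_equal(res$t_ems, 13)
  expect_equal(round(res$survival, 4), 0.0448)
  expect_identical(res$redundant, 0L)
  expect_identical(res$alerts_sent, 2L)
  # V2 accepts instead: arrives at 7 < ambulance (10) but after V1
  d2 <- draws_df(c("accept", "accept", "ignore"), c(0.5, 1, Inf))
  res2 <- simulate_incident(inc, policy_spec("send_n", 2), d2)
  expect_identical(res2$redundant, 1L)
  expect_equal(res2$objective, res2$survival - 0.01)
  expect_equal(round(res2$survival, 4), 0.0448)
})

test_that("with no volunteers the run reduces to the ambulance baseline", {
  inc <- test_incident(numeric(0), triage = 2, ems = 12)
  res <- simulate_incident(inc, policy_spec("send_all"),
                           draws_df(character(0), numeric(0)))
  expect_equal(round(res$survival, 4), 0.0191)
  expect_identical(res$redundant, 0L)
  expect_identical(res$alerts_sent, 0L)
  expect_equal(res$t_cpr, 13)
})

test_that("arrival exactly with the ambulance counts as redundant", {
  inc <- test_incident(c(8), triage = 2, ems = 12)  # ambulance at 10
  d <- draws_df("accept", 2)  # arrives at 0 + 2 + 8 = 10, a tie
  res <- simulate_incident(inc, policy_spec("send_n", 1), d)
  expect_identical(res$redundant, 1L)
  expect_equal(res$t_cpr, res$t_ems)
})

test_that("rejection replacement honours the keep-n window", {
  inc <- test_incident(c(2, 3, 4, 5), triage = 1, ems = 12)
  # V1 rejects at 1 min -> V3 alerted then; V2 rejects at 4 min (> 3, no
  # replacement); V3 accepts 1 min after its alert
  d <- draws_df(c("reject", "reject", "accept", "accept"), c(1, 4, 1, 0.5))
  res <- simulate_incident(inc, policy_spec("keep_n_until_t", 2, t_stop = 3),
                           d)
  expect_identical(res$alerts_sent, 3L)
  # V3 alerted at 1, accepts at 2, arrives at 6
  expect_equal(res$first_response_after_activation, 6)
  expect_identical(res$redundant, 0L)
})

test_that("phased batches repeat until an acceptance arrives", {
  inc <- test_incident(c(2, 3, 4, 5, 6, 7, 8), triage = 1, ems = 12)
  # everyone ignores except volunteer 7, who accepts 0.2 min after alert
  d <- draws_df(c(rep("ignore", 6), "accept"), c(rep(Inf, 6), 0.2))
  res <- simulate_incident(inc, sjas_policy(), d)
  # batches of 3 at 0, 0.5, 1.0 min exhaust the pool of 7
  expect_identical(res$alerts_sent, 7L)
  expect_equal(res$first_response_after_activation, 1 + 0.2 + 8)
  # an early acceptance stops the batch clock
  d2 <- draws_df(c("accept", rep("ignore", 6)), c(0.3, rep(Inf, 6)))
  res2 <- simulate_incident(inc, sjas_policy(), d2)
  expect_identical(res2$alerts_sent, 3L)
})

test_that("replicated evaluation is deterministic and seed-faithful", {
  inc <- list(test_incident(c(3, 5, 7)), test_incident(c(2, 9), id = 2L))
  sam <- response_sampler()
  a <- evaluate_policy(inc, policy_spec("send_n", 2), 50, 7, sam)
  b <- evaluate_policy(inc, policy_spec("send_n", 2), 50, 7, sam)
  expect_identical(a, b)
  c <- evaluate_policy(inc, policy_spec("send_n", 2), 50, 8, sam)
  expect_false(identical(a$mean_objective, c$mean_objective))
  # send 0 is the ambulance-only mean with zero redundancy
  z <- evaluate_policy(inc, policy_spec("send_n", 0), 10, 7, sam)
  expect_equal(z$mean_survival,
               mean(vapply(inc, function(x) {
                 survival_probability(1 + x$ems_response_from_call,
                                      1 + x$ems_response_from_call)
               }, numeric(1))), tolerance = 1e-12)
  expect_equal(z$mean_redundant, 0)
})

test_that("suppressing an acceptance never speeds up the first response", {
  set.seed(21)
  sam <- response_sampler()
  inc <- test_incident(sort(runif(5, 1, 9)))
  for (r in 1:20) {
    dr <- sample_response(sam, 5)
    res <- simulate_incident(inc, policy_spec("send_all"), dr)
    accepted <- which(dr$outcome == "accept")
    for (i in accepted) {
      dr2 <- dr
      dr2$outcome[i] <- "ignore"
      dr2$view_delay[i] <- Inf
      res2 <- simulate_incident(inc, policy_spec("send_all"), dr2)
      expect_gte(res2$t_cpr, res$t_cpr)
    }
  }
})

test_that("without a fatigue penalty, larger batches never hurt under CRN", {
  set.seed(31)
  instances <- lapply(1:15, function(i) {
    test_incident(sort(runif(sample(0:6, 1), 0.5, 9.5)), id = i)
  })
  sam <- response_sampler()
  gam0 <- tradeoff_params(0)
  means <- vapply(0:6, function(n) {
    evaluate_policy(instances, policy_spec("send_n", n), 40, 5, sam,
                    tradeoff = gam0)$mean_objective
  }, numeric(1))
  expect_true(all(diff(means) >= -1e-12))
})

test_that("simulation means agree with exact MDP policy values", {
  # memoryless responses make the DES and the MDP the same stochastic model
  cfg <- mdp_config(T_steps = 36, travel_steps = c(12L, 24L),
                    p_accept = 0.02, p_reject = 0.03, cancel_steps = 180,
                    tradeoff = tradeoff_params(0.01))
  inc <- incident(1L, 0, 3, c(1, 2))  # 36 steps of 5 s = 3 min
  sam <- memoryless_response_sampler(0.02, 0.03, 5)
  for (spec in list(policy_spec("send_n", 2),
                    policy_spec("keep_n_until_t", 1, t_stop = 3))) {
    exact <- evaluate_fixed_policy(cfg, spec)
    sim <- evaluate_policy(list(inc), spec, 20000, 13, sam)
    expect_lt(abs(sim$mean_objective - exact$value),
              3 * sim$se_objective + 1e-9)
  }
})

test_that("mismatched draw vectors are rejected", {
  inc <- test_incident(c(3, 5))
  expect_error(simulate_incident(inc, policy_spec("send_all"),
                                 draws_df("accept", 1)),
               "align")
  expect_error(simulate_incident(incident(1, 1, 12, c(5, 3)),
                                 policy_spec("send_all"),
                                 draws_df(c("a", "b"), c(1, 2))),
               "sorted")
})
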