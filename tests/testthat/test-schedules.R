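# Operant schedule engines, curricula and devaluation sessions.

fast_agent <- function(rate, deterministic = TRUE) {
  agent_params(
    nose_poke_rate_hz = rate, inactive_rate_hz = 0,
    magazine_check_rate_hz = 0, deterministic = deterministic
  )
}

test_that("ratio-1 schedule reinforces every active poke", {
  s <- simulate_session(
    schedule_spec("RR", 1, session_cap_s = 60, reward_cap = 10000),
    fast_agent(1, deterministic = FALSE),
    seed = 1
  )
  pokes <- s[s$event_type == "nose_poke_active", ]
  expect_gt(nrow(pokes), 0)
  expect_true(all(pokes$rewarded))
})

test_that("fast responder on a low ratio terminates at the reward cap", {
  s <- simulate_session(schedule_spec("RR", 2), fast_agent(2), seed = 2)
  expect_identical(attr(s, "termination"), "reward_cap")
  expect_equal(attr(s, "n_rewards"), 60)
  expect_lt(attr(s, "duration_s"), 1800)
})

test_that("slow responder terminates at the time cap with few rewards", {
  s <- simulate_session(
    schedule_spec("RI", 60),
    agent_params(nose_poke_rate_hz = 1 / 200),
    seed = 3
  )
  expect_identical(attr(s, "termination"), "time_cap")
  expect_equal(attr(s, "duration_s"), 1800)
  expect_lt(attr(s, "n_rewards"), 60)
})

test_that("RI inter-reward intervals have mean equal to the schedule value", {
  s <- simulate_session(
    schedule_spec("RI", 30, session_cap_s = Inf, reward_cap = 1000),
    fast_agent(30),
    seed = 4
  )
  rt <- s$time_s[s$event_type == "reward_delivery"]
  iri <- diff(c(0, rt))
  expect_gte(length(iri), 1000)
  sem <- sd(iri) / sqrt(length(iri))
  expect_lt(abs(mean(iri) - 30), 3 * sem)
})

test_that("RR pokes per reward are geometric with the schedule's mean", {
  s <- simulate_session(
    schedule_spec("RR", 5, session_cap_s = Inf, reward_cap = 2000),
    fast_agent(5),
    seed = 5
  )
  pokes <- s[s$event_type == "nose_poke_active", ]
  gaps <- diff(c(0, which(pokes$rewarded))) # pokes per reward, geometric
  sem <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 5), 3 * sem)
  # geometric(1/5): P(gap = 1) = 0.2, P(gap > 5) = (4/5)^5
  expect_lt(abs(mean(gaps == 1) - 0.2), 3 * sd(gaps == 1) / sqrt(length(gaps)))
  expect_lt(
    abs(mean(gaps > 5) - (4 / 5)^5),
    3 * sd(gaps > 5) / sqrt(length(gaps))
  )
})

test_that("no session exceeds its caps and event times are ordered", {
  for (seed in 1:10) {
    kind <- if (seed %% 2) "RR" else "RI"
    s <- simulate_session(
      schedule_spec(kind, if (kind == "RR") 3 else 20,
        session_cap_s = 120, reward_cap = 15
      ),
      agent_params(nose_poke_rate_hz = 1),
      seed = seed
    )
    expect_lte(attr(s, "n_rewards"), 15)
    expect_lte(attr(s, "duration_s"), 120)
    expect_false(is.unsorted(s$time_s))
    expect_true(all(s$time_s >= 0))
    if (attr(s, "termination") == "reward_cap") {
      expect_equal(attr(s, "n_rewards"), 15)
    }
    # every magazine exit is preceded by at least as many entries
    n_entry <- cumsum(s$event_type == "magazine_entry")
    n_exit <- cumsum(s$event_type == "magazine_exit")
    expect_true(all(n_exit <= n_entry))
  }
})

test_that("identical seeds give bit-identical sessions", {
  a <- simulate_session(schedule_spec("RI", 30), agent_params(0.5), seed = 42)
  b <- simulate_session(schedule_spec("RI", 30), agent_params(0.5), seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "duration_s"), attr(b, "duration_s"))
})

test_that("curricula follow the printed stage progressions", {
  ri <- simulate_curriculum("RI_track", agent_params(0.5), seed = 6,
    session_cap_s = 60
  )
  vals <- vapply(ri, function(s) attr(s, "schedule")$value, 0)
  expect_equal(vals, c(30, 30, 60, 60, 120, 120, 120, 120))

  rr <- simulate_curriculum("RR_track", agent_params(0.5), seed = 7,
    session_cap_s = 60
  )
  vals <- vapply(rr, function(s) attr(s, "schedule")$value, 0)
  expect_equal(vals[1], 2)
  expect_equal(vals[length(vals)], 20)

  expect_error(
    simulate_curriculum("RI_track", agent_params(0.5), days = c(9, 9, 9)),
    "permitted ranges"
  )
})

test_that("a non-responding agent earns nothing and runs to the time cap", {
  sessions <- simulate_curriculum("RI_track",
    agent_params(nose_poke_rate_hz = 0, magazine_check_rate_hz = 0),
    seed = 8, session_cap_s = 30
  )
  for (s in sessions) {
    expect_identical(attr(s, "termination"), "time_cap")
    expect_equal(attr(s, "n_rewards"), 0)
  }
})

test_that("devaluation scales responding by the devaluation factor", {
  # habit agent: factor 1 leaves the rate unchanged in expectation
  agent_habit <- agent_params(nose_poke_rate_hz = 0.5, devaluation_factor = 1)
  v <- simulate_devaluation_pair(agent_habit, "valued", 600, seed = 9)
  d <- simulate_devaluation_pair(agent_habit, "devalued", 600, seed = 9)
  expect_equal(count_active_pokes(v), count_active_pokes(d))
  expect_equal(attr(v, "n_rewards"), 0) # extinction never reinforces

  # goal agent: devalued/valued count ratio approaches the factor
  agent_goal <- agent_params(nose_poke_rate_hz = 0.5, devaluation_factor = 0.3)
  coh <- simulate_devaluation_cohort(200, agent_goal, 600, seed = 10)
  ratio <- sum(coh$devalued) / sum(coh$valued)
  # delta-method SEM of a Poisson(lambda_d)/Poisson(lambda_v) total ratio
  sem <- ratio * sqrt(1 / sum(coh$devalued) + 1 / sum(coh$valued))
  expect_lt(abs(ratio - 0.3), 3 * sem)

  # zero rate: no pokes in either condition
  z <- simulate_devaluation_pair(agent_params(nose_poke_rate_hz = 0), "devalued",
    600,
    seed = 11
  )
  expect_equal(count_active_pokes(z), 0)
  expect_error(simulate_devaluation_pair(agent_habit, "valued", -5), "positive")
})

test_that("invalid schedules and degenerate setups error", {
  expect_error(schedule_spec("RR", -2), "positive")
  expect_error(schedule_spec("RI"), "positive")
  expect_error(
    simulate_session(
      schedule_spec("RR", 2, session_cap_s = Inf, reward_cap = 60),
      agent_params(nose_poke_rate_hz = 0)
    ),
    "degenerate agent"
  )
  expect_error(agent_params(nose_poke_rate_hz = -1), "non-negative")
  expect_error(agent_params(devaluation_factor = 2), "0, 1")
})
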