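make_schools <- function(xs, ys, radius = 1, fish = 10) {
  tibble::tibble(id = seq_along(xs), x = xs, y = ys, radius = radius,
                 fish = fish, born_at = 0)
}

test_that("sense_schools returns the nearest detectable school", {
  ag <- agent_state(1, x = 5, y = 5)
  expect_null(sense_schools(ag, make_schools(15, 15), r_sense = 2, L = 20))
  hit <- sense_schools(ag, make_schools(5, 5), r_sense = 2, L = 20)
  expect_equal(hit$id, 1L)
  # empty schools are invisible
  expect_null(sense_schools(ag, make_schools(5, 5, fish = 0), r_sense = 2, L = 20))

  # nearest among several, versus an exhaustive linear-scan oracle
  set.seed(21)
  L <- 20
  for (i in 1:50) {
    sch <- make_schools(stats::runif(6, 0, L), stats::runif(6, 0, L))
    ag <- agent_state(1, x = stats::runif(1, 0, L), y = stats::runif(1, 0, L))
    d <- vapply(seq_len(6), function(k)
      torus_distance(c(ag$x, ag$y), c(sch$x[k], sch$y[k]), L), 0)
    ok <- d <= 2 + sch$radius
    got <- sense_schools(ag, sch, r_sense = 2, L = L)
    if (!any(ok)) {
      expect_null(got)
    } else {
      expect_equal(got$id, sch$id[which(ok)[which.min(d[ok])]])
    }
  }
})

test_that("intermittent search moves at constant speed and turns at the exponential rate", {
  p <- tiny_agents(turn_rate = 0)
  ag <- agent_state(1, x = 1, y = 1, heading = pi / 4)
  dt <- 0.1
  for (i in 1:30) {
    prev <- c(ag$x, ag$y)
    ag <- search_step(ag, p, L = 20, dt = dt)
    d <- torus_delta(prev, c(ag$x, ag$y), 20)
    expect_equal(sqrt(sum(d^2)), p$v * dt, tolerance = 1e-12)
    # ballistic limit: heading never changes
    expect_equal(atan2(d[2], d[1]), pi / 4, tolerance = 1e-9)
  }

  # MSD: ballistic at lags << 1/turn_rate, diffusive at lags >> 1/turn_rate
  set.seed(31)
  p <- tiny_agents(turn_rate = 1)
  n_walkers <- 150
  n_steps <- 400
  dt <- 0.1
  disp <- array(0, c(n_walkers, n_steps, 2))
  for (w in seq_len(n_walkers)) {
    ag <- agent_state(1, x = 10, y = 10,
                      heading = stats::runif(1, 0, 2 * pi))
    prev <- c(ag$x, ag$y)
    for (s in seq_len(n_steps)) {
      ag <- search_step(ag, p, L = 20, dt = dt)
      disp[w, s, ] <- torus_delta(prev, c(ag$x, ag$y), 20)
      prev <- c(ag$x, ag$y)
    }
  }
  traj <- apply(disp, c(1, 3), cumsum)          # unwrapped trajectories
  msd <- function(lag) mean(rowSums((traj[lag, , ] - 0)^2))
  # short lag (0.2 = 0.2/turn_rate): near-ballistic, MSD ~ (v t)^2
  expect_equal(msd(2), (p$v * 0.2)^2, tolerance = 0.15)
  # long lags (20 and 40 >> 1/turn_rate = 1): diffusive, MSD doubles
  expect_equal(msd(400) / msd(200), 2, tolerance = 0.25)
})

test_that("move_towards takes the shorter periodic arc and lands exactly", {
  p <- tiny_agents()
  ag <- agent_state(1, x = 5, y = 5)
  same <- move_towards(ag, c(5, 5), p, L = 20, dt = 0.1)
  expect_equal(c(same$x, same$y), c(5, 5))

  # target across the boundary: step direction must match the
  # minimal-image direction, i.e. cross the boundary, not the interior
  ag <- agent_state(1, x = 0.5, y = 10)
  out <- move_towards(ag, c(19.5, 10), p, L = 20, dt = 0.1)
  expect_lt(out$x, 0.5)  # moved towards 0, wrapping leftwards

  # distance decreases by exactly min(v dt, distance)
  set.seed(41)
  for (i in 1:30) {
    ag <- agent_state(1, x = stats::runif(1, 0, 20), y = stats::runif(1, 0, 20))
    tgt <- stats::runif(2, 0, 20)
    d0 <- torus_distance(c(ag$x, ag$y), tgt, 20)
    stepped <- move_towards(ag, tgt, p, L = 20, dt = 0.7)
    d1 <- torus_distance(c(stepped$x, stepped$y), tgt, 20)
    expect_equal(d0 - d1, min(p$v * 0.7, d0), tolerance = 1e-9)
  }
})

test_that("harvest_step removes at C_q dt, caps at the school, and reverts", {
  p <- tiny_agents(C_q = 5)
  st <- stock_state()
  sch <- make_schools(1, 1, fish = 100)
  ag <- agent_state(1, x = 1, y = 1)
  ag$mode <- "harvesting"
  r <- harvest_step(ag, sch, p, st, dt = 0.1)
  expect_equal(r$caught, 0.5)
  expect_equal(r$agent$catch_total, 0.5)
  expect_equal(r$agent$mode, "harvesting")

  sch$fish <- 0.2
  r2 <- harvest_step(ag, sch, p, st, dt = 0.1)
  expect_equal(r2$caught, 0.2)
  expect_equal(r2$school$fish, 0)
  expect_equal(r2$agent$mode, "searching")
})

test_that("search-time estimates are consistent with an independent first-passage simulation", {
  # static single school, near-ballistic searcher
  w <- world_config(15, 1, 2, 10, tau_l = Inf, dt = 0.1)
  p <- tiny_agents(turn_rate = 1e-4)
  set.seed(51)
  est <- estimate_search_time(w, p, n_trials = 600)
  expect_gt(est$tau_s_hat, 0)

  # independent oracle: direct geometric simulation of a ballistic walker
  # on the torus until the school's edge enters the sensory zone
  set.seed(52)
  oracle_times <- replicate(600, {
    sx <- stats::runif(1, 0, 15); sy <- stats::runif(1, 0, 15)
    x <- stats::runif(1, 0, 15); y <- stats::runif(1, 0, 15)
    th <- stats::runif(1, 0, 2 * pi)
    t <- 0
    repeat {
      if (torus_distance(c(x, y), c(sx, sy), 15) <= p$r_sense + w$F_s) break
      if (stats::runif(1) < 1 - exp(-p$turn_rate * w$dt))
        th <- stats::runif(1, 0, 2 * pi)
      x <- (x + p$v * w$dt * cos(th)) %% 15
      y <- (y + p$v * w$dt * sin(th)) %% 15
      t <- t + w$dt
      if (t > 5000) break
    }
    t
  })
  se <- sqrt(est$stderr^2 + var(oracle_times) / length(oracle_times))
  expect_lt(abs(est$tau_s_hat - mean(oracle_times)), 3 * se)
})

test_that("search time responds to school density and is seed-stable", {
  p <- tiny_agents(turn_rate = 0.05)
  w4 <- world_config(20, 4, 1.5, 10, 100, 0.1)
  w2 <- world_config(20, 2, 1.5, 10, 100, 0.1)
  set.seed(61)
  e4 <- estimate_search_time(w4, p, n_trials = 800)
  e2 <- estimate_search_time(w2, p, n_trials = 800)
  # halving school count raises the search time (well beyond 2 SE)
  expect_gt(e2$tau_s_hat - e4$tau_s_hat, 2 * sqrt(e2$stderr^2 + e4$stderr^2))

  set.seed(62)
  e4b <- estimate_search_time(w4, p, n_trials = 800)
  expect_lt(abs(e4$tau_s_hat - e4b$tau_s_hat),
            3 * sqrt(e4$stderr^2 + e4b$stderr^2))
  expect_error(estimate_search_time(w4, p, n_trials = 50), ">= 100")
})

test_that("turn-rate optimization returns the encounter-rate minimum", {
  w <- tiny_world()
  p <- tiny_agents()
  set.seed(71)
  single <- optimize_turn_rate(w, p, candidate_rates = 0.3, n_trials = 150)
  expect_equal(single$turn_rate_star, 0.3)
  expect_gt(single$tau_s_hat, 0)

  # saturated detection: school radius near L/2 makes all rates equal
  wsat <- world_config(20, 4, 9.9, 10, 100, 0.1)
  set.seed(72)
  sat <- optimize_turn_rate(wsat, p, candidate_rates = c(0.01, 1),
                            n_trials = 150)
  expect_true(all(abs(diff(sat$table$tau_s_hat)) <=
                    2 * sqrt(sum(sat$table$stderr^2)) + 1e-12))

  # returned optimum beats every candidate on a fresh-seed re-run,
  # within 2 pooled standard errors
  rates <- c(0.02, 0.1, 0.5, 2.5)
  set.seed(73)
  opt <- optimize_turn_rate(w, p, candidate_rates = rates, n_trials = 400)
  set.seed(74)
  fresh <- optimize_turn_rate(w, p, candidate_rates = rates, n_trials = 400)
  star <- fresh$table[fresh$table$turn_rate == opt$turn_rate_star, ]
  pooled <- sqrt(star$stderr^2 + fresh$table$stderr^2)
  expect_true(all(star$tau_s_hat <= fresh$table$tau_s_hat + 2 * pooled))
  expect_error(optimize_turn_rate(w, p, candidate_rates = numeric(0)),
               "non-empty")
})
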