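test_that("catch_rate_series computes windowed active-time rates", {
  # constant catch c per step: H = c/dt in every window
  catch <- matrix(0.25, nrow = 10, ncol = 2)
  res <- fake_result(catch, dt = 0.5)
  ser <- catch_rate_series(res, window = 2.5)
  expect_equal(unique(ser$H), 0.25 / 0.5)
  expect_equal(sort(unique(ser$window)), 1:2)

  # ledger: sum over windows of H * active_time equals the total catch
  set.seed(91)
  catch <- matrix(stats::runif(60), nrow = 20, ncol = 3)
  res <- fake_result(catch, dt = 0.5)
  ser <- catch_rate_series(res, window = 1.7)
  tot <- ser |>
    dplyr::group_by(agent) |>
    dplyr::summarise(t = sum(H * active_time))
  expect_equal(tot$t, colSums(catch), tolerance = 1e-12)

  # windows after retirement are flagged missing
  active <- matrix(TRUE, 10, 2)
  active[6:10, 2] <- FALSE
  catch <- matrix(0.1, 10, 2); catch[6:10, 2] <- 0
  res <- fake_result(catch, active = active, dt = 1,
                     retire_time = c(NA, 5))
  ser <- catch_rate_series(res, window = 5)
  expect_true(is.na(ser$H[ser$agent == 2 & ser$window == 2]))
  expect_false(anyNA(ser$H[ser$agent == 1]))
  expect_error(catch_rate_series(res, window = 0.5), ">= dt")
})

test_that("cpue divides catch by active time", {
  catch <- matrix(c(rep(2, 5), rep(0, 5)), nrow = 5)  # agent 1: 10 fish
  res <- fake_result(catch, dt = 1)
  cp <- cpue(res)
  expect_equal(cp$cpue[1], 10 / 5)
  expect_equal(cp$cpue[2], 0)

  # zero active time: flagged NA, excluded from the fleet mean
  active <- cbind(rep(TRUE, 5), rep(FALSE, 5))
  res <- fake_result(catch, active = active, dt = 1)
  expect_warning(cp <- cpue(res), "zero active time")
  expect_true(is.na(cp$cpue[2]))
  expect_equal(attr(cp, "fleet_mean"), 2)
})

test_that("objective functions reproduce hand-computed ratios", {
  # O_CPUE: H == 2 vs H == 1 gives scores {1, 0.5}
  ser <- toy_series(list("0" = c(2, 2), "1" = c(1, 1)))
  oc <- objective_cpue(ser)
  expect_equal(oc$value[oc$lam == 0], 1)
  expect_equal(oc$value[oc$lam == 1], 0.5)

  # single lambda: self-normalization to 1
  expect_equal(objective_cpue(toy_series(list("0.5" = c(3, 3))))$value, 1)

  # O_equity: between-agent sds {2*sqrt(2), sqrt(2)} give {0.5, 1}
  ser <- toy_series(list("0" = c(0, 4), "1" = c(1, 3)))
  oe <- objective_equity(ser)
  expect_equal(oe$value[oe$lam == 0], 0.5)
  expect_equal(oe$value[oe$lam == 1], 1)
  # scale invariance
  oe7 <- objective_equity(dplyr::mutate(ser, H = 7 * H))
  expect_equal(oe$value, oe7$value)
  # identical agents attain the maximum (eps-regularized)
  oid <- objective_equity(toy_series(list("0" = c(2, 2), "1" = c(1, 3))))
  expect_equal(oid$value[oid$lam == 0], 1, tolerance = 1e-6)

  # O_stability: temporal sds {4, 2} give {0.5, 1}
  mk <- function(lam, hs) tidyr::expand_grid(
    lam = lam, replicate = 1L, agent = 1:2, window = seq_along(hs)) |>
    dplyr::mutate(H = hs[window])
  ser <- dplyr::bind_rows(mk(0, c(0, 8, 0, 8)), mk(1, c(0, 4, 0, 4)))
  os <- objective_stability(ser)
  expect_equal(os$value[os$lam == 0], 0.5, tolerance = 1e-9)
  expect_equal(os$value[os$lam == 1], 1)
  # permuting agent labels changes nothing
  perm <- ser |> dplyr::mutate(agent = 3 - agent)
  expect_equal(objective_stability(perm)$value, os$value)

  # normalization: max is exactly 1 for each objective
  set.seed(101)
  ser <- tidyr::expand_grid(lam = c(0, 0.5, 1), replicate = 1:3,
                            agent = 1:4, window = 1:5) |>
    dplyr::mutate(H = stats::runif(dplyr::n()))
  expect_identical(max(objective_cpue(ser)$value), 1)
  expect_identical(max(objective_equity(ser)$value), 1)
  expect_identical(max(objective_stability(ser)$value), 1)
})

test_that("percentile groups rank by CPUE with documented tie rules", {
  df <- tibble::tibble(replicate = 1L, agent = 1:10, cpue = 10:1 / 10)
  gr <- percentile_groups(df, q = 0.1)
  expect_equal(gr$agent[gr$group == "top"], 1L)
  expect_equal(gr$agent[gr$group == "bottom"], 10L)

  # all-equal CPUE: ties broken by agent id, groups still full-size
  df <- tibble::tibble(replicate = 1L, agent = 1:10, cpue = 1)
  gr <- percentile_groups(df, q = 0.2)
  expect_equal(sort(gr$agent[gr$group == "bottom"]), 1:2)
  expect_equal(sort(gr$agent[gr$group == "top"]), 1:2)

  # group means bracket the fleet mean (order statistics, exact)
  set.seed(111)
  df <- tidyr::expand_grid(replicate = 1:5, agent = 1:20) |>
    dplyr::mutate(cpue = stats::runif(dplyr::n()))
  gr <- percentile_groups(df, q = 0.1)
  means <- gr |> dplyr::group_by(group) |>
    dplyr::summarise(m = mean(cpue))
  fleet <- mean(df$cpue)
  expect_lte(means$m[means$group == "bottom"], fleet)
  expect_gte(means$m[means$group == "top"], fleet)

  expect_error(percentile_groups(tibble::tibble(replicate = 1, agent = 1:5,
                                                cpue = 1:5), q = 0.1),
               ">= 1 agent")
  expect_error(percentile_groups(df, q = 0.7), "in \\(0, 0.5\\)")
})

test_that("optimal_lambda is the grid arg-max with small-lambda ties", {
  grid <- seq(0, 1, 0.1)
  expect_equal(optimal_lambda(tibble::tibble(lam = grid, value = grid)), 1)
  expect_equal(optimal_lambda(tibble::tibble(lam = grid, value = 1)), 0)
  set.seed(121)
  for (i in 1:20) {
    v <- -(grid - stats::runif(1))^2  # unimodal
    expect_equal(optimal_lambda(tibble::tibble(lam = grid, value = v)),
                 grid[which.max(v)])
  }
})

test_that("divergence index and IFQ/TAC ratio follow their definitions", {
  expect_equal(divergence_index(0.4, 0.4), 0)
  expect_equal(divergence_index(0.2, 0.8), 0.75)
  expect_equal(divergence_index(0, 0), 0)
  expect_warning(d <- divergence_index(0.3, 0), "flag")
  expect_true(is.na(d))

  expect_equal(ifq_tac_ratio(1, 1), 0)
  expect_equal(ifq_tac_ratio(1.2, 1.0), 0.2)
  # swapping arguments maps r to 1/(1+r) - 1
  r <- ifq_tac_ratio(1.3, 0.8)
  expect_equal(ifq_tac_ratio(0.8, 1.3), 1 / (1 + r) - 1)
  expect_warning(u <- ifq_tac_ratio(1, 0), "undefined")
  expect_true(is.na(u))
})
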