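test_that("exemplar scenarios encode the species sign structure", {
  wh <- build_scenario("whiting")
  gf <- build_scenario("groundfish")
  expect_gt(wh$world$F_s, gf$world$F_s)     # larger schools
  expect_gt(wh$world$F_n, gf$world$F_n)     # more fish per school
  expect_lt(wh$world$tau_l, gf$world$tau_l) # more mobile
  # everything else is shared between the two exemplars
  expect_equal(wh$world$L, gf$world$L)
  expect_equal(wh$world$n_schools, gf$world$n_schools)
  expect_equal(wh$n_agents, gf$n_agents)
  expect_equal(wh$T, gf$T)
  expect_error(build_scenario("rockfish"), "groundfish")
})

test_that("custom scenarios round-trip and hash on content", {
  spec <- list(name = "toy",
               world = list(L = 20, n_schools = 3, F_s = 1, F_n = 10,
                            tau_l = 50, dt = 0.1),
               agents = list(v = 1, r_sense = 1.5, C_q = 1, turn_rate = 0.1),
               n_agents = 4, T = 30, t_max = 500)
  sc <- build_scenario(spec = spec)
  json <- jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA)
  sc2 <- build_scenario(spec = jsonlite::fromJSON(json))
  expect_identical(sc$hash, sc2$hash)
  expect_identical(sc$world, sc2$world)

  spec$world$F_n <- 11
  expect_false(identical(build_scenario(spec = spec)$hash, sc$hash))
})

toy_scenario <- function() {
  build_scenario(spec = list(
    name = "toy",
    world = list(L = 20, n_schools = 4, F_s = 1.5, F_n = 30, tau_l = 100,
                 dt = 0.1),
    agents = list(v = 1, r_sense = 2, C_q = 1, turn_rate = 0.05),
    n_agents = 5, T = 60, t_max = 2000))
}

test_that("run_sweep is deterministic, resumable and append-only", {
  sc <- toy_scenario()
  g1 <- sweep_grid(lam = c(0, 1), depletion = 0, management = "TAC",
                   replicates = 1, master_seed = 5)
  t1 <- run_sweep(g1, sc)
  expect_equal(nrow(t1), 2)
  # single cell wraps exactly one season's summary
  cfg <- scenario_season_config(sc, lam = 0)
  res <- run_season(cfg, t1$seed[t1$lam == 0])
  expect_equal(t1$total_catch[t1$lam == 0], res$cumulative_harvest)
  expect_equal(t1$duration[t1$lam == 0], res$duration)

  # pure function of (scenario hash, grid, master seed)
  t1b <- run_sweep(g1, sc)
  expect_equal(as.data.frame(t1), as.data.frame(t1b))
  g2 <- sweep_grid(lam = c(0, 1), depletion = 0, management = "TAC",
                   replicates = 1, master_seed = 6)
  expect_false(isTRUE(all.equal(run_sweep(g2, sc)$seed, t1$seed)))

  # doubling replicates with the old table as prior appends, never mutates
  g4 <- sweep_grid(lam = c(0, 1), depletion = 0, management = "TAC",
                   replicates = 2, master_seed = 5)
  t4 <- run_sweep(g4, sc, prior = t1)
  expect_equal(nrow(t4), 4)
  old <- t4[t4$replicate == 1, ]
  expect_equal(as.list(old[order(old$lam), names(t1)]),
               as.list(t1[order(t1$lam), ]), ignore_attr = TRUE)
})

test_that("analyze_sweep degrades gracefully and names missing axes", {
  sc <- toy_scenario()
  tab <- run_sweep(sweep_grid(lam = 0.5, depletion = 0, management = "TAC",
                              replicates = 3, master_seed = 9), sc)
  # single-lambda table: point curves, no crash
  an <- suppressMessages(analyze_sweep(tab, q = 0.2))
  expect_equal(nrow(an$fleet_cpue), 1)
  expect_equal(unique(an$group_cpue$lam), 0.5)
  # explicitly requesting a product with a missing axis errors, naming it
  expect_error(analyze_sweep(tab, q = 0.2, products = "ifq_tac"),
               "management")
  expect_error(analyze_sweep(tab, q = 0.2, products = "objectives"),
               "lam")
})

test_that("the command-line interface runs, lists and fails loudly", {
  cli <- system.file("cli", "fleetsim.R", package = "fleetsim")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(cli, "scenarios"), stdout = TRUE, stderr = TRUE)
  expect_true(any(grepl("whiting", out)))
  expect_true(any(grepl("groundfish", out)))

  # analyze on an empty directory: nonzero exit with a clear message
  empty <- withr::local_tempdir()
  res <- suppressWarnings(
    system2(rscript, c(cli, "analyze", "--in", empty),
            stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(res, "status")))
  expect_true(any(grepl("no sweep tables", res)))

  # run twice with the same seed: identical outputs
  cfgfile <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    world = list(L = 20, n_schools = 4, F_s = 1.5, F_n = 30, tau_l = 100,
                 dt = 0.1),
    agents = list(v = 1, r_sense = 2, C_q = 1, turn_rate = 0.05),
    sharing = list(lam = 0.5),
    management = list(kind = "TAC", T = 40, n_agents = 4, t_max = 2000)
  ), cfgfile, auto_unbox = TRUE, digits = NA)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- system2(rscript, c(cli, "run", "--config", cfgfile, "--seed", "7",
                           "--out", d1), stdout = TRUE, stderr = TRUE)
  s2 <- system2(rscript, c(cli, "run", "--config", cfgfile, "--seed", "7",
                           "--out", d2), stdout = TRUE, stderr = TRUE)
  expect_null(attr(s1, "status"))
  expect_identical(readLines(file.path(d1, "catch_matrix.csv")),
                   readLines(file.path(d2, "catch_matrix.csv")))
})
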