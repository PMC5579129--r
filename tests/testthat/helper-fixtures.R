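# shared fixtures: small, fast configurations used across test files

tiny_world <- function(L = 20, n_schools = 4, F_s = 1.5, F_n = 30,
                       tau_l = 100, dt = 0.1) {
  world_config(L, n_schools, F_s, F_n, tau_l, dt)
}

tiny_agents <- function(v = 1, r_sense = 2, C_q = 1, turn_rate = 0.05) {
  agent_params(v, r_sense, C_q, turn_rate)
}

quick_cfg <- function(kind = "TAC", lam = 0.5, n_agents = 5, T = 60,
                      t_max = 2000, P = Inf, world = tiny_world(),
                      agents = tiny_agents()) {
  season_config(
    world = world, agents = agents, n_agents = n_agents, lam = lam,
    policy = management_policy(kind, T = T, n_agents = n_agents, t_max = t_max),
    P = P
  )
}

# hand-built season_result for exact metric toys: catch/active given as
# step x agent matrices
fake_result <- function(catch, active = NULL, dt = 1, retire_time = NULL) {
  n_steps <- nrow(catch)
  n <- ncol(catch)
  if (is.null(active)) active <- matrix(TRUE, n_steps, n)
  cfg <- season_config(
    world = world_config(10, 1, 1, 1e6, 1e6, dt),
    agents = agent_params(1, 1, 1, 0),
    n_agents = n, lam = 0,
    policy = management_policy("TAC", T = 1e6, n_agents = n,
                               t_max = n_steps * dt * 10)
  )
  structure(
    list(config = cfg, seed = 0L, config_hash = "fake",
         catch = catch, active = active,
         retire_time = retire_time %||% rep(NA_real_, n),
         catch_total = colSums(catch),
         cumulative_harvest = sum(catch),
         stock_trace = cumsum(rowSums(catch)),
         duration = n_steps * dt, n_steps = n_steps,
         terminated_by = "quota"),
    class = "season_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# window-level toy series for the objective functions: one H value per
# (lam, replicate, agent, window)
toy_series <- function(H_by_lam, n_agents = 2, n_windows = 4) {
  purrr::map_dfr(names(H_by_lam), function(l) {
    h <- H_by_lam[[l]]
    tidyr::expand_grid(replicate = 1L, agent = seq_len(n_agents),
                       window = seq_len(n_windows)) |>
      dplyr::mutate(lam = as.numeric(l), H = h[.data$agent])
  })
}
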