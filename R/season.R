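#' Management policy: TAC or IFQ season closure
#'
#' Under a total allowable catch (TAC) the season ends as soon as the
#' fleet's collective catch reaches `T`, irrespective of individual
#' catches. Under individual fishery quotas (IFQ) each agent holds
#' `T_i = T / n_agents` and retires (stops moving, harvesting, sending and
#' receiving information) on reaching it; the season ends when all agents
#' have retired. Quotas are not transferable. Both policies additionally
#' stop at the hard time cap `t_max` (with a warning), which matters when
#' depletion makes `T` unreachable.
#'
#' @param kind `"TAC"` or `"IFQ"`.
#' @param T Total allowed catch for the fleet (fish).
#' @param n_agents Number of agents (used for `T_i` under IFQ).
#' @param t_max Hard time cap (time units).
#' @return An object of class `management_policy` with field `T_i`.
#' @export
management_policy <- function(kind = c("TAC", "IFQ"), T, n_agents, t_max) {
  kind <- match.arg(kind)
  check_number(T, "T", 0, strict = TRUE)
  check_number(t_max, "t_max", 0, strict = TRUE)
  if (n_agents < 1) abort_input("`n_agents` must be >= 1")
  structure(
    list(kind = kind, T = as.numeric(T), n_agents = as.integer(n_agents),
         T_i = as.numeric(T) / as.integer(n_agents), t_max = as.numeric(t_max)),
    class = "management_policy"
  )
}

#' Full single-season configuration
#'
#' Bundles the world, agent, sharing and management parameters of one
#' model run. With `P` finite, depletion is enabled: replacement schools
#' shrink in proportion to the remaining stock `P - cumulative_harvest`.
#' The allowed depletion level is the fraction `T / P`.
#'
#' @param world A [world_config()].
#' @param agents An [agent_params()].
#' @param n_agents Fleet size.
#' @param lam Information-sharing tie weight in `[0, 1]`.
#' @param policy A [management_policy()].
#' @param P Total stock (fish); `Inf` disables depletion.
#' @return An object of class `season_config`.
#' @export
season_config <- function(world, agents, n_agents, lam, policy, P = Inf) {
  stopifnot(inherits(world, "world_config"), inherits(agents, "agent_params"),
            inherits(policy, "management_policy"))
  net <- sharing_network(n_agents, lam)
  if (policy$n_agents != n_agents)
    abort_input("`policy` was built for a different fleet size")
  check_number(P, "P", 0, strict = TRUE, finite = FALSE)
  structure(
    list(world = world, agents = agents, n_agents = as.integer(n_agents),
         sharing = net, policy = policy, P = P,
         depletion = is.finite(P)),
    class = "season_config"
  )
}

engine_cfg <- function(cfg) {
  list(L = cfg$world$L, n_schools = cfg$world$n_schools, F_s = cfg$world$F_s,
       F_n = cfg$world$F_n, tau_l = cfg$world$tau_l, dt = cfg$world$dt,
       n_agents = cfg$n_agents, v = cfg$agents$v, r_sense = cfg$agents$r_sense,
       C_q = cfg$agents$C_q, turn_rate = cfg$agents$turn_rate,
       lam = cfg$sharing$lam,
       mgmt = if (cfg$policy$kind == "IFQ") 1L else 0L,
       T = cfg$policy$T, t_max = cfg$policy$t_max,
       depletion = cfg$depletion, P = cfg$P)
}

#' Run one fishing season
#'
#' Executes the per-step update loop until the management rule closes the
#' season (or `t_max` is hit): school turnover, sensing, information
#' emission and resolution, movement, harvest settlement in randomized
#' agent order, then the management check. A model run represents a single
#' fishing season; the full per-agent catch and activity record is
#' returned.
#'
#' @param cfg A [season_config()].
#' @param seed Integer seed; the same seed reproduces the season
#'   bit-identically.
#' @return An object of class `season_result`: list with the config
#'   snapshot, `seed`, per-step-per-agent `catch` and `active` matrices,
#'   `retire_time`, `catch_total`, `cumulative_harvest`, `stock_trace`,
#'   `duration`, `n_steps` and `terminated_by` (`"quota"` or `"t_max"`).
#' @examples
#' cfg <- season_config(
#'   world = world_config(40, 10, 2, 50, 100, 0.1),
#'   agents = agent_params(v = 1, r_sense = 2, C_q = 1, turn_rate = 0.2),
#'   n_agents = 5, lam = 0.5,
#'   policy = management_policy("TAC", T = 50, n_agents = 5, t_max = 500)
#' )
#' res <- run_season(cfg, seed = 1)
#' glance(res)
#' @export
run_season <- function(cfg, seed) {
  if (!inherits(cfg, "season_config"))
    abort_input("`cfg` must be a season_config")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_input("`seed` must be a single integer")
  set.seed(as.integer(seed))
  raw <- cpp_run_season(engine_cfg(cfg))
  if (raw$terminated_by == "t_max")
    warning("season hit the t_max cap before the quota closed it",
            call. = FALSE)
  structure(
    c(list(config = cfg, seed = as.integer(seed),
           config_hash = config_hash(cfg)),
      raw),
    class = "season_result"
  )
}

#' Run independent replicate seasons
#'
#' Each seed drives an independent random stream, so results are
#' order-independent: permuting `seeds` permutes the results identically.
#'
#' @param cfg A [season_config()].
#' @param seeds Vector of distinct integer seeds.
#' @return List of [run_season()] results (class `season_result_list`).
#' @export
run_replicates <- function(cfg, seeds) {
  if (anyDuplicated(seeds)) abort_input("`seeds` must be distinct")
  structure(lapply(seeds, function(s) run_season(cfg, s)),
            class = "season_result_list")
}

#' @export
print.season_result <- function(x, ...) {
  cat(sprintf(
    "<season_result> %s, lam = %.2f, %d agents, %d steps (duration %.1f)\n",
    x$config$policy$kind, x$config$sharing$lam, x$config$n_agents,
    x$n_steps, x$duration))
  cat(sprintf("  total catch %.2f / T = %g; closed by %s; seed %d\n",
              x$cumulative_harvest, x$config$policy$T, x$terminated_by,
              x$seed))
  invisible(x)
}

#' Tidy a season result into a long per-step table
#'
#' @param x A `season_result`.
#' @param ... Unused.
#' @return Tibble with columns `step, time, agent, catch, active`.
#' @export
tidy.season_result <- function(x, ...) {
  n_steps <- x$n_steps
  n <- x$config$n_agents
  dt <- x$config$world$dt
  tibble::tibble(
    step = rep(seq_len(n_steps), times = n),
    time = rep(seq_len(n_steps) * dt, times = n),
    agent = rep(seq_len(n), each = n_steps),
    catch = as.vector(x$catch),
    active = as.vector(x$active)
  )
}

#' One-row summary of a season
#'
#' @param x A `season_result`.
#' @param ... Unused.
#' @return One-row tibble: management, sharing level, fleet size, total
#'   catch, duration, number retired, closure cause, seed, config hash.
#' @export
glance.season_result <- function(x, ...) {
  tibble::tibble(
    management = x$config$policy$kind,
    lam = x$config$sharing$lam,
    n_agents = x$config$n_agents,
    total_catch = x$cumulative_harvest,
    duration = x$duration,
    n_steps = x$n_steps,
    n_retired = sum(!is.na(x$retire_time)),
    terminated_by = x$terminated_by,
    seed = x$seed,
    config_hash = x$config_hash
  )
}

#' Write a season result to disk
#'
#' Writes the per-step per-agent catch matrix as CSV (header row of agent
#' ids, one row per step) and a JSON summary (duration, totals, retirement
#' times, seed, config hash, full config).
#'
#' @param result A `season_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_season_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  catch <- as.data.frame(result$catch)
  names(catch) <- paste0("agent_", seq_len(ncol(catch)))
  csv <- file.path(dir, "catch_matrix.csv")
  utils::write.csv(catch, csv, row.names = FALSE)
  summ <- list(
    seed = result$seed,
    config_hash = result$config_hash,
    duration = result$duration,
    n_steps = result$n_steps,
    terminated_by = result$terminated_by,
    cumulative_harvest = result$cumulative_harvest,
    catch_total = result$catch_total,
    retire_time = result$retire_time,
    config = unclass_deep(result$config)
  )
  js <- file.path(dir, "season_summary.json")
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(c(csv, js))
}
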