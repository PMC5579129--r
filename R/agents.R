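#' Fishing-agent parameters
#'
#' Agents move at constant speed `v`, sense schools within a circular zone
#' of radius `r_sense` around them (a school is detectable when its edge
#' enters the zone, i.e. center distance `<= r_sense + F_s`), and harvest
#' at the constant catchability rate `C_q` while positioned on a school.
#' While searching they move ballistically and redraw a uniformly random
#' heading as a Poisson process with rate `turn_rate`.
#'
#' @param v Speed (length/time).
#' @param r_sense Sensory radius (length).
#' @param C_q Catch rate while on a school (fish/time).
#' @param turn_rate Heading-redraw rate while searching (1/time); 0 gives
#'   purely ballistic search.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(v, r_sense, C_q, turn_rate) {
  check_number(v, "v", 0, strict = TRUE)
  check_number(r_sense, "r_sense", 0, strict = TRUE)
  check_number(C_q, "C_q", 0, strict = TRUE)
  check_number(turn_rate, "turn_rate", 0)
  structure(list(v = as.numeric(v), r_sense = as.numeric(r_sense),
                 C_q = as.numeric(C_q), turn_rate = as.numeric(turn_rate)),
            class = "agent_params")
}

#' Construct an agent state record
#'
#' @param id Agent identifier.
#' @param x,y Position in `[0, L)^2`.
#' @param heading Heading angle (radians).
#' @param mode One of `"searching"`, `"traveling_to_info"`, `"harvesting"`,
#'   `"retired"`.
#' @return One-row tibble with the agent's kinematic state, target, catch
#'   ledger and activity clock.
#' @export
agent_state <- function(id = 1L, x = 0, y = 0, heading = 0, mode = "searching") {
  mode <- match.arg(mode, c("searching", "traveling_to_info", "harvesting", "retired"))
  tibble::tibble(
    id = as.integer(id), x = x, y = y,
    hx = cos(heading), hy = sin(heading),
    mode = mode, target = NA_integer_, tx = NA_real_, ty = NA_real_,
    catch_total = 0, active_time = 0, info_source = NA_integer_
  )
}

#' Sense the local environment for fish schools
#'
#' Returns the nearest school (minimal-image distance) whose edge lies
#' within the agent's sensory zone, i.e. whose center is within
#' `r_sense + radius` of the agent, among schools that still hold fish.
#'
#' @param agent One-row agent tibble.
#' @param schools School tibble.
#' @param r_sense Sensory radius.
#' @param L Domain side length.
#' @return One-row school tibble, or `NULL` if nothing is in range.
#' @export
sense_schools <- function(agent, schools, r_sense, L) {
  if (nrow(schools) == 0) return(NULL)
  d <- torus_distance(c(agent$x, agent$y), cbind(schools$x, schools$y), L)
  ok <- d <= r_sense + schools$radius & schools$fish > 0
  if (!any(ok)) return(NULL)
  schools[which(ok)[which.min(d[ok])], ]
}

#' One intermittent-search step
#'
#' With probability `1 - exp(-turn_rate * dt)` the heading is redrawn
#' uniformly on the circle; the agent then advances `v * dt` along its
#' heading and wraps periodically.
#'
#' @param agent One-row agent tibble in searching mode.
#' @param params An [agent_params()].
#' @param L Domain side length.
#' @param dt Timestep.
#' @return Updated agent tibble.
#' @export
search_step <- function(agent, params, L, dt) {
  stopifnot(agent$mode == "searching")
  p_turn <- 1 - exp(-params$turn_rate * dt)
  if (p_turn > 0 && stats::runif(1) < p_turn) {
    th <- stats::runif(1, 0, 2 * pi)
    agent$hx <- cos(th)
    agent$hy <- sin(th)
  }
  agent$x <- (agent$x + params$v * dt * agent$hx) %% L
  agent$y <- (agent$y + params$v * dt * agent$hy) %% L
  agent
}

#' Move directly towards a target position
#'
#' Advances `v * dt` along the minimal-image direction to `target` (so
#' paths cross the periodic boundary whenever that arc is shorter), landing
#' exactly on the target when it is within reach.
#'
#' @param agent One-row agent tibble.
#' @param target Length-2 position.
#' @param params An [agent_params()].
#' @param L Domain side length.
#' @param dt Timestep.
#' @return Updated agent tibble.
#' @export
move_towards <- function(agent, target, params, L, dt) {
  d <- torus_delta(c(agent$x, agent$y), target, L)
  dist <- sqrt(sum(d^2))
  step <- params$v * dt
  if (dist <= step) {
    agent$x <- target[1] %% L
    agent$y <- target[2] %% L
  } else {
    agent$x <- (agent$x + step * d[1] / dist) %% L
    agent$y <- (agent$y + step * d[2] / dist) %% L
  }
  agent
}

#' One harvesting step on a school
#'
#' The agent requests `C_q * dt` fish; the actual removal is capped by the
#' school's remaining content via [deplete_school()]. If the school is
#' emptied the agent reverts to searching.
#'
#' @param agent One-row agent tibble in harvesting mode.
#' @param school One-row school tibble.
#' @param params An [agent_params()].
#' @param stock A [stock_state()].
#' @param dt Timestep.
#' @return List with `agent`, `school`, `stock` (updated) and `caught`.
#' @export
harvest_step <- function(agent, school, params, stock, dt) {
  stopifnot(agent$mode == "harvesting")
  res <- deplete_school(school, params$C_q * dt, stock)
  agent$catch_total <- agent$catch_total + res$removed
  if (res$school$fish <= 0) {
    agent$mode <- "searching"
    agent$target <- NA_integer_
  }
  list(agent = agent, school = res$school, stock = res$stock, caught = res$removed)
}

#' Monte-Carlo estimate of the mean search time
#'
#' Simulates `n_trials` independent episodes of a lone intermittent
#' searcher (schools present and turning over, no information sharing) and
#' returns the mean time to first school encounter with its standard
#' error. Trials that reach `max_time` without an encounter are censored at
#' `max_time`, which biases the estimate low if `max_time` is set too
#' small.
#'
#' @param world_cfg A [world_config()].
#' @param params An [agent_params()].
#' @param n_trials Number of independent episodes (`>= 100`).
#' @param max_time Episode cap (time units).
#' @return A `search_characterization`: list with `turn_rate_star`,
#'   `tau_s_hat`, `stderr`, `n_trials`.
#' @export
estimate_search_time <- function(world_cfg, params, n_trials = 400,
                                 max_time = 200 * world_cfg$L / params$v) {
  if (n_trials < 100) abort_input("`n_trials` must be >= 100")
  times <- cpp_first_encounter(engine_cfg_search(world_cfg, params),
                               params$turn_rate, as.integer(n_trials), max_time)
  structure(
    list(turn_rate_star = params$turn_rate,
         tau_s_hat = mean(times),
         stderr = stats::sd(times) / sqrt(length(times)),
         n_trials = as.integer(n_trials)),
    class = "search_characterization"
  )
}

#' Choose the encounter-optimal turn rate
#'
#' Estimates the mean first-encounter time of a lone searcher for each
#' candidate turn rate by Monte-Carlo and returns the rate minimizing the
#' estimated search time, ties broken toward the smaller rate. This is run
#' once per scenario, before the season: the fleet is treated as
#' pre-adapted to the target species.
#'
#' @param world_cfg A [world_config()].
#' @param params An [agent_params()]; its `turn_rate` field is ignored.
#' @param candidate_rates Turn rates to compare (1/time). Default: 15
#'   log-spaced values spanning `[0.01 v/L, 100 v/L]`, bracketing the
#'   ballistic and diffusive extremes.
#' @param n_trials Episodes per candidate (`>= 100`).
#' @param max_time Episode cap.
#' @return A `search_characterization` for the winning rate, with the full
#'   per-candidate table in `$table`.
#' @export
optimize_turn_rate <- function(world_cfg, params,
                               candidate_rates = default_turn_rates(world_cfg, params),
                               n_trials = 400,
                               max_time = 200 * world_cfg$L / params$v) {
  if (length(candidate_rates) == 0) abort_input("`candidate_rates` must be non-empty")
  if (n_trials < 100) abort_input("`n_trials` must be >= 100")
  cfg <- engine_cfg_search(world_cfg, params)
  tab <- purrr::map_dfr(sort(candidate_rates), function(r) {
    times <- cpp_first_encounter(cfg, r, as.integer(n_trials), max_time)
    tibble::tibble(turn_rate = r, tau_s_hat = mean(times),
                   stderr = stats::sd(times) / sqrt(length(times)))
  })
  best <- which.min(tab$tau_s_hat)  # which.min takes the first = smaller rate
  structure(
    list(turn_rate_star = tab$turn_rate[best],
         tau_s_hat = tab$tau_s_hat[best],
         stderr = tab$stderr[best],
         n_trials = as.integer(n_trials),
         table = tab),
    class = "search_characterization"
  )
}

#' Default turn-rate candidate grid
#'
#' @inheritParams optimize_turn_rate
#' @param n Number of candidates.
#' @return Numeric vector of log-spaced rates.
#' @export
default_turn_rates <- function(world_cfg, params, n = 15) {
  exp(seq(log(0.01 * params$v / world_cfg$L),
          log(100 * params$v / world_cfg$L), length.out = n))
}

engine_cfg_search <- function(world_cfg, params) {
  list(L = world_cfg$L, n_schools = world_cfg$n_schools, F_s = world_cfg$F_s,
       tau_l = world_cfg$tau_l, dt = world_cfg$dt,
       v = params$v, r_sense = params$r_sense)
}

#' @export
print.search_characterization <- function(x, ...) {
  cat(sprintf(
    "Search characterization: turn_rate* = %.4g, tau_s = %.4g (SE %.3g, n = %d)\n",
    x$turn_rate_star, x$tau_s_hat, x$stderr, x$n_trials))
  invisible(x)
}
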