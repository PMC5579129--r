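#' World configuration: periodic domain and fish-school parameters
#'
#' The resource landscape is a flat torus of side `L` holding a constant
#' number of circular fish schools. Each school has radius `F_s` and starts
#' with `F_n` fish; schools disappear and are replaced at random locations
#' as a Poisson process with expected lifespan `tau_l`, so the landscape is
#' stochastic while search difficulty (school count) stays constant.
#'
#' @param L Domain side length (length units).
#' @param n_schools Number of schools concurrently present (constant).
#' @param F_s School radius (length units); must satisfy `0 < F_s < L/2`.
#' @param F_n Initial fish per school (fish; continuous).
#' @param tau_l Expected school lifespan (time units); may be `Inf` for a
#'   frozen landscape.
#' @param dt Simulation timestep (time units); must satisfy
#'   `dt <= tau_l / 10` so turnover is resolved.
#' @return An object of class `world_config`.
#' @examples
#' world_config(L = 40, n_schools = 10, F_s = 1.5, F_n = 40, tau_l = 200, dt = 0.1)
#' @export
world_config <- function(L, n_schools, F_s, F_n, tau_l, dt) {
  check_number(L, "L", 0, strict = TRUE)
  if (!is.numeric(n_schools) || n_schools < 1 || n_schools != round(n_schools))
    abort_input("`n_schools` must be a positive integer")
  check_number(F_s, "F_s", 0, strict = TRUE)
  if (F_s >= L / 2) abort_input("`F_s` must be < L/2")
  check_number(F_n, "F_n", 0, strict = TRUE)
  check_number(tau_l, "tau_l", 0, strict = TRUE, finite = FALSE)
  check_number(dt, "dt", 0, strict = TRUE)
  if (is.finite(tau_l) && dt > tau_l / 10)
    abort_input("`dt` must be <= tau_l/10 to resolve school turnover")
  structure(
    list(L = as.numeric(L), n_schools = as.integer(n_schools),
         F_s = as.numeric(F_s), F_n = as.numeric(F_n),
         tau_l = as.numeric(tau_l), dt = as.numeric(dt)),
    class = "world_config"
  )
}

#' Total-stock state for depletion bookkeeping
#'
#' `P` is the total stock for the season and is distinct from the number of
#' fish present in the domain at any moment. With depletion enabled, each
#' replacement school spawns with `F_n * max(0, (P - cumulative_harvest)/P)`
#' fish, so renewal shuts down progressively as the fleet's cumulative
#' harvest approaches `P`.
#'
#' @param P Total stock (fish); `Inf` when depletion is disabled.
#' @param cumulative_harvest Fish removed by all agents so far.
#' @param depletion_enabled Logical flag.
#' @return An object of class `stock_state`.
#' @export
stock_state <- function(P = Inf, cumulative_harvest = 0, depletion_enabled = is.finite(P)) {
  check_number(P, "P", 0, strict = TRUE, finite = FALSE)
  check_number(cumulative_harvest, "cumulative_harvest", 0)
  if (depletion_enabled && !is.finite(P))
    abort_input("depletion requires a finite total stock `P`")
  structure(
    list(P = P, cumulative_harvest = cumulative_harvest,
         depletion_enabled = isTRUE(depletion_enabled)),
    class = "stock_state"
  )
}

#' Minimal-image distance on the periodic domain
#'
#' Euclidean distance between points on the flat torus `[0, L)^2`, taking
#' the shortest of the periodic images in each coordinate.
#'
#' @param a,b Positions: length-2 numeric vectors, or n x 2 matrices for
#'   vectorized use.
#' @param L Domain side length.
#' @return Numeric vector of distances, each `<= L * sqrt(2) / 2`.
#' @examples
#' torus_distance(c(0.5, 0), c(9.5, 0), L = 10)  # 1, across the boundary
#' @export
torus_distance <- function(a, b, L) {
  if (!all(is.finite(a)) || !all(is.finite(b)) || !all(is.finite(L)))
    abort_input("positions and `L` must be finite")
  d <- torus_delta(a, b, L)
  unname(sqrt(d[, 1]^2 + d[, 2]^2))
}

as_pos_matrix <- function(x) {
  m <- rbind(x)
  dimnames(m) <- NULL
  m
}

# minimal-image displacement from a to b, component-wise in (-L/2, L/2];
# a and b may be length-2 vectors or n x 2 matrices (1-row recycling)
torus_delta <- function(a, b, L) {
  a <- as_pos_matrix(a)
  b <- as_pos_matrix(b)
  if (nrow(a) != nrow(b)) {
    if (nrow(a) == 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
    else if (nrow(b) == 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
    else abort_input("position sets must have matching or single rows")
  }
  d <- (b - a) %% L
  d - L * (d > L / 2)
}

#' Spawn a replacement fish school
#'
#' Places a school uniformly at random on the domain. Its initial fish
#' content is `F_n` when depletion is disabled, and
#' `F_n * max(0, (P - cumulative_harvest) / P)` otherwise, so that renewal
#' weakens in proportion to how much of the total stock has been removed.
#'
#' @param cfg A [world_config()].
#' @param stock A [stock_state()].
#' @param id School identifier for the new school.
#' @param born_at Spawn time.
#' @return One-row tibble with columns `id, x, y, radius, fish, born_at`.
#' @export
spawn_school <- function(cfg, stock, id = 1L, born_at = 0) {
  stopifnot(inherits(cfg, "world_config"), inherits(stock, "stock_state"))
  tibble::tibble(
    id = as.integer(id),
    x = stats::runif(1, 0, cfg$L),
    y = stats::runif(1, 0, cfg$L),
    radius = cfg$F_s,
    fish = spawned_fish(cfg, stock),
    born_at = born_at
  )
}

spawned_fish <- function(cfg, stock) {
  if (!stock$depletion_enabled) return(cfg$F_n)
  cfg$F_n * max(0, (stock$P - stock$cumulative_harvest) / stock$P)
}

#' Initialize the school field
#'
#' @inheritParams spawn_school
#' @return Tibble of `n_schools` schools.
#' @export
init_schools <- function(cfg, stock = stock_state()) {
  dplyr::bind_rows(lapply(seq_len(cfg$n_schools), function(i)
    spawn_school(cfg, stock, id = i)))
}

#' One school-turnover step
#'
#' Each school independently dies with probability `1 - exp(-dt / tau_l)`
#' (the exact exponential marginal for a Poisson lifespan, irrespective of
#' `dt`); schools that have been fished empty are replaced as if their
#' lifespan had ended. Every death is immediately replaced via
#' [spawn_school()], keeping the school count constant.
#'
#' @param schools Tibble of schools as produced by [init_schools()].
#' @param cfg A [world_config()].
#' @param stock A [stock_state()].
#' @param now Current time, recorded as `born_at` for replacements.
#' @return Tibble of schools, same number of rows.
#' @export
turnover_step <- function(schools, cfg, stock, now = 0) {
  stopifnot(nrow(schools) == cfg$n_schools)
  p_death <- if (is.finite(cfg$tau_l)) 1 - exp(-cfg$dt / cfg$tau_l) else 0
  dies <- schools$fish <= 0 | stats::runif(nrow(schools)) < p_death
  next_id <- max(schools$id)
  for (k in which(dies)) {
    next_id <- next_id + 1L
    schools[k, ] <- spawn_school(cfg, stock, id = next_id, born_at = now)
  }
  schools
}

#' Remove fish from a school, capped by what remains
#'
#' The harvested amount is `min(amount, fish remaining)`; the school's fish
#' content and the stock's cumulative-harvest ledger are updated in step,
#' so total removals always balance the fleet's catch exactly.
#'
#' @param school One-row school tibble.
#' @param amount Requested removal (fish, `>= 0`).
#' @param stock A [stock_state()].
#' @return List with elements `school` (updated), `removed` (fish actually
#'   taken) and `stock` (updated ledger).
#' @export
deplete_school <- function(school, amount, stock) {
  if (!is.numeric(amount) || length(amount) != 1L || is.na(amount) || amount < 0)
    abort_input("`amount` must be a single non-negative number")
  removed <- min(amount, school$fish)
  school$fish <- school$fish - removed
  stock$cumulative_harvest <- stock$cumulative_harvest + removed
  list(school = school, removed = removed, stock = stock)
}
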