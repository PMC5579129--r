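#' Windowed catch-rate series H_i(t)
#'
#' Splits the season into tumbling windows and computes, for every agent
#' and window, the catch rate `H[i, w]` = (catch of agent i in window w) /
#' (time agent i was active in window w). Windows in which the agent was
#' inactive throughout (after IFQ retirement) are marked missing. The
#' active-time denominator makes the rate a catch per unit of effort,
#' with effort proportional to time spent fishing.
#'
#' @param result A [run_season()] result.
#' @param window Averaging-window length (time units); default is
#'   `duration / 50`. Must be `>= dt` and `<= duration`.
#' @return Tibble with columns `agent, window, t_start, t_end, catch,
#'   active_time, H`.
#' @export
catch_rate_series <- function(result, window = result$duration / 50) {
  dt <- result$config$world$dt
  if (!is.numeric(window) || length(window) != 1L || window < dt)
    abort_input("`window` must be a single number >= dt")
  if (window > result$duration + 1e-9)
    abort_input("`window` must not exceed the season duration")
  n_steps <- result$n_steps
  times <- (seq_len(n_steps) - 0.5) * dt
  w <- pmin(floor(times / window), ceiling(result$duration / window) - 1) + 1L
  n <- result$config$n_agents
  long <- tibble::tibble(
    agent = rep(seq_len(n), each = n_steps),
    window = rep(w, times = n),
    catch = as.vector(result$catch),
    active = as.vector(result$active)
  )
  out <- long |>
    dplyr::group_by(.data$agent, .data$window) |>
    dplyr::summarise(catch = sum(.data$catch),
                     active_time = sum(.data$active) * dt,
                     .groups = "drop") |>
    dplyr::mutate(t_start = (.data$window - 1) * window,
                  t_end = pmin(.data$window * window, result$duration),
                  H = ifelse(.data$active_time > 0,
                             .data$catch / .data$active_time, NA_real_))
  out[, c("agent", "window", "t_start", "t_end", "catch", "active_time", "H")]
}

#' Catch per unit of effort
#'
#' `CPUE_i = catch_total_i / active_time_i`, where active time is the time
#' the agent spent in the fishery (the whole season under a TAC; until
#' retirement under IFQ). Effort is proportional to time spent fishing,
#' searching included.
#'
#' @param result A [run_season()] result.
#' @return Tibble with columns `agent, catch_total, active_time, cpue`,
#'   plus the fleet mean as attribute `fleet_mean` (agents with zero
#'   active time are flagged `NA` and excluded from the mean with a
#'   warning).
#' @export
cpue <- function(result) {
  if (result$duration <= 0) abort_input("season duration must be > 0")
  dt <- result$config$world$dt
  active_time <- colSums(result$active) * dt
  out <- tibble::tibble(
    agent = seq_len(result$config$n_agents),
    catch_total = result$catch_total,
    active_time = active_time,
    cpue = ifelse(active_time > 0, result$catch_total / active_time, NA_real_)
  )
  if (anyNA(out$cpue))
    warning("agent(s) with zero active time: CPUE undefined, excluded from fleet mean",
            call. = FALSE)
  attr(out, "fleet_mean") <- mean(out$cpue, na.rm = TRUE)
  out
}

# per-(lam, replicate) window statistics behind the three objectives;
# aggregation order: windows within a season, then agents, then replicates
h_window_stats <- function(series) {
  need <- c("lam", "replicate", "agent", "window", "H")
  if (!all(need %in% names(series)))
    abort_input(paste("`series` needs columns:", paste(need, collapse = ", ")))
  by_agent <- series |>
    dplyr::group_by(.data$lam, .data$replicate, .data$agent) |>
    dplyr::summarise(H_bar = mean(.data$H, na.rm = TRUE), .groups = "drop")
  between <- by_agent |>
    dplyr::group_by(.data$lam, .data$replicate) |>
    dplyr::summarise(mean_H = mean(.data$H_bar),
                     sd_between = stats::sd(.data$H_bar), .groups = "drop")
  over_time <- series |>
    dplyr::group_by(.data$lam, .data$replicate, .data$window) |>
    dplyr::summarise(H_t = mean(.data$H, na.rm = TRUE), .groups = "drop") |>
    dplyr::group_by(.data$lam, .data$replicate) |>
    dplyr::summarise(sd_over_time = stats::sd(.data$H_t, na.rm = TRUE),
                     .groups = "drop")
  dplyr::left_join(between, over_time, by = c("lam", "replicate"))
}

# replicate-averaged stats -> normalized objective curves (max exactly 1);
# degenerate zero std regularized by eps = 1e-9 * fleet mean catch rate
objective_curves_from_stats <- function(stats_df) {
  agg <- stats_df |>
    dplyr::group_by(.data$lam) |>
    dplyr::summarise(mean_H = mean(.data$mean_H),
                     sd_between = mean(.data$sd_between),
                     sd_over_time = mean(.data$sd_over_time),
                     .groups = "drop")
  eps <- 1e-9 * mean(agg$mean_H)
  tibble::tibble(
    lam = agg$lam,
    o_cpue = agg$mean_H / max(agg$mean_H),
    o_equity = min(agg$sd_between + eps) / (agg$sd_between + eps),
    o_stability = min(agg$sd_over_time + eps) / (agg$sd_over_time + eps)
  )
}

#' Normalized fleet catch-rate objective O_CPUE
#'
#' The catch rate averaged over windows, agents and replicates for each
#' sharing level, normalized by its maximum over the lambda grid, so the
#' best sharing level scores exactly 1.
#'
#' @param series Window-level tibble with columns
#'   `lam, replicate, agent, window, H` (stack of [catch_rate_series()]
#'   outputs over replicates and sharing levels).
#' @return Tibble `lam, value` with `max(value) == 1`.
#' @export
objective_cpue <- function(series) {
  if (length(unique(series$lam)) < 1) abort_input("empty series")
  cur <- objective_curves_from_stats(h_window_stats(series))
  tibble::tibble(lam = cur$lam, value = cur$o_cpue)
}

#' Normalized equity objective O_equity
#'
#' The between-agent standard deviation of time-averaged catch rates,
#' inverted and normalized so the variance-minimizing sharing level scores
#' exactly 1. Scale-invariant: multiplying all catch rates by a constant
#' leaves it unchanged.
#'
#' @inheritParams objective_cpue
#' @return Tibble `lam, value` with `max(value) == 1`.
#' @export
objective_equity <- function(series) {
  if (length(unique(series$agent)) < 2) abort_input("O_equity needs >= 2 agents")
  cur <- objective_curves_from_stats(h_window_stats(series))
  tibble::tibble(lam = cur$lam, value = cur$o_equity)
}

#' Normalized stability objective O_stability
#'
#' The standard deviation over time of the agent-averaged catch rate
#' (the steadiness of the fleet's landed flux), inverted and normalized so
#' the most stable sharing level scores exactly 1.
#'
#' @inheritParams objective_cpue
#' @return Tibble `lam, value` with `max(value) == 1`.
#' @export
objective_stability <- function(series) {
  if (length(unique(series$window)) < 2) abort_input("O_stability needs >= 2 windows")
  cur <- objective_curves_from_stats(h_window_stats(series))
  tibble::tibble(lam = cur$lam, value = cur$o_stability)
}

#' Successful and unsuccessful agent groups by CPUE percentile
#'
#' Per replicate, agents are ranked by CPUE and the top and bottom
#' `ceiling(q * N)` agents form the successful/unsuccessful groups.
#' Membership is per replicate: the identity of successful agents changes
#' from season to season, since success reflects luck in encountering
#' schools, not skill. Ties are broken by agent id.
#'
#' @param cpue_df Tibble with columns `replicate, agent, cpue` (any other
#'   grouping columns are preserved).
#' @param q Group fraction, `0 < q < 0.5`; `ceiling(q * N)` must be at
#'   least 1 agent, i.e. `N * q >= 1` is not required but `q * N < 1`
#'   with `N` agents still yields one agent per group only when
#'   `ceiling(q*N) >= 1`; `q*N < 1` raises an error.
#' @return `cpue_df` rows for group members with an extra `group` column
#'   (`"bottom"` / `"top"`).
#' @export
percentile_groups <- function(cpue_df, q = 0.1) {
  if (!is.numeric(q) || q <= 0 || q >= 0.5)
    abort_input("`q` must be in (0, 0.5)")
  grp_one <- function(df) {
    n <- nrow(df)
    if (n * q < 1) abort_input("`q * N` must be >= 1 agent per group")
    k <- ceiling(q * n)
    bot <- df[order(df$cpue, df$agent), ][seq_len(k), ]
    top <- df[order(-df$cpue, df$agent), ][seq_len(k), ]
    bot$group <- "bottom"
    top$group <- "top"
    dplyr::bind_rows(bot, top)
  }
  extra <- setdiff(names(cpue_df), c("agent", "cpue"))
  cpue_df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(extra))) |>
    dplyr::group_modify(~ grp_one(.x)) |>
    dplyr::ungroup()
}

#' Sharing level maximizing a CPUE curve on the lambda grid
#'
#' Arg-max over the grid; ties broken toward the smaller sharing level.
#'
#' @param curve Tibble with columns `lam` and `value` (group or fleet CPUE
#'   per sharing level, typically replicate-averaged).
#' @return The optimal `lam` (scalar).
#' @export
optimal_lambda <- function(curve) {
  stopifnot(all(c("lam", "value") %in% names(curve)))
  curve <- curve[order(curve$lam), ]
  curve$lam[which.max(curve$value)]
}

#' Divergence index between group sharing optima
#'
#' `1 - lam_plus / lam_minus`, where `lam_plus` is the CPUE-optimal
#' sharing level for successful agents and `lam_minus` for unsuccessful
#' ones. Near 0 means all agents optimize CPUE at a similar sharing level;
#' near 1 means strongly diverging incentives. When `lam_minus = 0`
#' the index is 0 if `lam_plus = 0` (no-sharing consensus) and otherwise
#' flagged undefined (`NA` with a warning) -- a configuration that cannot
#' arise when sharing favors unsuccessful agents at least as much as
#' successful ones.
#'
#' @param lam_plus,lam_minus Group-optimal sharing levels (vectorized).
#' @return Numeric vector.
#' @export
divergence_index <- function(lam_plus, lam_minus) {
  out <- 1 - lam_plus / lam_minus
  zero <- lam_minus == 0
  out[zero & lam_plus == 0] <- 0
  bad <- zero & lam_plus > 0
  if (any(bad, na.rm = TRUE)) {
    out[bad] <- NA_real_
    warning("lam_minus = 0 with lam_plus > 0: divergence undefined (data-quality flag)",
            call. = FALSE)
  }
  out
}

#' Relative CPUE advantage of IFQ over TAC management
#'
#' `H_IFQ / H_TAC - 1`: positive values mean better catch rates under
#' individual quotas, negative values better rates under a fleet-wide
#' total allowable catch.
#'
#' @param h_ifq,h_tac Group or fleet CPUE under the two regimes
#'   (vectorized).
#' @return Numeric vector (`NA` with a warning where `h_tac = 0`).
#' @export
ifq_tac_ratio <- function(h_ifq, h_tac) {
  out <- h_ifq / h_tac - 1
  if (any(h_tac == 0, na.rm = TRUE)) {
    out[h_tac == 0] <- NA_real_
    warning("h_tac = 0: ratio undefined", call. = FALSE)
  }
  out
}
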