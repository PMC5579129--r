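#' Build a named or custom scenario
#'
#' A scenario freezes one parameterization of the world and fleet so that
#' results cite an exact, content-hashed configuration. Two exemplar
#' scenarios ship with the package, contrasting two corners of parameter
#' space for West-Coast-like target species:
#'
#' * `"whiting"` -- a mobile midwater species: large schools (larger
#'   `F_s`), many fish per school (larger `F_n`), short school lifespan
#'   (smaller `tau_l`).
#' * `"groundfish"` -- a sedentary demersal species: smaller schools,
#'   fewer fish per school, longer lifespan.
#'
#' All other parameters are equal between the two. The absolute values are
#' package calibration constants documented in the scenario files (they
#' set search times and season lengths at a workable simulation scale, not
#' the ecology of real stocks).
#'
#' @param name `"whiting"`, `"groundfish"`, or `NULL` when `spec` is
#'   given.
#' @param spec A named list with fields `name, world, agents, n_agents,
#'   T, t_max` (and optional `notes`) for a custom scenario; `world` and
#'   `agents` are passed to [world_config()] / [agent_params()].
#' @return An object of class `scenario` with a `hash` field.
#' @examples
#' sc <- build_scenario("groundfish")
#' sc$world$F_s < build_scenario("whiting")$world$F_s
#' @export
build_scenario <- function(name = NULL, spec = NULL) {
  if (is.null(spec)) {
    if (is.null(name))
      abort_input("give a scenario `name` or a custom `spec`")
    file <- system.file("extdata", "scenarios", paste0(name, ".json"),
                        package = "fleetsim")
    if (file == "")
      abort_input(sprintf("unknown scenario '%s'; available: %s", name,
                          paste(list_scenarios(), collapse = ", ")))
    spec <- jsonlite::read_json(file, simplifyVector = TRUE)
  }
  need <- c("name", "world", "agents", "n_agents", "T", "t_max")
  if (!all(need %in% names(spec)))
    abort_input(paste("scenario spec needs fields:", paste(need, collapse = ", ")))
  sc <- list(
    name = spec$name,
    world = do.call(world_config, as.list(spec$world)),
    agents = do.call(agent_params, as.list(spec$agents)),
    n_agents = as.integer(spec$n_agents),
    T = spec$T,
    t_max = spec$t_max,
    notes = spec$notes %||% "",
    provenance = spec$provenance %||% ""
  )
  sc$hash <- config_hash(sc[c("name", "world", "agents", "n_agents", "T", "t_max")])
  structure(sc, class = "scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' List the scenarios shipped with the package
#' @return Character vector of scenario names.
#' @export
list_scenarios <- function() {
  files <- list.files(system.file("extdata", "scenarios", package = "fleetsim"),
                      pattern = "\\.json$")
  sub("\\.json$", "", files)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s [%s]\n", x$name, x$hash))
  w <- x$world
  cat(sprintf("  world: L=%g n_schools=%d F_s=%g F_n=%g tau_l=%g dt=%g\n",
              w$L, w$n_schools, w$F_s, w$F_n, w$tau_l, w$dt))
  a <- x$agents
  cat(sprintf("  agents: n=%d v=%g r_sense=%g C_q=%g turn_rate=%g\n",
              x$n_agents, a$v, a$r_sense, a$C_q, a$turn_rate))
  cat(sprintf("  season: T=%g t_max=%g\n", x$T, x$t_max))
  if (nzchar(x$notes)) cat(" ", x$notes, "\n")
  invisible(x)
}

#' Instantiate a season configuration from a scenario
#'
#' @param scenario A [build_scenario()] object.
#' @param lam Sharing level in `[0, 1]`.
#' @param management `"TAC"` or `"IFQ"`.
#' @param depletion Allowed depletion fraction `T / P`; 0 disables
#'   depletion, 0.9 is the high-depletion setting.
#' @param tau_l Optional override of the school lifespan (the species
#'   mobility axis; mobility is `1 / tau_l`).
#' @return A [season_config()].
#' @export
scenario_season_config <- function(scenario, lam, management = "TAC",
                                   depletion = 0, tau_l = NULL) {
  if (!is.numeric(depletion) || depletion < 0 || depletion >= 1)
    abort_input("`depletion` (T/P) must be in [0, 1)")
  world <- scenario$world
  if (!is.null(tau_l))
    world <- world_config(world$L, world$n_schools, world$F_s, world$F_n,
                          tau_l, world$dt)
  season_config(
    world = world,
    agents = scenario$agents,
    n_agents = scenario$n_agents,
    lam = lam,
    policy = management_policy(management, T = scenario$T,
                               n_agents = scenario$n_agents,
                               t_max = scenario$t_max),
    P = if (depletion > 0) scenario$T / depletion else Inf
  )
}

#' Define a sweep grid over the experimental axes
#'
#' The default grid reproduces the experimental design of the study
#' conditions: sharing levels 0 to 1 in 11 steps, the scenario's own
#' mobility (override `tau_l` with a log-spaced vector for mobility
#' sweeps), depletion fractions including 0 (disabled) and 0.9 (high
#' depletion), both management regimes, 30 replicate seasons per cell.
#'
#' @param lam Sharing levels.
#' @param tau_l School-lifespan values (`NULL` = scenario default).
#' @param depletion Depletion fractions `T / P` in `[0, 1)`.
#' @param management Subset of `c("TAC", "IFQ")`.
#' @param replicates Seasons per cell (`>= 1`).
#' @param master_seed Master seed; every per-season seed derives from it
#'   deterministically.
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(lam = seq(0, 1, by = 0.1), tau_l = NULL,
                       depletion = 0, management = c("TAC", "IFQ"),
                       replicates = 30, master_seed = 1) {
  management <- match.arg(management, c("TAC", "IFQ"), several.ok = TRUE)
  if (length(lam) == 0 || length(depletion) == 0 || replicates < 1)
    abort_input("grids must be non-empty and replicates >= 1")
  structure(
    list(lam = sort(unique(lam)), tau_l = tau_l,
         depletion = sort(unique(depletion)), management = management,
         replicates = as.integer(replicates),
         master_seed = as.integer(master_seed)),
    class = "sweep_grid"
  )
}

# deterministic per-cell seed stream: a function of master seed and cell
# content only, so identical cells get identical seeds across sweeps
cell_seeds <- function(grid, scenario_hash, management, tau_l, depletion, lam) {
  key <- config_hash(list(scenario_hash, management, tau_l, depletion, lam))
  base <- (strtoi(key, 16L) + grid$master_seed) %% 2147483646L + 1L
  derive_seeds(base, grid$replicates)
}

summarize_season <- function(res, window_n = 50) {
  cp <- suppressWarnings(cpue(res))
  series <- catch_rate_series(res, window = res$duration / window_n)
  by_agent <- series |>
    dplyr::group_by(.data$agent) |>
    dplyr::summarise(H_bar = mean(.data$H, na.rm = TRUE), .groups = "drop")
  by_window <- series |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(H_t = mean(.data$H, na.rm = TRUE), .groups = "drop")
  tibble::tibble(
    duration = res$duration,
    n_steps = res$n_steps,
    total_catch = res$cumulative_harvest,
    terminated_by = res$terminated_by,
    n_retired = sum(!is.na(res$retire_time)),
    mean_H = mean(by_agent$H_bar),
    sd_between = stats::sd(by_agent$H_bar),
    sd_over_time = stats::sd(by_window$H_t, na.rm = TRUE),
    cpue = list(cp$cpue)
  )
}

#' Run a full sweep over the experimental grid
#'
#' Executes [run_replicates()] for every grid cell (management x mobility
#' x depletion x sharing level) and returns one summary record per
#' completed season, in long format. The whole table is a pure function of
#' the scenario hash, the grid and the master seed. A previous (partial)
#' table can be passed as `prior`: completed seasons are matched by
#' configuration hash and seed and carried over instead of re-run, and
#' extending `replicates` appends new records without changing existing
#' ones. Per-season failures are logged and the sweep continues.
#'
#' @param grid A [sweep_grid()].
#' @param scenario A [build_scenario()] object.
#' @param window_n Windows per season for the catch-rate series behind the
#'   objective statistics.
#' @param prior Optional earlier `sweep_table` for resumption.
#' @param quiet Suppress per-cell progress messages.
#' @return A tibble of class `sweep_table`; one row per season with cell
#'   coordinates, seed, configuration hash, season summary statistics and
#'   a list-column `cpue` of per-agent CPUE vectors.
#' @export
run_sweep <- function(grid, scenario, window_n = 50, prior = NULL,
                      quiet = TRUE) {
  stopifnot(inherits(grid, "sweep_grid"), inherits(scenario, "scenario"))
  tau_vals <- grid$tau_l %||% scenario$world$tau_l
  cells <- tidyr::expand_grid(
    management = grid$management, tau_l = tau_vals,
    depletion = grid$depletion, lam = grid$lam
  )
  rows <- vector("list", nrow(cells) * grid$replicates)
  k <- 0L
  n_capped <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    cfg <- scenario_season_config(scenario, lam = cell$lam,
                                  management = cell$management,
                                  depletion = cell$depletion,
                                  tau_l = cell$tau_l)
    chash <- config_hash(cfg)
    seeds <- cell_seeds(grid, scenario$hash, cell$management, cell$tau_l,
                        cell$depletion, cell$lam)
    for (r in seq_len(grid$replicates)) {
      k <- k + 1L
      if (!is.null(prior)) {
        hit <- prior[prior$config_hash == chash & prior$seed == seeds[r], ]
        if (nrow(hit) == 1) {
          rows[[k]] <- hit
          next
        }
      }
      rows[[k]] <- tryCatch({
        res <- withCallingHandlers(
          run_season(cfg, seeds[r]),
          warning = function(w) {
            if (grepl("t_max", conditionMessage(w))) {
              n_capped <<- n_capped + 1L
              invokeRestart("muffleWarning")
            }
          })
        dplyr::bind_cols(
          tibble::tibble(scenario = scenario$name,
                         management = cell$management, tau_l = cell$tau_l,
                         depletion = cell$depletion, lam = cell$lam,
                         replicate = r, seed = seeds[r], config_hash = chash),
          summarize_season(res, window_n = window_n))
      }, error = function(e) {
        message(sprintf("cell (%s, tau_l=%g, depl=%g, lam=%g) seed %d failed: %s",
                        cell$management, cell$tau_l, cell$depletion, cell$lam,
                        seeds[r], conditionMessage(e)))
        NULL
      })
    }
    if (!quiet)
      message(sprintf("cell %d/%d done", ci, nrow(cells)))
  }
  out <- dplyr::bind_rows(rows)
  if (n_capped > 0)
    message(sprintf("%d season(s) terminated at the t_max cap", n_capped))
  attr(out, "scenario_hash") <- scenario$hash
  attr(out, "grid") <- grid
  class(out) <- c("sweep_table", class(out))
  out
}

unnest_cpue <- function(table) {
  table |>
    dplyr::mutate(agent = list(seq_along(.data$cpue[[1]]))) |>
    tidyr::unnest(c("agent", "cpue"))
}

check_axis <- function(table, product, cols, min_lengths) {
  for (i in seq_along(cols)) {
    if (length(unique(table[[cols[i]]])) < min_lengths[i])
      abort_input(sprintf(
        "product '%s' needs the '%s' grid dimension (>= %d values present)",
        product, cols[i], min_lengths[i]))
  }
}

#' Figure-level analyses of a sweep table
#'
#' Computes, from a long sweep table:
#'
#' * `fleet_cpue` -- fleet-mean CPUE vs sharing level with the 80%
#'   inter-agent interval (10th/90th percentile of agent-season CPUE);
#' * `group_cpue` -- replicate-averaged CPUE curves for the successful
#'   (top `q`) and unsuccessful (bottom `q`) groups, membership ranked per
#'   replicate;
#' * `group_optima` -- per (management, mobility, depletion): the
#'   group-optimal sharing levels `lam_plus`/`lam_minus` and the
#'   divergence index `1 - lam_plus/lam_minus`;
#' * `ifq_tac` -- per (mobility, depletion, group): `H_IFQ/H_TAC - 1`
#'   comparing each group's optimal CPUE across management regimes
#'   (needs both regimes in the table);
#' * `objectives` -- normalized O_CPUE / O_equity / O_stability curves
#'   over the sharing grid per (management, mobility, depletion).
#'
#' @param table A [run_sweep()] result.
#' @param q Percentile-group fraction (default 0.1: top/bottom 10%).
#' @param products Character subset of
#'   `c("fleet_cpue","group_cpue","group_optima","ifq_tac","objectives")`;
#'   `NULL` computes every product whose grid axes are present and skips
#'   the rest with a message, while an explicitly requested product with
#'   a missing axis is an error naming the dimension.
#' @return A named list of tibbles, class `sweep_analysis`.
#' @export
analyze_sweep <- function(table, q = 0.1, products = NULL) {
  all_products <- c("fleet_cpue", "group_cpue", "group_optima", "ifq_tac",
                    "objectives")
  explicit <- !is.null(products)
  products <- products %||% all_products
  products <- match.arg(products, all_products, several.ok = TRUE)
  out <- list()
  key <- c("scenario", "management", "tau_l", "depletion")

  ag <- unnest_cpue(table)
  if ("fleet_cpue" %in% products) {
    out$fleet_cpue <- ag |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(key, "lam")))) |>
      dplyr::summarise(
        cpue_mean = mean(.data$cpue, na.rm = TRUE),
        cpue_lo = stats::quantile(.data$cpue, 0.10, na.rm = TRUE, names = FALSE),
        cpue_hi = stats::quantile(.data$cpue, 0.90, na.rm = TRUE, names = FALSE),
        .groups = "drop")
  }

  need_groups <- any(c("group_cpue", "group_optima", "ifq_tac") %in% products)
  if (need_groups) {
    groups <- percentile_groups(
      ag[, c(key, "lam", "replicate", "agent", "cpue")], q = q)
    out$group_cpue <- groups |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(key, "lam", "group", "replicate")))) |>
      dplyr::summarise(cpue = mean(.data$cpue, na.rm = TRUE), .groups = "drop") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(key, "lam", "group")))) |>
      dplyr::summarise(cpue = mean(.data$cpue, na.rm = TRUE), .groups = "drop")
  }

  if (any(c("group_optima", "ifq_tac") %in% products)) {
    optima <- out$group_cpue |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(key, "group")))) |>
      dplyr::group_modify(~ tibble::tibble(
        lam_opt = optimal_lambda(dplyr::rename(.x, value = "cpue")),
        cpue_opt = max(.x$cpue))) |>
      dplyr::ungroup()
    if ("group_optima" %in% products) {
      out$group_optima <- optima |>
        dplyr::select(-"cpue_opt") |>
        tidyr::pivot_wider(names_from = "group", values_from = "lam_opt") |>
        dplyr::rename(lam_plus = "top", lam_minus = "bottom") |>
        dplyr::mutate(divergence = divergence_index(.data$lam_plus, .data$lam_minus))
    }
    if ("ifq_tac" %in% products) {
      if (length(unique(table$management)) < 2) {
        msg <- "product 'ifq_tac' needs the 'management' grid dimension (both TAC and IFQ)"
        if (explicit && "ifq_tac" %in% products) abort_input(msg) else message(msg)
      } else {
        out$ifq_tac <- optima |>
          dplyr::select(-"lam_opt") |>
          tidyr::pivot_wider(names_from = "management", values_from = "cpue_opt") |>
          dplyr::mutate(ratio = ifq_tac_ratio(.data$IFQ, .data$TAC))
      }
    }
  }

  if ("objectives" %in% products) {
    if (length(unique(table$lam)) < 2 && explicit)
      abort_input("product 'objectives' needs the 'lam' grid dimension (>= 2 values)")
    out$objectives <- table |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
      dplyr::group_modify(~ objective_curves_from_stats(.x)) |>
      dplyr::ungroup()
  }

  structure(c(out, list(q = q)), class = "sweep_analysis")
}

#' @export
print.sweep_analysis <- function(x, ...) {
  cat("<sweep_analysis> products:",
      paste(setdiff(names(x), "q"), collapse = ", "), "\n")
  invisible(x)
}
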