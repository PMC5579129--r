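#' Reciprocal information-sharing network
#'
#' The fleet shares school locations over a complete graph with a uniform
#' tie weight `lambda`: each timestep, every (harvester, searcher) pair
#' independently transmits the harvester's school location with
#' probability `lambda`. Ties are reciprocal, so roles swap symmetrically
#' as agents alternate between searching and harvesting. `lambda` is a
#' fixed, fleet-wide (consensus) parameter, never a per-agent strategic
#' choice.
#'
#' @param n_agents Number of agents.
#' @param lam Tie weight in `[0, 1]`.
#' @return An object of class `sharing_network`.
#' @export
sharing_network <- function(n_agents, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0 || lam > 1)
    abort_input("`lam` must be a single number in [0, 1]")
  if (n_agents < 1) abort_input("`n_agents` must be >= 1")
  structure(list(n_agents = as.integer(n_agents), lam = lam,
                 topology = "complete"),
            class = "sharing_network")
}

#' Emit school-location messages from harvesters to searchers
#'
#' For each (harvester, searcher) pair a message carrying the harvester's
#' school location is delivered independently with probability `lambda`.
#' Sharing opportunity is re-sampled each timestep while the sender keeps
#' harvesting (a lambda-weighted continuous broadcast), so the tie weight
#' controls the intensity of information flow rather than a one-shot
#' disclosure at discovery. Retired agents neither send nor receive.
#'
#' @param harvesters Agent tibble, all in `harvesting` mode, with `tx, ty`
#'   holding their school location and `target` the school id.
#' @param searchers Agent tibble of receivers (searching or traveling).
#' @param net A [sharing_network()].
#' @return Tibble of messages: `from_agent, to_agent, school_id, x, y`.
#' @export
emit_information <- function(harvesters, searchers, net) {
  stopifnot(all(harvesters$mode == "harvesting"))
  harvesters <- harvesters[harvesters$mode != "retired", ]
  searchers <- searchers[searchers$mode %in% c("searching", "traveling_to_info"), ]
  if (nrow(harvesters) == 0 || nrow(searchers) == 0 || net$lam == 0)
    return(empty_messages())
  pairs <- tidyr::expand_grid(h = seq_len(nrow(harvesters)),
                              s = seq_len(nrow(searchers)))
  pairs <- pairs[harvesters$id[pairs$h] != searchers$id[pairs$s], ]
  sent <- net$lam == 1 | stats::runif(nrow(pairs)) < net$lam
  pairs <- pairs[sent, ]
  tibble::tibble(
    from_agent = harvesters$id[pairs$h],
    to_agent = searchers$id[pairs$s],
    school_id = harvesters$target[pairs$h],
    x = harvesters$tx[pairs$h],
    y = harvesters$ty[pairs$h]
  )
}

empty_messages <- function() {
  tibble::tibble(from_agent = integer(), to_agent = integer(),
                 school_id = integer(), x = numeric(), y = numeric())
}

#' Resolve an agent's inbox against its own senses
#'
#' Local sensing has priority: if a school lies within the agent's own
#' sensory zone the inbox is ignored. Otherwise the agent targets the
#' nearest message location (minimal-image; ties broken by lower sender
#' id) and enters `traveling_to_info`. A traveling agent whose targeted
#' school has vanished or been emptied drops the target and resumes
#' searching. Messages are ephemeral: only the chosen target location is
#' retained.
#'
#' @param agent One-row agent tibble (searching or traveling).
#' @param inbox Message tibble from [emit_information()] addressed to this
#'   agent.
#' @param schools School tibble (current landscape).
#' @param params An [agent_params()].
#' @param L Domain side length.
#' @return Updated one-row agent tibble.
#' @export
resolve_information <- function(agent, inbox, schools, params, L) {
  stopifnot(agent$mode %in% c("searching", "traveling_to_info"))
  sensed <- sense_schools(agent, schools, params$r_sense, L)
  if (!is.null(sensed)) {
    # harvest-approach to the locally sensed school wins over any message
    agent$target <- sensed$id
    agent$tx <- sensed$x
    agent$ty <- sensed$y
    agent$info_source <- NA_integer_
    return(agent)
  }
  inbox <- inbox[inbox$to_agent == agent$id, , drop = FALSE]
  if (nrow(inbox) > 0) {
    d <- torus_distance(c(agent$x, agent$y), cbind(inbox$x, inbox$y), L)
    best <- order(d, inbox$from_agent)[1]
    agent$mode <- "traveling_to_info"
    agent$target <- inbox$school_id[best]
    agent$tx <- inbox$x[best]
    agent$ty <- inbox$y[best]
    agent$info_source <- inbox$from_agent[best]
    return(agent)
  }
  if (agent$mode == "traveling_to_info") {
    tgt <- schools[match(agent$target, schools$id), , drop = FALSE]
    if (nrow(tgt) == 0 || is.na(tgt$id[1]) || tgt$fish[1] <= 0) {
      agent$mode <- "searching"
      agent$target <- NA_integer_
      agent$tx <- NA_real_
      agent$ty <- NA_real_
      agent$info_source <- NA_integer_
    }
  }
  agent
}
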