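# Three-round iterative bait-prey screen over a prediction provider.
#
# Round 1: bait vs every candidate; passers become Group 1.
# Round 2: Group 1 vs the Round-1 failures (bridging interactions) plus all
#   unordered intra-Group-1 pairs (edges only, no new nodes).
# Round 3: remaining candidates vs the consolidated core
#   (bait + Group 1 + Group 2); passers become Group 3.
#
# Pairs are evaluated once (cached by unordered key), candidates are
# processed in lexicographic order, and a missing prediction counts as
# non-passing (logged; an error under strict = TRUE), so runs are fully
# deterministic for a deterministic provider.

new_screen_state <- function(provider, config, strict) {
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$skipped <- character()
  env$n_evaluated <- 0L
  env$provider <- provider
  env$config <- config
  env$strict <- strict
  env
}

# Returns the one-row score tibble for a pair, or NULL for a skipped pair.
screen_score <- function(state, a, b) {
  key <- pair_key(a, b)
  if (!is.null(state$cache[[key]])) {
    cached <- state$cache[[key]]
    return(if (identical(cached, "skipped")) NULL else cached)
  }
  preds <- tryCatch(state$provider(a, b), error = function(e) {
    if (state$strict) {
      abort(sprintf("Prediction provider failed for pair %s: %s", key,
                    conditionMessage(e)), class = "lisnet_provider_error")
    }
    NULL
  })
  if (is.null(preds) || length(preds) == 0L) {
    if (state$strict) {
      abort(sprintf("No predictions for pair %s (strict mode).", key),
            class = "lisnet_missing_prediction")
    }
    warn(sprintf("No predictions for pair %s: treated as non-passing.", key),
         class = "lisnet_missing_prediction_warning")
    state$skipped <- c(state$skipped, key)
    state$cache[[key]] <- "skipped"
    return(NULL)
  }
  s <- score_pair(preds, state$config, protein_a = min(a, b),
                  protein_b = max(a, b))
  state$n_evaluated <- state$n_evaluated + 1L
  state$cache[[key]] <- s
  s
}

empty_edges <- function() {
  tibble(from = character(), to = character(), lis = numeric(),
         lia = numeric(), round = integer())
}

edge_row <- function(u, v, s, round) {
  tibble(from = min(u, v), to = max(u, v), lis = s$lis, lia = s$lia,
         round = as.integer(round))
}

#' Round 1: model the bait against every candidate
#'
#' Each candidate is scored against the bait; passers become Group 1 with
#' an edge to the bait, and the rest (including candidates with absent
#' predictions) form the failed set carried into Round 2.
#'
#' @param bait Bait id.
#' @param candidates Character vector of candidate prey ids.
#' @param provider Prediction provider: `function(a, b)` returning a list
#'   of [pae_prediction()] (empty/`NULL` for absent pairs).
#' @param config A [score_config()].
#' @param strict Error on absent predictions instead of logging.
#' @return List with `group1`, `edges`, `failed` (and the internal state
#'   when composed by [run_screen()]).
#' @export
screen_round1 <- function(bait, candidates, provider,
                          config = score_config(), strict = FALSE) {
  state <- new_screen_state(provider, config, strict)
  res <- run_round1(state, bait, sort(unique(as.character(candidates))))
  res$state <- NULL
  res
}

run_round1 <- function(state, bait, candidates) {
  group1 <- character(); edges <- empty_edges(); failed <- character()
  for (cand in candidates) {
    s <- screen_score(state, bait, cand)
    if (!is.null(s) && s$passed) {
      group1 <- c(group1, cand)
      edges <- dplyr::bind_rows(edges, edge_row(bait, cand, s, 1L))
    } else {
      failed <- c(failed, cand)
    }
  }
  list(group1 = group1, edges = edges, failed = failed, state = state)
}

run_round2 <- function(state, group1, failed) {
  group2 <- character(); edges <- empty_edges()
  for (f in failed) {
    for (g in group1) {
      s <- screen_score(state, g, f)
      if (!is.null(s) && s$passed) {
        if (!f %in% group2) group2 <- c(group2, f)
        edges <- dplyr::bind_rows(edges, edge_row(g, f, s, 2L))
      }
    }
  }
  if (length(group1) >= 2L) {
    for (i in seq_len(length(group1) - 1L)) {
      for (j in (i + 1L):length(group1)) {
        s <- screen_score(state, group1[i], group1[j])
        if (!is.null(s) && s$passed) {
          edges <- dplyr::bind_rows(edges, edge_row(group1[i], group1[j], s, 2L))
        }
      }
    }
  }
  list(group2 = sort(group2), edges = edges)
}

run_round3 <- function(state, remaining, core) {
  group3 <- character(); edges <- empty_edges()
  for (r in remaining) {
    for (cr in core) {
      s <- screen_score(state, r, cr)
      if (!is.null(s) && s$passed) {
        if (!r %in% group3) group3 <- c(group3, r)
        edges <- dplyr::bind_rows(edges, edge_row(r, cr, s, 3L))
      }
    }
  }
  list(group3 = sort(group3), edges = edges)
}

#' Run the three-round iterative PPI screen
#'
#' Composes the three rounds (direct, bridging, tertiary) over a bait, its
#' candidate interactome and a prediction provider, and returns the grouped
#' LIS-weighted network. Every retained edge satisfies the retention
#' thresholds of `config`; every retained node is connected to the bait
#' through passing edges. A run manifest records the configuration, counts
#' per round and any skipped (prediction-less) pairs.
#'
#' @inheritParams screen_round1
#' @param candidates Candidate preys: a character vector or a tibble with a
#'   `prey_id` column (e.g. from [select_candidates()]).
#' @param include_bait_in_core Keep the bait in the Round-3 core set
#'   (bait + Group 1 + Group 2). Default TRUE, the literal reading of the
#'   consolidated core.
#' @return A `ppi_network`: list with `nodes` (tibble `id`, `group`),
#'   `edges` (tibble `from`, `to`, `lis`, `lia`, `round`), `config`,
#'   `manifest`.
#' @examples
#' sc <- simulate_interactome(n_direct = 1, n_bridge = 1, n_decoy = 1,
#'                            chain_len = 30, patch = 20,
#'                            seed = 11)
#' cfg <- score_config(tau_lia = 500)  # thresholds sized to the toy chains
#' net <- run_screen(sc$bait, sc$candidates, sc$provider, cfg)
#' glance(net)
#' @export
run_screen <- function(bait, candidates, provider, config = score_config(),
                       strict = FALSE, include_bait_in_core = TRUE) {
  if (is.data.frame(candidates)) candidates <- candidates$prey_id
  candidates <- sort(unique(as.character(candidates)))
  if (bait %in% candidates) {
    abort("The bait cannot appear in its own candidate list.",
          class = "lisnet_config_error")
  }
  state <- new_screen_state(provider, config, strict)

  r1 <- run_round1(state, bait, candidates)
  r2 <- run_round2(state, r1$group1, r1$failed)
  remaining <- setdiff(candidates, c(r1$group1, r2$group2))
  core <- c(if (include_bait_in_core) bait, r1$group1, r2$group2)
  r3 <- run_round3(state, remaining, sort(core))

  nodes <- tibble(
    id = c(bait, r1$group1, r2$group2, r3$group3),
    group = c("bait", rep("group1", length(r1$group1)),
              rep("group2", length(r2$group2)),
              rep("group3", length(r3$group3))))
  edges <- dplyr::bind_rows(r1$edges, r2$edges, r3$edges) |>
    dplyr::arrange(.data$round, .data$from, .data$to)

  manifest <- list(
    bait = bait,
    n_candidates = length(candidates),
    config = unclass(config),
    strict = strict,
    include_bait_in_core = include_bait_in_core,
    rounds = list(
      round1 = list(n_passed = length(r1$group1), n_failed = length(r1$failed)),
      round2 = list(n_group2 = length(r2$group2), n_edges = nrow(r2$edges)),
      round3 = list(n_group3 = length(r3$group3), n_edges = nrow(r3$edges))),
    n_pairs_evaluated = state$n_evaluated,
    skipped_pairs = sort(unique(state$skipped)))

  net <- structure(list(nodes = nodes, edges = edges, config = config,
                        manifest = manifest),
                   class = "ppi_network")
  validate_ppi_network(net)
  net
}

#' Validate the structural invariants of a PPI network
#'
#' Checks: exactly one bait; disjoint groups; every edge passes the
#' classification thresholds of the snapshot config; every non-bait node
#' has at least one edge and is connected to the bait through passing
#' edges.
#'
#' @param net A `ppi_network`.
#' @return `net`, invisibly; aborts on violation.
#' @export
validate_ppi_network <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  nodes <- net$nodes; edges <- net$edges
  if (sum(nodes$group == "bait") != 1L) {
    abort("A network must have exactly one bait node.",
          class = "lisnet_invariant_error")
  }
  if (anyDuplicated(nodes$id)) {
    abort("Node groups must be disjoint (duplicate node id found).",
          class = "lisnet_invariant_error")
  }
  if (nrow(edges) > 0) {
    if (!all(classify_interaction(edges$lis, edges$lia, net$config))) {
      abort("Every edge must satisfy the retention thresholds.",
            class = "lisnet_invariant_error")
    }
    if (!all(c(edges$from, edges$to) %in% nodes$id)) {
      abort("Edge endpoints must be network nodes.",
            class = "lisnet_invariant_error")
    }
  }
  bait <- nodes$id[nodes$group == "bait"]
  others <- setdiff(nodes$id, bait)
  if (length(others) > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = nodes$id)
    comp <- igraph::components(g)
    if (any(comp$membership[others] != comp$membership[[bait]])) {
      abort("Every node must be connected to the bait through passing edges.",
            class = "lisnet_invariant_error")
    }
  }
  invisible(net)
}

#' @export
print.ppi_network <- function(x, ...) {
  counts <- table(factor(x$nodes$group,
                         levels = c("bait", "group1", "group2", "group3")))
  cat(sprintf(
    "<ppi_network> bait %s: %d Group-1, %d Group-2, %d Group-3 nodes; %d edges\n",
    x$manifest$bait, counts[["group1"]], counts[["group2"]],
    counts[["group3"]], nrow(x$edges)))
  invisible(x)
}

#' Write the run manifest as JSON
#'
#' @param net A `ppi_network`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  jsonlite::write_json(net$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
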