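# Independent oracles, deliberately naive: double loops and exhaustive
# set logic, sharing no code with the package internals they check.

# Brute-force LIS/LIA for one model: walk every index pair, keep those
# spanning the chain boundary, accumulate sub-cutoff confidences.
oracle_score_model <- function(pred, cutoff = 12) {
  n <- nrow(pred$pae)
  in_a <- function(i) i <= pred$len_a
  lia <- 0L
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (in_a(i) != in_a(j) && pred$pae[i, j] < cutoff) {
        lia <- lia + 1L
        acc <- acc + (cutoff - pred$pae[i, j]) / cutoff
      }
    }
  }
  list(lis = if (lia > 0) acc / lia else 0, lia = lia)
}

# Brute-force inter-chain multiset.
oracle_interchain <- function(pred) {
  n <- nrow(pred$pae)
  out <- numeric()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if ((i <= pred$len_a) != (j <= pred$len_a)) {
        out <- c(out, pred$pae[i, j])
      }
    }
  }
  out
}

# Random prediction with arbitrary PAE values, for oracle-equivalence runs.
random_prediction <- function(seed, len_range = c(5, 50), pae_max = 31.75) {
  withr::with_seed(seed, {
    la <- sample(len_range[1]:len_range[2], 1)
    lb <- sample(len_range[1]:len_range[2], 1)
    n <- la + lb
    pae_prediction(matrix(runif(n * n, 0, pae_max), n, n), la, lb,
                   model_id = sprintf("rnd_%d", seed))
  })
}

# Exhaustive screen oracle: score every unordered pair once, then assign
# groups breadth-first from the bait and collect edges per the round
# semantics (round 1: bait-candidate; round 2: group1-failed and
# intra-group1; round 3: remaining-core).
oracle_screen <- function(bait, candidates, provider,
                          config = lisnet::score_config()) {
  candidates <- sort(candidates)
  ids <- c(bait, candidates)
  passes <- function(a, b) {
    preds <- provider(a, b)
    if (is.null(preds) || length(preds) == 0) return(FALSE)
    lisnet::score_pair(preds, config)$passed
  }
  pass <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j) pass[i, j] <- pass[j, i] <- passes(ids[i], ids[j])
    }
  }
  g1 <- candidates[pass[bait, candidates]]
  failed <- setdiff(candidates, g1)
  g2 <- failed[vapply(failed, function(f) any(pass[f, g1]), logical(1))]
  remaining <- setdiff(candidates, c(g1, g2))
  core <- c(bait, g1, g2)
  g3 <- remaining[vapply(remaining, function(r) any(pass[r, core]), logical(1))]

  ekey <- function(u, v) paste(sort(c(u, v)), collapse = "|")
  edges <- character()
  for (c1 in g1) edges <- c(edges, ekey(bait, c1))
  for (f in g2) for (g in g1) if (pass[f, g]) edges <- c(edges, ekey(f, g))
  if (length(g1) >= 2) {
    cmb <- utils::combn(g1, 2)
    for (k in seq_len(ncol(cmb))) {
      if (pass[cmb[1, k], cmb[2, k]]) edges <- c(edges, ekey(cmb[1, k], cmb[2, k]))
    }
  }
  for (r in g3) for (cr in core) if (pass[r, cr]) edges <- c(edges, ekey(r, cr))
  list(group1 = sort(g1), group2 = sort(g2), group3 = sort(g3),
       edges = sort(unique(edges)))
}

edge_keys <- function(net) {
  sort(paste(net$edges$from, net$edges$to, sep = "|"))
}

nodes_of_group <- function(net, grp) {
  sort(net$nodes$id[net$nodes$group == grp])
}
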