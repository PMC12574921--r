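# The three-round screen against planted truth and the exhaustive oracle.

test_that("planted direct, bridge and tertiary candidates land in their groups", {
  sc <- simulate_interactome(n_direct = 3, n_bridge = 2, n_tertiary = 1,
                             n_decoy = 4, seed = 17)
  net <- run_screen(sc$bait, sc$candidates, sc$provider)
  truth <- sc$truth
  expect_setequal(nodes_of_group(net, "group1"),
                  truth$prey_id[truth$class == "direct"])
  expect_setequal(nodes_of_group(net, "group2"),
                  truth$prey_id[truth$class == "bridge"])
  expect_setequal(nodes_of_group(net, "group3"),
                  truth$prey_id[truth$class == "tertiary"])
  expect_false(any(truth$prey_id[truth$class == "decoy"] %in% net$nodes$id))

  # a bridge planted against exactly one anchor gets exactly that edge
  brg <- truth$prey_id[truth$class == "bridge"][1]
  anchor <- truth$anchor[truth$prey_id == brg]
  e <- net$edges[net$edges$from == min(brg, anchor) &
                   net$edges$to == max(brg, anchor), ]
  expect_identical(nrow(e), 1L)
  expect_identical(e$round, 2L)
  # its only round-2 edge is that anchor edge (a planted tertiary may add
  # a round-3 edge through it later)
  r2 <- net$edges[net$edges$round == 2L, ]
  expect_identical(sum(r2$from == brg | r2$to == brg), 1L)
})

test_that("trivial candidate sets behave", {
  sc <- simulate_interactome(n_direct = 1, n_bridge = 1, n_decoy = 1, seed = 2)
  net0 <- run_screen(sc$bait, character(), sc$provider)
  expect_identical(nrow(net0$nodes), 1L)
  expect_identical(nrow(net0$edges), 0L)

  # all candidates direct: groups 2 and 3 stay empty
  sc2 <- simulate_interactome(n_direct = 3, n_bridge = 0, n_tertiary = 0,
                              n_decoy = 0, seed = 3)
  net2 <- run_screen(sc2$bait, sc2$candidates, sc2$provider)
  expect_identical(glance(net2)$n_group2, 0L)
  expect_identical(glance(net2)$n_group3, 0L)

  expect_error(run_screen("X", c("X", "Y"), sc$provider),
               class = "lisnet_config_error")
})

test_that("missing predictions follow the non-strict/strict policy", {
  sc <- simulate_interactome(n_direct = 2, n_bridge = 0, n_decoy = 0, seed = 5)
  gappy <- function(a, b) {
    if ("dir_02" %in% c(a, b)) NULL else sc$provider(a, b)
  }
  warns <- capture_warnings(net <- run_screen(sc$bait, sc$candidates, gappy))
  expect_true(all(grepl("dir_02", warns)))  # one per skipped pair
  expect_gte(length(warns), 1L)
  expect_false("dir_02" %in% net$nodes$id)
  expect_true("dir_01" %in% nodes_of_group(net, "group1"))
  expect_true(any(grepl("dir_02", net$manifest$skipped_pairs)))
  expect_error(
    suppressWarnings(run_screen(sc$bait, sc$candidates, gappy, strict = TRUE)),
    class = "lisnet_missing_prediction")
})

test_that("screen equals the exhaustive all-pairs oracle on small instances", {
  for (seed in c(101, 102, 103)) {
    sc <- simulate_interactome(n_direct = 2, n_bridge = 2, n_tertiary = 1,
                               n_decoy = 3, chain_len = 40, patch = 24,
                               seed = seed)
    cfg <- score_config(tau_lia = 1000)  # thresholds sized to the 40-res chains
    net <- run_screen(sc$bait, sc$candidates, sc$provider, cfg)
    orc <- oracle_screen(sc$bait, sc$candidates, sc$provider, cfg)
    expect_identical(nodes_of_group(net, "group1"), orc$group1)
    expect_identical(nodes_of_group(net, "group2"), orc$group2)
    expect_identical(nodes_of_group(net, "group3"), orc$group3)
    expect_identical(edge_keys(net), orc$edges)
  }
})

test_that("pair evaluations are cached and bounded by the staged formula", {
  sc <- simulate_interactome(n_direct = 2, n_bridge = 1, n_tertiary = 0,
                             n_decoy = 2, chain_len = 30, patch = 20, seed = 9)
  cfg <- score_config(tau_lia = 500)
  calls <- new.env(); calls$keys <- character()
  counting <- function(a, b) {
    calls$keys <- c(calls$keys, paste(sort(c(a, b)), collapse = "|"))
    sc$provider(a, b)
  }
  net <- run_screen(sc$bait, sc$candidates, counting, cfg)
  expect_identical(anyDuplicated(calls$keys), 0L)  # unordered-pair cache

  n_c <- length(sc$candidates)
  g1 <- glance(net)$n_group1; g2 <- glance(net)$n_group2
  n_failed <- n_c - g1
  n_rem <- n_c - g1 - g2
  bound <- n_c + g1 * n_failed + g1 * (g1 - 1) / 2 + n_rem * (1 + g1 + g2)
  expect_lte(length(calls$keys), bound)
  expect_identical(net$manifest$n_pairs_evaluated, length(calls$keys))
})

test_that("identical inputs give identical networks and manifests", {
  sc <- simulate_interactome(n_direct = 2, n_bridge = 1, n_decoy = 2, seed = 23)
  n1 <- run_screen(sc$bait, sc$candidates, sc$provider)
  n2 <- run_screen(sc$bait, sc$candidates, sc$provider)
  expect_identical(n1$nodes, n2$nodes)
  expect_identical(n1$edges, n2$edges)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_manifest(n1, f1); write_manifest(n2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("network invariants hold across randomised planted scenarios", {
  for (seed in 1:15) {
    cls <- withr::with_seed(seed, c(sample(0:3, 1), sample(0:2, 1),
                                    sample(0:2, 1), sample(0:3, 1)))
    if (cls[1] == 0) cls[2:3] <- 0   # bridges/tertiaries need anchors
    if (cls[2] == 0) cls[3] <- 0
    sc <- simulate_interactome(n_direct = max(cls[1], 1), n_bridge = cls[2],
                               n_tertiary = cls[3], n_decoy = cls[4],
                               chain_len = 30, patch = 20, seed = seed)
    cfg <- score_config(tau_lia = 500)
    net <- run_screen(sc$bait, sc$candidates, sc$provider, cfg)
    expect_silent(validate_ppi_network(net))
    expect_identical(anyDuplicated(net$nodes$id), 0L)
    expect_true(all(classify_interaction(net$edges$lis, net$edges$lia, cfg)))
  }
})

test_that("dir_provider reads the canonical pair files from disk", {
  dir <- withr::local_tempdir()
  preds <- simulate_pae_prediction(30, 30, interface_spec(20, 20),
                                   n_models = 2, seed = 31)
  for (p in preds) {
    write_pae_prediction(p, file.path(dir, pair_filename("B", "A", p$model_id)))
  }
  prov <- dir_provider(dir)
  got <- prov("A", "B")
  expect_length(got, 2)
  expect_identical(got[[1]]$pae, preds[[1]]$pae)
  expect_identical(prov("B", "A")[[2]]$pae, got[[2]]$pae)  # symmetric lookup
  expect_length(prov("A", "C"), 0)
})
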