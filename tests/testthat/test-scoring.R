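test_that("interchain_cells returns exactly the boundary-spanning values", {
  p <- pae_prediction(matrix(runif(25, 0, 31), 5, 5), 2, 3)
  cells <- interchain_cells(p)
  expect_length(cells, 2 * 2 * 3)
  expect_equal(sort(cells), sort(oracle_interchain(p)))

  # symmetric matrix: the two blocks carry equal multisets
  m <- matrix(runif(144, 0, 31), 12, 12)
  m <- (m + t(m)) / 2
  ps <- pae_prediction(m, 5, 7)
  bl <- ps$pae[1:5, 6:12]
  expect_equal(sort(interchain_cells(ps)), sort(c(bl, bl)))

  expect_error(pae_prediction(matrix(0, 4, 4), 2, 3),
               class = "lisnet_format_error")
})

test_that("score_model reproduces the worked 2+2-chain example", {
  m <- matrix(30, 4, 4)
  m[1:2, 3:4] <- matrix(c(3, 6, 9, 12), 2, 2, byrow = TRUE)
  s <- score_model(pae_prediction(m, 2, 2))
  expect_identical(s$lia, 3L)          # 12 excluded by the strict cutoff
  expect_equal(s$lis, 0.5)             # mean(0.75, 0.50, 0.25)
})

test_that("score_model attains its closed-form limits", {
  m0 <- matrix(0, 120, 120)
  s0 <- score_model(pae_prediction(m0, 60, 60))
  expect_equal(s0$lis, 1.0)
  expect_identical(s0$lia, 7200L)      # 2 * 60 * 60

  m12 <- matrix(12, 10, 10)
  s12 <- score_model(pae_prediction(m12, 4, 6))
  expect_identical(s12$lia, 0L)
  expect_identical(s12$lis, 0)
})

test_that("score_model matches the brute-force oracle on random predictions", {
  for (seed in 1:50) {
    p <- random_prediction(seed, len_range = c(5, 30))
    s <- score_model(p)
    o <- oracle_score_model(p)
    expect_identical(s$lia, as.integer(o$lia))
    expect_lt(abs(s$lis - o$lis), 1e-12)
  }
})

test_that("score_model is monotone in inter-chain PAE and blind to intra-chain cells", {
  p <- random_prediction(99, len_range = c(8, 12))
  base <- score_model(p)
  # push one sub-cutoff inter-chain cell above the cutoff: lia drops
  cells <- which(
    outer(seq_len(nrow(p$pae)) <= p$len_a, seq_len(nrow(p$pae)) <= p$len_a,
          "!=") & p$pae < 12, arr.ind = TRUE)
  p2 <- p
  p2$pae[cells[1, 1], cells[1, 2]] <- 20
  s2 <- score_model(p2)
  expect_lt(s2$lia, base$lia)
  # rewriting an intra-chain block changes nothing
  p3 <- p
  p3$pae[seq_len(p$len_a), seq_len(p$len_a)] <- 0.5
  expect_identical(score_model(p3)[c("lis", "lia")], base[c("lis", "lia")])
})

test_that("classification boundary is inclusive at the printed thresholds", {
  expect_true(classify_interaction(0.203, 3432))
  expect_false(classify_interaction(0.5, 3))
  expect_false(classify_interaction(0.202, 5000))
  expect_false(classify_interaction(0.203, 3431.999))
  cfg <- score_config(tau_lis = 0.5, tau_lia = 10)
  expect_true(classify_interaction(0.5, 10, cfg))
  expect_false(classify_interaction(0.4999, 10, cfg))
})

test_that("aggregation combines per-model scores as documented", {
  pm <- tibble::tibble(model_id = c("m1", "m2"), lis = c(0.4, 0.6),
                       lia = c(4000, 2000))
  s_mean <- aggregate_scores(pm, score_config(aggregation = "mean"))
  expect_equal(s_mean$lis, 0.5)
  expect_equal(s_mean$lia, 3000)
  s_max <- aggregate_scores(pm, score_config(aggregation = "max"))
  expect_equal(s_max$lis, 0.6)
  expect_equal(s_max$lia, 4000)
  s_best <- aggregate_scores(pm, score_config(aggregation = "best_model"))
  expect_equal(s_best$lis, 0.6)
  expect_equal(s_best$lia, 2000)      # both fields from the best-LIS model

  # single model: identity under every method
  one <- pm[1, ]
  for (agg in c("mean", "max", "best_model")) {
    s <- aggregate_scores(one, score_config(aggregation = agg))
    expect_equal(s$lis, 0.4)
    expect_equal(s$lia, 4000)
  }

  # max-aggregated lis always >= mean-aggregated lis
  for (seed in 1:20) {
    pmr <- withr::with_seed(seed, tibble::tibble(
      model_id = sprintf("m%d", 1:5), lis = runif(5), lia = runif(5, 0, 8000)))
    expect_gte(aggregate_scores(pmr, score_config(aggregation = "max"))$lis,
               aggregate_scores(pmr, score_config(aggregation = "mean"))$lis)
  }

  expect_error(aggregate_scores(tibble::tibble(lis = numeric(), lia = numeric())),
               class = "lisnet_missing_prediction")
})

test_that("score_pair wraps parse -> score -> aggregate -> classify", {
  # one planted mirrored-patch model: passes the default thresholds
  pred <- simulate_pae_prediction(100, 100, interface_spec(), seed = 4)[[1]]
  s <- score_pair(list(pred), protein_a = "A", protein_b = "B")
  expect_true(s$passed)
  expect_equal(s$lia, 7200)
  expect_gte(s$lis, 1 / 3)

  # decoy: fails with zero interface
  dec <- simulate_pae_prediction(100, 100, NULL, seed = 4)[[1]]
  sd <- score_pair(list(dec))
  expect_false(sd$passed)
  expect_equal(sd$lia, 0)

  # five identical files score identically to one under mean aggregation
  f <- withr::local_tempfile(fileext = ".json")
  write_pae_prediction(pred, f)
  s5 <- score_pair(rep(f, 5))
  expect_equal(s5$lis, s$lis)
  expect_equal(s5$lia, s$lia)
  expect_identical(s5$n_models, 5L)

  expect_error(score_pair(list()), class = "lisnet_missing_prediction")
})

test_that("lia counts both off-diagonal blocks by default, max-of-blocks on request", {
  m <- matrix(30, 4, 4)
  m[1:2, 3:4] <- 5        # A->B: 4 sub-cutoff cells
  m[3:4, 1:2] <- c(5, 30, 30, 30)  # B->A: 1 sub-cutoff cell
  p <- pae_prediction(m, 2, 2)
  expect_identical(score_model(p)$lia, 5L)
  expect_identical(score_model(p, score_config(lia_blocks = "max"))$lia, 4L)
})
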