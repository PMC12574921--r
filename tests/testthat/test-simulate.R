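# Generators: determinism, planted structure, distributional sanity.

test_that("spectral-count simulation is deterministic and validates its config", {
  a <- simulate_spectral_counts(20, 3, 5, enriched_prey_ids = "prey_003",
                                fold = 4, seed = 42)
  b <- simulate_spectral_counts(20, 3, 5, enriched_prey_ids = "prey_003",
                                fold = 4, seed = 42)
  expect_identical(a, b)
  c <- simulate_spectral_counts(20, 3, 5, enriched_prey_ids = "prey_003",
                                fold = 4, seed = 43)
  expect_false(identical(a$counts, c$counts))

  expect_error(simulate_spectral_counts(5, 3, 5, enriched_prey_ids = "nope"),
               class = "lisnet_config_error")
  expect_error(simulate_spectral_counts(5, 3, 0), class = "lisnet_config_error")
  expect_error(simulate_spectral_counts(5, 3, 5, enriched_prey_ids = "prey_001",
                                        fold = 1),
               class = "lisnet_config_error")
})

test_that("control counts track the background rate; planting shifts only the bait arm", {
  sim <- simulate_spectral_counts(1500, 2, background_rate = 5, seed = 7)
  ctrl <- unlist(sim$counts[, c("control_1", "control_2")])
  se <- sqrt(5 / length(ctrl))
  expect_lt(abs(mean(ctrl) - 5), 3 * se)

  # with no planted effect and many replicates (where the ratio-of-means
  # estimator loses its small-sample bias) fold changes centre on 1
  big <- simulate_spectral_counts(400, 40, background_rate = 5, seed = 8)
  fc <- select_candidates(big$counts, min_fold = 0)$fold_change
  expect_lt(abs(mean(fc) - 1), 0.02)

  enriched <- sprintf("prey_%03d", 1:100)
  sim2 <- simulate_spectral_counts(300, 4, 5, enriched_prey_ids = enriched,
                                   fold = 4, seed = 11)
  bait <- as.matrix(sim2$counts[, grep("^bait", names(sim2$counts))])
  is_enr <- sim2$counts$prey_id %in% enriched
  expect_gt(mean(bait[is_enr, ]), 3 * mean(bait[!is_enr, ]))
})

test_that("negative-binomial option keeps the mean but adds dispersion", {
  po <- simulate_spectral_counts(800, 2, 10, seed = 5)
  nb <- simulate_spectral_counts(800, 2, 10, seed = 5, dispersion = 1)
  vpo <- var(as.numeric(unlist(po$counts[, -1])))
  vnb <- var(as.numeric(unlist(nb$counts[, -1])))
  expect_lt(abs(mean(unlist(nb$counts[, -1])) - 10), 1)
  expect_gt(vnb, 2 * vpo)
})

test_that("PAE simulation plants the promised interface geometry", {
  preds <- simulate_pae_prediction(100, 100, interface_spec(), n_models = 3,
                                   seed = 1)
  expect_length(preds, 3)
  for (p in preds) {
    expect_identical(dim(p$pae), c(200L, 200L))
    s <- score_model(p)
    expect_identical(s$lia, 7200L)       # mirrored 60x60 patch, rest >= 20
    expect_gte(s$lis, 1 / 3)             # patch values <= 8 vs cutoff 12
    expect_true(classify_interaction(s$lis, s$lia))
  }

  # no interface: nothing below the cutoff anywhere between chains
  decoys <- simulate_pae_prediction(100, 100, NULL, n_models = 2, seed = 1)
  for (p in decoys) {
    s <- score_model(p)
    expect_identical(s$lia, 0L)
    expect_identical(s$lis, 0)
  }

  expect_identical(simulate_pae_prediction(50, 50, NULL, seed = 3),
                   simulate_pae_prediction(50, 50, NULL, seed = 3))
  expect_error(simulate_pae_prediction(40, 100, interface_spec(60, 60)),
               class = "lisnet_config_error")
  expect_error(interface_spec(pae_low_range = c(2, 25),
                              pae_high_range = c(20, 30)),
               class = "lisnet_config_error")
})

test_that("eye-image simulation plants intensities and keeps masks disjoint", {
  sim <- simulate_eye_images(c(ctrl = 40, mut = 120), background_value = 200,
                             noise_sd = 0, n_per_genotype = 3, seed = 2)
  expect_length(sim$images, 6)
  m <- measure_eyes(sim$images)
  expect_equal(m$eye_mean_red[m$genotype == "ctrl"], rep(40, 3))
  expect_equal(m$background_mean_red, rep(200, 6))
  for (img in sim$images) {
    expect_false(any(img$eye_mask & img$background_mask))
  }
  expect_identical(
    simulate_eye_images(c(a = 50), seed = 4)$images[[1]]$rgb,
    simulate_eye_images(c(a = 50), seed = 4)$images[[1]]$rgb)
  expect_error(simulate_eye_images(c(a = 500)), class = "lisnet_config_error")
  expect_error(simulate_eye_images(c(50)), class = "lisnet_config_error")
})

test_that("planted interactome truth is consistent with default classification", {
  sc <- simulate_interactome(n_direct = 2, n_bridge = 2, n_tertiary = 1,
                             n_decoy = 3, seed = 6)
  # every planted pair passes, every decoy pair fails
  for (i in seq_len(nrow(sc$planted_pairs))) {
    s <- score_pair(sc$provider(sc$planted_pairs$a[i], sc$planted_pairs$b[i]))
    expect_true(s$passed)
  }
  decoys <- sc$truth$prey_id[sc$truth$class == "decoy"]
  for (d in decoys[1:2]) {
    s <- score_pair(sc$provider(sc$bait, d))
    expect_false(s$passed)
    expect_equal(s$lia, 0)
  }
  # provider symmetry and repeatability
  a <- sc$planted_pairs$a[1]; b <- sc$planted_pairs$b[1]
  expect_identical(sc$provider(a, b)[[1]]$pae, sc$provider(b, a)[[1]]$pae)
})
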