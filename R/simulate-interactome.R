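#' Simulate a planted interactome scenario for the iterative screen
#'
#' Builds a bait plus a candidate list with known ground truth and a
#' matching prediction provider. Candidates fall into four planted classes:
#'
#' * *direct* interactors: an interface is planted for the bait pair, so
#'   they should land in Group 1;
#' * *bridges*: an interface is planted only with an assigned direct
#'   interactor (round-robin over the direct set), so they should land in
#'   Group 2;
#' * *tertiary* contacts: an interface is planted only with an assigned
#'   bridge, so they should land in Group 3 (none by default);
#' * *decoys*: every prediction involving them is interface-free, so they
#'   should be absent from the final network.
#'
#' The provider generates each pair's predictions lazily and
#' deterministically from a per-pair seed derived from `seed`, so it is
#' symmetric and repeatable, and planted interfaces use a mirrored
#' `patch x patch` low-error patch on `chain_len`-residue chains: with the
#' defaults the planted per-model LIA is `2 * 60 * 60 = 7200` and LIS is at
#' least `(12 - 8)/12 = 1/3`, clearing the default retention thresholds,
#' while decoy pairs score LIS = LIA = 0.
#'
#' @param n_direct,n_bridge,n_tertiary,n_decoy Planted class sizes.
#' @param bait Bait protein id.
#' @param chain_len Residue count of every simulated protein.
#' @param patch Planted patch side (residues).
#' @param n_models Models emitted per pair.
#' @param seed Integer seed.
#' @return List with `bait`, `candidates` (character, lexicographic),
#'   `provider` (function taking two protein ids, returning a list of
#'   [pae_prediction()]), `truth` (tibble: `prey_id`, `class`, `anchor`,
#'   `expected_group`), and `planted_pairs` (tibble of interface pairs).
#' @examples
#' sc <- simulate_interactome(n_direct = 2, n_bridge = 1, n_decoy = 2,
#'                            chain_len = 30, patch = 20, seed = 5)
#' score_pair(sc$provider(sc$bait, sc$truth$prey_id[1]))
#' @export
simulate_interactome <- function(n_direct = 5, n_bridge = 3, n_tertiary = 0,
                                 n_decoy = 12, bait = "bait",
                                 chain_len = 100, patch = 60, n_models = 1,
                                 seed = 1) {
  n_direct <- check_count(n_direct, "n_direct", min = 0)
  n_bridge <- check_count(n_bridge, "n_bridge", min = 0)
  n_tertiary <- check_count(n_tertiary, "n_tertiary", min = 0)
  n_decoy <- check_count(n_decoy, "n_decoy", min = 0)
  seed <- check_seed(seed)
  if (patch > chain_len) {
    abort("`patch` must not exceed `chain_len`.", class = "lisnet_config_error")
  }
  direct <- sprintf("dir_%02d", seq_len(n_direct))
  bridge <- if (n_bridge > 0) sprintf("brg_%02d", seq_len(n_bridge)) else character()
  tertiary <- if (n_tertiary > 0) sprintf("ter_%02d", seq_len(n_tertiary)) else character()
  decoy <- if (n_decoy > 0) sprintf("dcy_%02d", seq_len(n_decoy)) else character()
  if (length(bridge) > 0 && n_direct == 0) {
    abort("Bridges need at least one direct interactor to anchor to.",
          class = "lisnet_config_error")
  }
  if (length(tertiary) > 0 && length(bridge) == 0) {
    abort("Tertiary contacts need at least one bridge to anchor to.",
          class = "lisnet_config_error")
  }
  anchor_of <- c(
    setNames(rep(bait, n_direct), direct),
    setNames(direct[(seq_along(bridge) - 1L) %% n_direct + 1L], bridge),
    setNames(bridge[(seq_along(tertiary) - 1L) %% length(bridge) + 1L],
             tertiary))

  planted <- tibble(
    a = c(rep(bait, n_direct), unname(anchor_of[bridge]),
          unname(anchor_of[tertiary])),
    b = c(direct, bridge, tertiary))
  planted_keys <- purrr::map2_chr(planted$a, planted$b, pair_key)

  iface <- interface_spec(patch_len_a = patch, patch_len_b = patch,
                          mirrored = TRUE)
  provider <- function(a, b) {
    key <- pair_key(a, b)
    simulate_pae_prediction(
      chain_len, chain_len,
      interface = if (key %in% planted_keys) iface else NULL,
      n_models = n_models, seed = derive_seed(seed, key))
  }

  truth <- tibble(
    prey_id = c(direct, bridge, tertiary, decoy),
    class = c(rep("direct", n_direct), rep("bridge", length(bridge)),
              rep("tertiary", length(tertiary)), rep("decoy", n_decoy)),
    anchor = c(unname(anchor_of[c(direct, bridge, tertiary)]),
               rep(NA_character_, n_decoy)),
    expected_group = c(rep("group1", n_direct), rep("group2", length(bridge)),
                       rep("group3", length(tertiary)),
                       rep(NA_character_, n_decoy)))

  list(bait = bait, candidates = sort(truth$prey_id), provider = provider,
       truth = truth, planted_pairs = planted)
}

#' Prediction provider backed by a directory of PAE files
#'
#' Looks a pair's predictions up in `pred_dir`: every file named
#' `<A>__<B>*.json` (ids in lexicographic order, as produced by
#' [pair_filename()]) is parsed with [read_pae_prediction()]. Returns an
#' empty list when no file exists, which the screen treats per its
#' missing-data policy.
#'
#' @param pred_dir Directory of PAE JSON files.
#' @return A provider function of two protein ids.
#' @export
dir_provider <- function(pred_dir) {
  if (!dir.exists(pred_dir)) {
    abort(sprintf("Prediction directory not found: %s", pred_dir),
          class = "lisnet_config_error")
  }
  force(pred_dir)
  function(a, b) {
    stem <- pair_key(a, b)
    files <- sort(list.files(
      pred_dir, pattern = paste0("^", stem, "([._].*)?\\.json$"),
      full.names = TRUE))
    files <- files[!grepl("\\.chains\\.json$", files)]
    lapply(files, read_pae_prediction)
  }
}

#' Canonical PAE file name for an unordered protein pair
#'
#' @param a,b Protein ids.
#' @param model_id Model identifier appended to the stem.
#' @return File name `"<min>__<max>.<model_id>.json"`.
#' @export
pair_filename <- function(a, b, model_id = "model_1") {
  paste0(pair_key(a, b), ".", model_id, ".json")
}
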