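#' Specify a planted inter-chain contact patch
#'
#' Describes the synthetic interface planted into simulated PAE maps: a
#' rectangular low-error patch of `patch_len_a x patch_len_b` inter-chain
#' cells whose values are drawn from `pae_low_range`, while all other
#' inter-chain cells are drawn from `pae_high_range`. When `mirrored`, the
#' patch appears in both off-diagonal blocks, so it contributes
#' `2 * patch_len_a * patch_len_b` cells to the Local Interaction Area.
#'
#' @param patch_len_a,patch_len_b Patch extent (residues) on chains A and B.
#' @param pae_low_range Interval of PAE values inside the patch.
#' @param pae_high_range Interval of PAE values for the rest of the
#'   inter-chain blocks; must lie strictly above `pae_low_range`.
#' @param mirrored Plant the patch in both off-diagonal blocks. Default TRUE.
#' @return A list of class `interface_spec`.
#' @export
interface_spec <- function(patch_len_a = 60, patch_len_b = 60,
                           pae_low_range = c(2, 8),
                           pae_high_range = c(20, 31.75), mirrored = TRUE) {
  patch_len_a <- check_count(patch_len_a, "patch_len_a")
  patch_len_b <- check_count(patch_len_b, "patch_len_b")
  stopifnot(length(pae_low_range) == 2L, length(pae_high_range) == 2L)
  if (max(pae_low_range) >= min(pae_high_range)) {
    abort("`pae_low_range` must lie strictly below `pae_high_range`.",
          class = "lisnet_config_error")
  }
  if (min(pae_low_range) < 0) {
    abort("PAE ranges must be non-negative.", class = "lisnet_config_error")
  }
  structure(list(patch_len_a = patch_len_a, patch_len_b = patch_len_b,
                 pae_low_range = sort(as.numeric(pae_low_range)),
                 pae_high_range = sort(as.numeric(pae_high_range)),
                 mirrored = isTRUE(mirrored)),
            class = "interface_spec")
}

#' Simulate AlphaFold-Multimer PAE predictions for one protein pair
#'
#' Emulates the per-model PAE output of an AlphaFold-Multimer run on a
#' two-chain complex, at the score level only (no structures). Intra-chain
#' blocks are drawn from `intra_range` (chains are always confidently
#' placed internally); inter-chain blocks are drawn from the interface
#' spec's high range, except for the planted low-error patch (and its
#' mirror) when an `interface` is given. With `interface = NULL` every
#' inter-chain cell comes from `pae_high_range`, so default scoring yields
#' LIS = LIA = 0. The patch position is drawn uniformly within each chain,
#' per model. Deterministic per `seed`.
#'
#' @param len_a,len_b Chain lengths (residues); must accommodate the patch.
#' @param interface An [interface_spec()], or `NULL` for a non-interacting
#'   decoy pair.
#' @param n_models Number of models to emit.
#' @param seed Integer seed.
#' @param pae_high_range Inter-chain PAE range used when `interface` is
#'   `NULL` (ignored otherwise; the spec carries its own).
#' @param intra_range PAE range of the intra-chain blocks.
#' @param pae_max PAE ceiling of the output files. Default 31.75, the
#'   conventional cap in AlphaFold dumps.
#' @param iptm_range Range the metadata ipTM is drawn from; defaults to a
#'   high band for interface pairs and a low band for decoys.
#' @return List of `n_models` [pae_prediction()] objects.
#' @examples
#' preds <- simulate_pae_prediction(100, 100, interface_spec(), seed = 7)
#' score_model(preds[[1]])
#' @export
simulate_pae_prediction <- function(len_a, len_b, interface = NULL,
                                    n_models = 1, seed = 1,
                                    pae_high_range = c(20, 31.75),
                                    intra_range = c(0, 5),
                                    pae_max = 31.75,
                                    iptm_range = NULL) {
  len_a <- check_count(len_a, "len_a")
  len_b <- check_count(len_b, "len_b")
  n_models <- check_count(n_models, "n_models")
  seed <- check_seed(seed)
  if (!is.null(interface)) {
    stopifnot(inherits(interface, "interface_spec"))
    if (interface$patch_len_a > len_a || interface$patch_len_b > len_b) {
      abort("Planted patch exceeds a chain length.",
            class = "lisnet_config_error")
    }
    pae_high_range <- interface$pae_high_range
  }
  if (max(pae_high_range) > pae_max || max(intra_range) > pae_max) {
    abort("PAE ranges must not exceed `pae_max`.",
          class = "lisnet_config_error")
  }
  if (is.null(iptm_range)) {
    iptm_range <- if (is.null(interface)) c(0.05, 0.3) else c(0.7, 0.95)
  }

  n <- len_a + len_b
  ia <- seq_len(len_a)
  ib <- len_a + seq_len(len_b)
  withr::with_seed(seed, {
    lapply(seq_len(n_models), function(k) {
      m <- matrix(0, n, n)
      m[ia, ia] <- runif(len_a^2, intra_range[1], intra_range[2])
      m[ib, ib] <- runif(len_b^2, intra_range[1], intra_range[2])
      m[ia, ib] <- runif(len_a * len_b, pae_high_range[1], pae_high_range[2])
      m[ib, ia] <- runif(len_b * len_a, pae_high_range[1], pae_high_range[2])
      if (!is.null(interface)) {
        sa <- sample.int(len_a - interface$patch_len_a + 1L, 1L)
        sb <- sample.int(len_b - interface$patch_len_b + 1L, 1L)
        ra <- sa:(sa + interface$patch_len_a - 1L)
        rb <- len_a + (sb:(sb + interface$patch_len_b - 1L))
        np <- interface$patch_len_a * interface$patch_len_b
        m[ra, rb] <- runif(np, interface$pae_low_range[1],
                           interface$pae_low_range[2])
        if (interface$mirrored) {
          m[rb, ra] <- runif(np, interface$pae_low_range[1],
                             interface$pae_low_range[2])
        }
      }
      pae_prediction(m, len_a, len_b, model_id = sprintf("model_%d", k),
                     iptm = round(runif(1, iptm_range[1], iptm_range[2]), 3),
                     pae_max = pae_max)
    })
  })
}
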