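#' Construct a two-chain PAE prediction
#'
#' Wraps one AlphaFold-Multimer model's predicted aligned error (PAE) matrix
#' for a two-chain complex. The matrix is square with side `len_a + len_b`;
#' rows/columns `1..len_a` belong to chain A and the remainder to chain B.
#' PAE is an error estimate in Angstroms and need not be symmetric: entry
#' `[i, j]` is the expected error at residue `j` when the prediction is
#' aligned on residue `i`.
#'
#' @param pae Square numeric matrix of PAE values, side `len_a + len_b`,
#'   entries in `[0, pae_max]`.
#' @param len_a,len_b Residue counts of the two chains.
#' @param model_id Identifier of the AFM model (e.g. `"rank_1"`).
#' @param iptm Optional interface-weighted predicted TM-score in `[0, 1]`,
#'   carried as metadata only (never thresholded).
#' @param pae_max Maximum representable PAE; AlphaFold output files cap at
#'   31.75 by convention.
#' @return An object of class `pae_prediction`.
#' @examples
#' m <- matrix(15, 5, 5)
#' pae_prediction(m, len_a = 2, len_b = 3)
#' @export
pae_prediction <- function(pae, len_a, len_b, model_id = "model_1",
                           iptm = NULL, pae_max = 31.75) {
  len_a <- check_count(len_a, "len_a")
  len_b <- check_count(len_b, "len_b")
  if (!is.matrix(pae) || !is.numeric(pae) || nrow(pae) != ncol(pae)) {
    abort("`pae` must be a square numeric matrix.",
          class = "lisnet_format_error")
  }
  if (nrow(pae) != len_a + len_b) {
    abort(sprintf(
      "PAE matrix side (%d) does not equal len_a + len_b (%d + %d = %d).",
      nrow(pae), len_a, len_b, len_a + len_b), class = "lisnet_format_error")
  }
  if (anyNA(pae) || min(pae) < 0 || max(pae) > pae_max) {
    abort(sprintf("PAE entries must lie in [0, %s] with no missing values.",
                  format(pae_max)), class = "lisnet_format_error")
  }
  if (!is.null(iptm)) {
    iptm <- check_number(iptm, "iptm", min = 0)
    if (iptm > 1) abort("`iptm` must lie in [0, 1].",
                        class = "lisnet_format_error")
  }
  structure(
    list(pae = unname(pae), len_a = len_a, len_b = len_b,
         model_id = as.character(model_id), iptm = iptm, pae_max = pae_max),
    class = "pae_prediction")
}

#' @export
print.pae_prediction <- function(x, ...) {
  cat(sprintf("<pae_prediction> %s: chains %d + %d residues, PAE in [%.2f, %.2f]",
              x$model_id, x$len_a, x$len_b, min(x$pae), max(x$pae)))
  if (!is.null(x$iptm)) cat(sprintf(", ipTM %.3f", x$iptm))
  cat("\n")
  invisible(x)
}

#' Scoring configuration for LIS/LIA classification
#'
#' Bundles the tunable constants of interface scoring. The decision
#' boundary used throughout is LIS >= `tau_lis` AND LIA >= `tau_lia`
#' (both inclusive); the PAE cutoff that defines the local interface is
#' strict (`pae < pae_cutoff`).
#'
#' @param pae_cutoff PAE value (Angstroms) below which an inter-chain
#'   residue pair counts as part of the predicted interface. Default 12.
#' @param tau_lis Inclusive LIS threshold for a positive call. Default 0.203.
#' @param tau_lia Inclusive LIA threshold for a positive call. Default 3432.
#' @param aggregation How per-model scores combine into one score per pair:
#'   `"mean"` (arithmetic mean of LIS and of LIA), `"max"` (per-field
#'   maxima) or `"best_model"` (both fields from the model with highest
#'   LIS; ties broken by lowest `model_id`).
#' @param lia_blocks Count sub-cutoff cells in `"both"` off-diagonal blocks
#'   of the (asymmetric) PAE matrix, or take the `"max"` of the two blocks.
#' @param pae_max Maximum representable PAE value. Default 31.75.
#' @return A list of class `score_config`.
#' @export
score_config <- function(pae_cutoff = 12, tau_lis = 0.203, tau_lia = 3432,
                         aggregation = c("mean", "max", "best_model"),
                         lia_blocks = c("both", "max"), pae_max = 31.75) {
  pae_cutoff <- check_number(pae_cutoff, "pae_cutoff", min = 0, strict = TRUE)
  pae_max <- check_number(pae_max, "pae_max", min = pae_cutoff)
  structure(
    list(pae_cutoff = pae_cutoff,
         tau_lis = check_number(tau_lis, "tau_lis", min = 0),
         tau_lia = check_number(tau_lia, "tau_lia", min = 0),
         aggregation = match.arg(aggregation),
         lia_blocks = match.arg(lia_blocks),
         pae_max = pae_max),
    class = "score_config")
}

#' Extract the inter-chain PAE values of a two-chain prediction
#'
#' Returns every PAE entry that spans the chain boundary: the A-to-B block
#' (`len_a x len_b`) and the B-to-A block (`len_b x len_a`). Intra-chain
#' entries never contribute, so the result always holds
#' `2 * len_a * len_b` values.
#'
#' @param pred A [pae_prediction()].
#' @return Numeric vector of length `2 * len_a * len_b`.
#' @export
interchain_cells <- function(pred) {
  stopifnot(inherits(pred, "pae_prediction"))
  ia <- seq_len(pred$len_a)
  ib <- pred$len_a + seq_len(pred$len_b)
  c(pred$pae[ia, ib, drop = FALSE], pred$pae[ib, ia, drop = FALSE])
}

# Per-block variant used when lia_blocks = "max": returns list of the two
# off-diagonal blocks as plain vectors.
interchain_blocks <- function(pred) {
  ia <- seq_len(pred$len_a)
  ib <- pred$len_a + seq_len(pred$len_b)
  list(ab = as.vector(pred$pae[ia, ib, drop = FALSE]),
       ba = as.vector(pred$pae[ib, ia, drop = FALSE]))
}

#' Score one AFM model: Local Interaction Score and Area
#'
#' The Local Interaction Area (LIA) is the number of inter-chain residue
#' pairs whose PAE falls strictly below `pae_cutoff`; the Local Interaction
#' Score (LIS) rescales those sub-cutoff errors to confidences,
#' `(pae_cutoff - pae) / pae_cutoff`, and averages them. With no sub-cutoff
#' cell both scores are 0. LIS is always in `[0, 1]`; LIA is bounded by
#' `2 * len_a * len_b` (or `len_a * len_b` when `lia_blocks = "max"`).
#'
#' @param pred A [pae_prediction()].
#' @param config A [score_config()].
#' @return One-row tibble with columns `model_id`, `lis`, `lia`, `iptm`.
#' @examples
#' m <- matrix(30, 4, 4)
#' m[1:2, 3:4] <- c(3, 9, 6, 12)   # A->B block
#' score_model(pae_prediction(m, 2, 2))
#' @export
score_model <- function(pred, config = score_config()) {
  stopifnot(inherits(pred, "pae_prediction"), inherits(config, "score_config"))
  score_block <- function(v) {
    sel <- v[v < config$pae_cutoff]
    list(lia = length(sel),
         lis = if (length(sel)) mean((config$pae_cutoff - sel) / config$pae_cutoff) else 0)
  }
  if (config$lia_blocks == "both") {
    s <- score_block(interchain_cells(pred))
  } else {
    bl <- interchain_blocks(pred)
    sa <- score_block(bl$ab); sb <- score_block(bl$ba)
    s <- if (sa$lia >= sb$lia) sa else sb
  }
  tibble(model_id = pred$model_id, lis = s$lis, lia = as.integer(s$lia),
         iptm = pred$iptm %||% NA_real_)
}

#' Classify a LIS/LIA pair against the retention thresholds
#'
#' A protein pair is called a positive PPI when LIS >= `tau_lis` and
#' LIA >= `tau_lia`, both inclusive. Defaults reproduce the published
#' decision boundary LIS >= 0.203 and LIA >= 3432.
#'
#' @param lis,lia Aggregated scores (vectorised).
#' @param config A [score_config()].
#' @return Logical vector.
#' @examples
#' classify_interaction(0.203, 3432)   # TRUE: inclusive boundary
#' classify_interaction(0.202, 5000)   # FALSE
#' @export
classify_interaction <- function(lis, lia, config = score_config()) {
  stopifnot(is.numeric(lis), is.numeric(lia), inherits(config, "score_config"))
  lis >= config$tau_lis & lia >= config$tau_lia
}

#' Aggregate per-model scores into one interaction score
#'
#' AlphaFold-Multimer emits several models per pair; the screen applies the
#' retention thresholds to the aggregated score. Aggregation `"mean"`
#' averages LIS and LIA across models, `"max"` takes per-field maxima, and
#' `"best_model"` reports the fields of the model with the highest LIS
#' (ties broken by lowest `model_id`).
#'
#' @param per_model Tibble of per-model scores as returned by
#'   [score_model()] (columns `model_id`, `lis`, `lia`, optionally `iptm`).
#' @param config A [score_config()].
#' @param protein_a,protein_b Pair labels carried into the result.
#' @return One-row tibble with columns `protein_a`, `protein_b`, `lis`,
#'   `lia`, `iptm` (mean of available per-model values), `n_models`,
#'   `passed`.
#' @export
aggregate_scores <- function(per_model, config = score_config(),
                             protein_a = NA_character_,
                             protein_b = NA_character_) {
  stopifnot(inherits(config, "score_config"))
  per_model <- as_tibble(per_model)
  if (nrow(per_model) == 0L) {
    abort("No model scores to aggregate: at least one prediction is required.",
          class = "lisnet_missing_prediction")
  }
  if (!all(c("lis", "lia") %in% names(per_model))) {
    abort("`per_model` must have columns `lis` and `lia`.",
          class = "lisnet_format_error")
  }
  iptm_all <- if ("iptm" %in% names(per_model)) per_model$iptm else NA_real_
  iptm <- if (all(is.na(iptm_all))) NA_real_ else mean(iptm_all, na.rm = TRUE)
  agg <- switch(config$aggregation,
    mean = list(lis = mean(per_model$lis), lia = mean(per_model$lia)),
    max = list(lis = max(per_model$lis), lia = max(per_model$lia)),
    best_model = {
      ord <- order(-per_model$lis,
                   if ("model_id" %in% names(per_model))
                     per_model$model_id else seq_len(nrow(per_model)))
      best <- per_model[ord[1L], ]
      list(lis = best$lis, lia = best$lia)
    })
  tibble(protein_a = protein_a, protein_b = protein_b,
         lis = agg$lis, lia = agg$lia, iptm = iptm,
         n_models = nrow(per_model),
         passed = classify_interaction(agg$lis, agg$lia, config))
}

#' Score a protein pair from its prediction files or objects
#'
#' File-level wrapper: parses each AlphaFold-style PAE file (or accepts
#' in-memory [pae_prediction()] objects), scores every model, aggregates
#' and classifies.
#'
#' @param predictions Character vector of PAE file paths (see
#'   [read_pae_prediction()]) or a list of [pae_prediction()] objects.
#' @param config A [score_config()].
#' @inheritParams aggregate_scores
#' @return One-row tibble as from [aggregate_scores()].
#' @export
score_pair <- function(predictions, config = score_config(),
                       protein_a = NA_character_, protein_b = NA_character_) {
  if (is.character(predictions)) {
    predictions <- lapply(predictions, read_pae_prediction)
  }
  if (length(predictions) == 0L) {
    abort("No predictions supplied for this pair.",
          class = "lisnet_missing_prediction")
  }
  if (!all(vapply(predictions, inherits, logical(1), "pae_prediction"))) {
    abort("`predictions` must be file paths or `pae_prediction` objects.",
          class = "lisnet_format_error")
  }
  per_model <- purrr::map_dfr(predictions, score_model, config = config)
  aggregate_scores(per_model, config, protein_a = protein_a,
                   protein_b = protein_b)
}
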