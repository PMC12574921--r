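# AlphaFold-style PAE JSON input/output.
#
# Two dialects circulate for PAE dumps and both are accepted:
#   * "matrix": an object (possibly wrapped in a one-element array) with the
#     full square matrix under `predicted_aligned_error` (or `pae`);
#   * "paired": the legacy AFDB layout with parallel `residue1`, `residue2`
#     and `distance` arrays enumerating every cell.
# Chain lengths are not part of either dialect, so they are carried either
# embedded (`chain_lengths` key, written by write_pae_prediction()), via a
# `<file>.chains.json` sidecar, or passed explicitly.

#' Write a PAE prediction as AlphaFold-style JSON
#'
#' Emits the "matrix" dialect: the square matrix under
#' `predicted_aligned_error`, plus `max_predicted_aligned_error`, the two
#' chain lengths under `chain_lengths`, `model_id` and (when present)
#' `iptm`.
#'
#' @param pred A [pae_prediction()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pae_prediction <- function(pred, path) {
  stopifnot(inherits(pred, "pae_prediction"))
  obj <- list(
    predicted_aligned_error = pred$pae,
    max_predicted_aligned_error = pred$pae_max,
    chain_lengths = c(pred$len_a, pred$len_b),
    model_id = pred$model_id)
  if (!is.null(pred$iptm)) obj$iptm <- pred$iptm
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a PAE prediction from AlphaFold-style JSON
#'
#' Auto-detects the matrix and paired (legacy `residue1`/`residue2`/
#' `distance`) JSON dialects. Chain lengths are taken from the embedded
#' `chain_lengths` key if present, else from a `<path>.chains.json` sidecar
#' (keys `len_a`, `len_b`), else from the `len_a`/`len_b` arguments.
#'
#' @param path PAE JSON file.
#' @param len_a,len_b Chain lengths, required only when neither embedded
#'   nor sidecar lengths exist.
#' @param model_id Model identifier; defaults to the embedded `model_id`
#'   or the file stem.
#' @param verbose Report the detected dialect via [rlang::inform()].
#' @return A [pae_prediction()].
#' @export
read_pae_prediction <- function(path, len_a = NULL, len_b = NULL,
                                model_id = NULL, verbose = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("PAE file not found: %s", path),
          class = "lisnet_format_error")
  }
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort(sprintf("Cannot parse PAE JSON file %s: %s",
                                  path, conditionMessage(e)),
                          class = "lisnet_format_error")
                  })
  # Unwrap the one-element array some AlphaFold dumps use.
  if (is.data.frame(raw) && nrow(raw) == 1L) raw <- as.list(raw[1L, ])
  if (is.list(raw) && is.null(names(raw)) && length(raw) == 1L) raw <- raw[[1L]]

  if (!is.null(raw$predicted_aligned_error) || !is.null(raw$pae)) {
    dialect <- "matrix"
    m <- raw$predicted_aligned_error %||% raw$pae
    if (is.list(m)) m <- do.call(rbind, lapply(m, unlist))
    m <- as.matrix(m)
  } else if (!is.null(raw$residue1) && !is.null(raw$distance)) {
    dialect <- "paired"
    r1 <- unlist(raw$residue1); r2 <- unlist(raw$residue2)
    d <- unlist(raw$distance)
    n <- max(r1, r2)
    if (length(d) != n * n) {
      abort(sprintf("Paired PAE arrays in %s do not cover a full %dx%d matrix.",
                    path, n, n), class = "lisnet_format_error")
    }
    m <- matrix(NA_real_, n, n)
    m[cbind(r1, r2)] <- d
  } else {
    abort(sprintf(
      "File %s is neither a matrix-dialect nor a paired-dialect PAE dump.",
      path), class = "lisnet_format_error")
  }
  if (verbose) inform(sprintf("%s: detected %s-dialect PAE JSON.", path, dialect))

  lens <- raw$chain_lengths
  if (is.null(lens)) {
    sidecar <- paste0(path, ".chains.json")
    if (file.exists(sidecar)) {
      sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      lens <- c(sc$len_a, sc$len_b)
    }
  }
  if (is.null(lens)) lens <- c(len_a, len_b)
  if (length(lens) != 2L || is.null(lens)) {
    abort(sprintf(
      "Chain lengths for %s not found (no embedded record, no sidecar) and not supplied.",
      path), class = "lisnet_format_error")
  }
  pae_max <- raw$max_predicted_aligned_error %||% max(31.75, max(m))
  pae_prediction(m, len_a = lens[[1]], len_b = lens[[2]],
                 model_id = model_id %||% raw$model_id %||%
                   sub("\\.json$", "", basename(path)),
                 iptm = raw$iptm, pae_max = pae_max)
}
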