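#' Simulate a bait-versus-control IP-MS spectral-count table
#'
#' Generates replicate spectral counts for `n_prey` preys in two arms.
#' Control counts are i.i.d. Poisson(`background_rate`); bait counts are
#' Poisson(`background_rate * fold`) for the planted enriched preys and
#' Poisson(`background_rate`) otherwise. An optional negative-binomial
#' `dispersion` (the `size` parameter, smaller = noisier) replaces the
#' Poisson when replicate overdispersion is wanted; the mean structure is
#' unchanged. Fully reproducible from `seed`; the caller's RNG state is
#' untouched.
#'
#' @param n_prey Number of preys; ids are `prey_001`, `prey_002`, ...
#' @param n_replicates Replicates per arm.
#' @param background_rate Expected control spectral count (> 0).
#' @param enriched_prey_ids Prey ids planted as bait-enriched; must be a
#'   subset of the generated ids. Default none.
#' @param fold Planted bait/control ratio for enriched preys (> 1 when any
#'   prey is enriched).
#' @param seed Integer seed.
#' @param dispersion Optional negative-binomial size; `NULL` (default) for
#'   Poisson counts.
#' @return List with `counts` (tibble: `prey_id`, `bait_1..k`,
#'   `control_1..k`) and `truth` (tibble: `prey_id`, `enriched`,
#'   `true_fold`).
#' @examples
#' sim <- simulate_spectral_counts(6, 3, background_rate = 5,
#'                                 enriched_prey_ids = "prey_001",
#'                                 fold = 4, seed = 1)
#' sim$counts
#' @export
simulate_spectral_counts <- function(n_prey, n_replicates, background_rate,
                                     enriched_prey_ids = character(),
                                     fold = 4, seed = 1, dispersion = NULL) {
  n_prey <- check_count(n_prey, "n_prey")
  n_replicates <- check_count(n_replicates, "n_replicates")
  background_rate <- check_number(background_rate, "background_rate",
                                  min = 0, strict = TRUE)
  seed <- check_seed(seed)
  prey_ids <- sprintf("prey_%03d", seq_len(n_prey))
  enriched_prey_ids <- as.character(enriched_prey_ids)
  if (!all(enriched_prey_ids %in% prey_ids)) {
    abort("`enriched_prey_ids` must be a subset of the generated prey ids.",
          class = "lisnet_config_error")
  }
  if (length(enriched_prey_ids) > 0L) {
    fold <- check_number(fold, "fold", min = 1, strict = TRUE)
  }
  if (!is.null(dispersion)) {
    dispersion <- check_number(dispersion, "dispersion", min = 0, strict = TRUE)
  }
  enriched <- prey_ids %in% enriched_prey_ids
  bait_mu <- background_rate * ifelse(enriched, fold, 1)

  draw <- function(n, mu) {
    if (is.null(dispersion)) rpois(n, mu)
    else as.integer(rnbinom(n, size = dispersion, mu = mu))
  }
  counts <- withr::with_seed(seed, {
    bait <- vapply(bait_mu, function(mu) draw(n_replicates, mu),
                   integer(n_replicates))
    ctrl <- vapply(rep(background_rate, n_prey),
                   function(mu) draw(n_replicates, mu), integer(n_replicates))
    # vapply with n_replicates = 1 returns a vector; normalise to matrices
    bait <- matrix(bait, nrow = n_replicates)
    ctrl <- matrix(ctrl, nrow = n_replicates)
    cbind(t(bait), t(ctrl))
  })
  colnames(counts) <- c(sprintf("bait_%d", seq_len(n_replicates)),
                        sprintf("control_%d", seq_len(n_replicates)))
  list(
    counts = dplyr::bind_cols(tibble(prey_id = prey_ids), as_tibble(counts)),
    truth = tibble(prey_id = prey_ids, enriched = enriched,
                   true_fold = ifelse(enriched, fold, 1)))
}
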