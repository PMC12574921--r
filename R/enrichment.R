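#' Bait-versus-control fold change of spectral counts
#'
#' Summarises each arm by the arithmetic mean of its replicate spectral
#' counts and returns `(mean(bait) + pseudocount) / (mean(control) +
#' pseudocount)`. The pseudocount (default 1) keeps the ratio finite when a
#' prey is absent from the controls.
#'
#' @param bait_counts,control_counts Non-negative integer replicate counts
#'   (at least one per arm).
#' @param pseudocount Non-negative constant added to both arm means.
#' @return A single fold change.
#' @examples
#' fold_change(c(10, 14), c(2, 4), pseudocount = 0)  # 4
#' fold_change(6, 0)                                 # 7: pseudocount rescues 0
#' @export
fold_change <- function(bait_counts, control_counts, pseudocount = 1) {
  check_counts_arm(bait_counts, "bait_counts")
  check_counts_arm(control_counts, "control_counts")
  pseudocount <- check_number(pseudocount, "pseudocount", min = 0)
  denom <- mean(control_counts) + pseudocount
  if (denom == 0) {
    abort("Control mean is 0 with pseudocount 0: fold change undefined.",
          class = "lisnet_undefined_ratio")
  }
  (mean(bait_counts) + pseudocount) / denom
}

check_counts_arm <- function(x, name) {
  if (length(x) < 1L || !is.numeric(x) || anyNA(x) ||
      any(x < 0) || any(x != trunc(x))) {
    abort(sprintf("`%s` must be >= 1 non-negative integer replicate counts.",
                  name), class = "lisnet_config_error")
  }
  invisible(x)
}

#' Select the candidate interactome from a spectral-count table
#'
#' Applies the enrichment rule used to seed the structure-prediction
#' screen: a prey is a candidate when its bait-versus-control fold change
#' is *strictly* greater than `min_fold` (default 2, i.e. the ">2-fold"
#' rule). Candidates are ordered by descending fold change, ties broken
#' lexicographically by `prey_id`, so downstream runs are reproducible.
#'
#' @param table Spectral-count table: a data frame with a `prey_id` column
#'   plus bait and control replicate columns. Replicate columns are matched
#'   by the prefixes in `bait_prefix` / `control_prefix` (the layout
#'   written by [simulate_spectral_counts()] and read by
#'   [read_count_table()]).
#' @param min_fold Retention threshold; strict inequality.
#' @param pseudocount Passed to [fold_change()].
#' @param bait_prefix,control_prefix Regular-expression prefixes of the
#'   replicate columns.
#' @return Tibble with columns `prey_id` and `fold_change`, one row per
#'   retained prey, in the canonical order. Zero rows when nothing passes.
#' @examples
#' tab <- tibble::tibble(prey_id = c("p1", "p2"),
#'                       bait_1 = c(20, 3), bait_2 = c(24, 5),
#'                       control_1 = c(4, 4), control_2 = c(4, 4))
#' select_candidates(tab, pseudocount = 0)
#' @export
select_candidates <- function(table, min_fold = 2, pseudocount = 1,
                              bait_prefix = "^bait", control_prefix = "^control") {
  table <- as_tibble(table)
  if (!"prey_id" %in% names(table)) {
    abort("`table` must have a `prey_id` column.", class = "lisnet_format_error")
  }
  if (anyDuplicated(table$prey_id)) {
    abort("`prey_id` values must be unique.", class = "lisnet_format_error")
  }
  min_fold <- check_number(min_fold, "min_fold", min = 0)
  bait_cols <- grep(bait_prefix, names(table), value = TRUE)
  ctrl_cols <- grep(control_prefix, names(table), value = TRUE)
  if (length(bait_cols) < 1L || length(ctrl_cols) < 1L) {
    abort("Need at least one bait and one control replicate column.",
          class = "lisnet_format_error")
  }
  if (nrow(table) == 0L) {
    return(tibble(prey_id = character(), fold_change = numeric()))
  }
  fc <- purrr::map_dbl(seq_len(nrow(table)), function(i) {
    fold_change(as.numeric(table[i, bait_cols]),
                as.numeric(table[i, ctrl_cols]),
                pseudocount = pseudocount)
  })
  tibble(prey_id = table$prey_id, fold_change = fc) |>
    dplyr::filter(.data$fold_change > min_fold) |>
    dplyr::arrange(dplyr::desc(.data$fold_change), .data$prey_id)
}

#' Read / write a spectral-count table
#'
#' Tab-separated layout: `prey_id`, then bait replicate columns
#' (`bait_1..k`) and control replicate columns (`control_1..k`).
#'
#' @param path TSV file path.
#' @return `read_count_table()`: a tibble; `write_count_table()`: `path`,
#'   invisibly.
#' @export
read_count_table <- function(path) {
  as_tibble(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE))
}

#' @rdname read_count_table
#' @param table Count table to write.
#' @export
write_count_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
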