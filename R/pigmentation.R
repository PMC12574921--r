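#' Construct an eye image with measurement masks
#'
#' Bundles an RGB raster with the two user-supplied binary masks the
#' pigmentation assay needs: the eye region and a background reference
#' region. Intensities are on the 0..`max_value` grey scale (255 for 8-bit
#' images). No segmentation is performed; masks come from the user (or the
#' simulator).
#'
#' @param rgb Numeric array `height x width x 3` of channel intensities.
#' @param eye_mask,background_mask Logical matrices of the raster's shape;
#'   non-empty and disjoint.
#' @param genotype Genotype label of the fly.
#' @param fly_id Identifier of the individual fly.
#' @param max_value Intensity ceiling (255 for 8-bit, 65535 for 16-bit).
#' @return An object of class `eye_image`.
#' @export
eye_image <- function(rgb, eye_mask, background_mask, genotype,
                      fly_id = "fly_1", max_value = 255) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    abort("`rgb` must be a height x width x 3 array.",
          class = "lisnet_format_error")
  }
  shape <- dim(rgb)[1:2]
  for (nm in c("eye_mask", "background_mask")) {
    m <- get(nm)
    if (!is.matrix(m) || !is.logical(m) || !all(dim(m) == shape)) {
      abort(sprintf("`%s` must be a logical matrix matching the raster shape.",
                    nm), class = "lisnet_format_error")
    }
    if (!any(m)) {
      abort(sprintf("`%s` is empty: image unusable.", nm),
            class = "lisnet_unusable_image")
    }
  }
  if (any(eye_mask & background_mask)) {
    abort("Eye and background masks overlap.", class = "lisnet_config_error")
  }
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > max_value) {
    abort(sprintf("Intensities must lie in [0, %d].", max_value),
          class = "lisnet_format_error")
  }
  structure(list(rgb = rgb, eye_mask = eye_mask,
                 background_mask = background_mask,
                 genotype = as.character(genotype),
                 fly_id = as.character(fly_id),
                 max_value = max_value),
            class = "eye_image")
}

#' @export
print.eye_image <- function(x, ...) {
  cat(sprintf(
    "<eye_image> %s (%s): %dx%d px, eye mask %d px, background mask %d px\n",
    x$fly_id, x$genotype, dim(x$rgb)[1], dim(x$rgb)[2],
    sum(x$eye_mask), sum(x$background_mask)))
  invisible(x)
}

#' Measure eye pigmentation on the red channel
#'
#' Computes the arithmetic mean red-channel intensity over the eye mask and
#' over the background mask, and the background-corrected value. The
#' default convention subtracts the eye mean *from* the background mean
#' (`background - eye`), so a darker (more pigmented) eye gives a larger
#' corrected value; `"eye_minus_background"` covers the opposite reading.
#' Green and blue channels never enter the measurement.
#'
#' @param image An [eye_image()].
#' @param convention Direction of the background correction.
#' @return One-row tibble: `fly_id`, `genotype`, `eye_mean_red`,
#'   `background_mean_red`, `corrected`.
#' @export
measure_eye <- function(image,
                        convention = c("background_minus_eye",
                                       "eye_minus_background")) {
  stopifnot(inherits(image, "eye_image"))
  convention <- match.arg(convention)
  red <- image$rgb[, , 1]
  eye <- mean(red[image$eye_mask])
  bg <- mean(red[image$background_mask])
  corrected <- if (convention == "background_minus_eye") bg - eye else eye - bg
  tibble(fly_id = image$fly_id, genotype = image$genotype,
         eye_mean_red = eye, background_mean_red = bg, corrected = corrected)
}

#' @rdname measure_eye
#' @param images List of [eye_image()] objects.
#' @return `measure_eyes()`: tibble with one row per image.
#' @export
measure_eyes <- function(images,
                         convention = c("background_minus_eye",
                                        "eye_minus_background")) {
  purrr::map_dfr(images, measure_eye, convention = match.arg(convention))
}

#' Per-genotype pigmentation fold changes versus a control
#'
#' Each genotype's fold change is the ratio of its mean corrected intensity
#' to the control genotype's mean corrected intensity (fold change of group
#' means, the default convention); the mean of per-fly fold changes is
#' reported alongside, with the per-fly values in a list column. The
#' control genotype always maps to fold change 1.
#'
#' @param measurements Tibble from [measure_eyes()] (columns `genotype`,
#'   `corrected`).
#' @param control_genotype Genotype used as the normaliser; must be present
#'   with non-zero mean corrected intensity.
#' @return Tibble: `genotype`, `n`, `mean_corrected`, `fold_change`,
#'   `fold_change_per_fly_mean`, `fly_folds` (list column).
#' @examples
#' m <- tibble::tibble(genotype = rep(c("ctrl", "mut"), each = 2),
#'                     corrected = c(80, 80, 40, 40))
#' pigmentation_fold_changes(m, "ctrl")
#' @export
pigmentation_fold_changes <- function(measurements, control_genotype) {
  measurements <- as_tibble(measurements)
  stopifnot(all(c("genotype", "corrected") %in% names(measurements)))
  ctrl <- measurements$corrected[measurements$genotype == control_genotype]
  if (length(ctrl) == 0L) {
    abort(sprintf("No measurements for control genotype '%s'.",
                  control_genotype), class = "lisnet_config_error")
  }
  ctrl_mean <- mean(ctrl)
  if (ctrl_mean == 0) {
    abort("Control mean corrected intensity is 0: fold change undefined.",
          class = "lisnet_undefined_ratio")
  }
  measurements |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_corrected = mean(.data$corrected),
      fold_change = mean(.data$corrected) / ctrl_mean,
      fold_change_per_fly_mean = mean(.data$corrected / ctrl_mean),
      fly_folds = list(.data$corrected / ctrl_mean),
      .groups = "drop") |>
    dplyr::arrange(.data$genotype != control_genotype, .data$genotype)
}

#' Quantile-free pigmentation plot
#'
#' Box plot of background-corrected red-channel intensity per genotype.
#'
#' @param measurements Tibble from [measure_eyes()].
#' @return A ggplot object.
#' @export
plot_pigmentation <- function(measurements) {
  ggplot2::ggplot(as_tibble(measurements),
                  ggplot2::aes(x = .data$genotype, y = .data$corrected)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "firebrick", alpha = 0.4) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1) +
    ggplot2::labs(x = NULL, y = "Corrected red intensity (background - eye)") +
    ggplot2::theme_bw()
}
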