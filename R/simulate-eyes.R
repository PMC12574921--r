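#' Simulate fly-eye photographs with planted pigmentation
#'
#' Produces square RGB images with a central circular "eye" and a border
#' "background" reference region, disjoint by construction. Red-channel
#' eye pixels are Normal(planted genotype mean, `noise_sd`) clipped to the
#' bit depth; background pixels are Normal(`background_value`, `noise_sd`);
#' green and blue channels are arbitrary constants (they must never affect
#' measurements). With the default background-minus-eye convention the
#' planted corrected intensity of a genotype is
#' `background_value - genotype_intensities[g]`.
#'
#' @param genotype_intensities Named numeric vector: planted mean red value
#'   of the eye per genotype.
#' @param background_value Planted mean red value of the background region.
#' @param noise_sd Pixel noise standard deviation (0 for noiseless images).
#' @param size Image side in pixels (>= 16).
#' @param n_per_genotype Flies imaged per genotype.
#' @param seed Integer seed.
#' @param max_value Intensity ceiling (255 for 8-bit).
#' @return List with `images` (list of [eye_image()]) and `truth` (tibble:
#'   `genotype`, `planted_eye_mean`, `planted_corrected`).
#' @examples
#' sim <- simulate_eye_images(c(ctrl = 40, mut = 120), seed = 3,
#'                            n_per_genotype = 2, noise_sd = 0)
#' measure_eyes(sim$images)
#' @export
simulate_eye_images <- function(genotype_intensities, background_value = 200,
                                noise_sd = 2, size = 48, n_per_genotype = 10,
                                seed = 1, max_value = 255) {
  if (is.null(names(genotype_intensities)) ||
      any(!nzchar(names(genotype_intensities)))) {
    abort("`genotype_intensities` must be a named numeric vector.",
          class = "lisnet_config_error")
  }
  size <- check_count(size, "size")
  if (size < 16) abort("`size` must be >= 16 pixels.",
                       class = "lisnet_config_error")
  n_per_genotype <- check_count(n_per_genotype, "n_per_genotype")
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  seed <- check_seed(seed)
  vals <- c(genotype_intensities, background_value)
  if (any(vals < 0) || any(vals > max_value)) {
    abort(sprintf("Planted intensities must lie in [0, %d].", max_value),
          class = "lisnet_config_error")
  }

  # Central disc (eye) and border frame (background); the frame width and
  # disc radius keep the two regions disjoint at any size >= 16.
  border <- max(2L, size %/% 8L)
  radius <- size / 4
  ctr <- (size + 1) / 2
  dist <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
  eye_mask <- dist <= radius
  bg_mask <- matrix(FALSE, size, size)
  bg_mask[c(seq_len(border), size - seq_len(border) + 1L), ] <- TRUE
  bg_mask[, c(seq_len(border), size - seq_len(border) + 1L)] <- TRUE
  stopifnot(!any(eye_mask & bg_mask))

  clip <- function(x) pmin(pmax(x, 0), max_value)
  images <- list()
  withr::with_seed(seed, {
    for (g in names(genotype_intensities)) {
      for (f in seq_len(n_per_genotype)) {
        red <- matrix(background_value, size, size)
        red[eye_mask] <- clip(rnorm(sum(eye_mask), genotype_intensities[[g]],
                                    noise_sd))
        red[bg_mask] <- clip(rnorm(sum(bg_mask), background_value, noise_sd))
        rgb <- array(0, dim = c(size, size, 3))
        rgb[, , 1] <- red
        rgb[, , 2] <- 60   # constant green/blue: must never affect results
        rgb[, , 3] <- 40
        images[[length(images) + 1L]] <-
          eye_image(rgb, eye_mask, bg_mask, genotype = g,
                    fly_id = sprintf("%s_fly_%02d", g, f),
                    max_value = max_value)
      }
    }
  })
  list(images = images,
       truth = tibble(
         genotype = names(genotype_intensities),
         planted_eye_mean = as.numeric(genotype_intensities),
         planted_corrected = background_value -
           as.numeric(genotype_intensities)))
}

#' Read / write an eye image as PNG with mask PNGs
#'
#' Images are stored as standard RGB PNGs, masks as greyscale PNGs where
#' any non-zero pixel is in the mask. Intensities are rescaled between the
#' 0..`max_value` working scale and PNG's unit scale on the way through.
#'
#' @param image An [eye_image()].
#' @param image_path,eye_mask_path,background_mask_path PNG file paths.
#' @return `write_eye_image()`: paths, invisibly; `read_eye_image()`: an
#'   [eye_image()].
#' @export
write_eye_image <- function(image, image_path, eye_mask_path,
                            background_mask_path) {
  stopifnot(inherits(image, "eye_image"))
  png::writePNG(image$rgb / image$max_value, image_path)
  png::writePNG(image$eye_mask * 1, eye_mask_path)
  png::writePNG(image$background_mask * 1, background_mask_path)
  invisible(c(image_path, eye_mask_path, background_mask_path))
}

#' @rdname write_eye_image
#' @param genotype,fly_id Labels attached to the read image.
#' @param max_value Intensity ceiling of the working scale.
#' @export
read_eye_image <- function(image_path, eye_mask_path, background_mask_path,
                           genotype, fly_id = "fly_1", max_value = 255) {
  rgb <- png::readPNG(image_path)
  if (length(dim(rgb)) == 3L && dim(rgb)[3] == 4L) rgb <- rgb[, , 1:3]
  read_mask <- function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m > 0
  }
  eye_image(rgb * max_value, read_mask(eye_mask_path),
            read_mask(background_mask_path), genotype = genotype,
            fly_id = fly_id, max_value = max_value)
}

#' Measure a batch of images listed in a sample sheet
#'
#' The sheet is a TSV with columns `image`, `eye_mask`, `background_mask`,
#' `genotype` and optionally `fly_id`, one row per photographed fly.
#'
#' @param sheet_path Sample-sheet TSV path; relative image paths are
#'   resolved against the sheet's directory.
#' @inheritParams measure_eye
#' @return Tibble of measurements as from [measure_eyes()].
#' @export
measure_eye_sheet <- function(sheet_path,
                              convention = c("background_minus_eye",
                                             "eye_minus_background")) {
  sheet <- as_tibble(read.delim(sheet_path, stringsAsFactors = FALSE))
  stopifnot(all(c("image", "eye_mask", "background_mask", "genotype") %in%
                  names(sheet)))
  if (!"fly_id" %in% names(sheet)) {
    sheet$fly_id <- sprintf("fly_%03d", seq_len(nrow(sheet)))
  }
  root <- dirname(sheet_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(root, p))
  imgs <- purrr::pmap(sheet, function(image, eye_mask, background_mask,
                                      genotype, fly_id, ...) {
    read_eye_image(resolve(image), resolve(eye_mask),
                   resolve(background_mask), genotype = genotype,
                   fly_id = fly_id)
  })
  measure_eyes(imgs, convention = match.arg(convention))
}
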