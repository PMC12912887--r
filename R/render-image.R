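#' Camera response model for synthetic photographs
#'
#' Maps scene reflectance to raw pixel value. The linear model is
#' `pixel = gain * reflectance + offset`; the gamma model applies the usual
#' power-law encoding `pixel = gain * reflectance^(1/gamma) + offset`
#' (gamma = 1 reduces to linear). The response must be strictly increasing
#' over (0, 1].
#'
#' @param gain,offset linear response parameters (gain > 0).
#' @param gamma encoding exponent (>= 1 typical; 2.2 emulates a consumer
#'   camera's nonlinearity).
#' @return An object of class `camera_model` with a `$response(reflectance)`
#'   function.
#' @export
camera_model <- function(gain = 1, offset = 0, gamma = 1) {
  if (gain <= 0) stop("`gain` must be > 0", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  structure(
    list(gain = gain, offset = offset, gamma = gamma,
         response = function(reflectance) {
           gain * reflectance^(1 / gamma) + offset
         }),
    class = "camera_model"
  )
}

#' Render a flat synthetic photograph with embedded grey standards
#'
#' Builds a single-channel (or multi-channel) image consisting of flat
#' rectangular patches: the background fills the frame, a fish patch sits
#' in the upper half, and one patch per reflectance standard lies along the
#' bottom row. Pixel values are `camera$response(reflectance)` plus
#' optional Gaussian pixel noise. The returned region table uses 0-based,
#' half-open pixel intervals `[x0, x1) x [y0, y1)` so the calibration
#' module can locate every patch.
#'
#' @param fish_reflectance named per-channel reflectance(s) of the fish
#'   patch (a bare scalar renders one channel named `"grey"`).
#' @param background_reflectance per-channel reflectance(s) of the
#'   background, same channels as the fish.
#' @param standards numeric vector of >= 2 distinct nominal standard
#'   reflectances in (0, 1] (assumed spectrally flat: same reflectance in
#'   every channel).
#' @param camera a [camera_model()].
#' @param noise_sd Gaussian pixel noise SD (0 = noiseless).
#' @param width,height image size in pixels.
#' @return List with `image` (array height x width x channels, dimnames on
#'   the channel axis), `channels`, and `regions` (data frame: `region`,
#'   `x0`, `y0`, `x1`, `y1`, `nominal_reflectance` — NA for fish and
#'   background).
#' @export
render_synthetic_image <- function(fish_reflectance, background_reflectance,
                                   standards, camera = camera_model(),
                                   noise_sd = 0, width = 120, height = 90) {
  if (length(standards) < 2L) {
    stop("need at least 2 reflectance standards", call. = FALSE)
  }
  if (anyDuplicated(standards)) {
    stop("duplicate standard reflectances: linearisation underdetermined",
         call. = FALSE)
  }
  if (any(standards <= 0) || any(standards > 1)) {
    stop("standard reflectances must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(names(fish_reflectance))) {
    stopifnot(length(fish_reflectance) == length(background_reflectance))
    names(fish_reflectance) <- names(background_reflectance) <-
      if (length(fish_reflectance) == 1L) "grey" else
        paste0("ch", seq_along(fish_reflectance))
  }
  channels <- names(fish_reflectance)
  img <- array(0, dim = c(height, width, length(channels)),
               dimnames = list(NULL, NULL, channels))

  # patch layout: fish centred in the upper 2/3, standards along the bottom
  fish_box <- c(x0 = floor(width * 0.3), y0 = floor(height * 0.15),
                x1 = floor(width * 0.7), y1 = floor(height * 0.5))
  n_std <- length(standards)
  std_w <- floor(width / (n_std + 1))
  std_boxes <- lapply(seq_len(n_std), function(i) {
    x0 <- floor((i - 0.5) * width / n_std - std_w / 2) + std_w %/% 4
    c(x0 = x0, y0 = floor(height * 0.7), x1 = x0 + std_w %/% 2,
      y1 = floor(height * 0.95))
  })

  fill <- function(img, box, refl_per_channel) {
    for (ch in channels) {
      px <- camera$response(refl_per_channel[[ch]])
      img[(box["y0"] + 1):box["y1"], (box["x0"] + 1):box["x1"], ch] <- px
    }
    img
  }
  for (ch in channels) {
    img[, , ch] <- camera$response(background_reflectance[[ch]])
  }
  img <- fill(img, fish_box, fish_reflectance)
  for (i in seq_len(n_std)) {
    flat <- stats::setNames(rep(standards[i], length(channels)), channels)
    img <- fill(img, std_boxes[[i]], flat)
  }
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
  }
  regions <- rbind(
    data.frame(region = "fish", t(fish_box), nominal_reflectance = NA_real_),
    data.frame(region = "background",
               x0 = 0, y0 = 0, x1 = width, y1 = height,
               nominal_reflectance = NA_real_),
    do.call(rbind, lapply(seq_len(n_std), function(i) {
      data.frame(region = sprintf("standard_%02d", i), t(std_boxes[[i]]),
                 nominal_reflectance = standards[i])
    }))
  )
  rownames(regions) <- NULL
  list(image = img, channels = channels, regions = regions)
}

#' Write and read a synthetic image with its region sidecar
#'
#' The image is written as PNG (values clipped to `[0, 1]`) and the region
#' annotations as a JSON sidecar (`<path>.regions.json`) holding the patch
#' bounding boxes in 0-based, half-open pixel coordinates together with the
#' channel order.
#'
#' @param rendered a list as returned by [render_synthetic_image()].
#' @param path output PNG path.
#' @return `path`, invisibly (`write_synthetic_image`); a rendered-image
#'   list (`read_synthetic_image`). PNG quantises to 8-bit, so round trips
#'   are exact only to ~1/255; analyses that need exact values should stay
#'   with the in-memory arrays or CSV tables.
#' @export
write_synthetic_image <- function(rendered, path) {
  img <- pmin(pmax(rendered$image, 0), 1)
  # writePNG wants HxW (grey) or HxWx{2,3,4}
  if (dim(img)[3] == 1L) img <- img[, , 1]
  png::writePNG(img, path)
  sidecar <- list(channels = rendered$channels, regions = rendered$regions)
  jsonlite::write_json(sidecar, paste0(path, ".regions.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_synthetic_image
#' @export
read_synthetic_image <- function(path) {
  raw <- png::readPNG(path)
  sidecar <- jsonlite::read_json(paste0(path, ".regions.json"),
                                 simplifyVector = TRUE)
  channels <- sidecar$channels
  if (length(dim(raw)) == 2L) {
    img <- array(raw, dim = c(dim(raw), 1L),
                 dimnames = list(NULL, NULL, channels))
  } else {
    img <- raw
    dimnames(img) <- list(NULL, NULL, channels)
  }
  list(image = img, channels = channels, regions = sidecar$regions)
}
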