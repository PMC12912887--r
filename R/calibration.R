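#' Reflectance standards that accompany each background
#'
#' Each photograph carries two grey standards chosen to bracket the
#' expected reflectances in the scene: 4.88% and 41.73% for every
#' background except white, which carries 41.73% and 98.24%.
#'
#' @param background background label (`"white"` selects the bright pair).
#' @return Numeric vector of two nominal reflectances (fractions).
#' @examples
#' standards_for_background("white") # 0.4173 0.9824
#' standards_for_background("black") # 0.0488 0.4173
#' @export
standards_for_background <- function(background) {
  if (identical(background, "white")) c(0.4173, 0.9824) else c(0.0488, 0.4173)
}

#' Fit a per-channel pixel-to-reflectance linearisation
#'
#' Uses the grey standards embedded in a photograph to estimate, per
#' channel, the map from raw pixel value to scene reflectance — the
#' calibration step that turns arbitrary camera responses into linear
#' reflectance images. Two models are available:
#'
#' * `linear`: `reflectance = a + b * pixel`. With exactly two standards
#'   this is the exact two-point solution; with more, ordinary least
#'   squares.
#' * `power`: `reflectance = a * (pixel - c)^g`, fitted by least squares
#'   ([stats::nls()] with a log-log start), requiring >= 3 standards.
#'   Suited to gamma-encoded cameras.
#'
#' The fitted map must be strictly increasing over the observed pixel
#' range; standards whose pixel means decrease with nominal reflectance
#' trigger a monotonicity error, and coincident pixel means a
#' degenerate-fit error.
#'
#' @param rendered image list (`$image`, `$channels`, `$regions`) as
#'   returned by [render_synthetic_image()] / [read_synthetic_image()];
#'   standard regions are the rows of `$regions` with a non-missing
#'   `nominal_reflectance`.
#' @param model `"linear"` or `"power"`.
#' @return Object of class `channel_linearisation`: per-channel parameter
#'   list plus a `predict(lin, pixel, channel)` method.
#' @export
fit_channel_linearisation <- function(rendered, model = c("linear", "power")) {
  model <- match.arg(model)
  regions <- rendered$regions
  std <- regions[!is.na(regions$nominal_reflectance), , drop = FALSE]
  if (nrow(std) < 2L) {
    stop("need at least 2 standard regions", call. = FALSE)
  }
  if (anyDuplicated(std$nominal_reflectance)) {
    stop("duplicate standard reflectances: linearisation underdetermined",
         call. = FALSE)
  }
  if (model == "power" && nrow(std) < 3L) {
    stop("the power model needs >= 3 standards", call. = FALSE)
  }
  channels <- rendered$channels
  fits <- lapply(channels, function(ch) {
    px <- vapply(seq_len(nrow(std)), function(i) {
      roi_mean(rendered$image, std[i, ], ch)
    }, numeric(1))
    refl <- std$nominal_reflectance
    o <- order(refl)
    px <- px[o]; refl <- sort(refl)
    if (any(diff(px) == 0)) {
      stop("identical standard pixel means in channel ", ch,
           ": degenerate fit", call. = FALSE)
    }
    if (any(diff(px) < 0)) {
      stop("pixel value decreases with reflectance in channel ", ch,
           ": non-monotone response", call. = FALSE)
    }
    if (model == "linear") {
      if (length(px) == 2L) {
        b <- diff(refl) / diff(px)
        a <- refl[1] - b * px[1]
      } else {
        co <- stats::coef(stats::lm(refl ~ px))
        a <- co[[1]]; b <- co[[2]]
      }
      list(model = "linear", a = a, b = b, pixel_range = range(px))
    } else {
      # start from a log-log line through the data (assumes c ~ 0); if the
      # start already fits to machine precision (pure power camera), keep
      # it — nls would only report a singular gradient at the optimum
      ll <- stats::coef(stats::lm(log(refl) ~ log(px)))
      st <- list(a = exp(ll[[1]]), g = ll[[2]], c = 0)
      if (max(abs(st$a * px^st$g - refl)) < 1e-10) {
        p <- st
      } else {
        fit <- stats::nls(refl ~ a * (px - c)^g, start = st,
                          control = stats::nls.control(maxiter = 200,
                                                       warnOnly = TRUE))
        p <- as.list(stats::coef(fit))
      }
      list(model = "power", a = p$a, g = p$g, c = p$c, pixel_range = range(px))
    }
  })
  names(fits) <- channels
  lin <- structure(list(fits = fits, channels = channels),
                   class = "channel_linearisation")
  # round-trip check: fitted map must reproduce the standards it was fit on
  for (ch in channels) {
    px <- vapply(seq_len(nrow(std)), function(i) {
      roi_mean(rendered$image, std[i, ], ch)
    }, numeric(1))
    err <- abs(predict(lin, px, ch) - std$nominal_reflectance)
    tol <- if (model == "linear" && nrow(std) == 2L) 1e-9 else 0.02
    if (max(err) > tol) {
      warning("linearisation round-trip error ", signif(max(err), 3),
              " in channel ", ch, call. = FALSE)
    }
  }
  lin
}

#' @param object a `channel_linearisation`.
#' @param pixel raw pixel value(s).
#' @param channel channel name.
#' @param ... unused.
#' @rdname fit_channel_linearisation
#' @export
predict.channel_linearisation <- function(object, pixel, channel, ...) {
  f <- object$fits[[channel]]
  if (is.null(f)) stop("unknown channel: ", channel, call. = FALSE)
  if (f$model == "linear") {
    f$a + f$b * pixel
  } else {
    f$a * (pmax(pixel - f$c, 0))^f$g
  }
}

#' Apply a fitted linearisation to a whole image
#'
#' Converts every pixel to calibrated reflectance. Values outside
#' `[0, 1.2]` (noise can push flat patches past their nominal value) are
#' clipped with a warning rather than treated as errors.
#'
#' @inheritParams fit_channel_linearisation
#' @param lin a fitted `channel_linearisation`.
#' @return The rendered list with `$image` replaced by calibrated
#'   reflectances and `$calibrated = TRUE`.
#' @export
apply_linearisation <- function(rendered, lin) {
  img <- rendered$image
  for (ch in rendered$channels) {
    img[, , ch] <- predict(lin, img[, , ch], ch)
  }
  n_out <- sum(img < 0 | img > 1.2)
  if (n_out > 0) {
    warning(n_out, " calibrated pixel(s) outside [0, 1.2]; clipped",
            call. = FALSE)
    img <- pmin(pmax(img, 0), 1.2)
  }
  rendered$image <- img
  rendered$calibrated <- TRUE
  rendered
}

roi_mean <- function(image, box, channel) {
  if (box$x0 < 0 || box$y0 < 0 ||
      box$x1 > dim(image)[2] || box$y1 > dim(image)[1] ||
      box$x1 <= box$x0 || box$y1 <= box$y0) {
    stop("region out of image bounds or empty", call. = FALSE)
  }
  mean(image[(box$y0 + 1):box$y1, (box$x0 + 1):box$x1, channel])
}

#' Measure a region of interest
#'
#' Arithmetic mean pixel value per channel over a rectangular region
#' (0-based, half-open bounds), with the pixel count.
#'
#' @inheritParams fit_channel_linearisation
#' @param region either a region label present in `rendered$regions` or a
#'   list/one-row data frame with `x0`, `y0`, `x1`, `y1`.
#' @return Data frame with one row per channel: `region`, `channel`,
#'   `mean_reflectance`, `n_pixels`.
#' @export
measure_roi <- function(rendered, region) {
  if (is.character(region)) {
    hit <- rendered$regions[rendered$regions$region == region, , drop = FALSE]
    if (nrow(hit) != 1L) stop("unknown region: ", region, call. = FALSE)
    label <- region
    box <- hit
  } else {
    label <- if (!is.null(region$region)) region$region else "roi"
    box <- region
  }
  n_px <- (box$x1 - box$x0) * (box$y1 - box$y0)
  out <- lapply(rendered$channels, function(ch) {
    data.frame(region = label, channel = ch,
               mean_reflectance = roi_mean(rendered$image, box, ch),
               n_pixels = n_px)
  })
  do.call(rbind, out)
}

#' Midpoint-grey acclimation target
#'
#' Given the measured reflectances of the black and white papers, the
#' acclimation substrate should reflect their midpoint. The printed grey
#' that achieves it is found by searching a monotone printer curve (RGB
#' level to measured reflectance) for the level whose output is nearest the
#' target — the single-pass equivalent of iteratively printing and
#' re-measuring refined greyscale grids. Ties go to the lower level.
#'
#' @param black_reflectance,white_reflectance measured paper reflectances,
#'   fractions with `0 < black < white < 1` (equal values are allowed and
#'   return the common value).
#' @param printer_curve optional data frame with columns `level` (integer
#'   RGB value) and `reflectance`, strictly increasing in `reflectance`;
#'   when omitted only the target is returned.
#' @return List with `target_reflectance` and (when a curve is supplied)
#'   `rgb_level` and `printed_reflectance`.
#' @examples
#' midpoint_grey_target(0.059, 0.855)$target_reflectance # 0.457
#' @export
midpoint_grey_target <- function(black_reflectance, white_reflectance,
                                 printer_curve = NULL) {
  if (black_reflectance <= 0 || white_reflectance >= 1 ||
      black_reflectance > white_reflectance) {
    stop("need 0 < black <= white < 1", call. = FALSE)
  }
  target <- (black_reflectance + white_reflectance) / 2
  out <- list(target_reflectance = target)
  if (!is.null(printer_curve)) {
    stopifnot(all(c("level", "reflectance") %in% names(printer_curve)))
    pc <- printer_curve[order(printer_curve$level), , drop = FALSE]
    if (is.unsorted(pc$reflectance, strictly = TRUE)) {
      stop("printer curve must be strictly increasing in reflectance",
           call. = FALSE)
    }
    err <- abs(pc$reflectance - target)
    i <- which(err == min(err))[1L]  # ties -> lower level
    out$rgb_level <- pc$level[i]
    out$printed_reflectance <- pc$reflectance[i]
  }
  out
}
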