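#' Map camera-channel reflectances to cone catches
#'
#' Multiplies a receptor-by-channel coefficient matrix into the per-channel
#' reflectances of a region, yielding quantum catches for the SW, MW and LW
#' single cones and the double cone (`dbl`). The mapping matrix is
#' user-supplied: it encodes the receiver- and camera-specific conversion
#' from calibrated camera responses to receptor space, and no particular
#' coefficients are assumed.
#'
#' @param reflectance named numeric vector of per-channel reflectances
#'   (names must match `colnames(transform)`).
#' @param transform numeric matrix with rows named `SW`, `MW`, `LW`, `dbl`
#'   and one column per camera channel.
#' @return Named numeric vector of catches `q_SW`, `q_MW`, `q_LW`, `q_dbl`.
#'   All catches must come out strictly positive; a non-positive catch is a
#'   data error and aborts with the offending receptor named.
#' @examples
#' tr <- camera_to_cone_identity(c("R", "G", "B"))
#' map_camera_to_cones(c(R = 0.2, G = 0.2, B = 0.2), tr)
#' @export
map_camera_to_cones <- function(reflectance, transform) {
  receptors <- c("SW", "MW", "LW", "dbl")
  if (!is.matrix(transform) || !all(receptors %in% rownames(transform))) {
    stop("`transform` must be a matrix with rows SW, MW, LW, dbl",
         call. = FALSE)
  }
  if (is.null(names(reflectance)) ||
      !setequal(names(reflectance), colnames(transform))) {
    stop("channel names of `reflectance` must match transform columns",
         call. = FALSE)
  }
  q <- drop(transform[receptors, names(reflectance), drop = FALSE] %*%
              reflectance)
  if (any(!is.finite(q)) || any(q <= 0)) {
    bad <- receptors[!is.finite(q) | q <= 0]
    stop("non-positive cone catch for receptor(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  names(q) <- paste0("q_", receptors)
  q
}

#' Identity-like camera-to-cone mapping
#'
#' Maps three camera channels one-to-one onto LW, MW and SW (long to short
#' wavelength order R, G, B) and sets the double cone to their mean. Used by
#' the synthetic pipeline so the receptor-space math downstream is fully
#' exercised without asserting any real camera's coefficients.
#'
#' @param channels character vector of three channel names, longest
#'   wavelength first.
#' @return A 4 x 3 coefficient matrix suitable for [map_camera_to_cones()].
#' @export
camera_to_cone_identity <- function(channels = c("R", "G", "B")) {
  stopifnot(length(channels) == 3L)
  m <- rbind(
    SW  = c(0, 0, 1),
    MW  = c(0, 1, 0),
    LW  = c(1, 0, 0),
    dbl = c(1, 1, 1) / 3
  )
  colnames(m) <- channels
  m
}

#' Luminance of a stimulus
#'
#' Luminance is taken directly as the double-cone quantum catch: in the
#' avian model the double cone is assumed to mediate achromatic vision, so
#' no further transformation is applied.
#'
#' @param q_dbl double-cone quantum catch (> 0), or a named catch vector
#'   containing `q_dbl`.
#' @return The double-cone catch, unchanged.
#' @export
luminance <- function(q_dbl) {
  if (is.null(names(q_dbl))) {
    if (length(q_dbl) != 1L) {
      stop("`q_dbl` must be a single catch or a named catch vector",
           call. = FALSE)
    }
    v <- q_dbl
  } else {
    if (!"q_dbl" %in% names(q_dbl)) {
      stop("catch vector lacks the double-cone catch `q_dbl`", call. = FALSE)
    }
    v <- q_dbl[["q_dbl"]]
  }
  if (!is.finite(v) || v <= 0) {
    stop("double-cone catch must be finite and > 0", call. = FALSE)
  }
  v
}

#' Standardise single-cone catches to sum-to-one fractions
#'
#' Removes overall intensity by dividing each single-cone catch by the sum
#' of the three, so that the result lives on the unit simplex. Vectorised
#' over records.
#'
#' @param q_LW,q_MW,q_SW single-cone quantum catches (> 0). `q_LW` may also
#'   be a named vector containing all three.
#' @return A list with numeric components `s_LW`, `s_MW`, `s_SW` summing to
#'   one per record.
#' @examples
#' standardise_catches(2, 1, 1) # 0.50, 0.25, 0.25
#' @export
standardise_catches <- function(q_LW, q_MW = NULL, q_SW = NULL) {
  if (is.null(q_MW) && !is.null(names(q_LW))) {
    q <- q_LW
    q_LW <- q[["q_LW"]]; q_MW <- q[["q_MW"]]; q_SW <- q[["q_SW"]]
  }
  tot <- q_LW + q_MW + q_SW
  if (any(!is.finite(tot)) || any(tot <= 0)) {
    stop("sum of single-cone catches must be finite and > 0", call. = FALSE)
  }
  list(s_LW = q_LW / tot, s_MW = q_MW / tot, s_SW = q_SW / tot)
}

#' Trichromatic colour-space coordinates
#'
#' Maps sum-to-one standardised catches into the Cartesian coordinates of
#' the trichromatic (Maxwell-triangle) colour space:
#' \deqn{x = \sqrt{1/2}\,(s_{LW} - s_{MW}), \quad
#'       y = \sqrt{2/3}\,\left(s_{SW} - \frac{s_{LW} + s_{MW}}{2}\right).}
#' The achromatic point (1/3, 1/3, 1/3) maps to the origin and the three
#' pure-catch vertices are equidistant from it at \eqn{\sqrt{2/3}}.
#'
#' @param s_LW,s_MW,s_SW standardised catches (or a list/vector with those
#'   names as the first argument). Vectorised.
#' @return List with numeric components `x` and `y`.
#' @export
colour_space_xy <- function(s_LW, s_MW = NULL, s_SW = NULL) {
  if (is.null(s_MW) && (is.list(s_LW) || !is.null(names(s_LW)))) {
    s <- s_LW
    s_LW <- s[["s_LW"]]; s_MW <- s[["s_MW"]]; s_SW <- s[["s_SW"]]
  }
  list(
    x = sqrt(1 / 2) * (s_LW - s_MW),
    y = sqrt(2 / 3) * (s_SW - (s_LW + s_MW) / 2)
  )
}

#' Saturation: distance from the achromatic centre
#'
#' @param x,y colour-space coordinates (or a list with components `x`, `y`
#'   as the first argument). Vectorised.
#' @return Non-negative saturation \eqn{\sqrt{x^2 + y^2}}.
#' @export
saturation <- function(x, y = NULL) {
  if (is.null(y) && is.list(x)) {
    y <- x[["y"]]; x <- x[["x"]]
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("colour-space coordinates must be finite", call. = FALSE)
  }
  sqrt(x^2 + y^2)
}

#' Hue: signed medium-wave contrast
#'
#' Hue is the difference between the standardised medium-wave catch and the
#' mean of the longer- and shorter-wave catches,
#' \eqn{h = s_{MW} - (s_{LW} + s_{SW})/2}. It is a signed scalar in
#' \eqn{[-1/2, 1]}, not an angle: 0 means the stimulus is achromatic with
#' equal catches in all three channels; positive values are green-shifted,
#' negative values shifted toward the spectrum ends. Under the sum-to-one
#' constraint it is algebraically equal to \eqn{1.5\,s_{MW} - 0.5}.
#'
#' @inheritParams colour_space_xy
#' @return Numeric hue value(s).
#' @export
hue <- function(s_LW, s_MW = NULL, s_SW = NULL) {
  if (is.null(s_MW) && (is.list(s_LW) || !is.null(names(s_LW)))) {
    s <- s_LW
    s_LW <- s[["s_LW"]]; s_MW <- s[["s_MW"]]; s_SW <- s[["s_SW"]]
  }
  s_MW - (s_LW + s_SW) / 2
}

#' Compute all colour metrics for a cone-catch table
#'
#' Adds standardised catches, colour-space coordinates, luminance, hue and
#' saturation to a long-format table of cone-catch records (columns `q_SW`,
#' `q_MW`, `q_LW`, `q_dbl`).
#'
#' @param table data frame with catch columns `q_SW`, `q_MW`, `q_LW`,
#'   `q_dbl`, all strictly positive.
#' @return The table with columns `s_SW`, `s_MW`, `s_LW`, `x`, `y`,
#'   `luminance`, `hue`, `saturation` appended.
#' @export
add_colour_metrics <- function(table) {
  need <- c("q_SW", "q_MW", "q_LW", "q_dbl")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("table lacks catch column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- !stats::complete.cases(table[need]) |
    Reduce(`|`, lapply(table[need], function(q) q <= 0))
  if (any(bad)) {
    stop("non-positive or missing cone catch in row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  s  <- standardise_catches(table$q_LW, table$q_MW, table$q_SW)
  xy <- colour_space_xy(s)
  table$s_SW <- s$s_SW
  table$s_MW <- s$s_MW
  table$s_LW <- s$s_LW
  table$x <- xy$x
  table$y <- xy$y
  table$luminance  <- table$q_dbl
  table$hue        <- hue(s)
  table$saturation <- saturation(xy)
  table
}
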