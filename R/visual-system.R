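#' Define a receiver visual system
#'
#' A visual system bundles everything the receptor-noise-limited (RNL)
#' machinery needs about the receiver: the relative densities of the three
#' single-cone classes (short-, medium- and long-wave sensitive), the Weber
#' fraction of the reference (most abundant) cone, and the Weber fraction of
#' the achromatic double-cone channel.
#'
#' Receptor noise for the non-reference cones is propagated from the
#' reference cone by the square-root density ratio rule
#' \eqn{e_i = \sqrt{\eta_{ref} / \eta_i} \, e_{ref}}: rarer cone classes are
#' noisier in proportion to the square root of their relative scarcity.
#'
#' @param densities named numeric vector of relative cone densities with
#'   names `SW`, `MW`, `LW`. Only ratios matter; any common rescaling gives
#'   identical noises.
#' @param weber_ref Weber fraction of the reference cone (in (0, 1)).
#' @param reference name of the reference cone class (default `"MW"`, the
#'   most abundant class in the peafowl retina).
#' @param weber_achro Weber fraction of the achromatic (double-cone)
#'   channel, used for luminance JNDs.
#' @return An object of class `visual_system`: a list with elements
#'   `densities`, `reference`, `weber_ref`, `weber_achro` and `noise`
#'   (named numeric vector `SW`, `MW`, `LW` of propagated Weber fractions,
#'   carried at full precision).
#' @examples
#' vs <- visual_system(c(SW = 1.9, MW = 2.2, LW = 2.1),
#'                     weber_ref = 0.06, weber_achro = 0.2)
#' weber_4dp(vs$noise) # SW 0.0645, MW 0.0600, LW 0.0614
#' @seealso [peafowl_visual_system()] for the ready-made peafowl model,
#'   [receptor_noise()] for the propagation rule alone.
#' @export
visual_system <- function(densities, weber_ref, reference = "MW",
                          weber_achro = 0.2) {
  cones <- c("SW", "MW", "LW")
  if (!is.numeric(densities) || is.null(names(densities)) ||
      !setequal(names(densities), cones)) {
    stop("`densities` must be a numeric vector named SW, MW, LW", call. = FALSE)
  }
  densities <- densities[cones]
  if (any(!is.finite(densities)) || any(densities <= 0)) {
    stop("cone densities must be finite and > 0", call. = FALSE)
  }
  if (!reference %in% cones) {
    stop("`reference` must be one of SW, MW, LW", call. = FALSE)
  }
  for (w in c(weber_ref, weber_achro)) {
    if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0 || w >= 1) {
      stop("Weber fractions must be single numbers in (0, 1)", call. = FALSE)
    }
  }
  structure(
    list(
      densities   = densities,
      reference   = reference,
      weber_ref   = weber_ref,
      weber_achro = weber_achro,
      noise       = receptor_noise(densities, weber_ref, reference)
    ),
    class = "visual_system"
  )
}

#' Propagate receptor noise from the reference cone
#'
#' Applies \eqn{e_i = \sqrt{\eta_{ref} / \eta_i} \, e_{ref}} to every cone
#' class. The reference cone's own noise is returned unchanged. The rule is
#' homogeneous in the densities: scaling all densities by a common factor
#' leaves every noise untouched.
#'
#' @inheritParams visual_system
#' @return Named numeric vector of Weber fractions, one per cone class, in
#'   the order of `densities`.
#' @examples
#' receptor_noise(c(SW = 1.9, MW = 2.2, LW = 2.1), 0.06)
#' @export
receptor_noise <- function(densities, weber_ref, reference = "MW") {
  if (any(!is.finite(densities)) || any(densities <= 0)) {
    stop("cone densities must be finite and > 0", call. = FALSE)
  }
  if (!reference %in% names(densities)) {
    stop("reference cone '", reference, "' not found in `densities`",
         call. = FALSE)
  }
  sqrt(densities[[reference]] / densities) * weber_ref
}

#' Display a Weber fraction at the conventional 4-decimal precision
#'
#' Weber fractions are customarily reported to four decimal places by
#' truncation toward zero (the peafowl SW noise 0.064563... is reported as
#' 0.0645). Computation always carries full precision; this helper is for
#' display and reporting only.
#'
#' @param e Weber fraction(s).
#' @return `e` truncated to 4 decimal places.
#' @examples
#' weber_4dp(receptor_noise(c(SW = 1.9, MW = 2.2, LW = 2.1), 0.06))
#' @export
weber_4dp <- function(e) {
  trunc(e * 1e4) / 1e4
}

#' The trichromatic peafowl visual model
#'
#' Convenience constructor for the avian receiver used throughout the
#' pipeline: peafowl (*Pavo cristatus*) single-cone densities
#' SW 1.9 : MW 2.2 : LW 2.1, a Weber fraction of 0.06 for the most abundant
#' (MW) cone, and 0.2 for the achromatic double-cone channel. The
#' propagated noises are SW 0.0645, MW 0.06, LW 0.0614 at the conventional
#' 4-decimal display precision (see [weber_4dp()]).
#'
#' @return A [visual_system()] object.
#' @examples
#' weber_4dp(peafowl_visual_system()$noise)
#' @export
peafowl_visual_system <- function() {
  visual_system(c(SW = 1.9, MW = 2.2, LW = 2.1),
                weber_ref = 0.06, reference = "MW", weber_achro = 0.2)
}

#' @export
print.visual_system <- function(x, ...) {
  cat("Trichromatic visual system (reference cone:", x$reference, ")\n")
  cat("  densities:  ",
      paste(names(x$densities), sprintf("%.3g", x$densities),
            collapse = " : "), "\n")
  cat("  cone noise: ",
      paste(names(x$noise), sprintf("%.4f", weber_4dp(x$noise)),
            collapse = ", "), "\n")
  cat("  achromatic Weber fraction:", format(x$weber_achro), "\n")
  invisible(x)
}

#' Measured hue of the printed chromatic backgrounds
#'
#' Average hue values of the beige, brown and green printed backgrounds as
#' measured through the peafowl model. These are measured reference values
#' for labelling plots and orienting hue trajectories, not recomputable
#' quantities.
#'
#' @format Named numeric vector with entries `beige`, `brown`, `green`.
#' @export
background_hue_reference <- c(beige = 0.005, brown = 0.015, green = 0.075)
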