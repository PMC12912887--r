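#' Achromatic just-noticeable difference
#'
#' Receptor-noise-limited achromatic distance between two stimuli seen
#' through the double-cone channel, in the log-contrast form of the
#' Weber-fraction RNL model:
#' \deqn{\Delta L = \left| \ln(q_a / q_b) \right| / e_{dbl}.}
#' One JND is the contrast at which the receiver can just tell the stimuli
#' apart; the paper-cited equations are not printed in the source study, so
#' this is the standard log-linear form of the cited model.
#'
#' @param q_dbl_a,q_dbl_b double-cone catches of the two stimuli (> 0).
#'   Vectorised.
#' @param e_dbl achromatic Weber fraction (default 0.2).
#' @return Non-negative \eqn{\Delta L}, symmetric in its arguments and zero
#'   iff the catches are equal.
#' @examples
#' achromatic_jnd(1, exp(0.2)) # exactly 1 JND
#' @export
achromatic_jnd <- function(q_dbl_a, q_dbl_b, e_dbl = 0.2) {
  if (any(!is.finite(q_dbl_a)) || any(!is.finite(q_dbl_b)) ||
      any(q_dbl_a <= 0) || any(q_dbl_b <= 0)) {
    stop("double-cone catches must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(e_dbl) || e_dbl <= 0) {
    stop("achromatic Weber fraction must be > 0", call. = FALSE)
  }
  abs(log(q_dbl_a / q_dbl_b)) / e_dbl
}

#' Chromatic just-noticeable difference (trichromatic RNL model)
#'
#' Receptor-noise-limited chromatic distance between two stimuli for a
#' trichromatic receiver, using log receptor contrasts
#' \eqn{\Delta f_i = \ln(q_i^a / q_i^b)}:
#' \deqn{\Delta S^2 = \frac{e_{SW}^2 (\Delta f_{LW} - \Delta f_{MW})^2 +
#'   e_{MW}^2 (\Delta f_{LW} - \Delta f_{SW})^2 +
#'   e_{LW}^2 (\Delta f_{SW} - \Delta f_{MW})^2}
#'   {(e_{SW} e_{MW})^2 + (e_{SW} e_{LW})^2 + (e_{MW} e_{LW})^2}.}
#' Because only differences of the \eqn{\Delta f_i} enter, the distance is
#' invariant to a common rescaling of either stimulus's three catches
#' (intensity-free) and equals the noise-weighted distance of the two
#' stimuli in log receptor space orthogonal to the intensity direction.
#'
#' @param catch_a,catch_b named catch vectors (`q_SW`, `q_MW`, `q_LW`; a
#'   `q_dbl` element is ignored), or lists/data frames of such columns for
#'   vectorised use.
#' @param noises named numeric vector of cone Weber fractions `SW`, `MW`,
#'   `LW`, e.g. `peafowl_visual_system()$noise`.
#' @return Non-negative \eqn{\Delta S}, symmetric, zero iff the two
#'   stimuli's log contrasts agree across receptors up to a common shift.
#' @examples
#' vs <- peafowl_visual_system()
#' chromatic_jnd(c(q_SW = 1, q_MW = 1, q_LW = 1),
#'               c(q_SW = 1, q_MW = 1, q_LW = 1.1), vs$noise)
#' @export
chromatic_jnd <- function(catch_a, catch_b, noises) {
  get_q <- function(catch, r) {
    nm <- paste0("q_", r)
    if (!nm %in% names(catch)) {
      stop("catch lacks component ", nm, call. = FALSE)
    }
    catch[[nm]]
  }
  if (!all(c("SW", "MW", "LW") %in% names(noises))) {
    stop("`noises` must be named SW, MW, LW", call. = FALSE)
  }
  e <- noises[c("SW", "MW", "LW")]
  if (any(!is.finite(e)) || any(e <= 0)) {
    stop("cone noises must be finite and > 0", call. = FALSE)
  }
  qa <- lapply(c("SW", "MW", "LW"), get_q, catch = catch_a)
  qb <- lapply(c("SW", "MW", "LW"), get_q, catch = catch_b)
  ok <- function(q) all(is.finite(q)) && all(q > 0)
  if (!all(vapply(c(qa, qb), ok, logical(1)))) {
    stop("cone catches must be finite and > 0", call. = FALSE)
  }
  df_SW <- log(qa[[1]] / qb[[1]])
  df_MW <- log(qa[[2]] / qb[[2]])
  df_LW <- log(qa[[3]] / qb[[3]])
  e_SW <- e[["SW"]]; e_MW <- e[["MW"]]; e_LW <- e[["LW"]]
  num <- e_SW^2 * (df_LW - df_MW)^2 +
         e_MW^2 * (df_LW - df_SW)^2 +
         e_LW^2 * (df_SW - df_MW)^2
  den <- (e_SW * e_MW)^2 + (e_SW * e_LW)^2 + (e_MW * e_LW)^2
  sqrt(num / den)
}

#' Classify a JND value into detectability bands
#'
#' Interprets an RNL distance against the conventional thresholds: below
#' 1 JND the two stimuli are indistinguishable to the modelled receiver;
#' between 1 and 3 JNDs they may be detectable under good viewing
#' conditions ("conditional"); above 3 JNDs they are increasingly
#' distinguishable. The boundary values 1 and 3 fall in the conditional
#' band.
#'
#' @param jnd non-negative JND value(s).
#' @return Factor with levels `indistinguishable`, `conditional`,
#'   `distinguishable`.
#' @examples
#' classify_detectability(c(0.5, 2, 5))
#' @export
classify_detectability <- function(jnd) {
  if (any(!is.finite(jnd)) || any(jnd < 0)) {
    stop("JND values must be finite and >= 0", call. = FALSE)
  }
  cut(jnd, breaks = c(-Inf, 1, 3, Inf),
      labels = c("indistinguishable", "conditional", "distinguishable"),
      right = FALSE,
      include.lowest = TRUE) -> cats
  # "between 1 to 3" is inclusive on both ends: move exact 3s back into the
  # conditional band (cut() with right = FALSE puts 3 in the upper band)
  cats[jnd == 3] <- "conditional"
  cats
}

#' Score fish-versus-background discriminability for a metrics table
#'
#' For every fish row, computes the achromatic and chromatic JNDs against
#' that fish's own test background and classifies chromatic detectability.
#' The background is measured once, at minute 0, and that measurement is
#' reused for all later time points of the same fish, mirroring a design
#' where a background region is sampled per image series rather than per
#' frame.
#'
#' @param table long-format table containing fish rows (`is_background ==
#'   FALSE`) and one background row per fish (`is_background == TRUE`,
#'   `time_min == 0`), with catch columns `q_SW`, `q_MW`, `q_LW`, `q_dbl`.
#' @param visual_system a [visual_system()] object (defaults to the peafowl
#'   model).
#' @return The fish rows of `table` with `luminance_jnd`, `colour_jnd` and
#'   `category` columns appended.
#' @export
add_jnd <- function(table, visual_system = peafowl_visual_system()) {
  need <- c("fish_id", "is_background", "time_min",
            "q_SW", "q_MW", "q_LW", "q_dbl")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bg   <- table[table$is_background, , drop = FALSE]
  fish <- table[!table$is_background, , drop = FALSE]
  if (anyDuplicated(bg$fish_id)) {
    stop("more than one background row for fish: ",
         bg$fish_id[duplicated(bg$fish_id)][1L], call. = FALSE)
  }
  idx <- match(fish$fish_id, bg$fish_id)
  if (anyNA(idx)) {
    stop("no background row for fish: ",
         fish$fish_id[is.na(idx)][1L], call. = FALSE)
  }
  fish$luminance_jnd <- achromatic_jnd(fish$q_dbl, bg$q_dbl[idx],
                                       visual_system$weber_achro)
  fish$colour_jnd <- chromatic_jnd(
    fish[c("q_SW", "q_MW", "q_LW")],
    list(q_SW = bg$q_SW[idx], q_MW = bg$q_MW[idx], q_LW = bg$q_LW[idx]),
    visual_system$noise
  )
  fish$category <- classify_detectability(fish$colour_jnd)
  fish
}
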