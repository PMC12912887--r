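#' Describe a background-matching experiment
#'
#' An experiment design records the factorial structure the pipeline
#' assumes: populations of fish, background treatments (each with a nominal
#' reflectance, hue and saturation), a number of fish per population x
#' background cell, and the minutes at which each fish is photographed.
#'
#' The default design mirrors a four-population study with five background
#' treatments (black, white, beige, brown, green), 20 fish per cell and
#' photographs at minutes 0, 1, 8 and 15. Default background reflectances
#' for black (5.9%) and white (85.5%) are the measured reflectances of the
#' printed papers; the chromatic backgrounds carry the measured hues
#' (beige 0.005, brown 0.015, green 0.075) with generator-chosen
#' reflectances and saturations typical of printed sand and algae colours.
#'
#' @param populations character vector of population labels.
#' @param backgrounds data frame with columns `background`, `reflectance`
#'   (fraction in (0, 1)), `hue`, `saturation`.
#' @param fish_per_cell fish per population x background cell (>= 2).
#' @param time_points_min strictly increasing, non-negative minutes.
#' @param seed integer seed governing every random draw downstream.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(populations = c("Gizan", "Jeddah", "Khaybar", "Nawan"),
                              backgrounds = default_backgrounds(),
                              fish_per_cell = 20,
                              time_points_min = c(0, 1, 8, 15),
                              seed = 1L) {
  stopifnot(is.character(populations), length(populations) >= 1L,
            !anyDuplicated(populations))
  need <- c("background", "reflectance", "hue", "saturation")
  if (!is.data.frame(backgrounds) || !all(need %in% names(backgrounds))) {
    stop("`backgrounds` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(backgrounds$reflectance <= 0) || any(backgrounds$reflectance >= 1)) {
    stop("background reflectances must lie in (0, 1)", call. = FALSE)
  }
  if (fish_per_cell < 2) {
    stop("`fish_per_cell` must be >= 2", call. = FALSE)
  }
  if (length(time_points_min) < 1L || any(time_points_min < 0) ||
      is.unsorted(time_points_min, strictly = TRUE)) {
    stop("`time_points_min` must be non-negative and strictly increasing",
         call. = FALSE)
  }
  structure(
    list(populations = populations,
         backgrounds = backgrounds,
         fish_per_cell = as.integer(fish_per_cell),
         time_points_min = as.numeric(time_points_min),
         seed = as.integer(seed)),
    class = "experiment_design"
  )
}

#' @rdname experiment_design
#' @export
default_backgrounds <- function() {
  data.frame(
    background  = c("black", "white", "beige", "brown", "green"),
    reflectance = c(0.059, 0.855, 0.40, 0.20, 0.15),
    hue         = c(0, 0, 0.005, 0.015, 0.075),
    saturation  = c(0, 0, 0.05, 0.08, 0.10)
  )
}

#' Colour-change profile of one population
#'
#' The generator models each colour metric of a fish as an exponential
#' approach from the population baseline toward the background's nominal
#' value:
#' \deqn{m(t) = T + (m_0 - T)\,[g + (1 - g)\,e^{-k t}] + b_{fish} +
#'   \varepsilon(t),}
#' where `T` is the background target, `m_0` the population baseline, `k`
#' the per-minute approach rate, `g` the fraction of the initial gap left
#' unclosed as `t` grows, `b_fish` a fish-level random intercept drawn once
#' per fish from `N(0, fish_sd^2)` and `\varepsilon` i.i.d. measurement
#' noise `N(0, resid_sd^2)`. At `t = 0` the curve passes through `m_0`
#' exactly (before noise); with `g = 0` it converges to the target. A large
#' `k` reproduces change concentrated in the first minute; a small `k` a
#' steady drift. The exponential-approach form is a generator assumption,
#' not an estimate from any particular study.
#'
#' `rate_k`, `fish_sd`, `resid_sd` and the baselines are per-metric
#' (metrics: `luminance`, `hue`, `saturation`); scalars are recycled across
#' metrics, which is rarely what you want for `fish_sd`/`resid_sd` given
#' the very different scales of luminance and hue.
#'
#' @param baseline_luminance baseline double-cone catch (dbl-catch scale).
#' @param baseline_hue,baseline_saturation baseline chromatic metrics.
#' @param rate_k per-minute approach rate(s), named per metric or scalar.
#' @param asymptote_gap fraction of the initial gap left unclosed (0-1).
#' @param fish_sd,resid_sd random-intercept and residual SDs, named per
#'   metric or scalar.
#' @param sex_effect additive shift applied to male fish, named per metric
#'   or scalar (default 0 for all metrics).
#' @param instant_shift fraction of the fish-to-background gap closed
#'   instantaneously at minute 0 (reflective-platelet-like step change);
#'   default 0.
#' @return An object of class `population_profile`.
#' @export
population_profile <- function(baseline_luminance = 0.30,
                               baseline_hue = -0.02,
                               baseline_saturation = 0.06,
                               rate_k = 2,
                               asymptote_gap = 0.1,
                               fish_sd = c(luminance = 0.03, hue = 0.004,
                                           saturation = 0.010),
                               resid_sd = c(luminance = 0.015, hue = 0.002,
                                            saturation = 0.005),
                               sex_effect = 0,
                               instant_shift = 0) {
  metrics <- c("luminance", "hue", "saturation")
  per_metric <- function(v, what) {
    if (length(v) == 1L && is.null(names(v))) {
      v <- stats::setNames(rep(as.numeric(v), 3L), metrics)
    }
    if (!all(metrics %in% names(v))) {
      stop("`", what, "` must be a scalar or named per metric (",
           paste(metrics, collapse = ", "), ")", call. = FALSE)
    }
    v[metrics]
  }
  rate_k   <- per_metric(rate_k, "rate_k")
  fish_sd  <- per_metric(fish_sd, "fish_sd")
  resid_sd <- per_metric(resid_sd, "resid_sd")
  sex_effect <- per_metric(sex_effect, "sex_effect")
  if (any(rate_k < 0)) stop("`rate_k` must be >= 0", call. = FALSE)
  if (asymptote_gap < 0 || asymptote_gap > 1) {
    stop("`asymptote_gap` must lie in [0, 1]", call. = FALSE)
  }
  if (any(fish_sd < 0) || any(resid_sd < 0)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (instant_shift < 0 || instant_shift > 1) {
    stop("`instant_shift` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(baseline = c(luminance = baseline_luminance,
                      hue = baseline_hue,
                      saturation = baseline_saturation),
         rate_k = rate_k,
         asymptote_gap = asymptote_gap,
         fish_sd = fish_sd,
         resid_sd = resid_sd,
         sex_effect = sex_effect,
         instant_shift = instant_shift),
    class = "population_profile"
  )
}

#' Default population profiles: three rapid changers and one steady one
#'
#' Three populations share a fast approach rate (most change inside the
#' first minute) and the fourth approaches steadily, emulating the
#' fast/steady contrast commonly seen between populations. Baselines are
#' mid-grey-adapted fish (all fish start acclimated on an intermediate
#' grey).
#'
#' @param populations population labels.
#' @param steady label of the steady population (default the third).
#' @return Named list of [population_profile()] objects.
#' @export
default_population_profiles <- function(populations = c("Gizan", "Jeddah",
                                                        "Khaybar", "Nawan"),
                                        steady = populations[3L]) {
  profs <- lapply(populations, function(p) {
    if (identical(p, steady)) {
      population_profile(rate_k = 0.15, asymptote_gap = 0.25)
    } else {
      population_profile(rate_k = 2, asymptote_gap = 0.1)
    }
  })
  stats::setNames(profs, populations)
}

# run expr under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate the fish cohort for a design
#'
#' Draws one fish per population x background x replicate slot: unique ids,
#' sexes balanced within each cell up to rounding, and body lengths from a
#' normal distribution (mean 3.5 cm, SD 0.67 cm by default) truncated at
#' zero by redrawing. Deterministic given `design$seed`.
#'
#' @param design an [experiment_design()].
#' @param profiles named list of [population_profile()]s covering every
#'   population in the design (checked; profiles do not affect the cohort
#'   itself beyond validation).
#' @param length_mean,length_sd body-length distribution (cm).
#' @return Data frame with columns `fish_id`, `population`, `background`,
#'   `sex`, `length_cm`.
#' @export
generate_fish_cohort <- function(design, profiles,
                                 length_mean = 3.5, length_sd = 0.67) {
  check_profiles(design, profiles)
  with_seed(design$seed, cohort_draw(design, length_mean, length_sd))
}

check_profiles <- function(design, profiles) {
  miss <- setdiff(design$populations, names(profiles))
  if (length(miss)) {
    stop("no population profile for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

cohort_draw <- function(design, length_mean = 3.5, length_sd = 0.67) {
  cells <- expand.grid(population = design$populations,
                       background = design$backgrounds$background,
                       stringsAsFactors = FALSE)
  n <- design$fish_per_cell
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sexes <- rep(c("F", "M"), length.out = n)[sample.int(n)]
    len <- stats::rnorm(n, length_mean, length_sd)
    while (any(len <= 0)) {
      len[len <= 0] <- stats::rnorm(sum(len <= 0), length_mean, length_sd)
    }
    data.frame(
      fish_id = sprintf("%s_%s_%02d", cells$population[i],
                        cells$background[i], seq_len(n)),
      population = cells$population[i],
      background = cells$background[i],
      sex = sexes,
      length_cm = len
    )
  })
  do.call(rbind, rows)
}

#' Simulate one metric trajectory
#'
#' Evaluates the exponential-approach trajectory of
#' [population_profile()] for a single metric:
#' `target + (m0 - target) * (gap + (1 - gap) * exp(-k * t)) + b_fish + eps`.
#' With both noise terms zero the closed form holds exactly; with `k = 0`
#' the metric stays at `m0`.
#'
#' @param m0 baseline metric value at minute 0.
#' @param target background nominal value for the metric.
#' @param times non-negative minutes (non-empty).
#' @param rate_k per-minute approach rate (>= 0).
#' @param asymptote_gap fraction of the gap left unclosed at large `t`.
#' @param b_fish fish-level intercept (a single draw, default 0).
#' @param resid_sd residual noise SD (draws one deviate per time point when
#'   positive).
#' @return Numeric vector of metric values, one per time point.
#' @examples
#' simulate_colour_trajectory(10, 2, times = 1, rate_k = 1) # 2 + 8/e
#' @export
simulate_colour_trajectory <- function(m0, target, times, rate_k,
                                       asymptote_gap = 0, b_fish = 0,
                                       resid_sd = 0) {
  if (length(times) < 1L) stop("`times` must be non-empty", call. = FALSE)
  if (any(times < 0)) stop("negative time", call. = FALSE)
  if (rate_k < 0) stop("`rate_k` must be >= 0", call. = FALSE)
  m <- target + (m0 - target) *
    (asymptote_gap + (1 - asymptote_gap) * exp(-rate_k * times)) + b_fish
  if (resid_sd > 0) m <- m + stats::rnorm(length(times), 0, resid_sd)
  m
}

#' Invert hue and saturation to standardised catches
#'
#' Recovers a sum-to-one catch triple from a (hue, saturation) pair.
#' Hue fixes the medium-wave fraction via `s_MW = (2 h + 1) / 3`; writing
#' `d = s_LW - s_SW`, saturation then satisfies the closed-form identity
#' \deqn{S^2 = (1 - 3 s_{MW})^2 / 6 + d^2 / 2,}
#' so `d` is determined up to sign. The generator always takes `d >= 0`
#' (long-wavelength dominant, matching sand-coloured fish and substrates).
#' A saturation below the minimum attainable for the given hue
#' (`|h| * sqrt(2/3)`) is clamped to that minimum with a warning; fractions
#' are floored at 1e-6 to keep catches strictly positive.
#'
#' @param hue hue value(s) in (-0.5, 1).
#' @param saturation saturation value(s) >= 0.
#' @return List with components `s_LW`, `s_MW`, `s_SW`.
#' @export
catches_from_metrics <- function(hue, saturation) {
  s_MW <- (2 * hue + 1) / 3
  d2 <- 2 * saturation^2 - (4 / 3) * hue^2
  if (any(d2 < -1e-12)) {
    warning("saturation below the minimum attainable for the given hue; ",
            "clamped", call. = FALSE)
  }
  d <- sqrt(pmax(d2, 0))
  c_rest <- 1 - s_MW
  # d > c_rest would need a negative short-wave fraction: cap at the
  # simplex edge (maximum attainable saturation for the given hue)
  if (any(d > c_rest)) {
    warning("saturation above the maximum attainable for the given hue; ",
            "clamped", call. = FALSE)
    d <- pmin(d, c_rest)
  }
  s_LW <- (c_rest + d) / 2
  s_SW <- (c_rest - d) / 2
  floor_q <- 1e-6
  list(s_LW = pmax(s_LW, floor_q),
       s_MW = pmax(s_MW, floor_q),
       s_SW = pmax(s_SW, floor_q))
}

#' Generate a full cone-catch experiment table
#'
#' Runs the trajectory model for every fish and time point, converts the
#' metric trajectories (luminance, hue, saturation) to cone catches, and
#' appends one background row per fish measured at minute 0 (backgrounds
#' are sampled from the photograph series once, with the same measurement
#' noise as the fish regions). Cone catches are floored at 1e-6, so they
#' are strictly positive as the log-contrast JND machinery requires.
#' Deterministic given `design$seed`.
#'
#' @inheritParams generate_fish_cohort
#' @return Long-format data frame with columns `fish_id`, `population`,
#'   `background`, `sex`, `length_cm`, `time_min`, `is_background`, `q_SW`,
#'   `q_MW`, `q_LW`, `q_dbl`. Fish contribute one row per time point;
#'   backgrounds one row per fish at `time_min == 0`.
#' @export
generate_cone_catch_table <- function(design, profiles) {
  check_profiles(design, profiles)
  with_seed(design$seed, {
    cohort <- cohort_draw(design)
    bgs <- design$backgrounds
    times <- design$time_points_min
    nt <- length(times)
    metrics <- c("luminance", "hue", "saturation")
    fish_rows <- vector("list", nrow(cohort))
    bg_rows <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      f <- cohort[i, ]
      prof <- profiles[[f$population]]
      bg <- bgs[bgs$background == f$background, ]
      target <- c(luminance = bg$reflectance, hue = bg$hue,
                  saturation = bg$saturation)
      traj <- matrix(NA_real_, nrow = nt, ncol = 3,
                     dimnames = list(NULL, metrics))
      for (m in metrics) {
        b_fish <- if (prof$fish_sd[[m]] > 0) {
          stats::rnorm(1, 0, prof$fish_sd[[m]])
        } else 0
        sex_add <- if (f$sex == "M") prof$sex_effect[[m]] else 0
        m0 <- prof$baseline[[m]] +
          prof$instant_shift * (target[[m]] - prof$baseline[[m]])
        traj[, m] <- simulate_colour_trajectory(
          m0, target[[m]], times, prof$rate_k[[m]],
          prof$asymptote_gap, b_fish + sex_add, prof$resid_sd[[m]]
        )
      }
      # a measured saturation is a norm: floor simulated values at the
      # minimum attainable for the simulated hue (active near achromatic
      # targets, where independent hue/saturation noise can disagree)
      traj[, "saturation"] <- pmax(traj[, "saturation"],
                                   abs(traj[, "hue"]) * sqrt(2 / 3))
      s <- catches_from_metrics(traj[, "hue"], traj[, "saturation"])
      fish_rows[[i]] <- data.frame(
        fish_id = f$fish_id, population = f$population,
        background = f$background, sex = f$sex, length_cm = f$length_cm,
        time_min = times, is_background = FALSE,
        q_SW = s$s_SW, q_MW = s$s_MW, q_LW = s$s_LW,
        q_dbl = pmax(traj[, "luminance"], 1e-6)
      )
      bg_noise <- vapply(metrics, function(m) {
        if (prof$resid_sd[[m]] > 0) stats::rnorm(1, 0, prof$resid_sd[[m]]) else 0
      }, numeric(1))
      bm <- target + bg_noise
      sb <- catches_from_metrics(
        bm[["hue"]], max(bm[["saturation"]], abs(bm[["hue"]]) * sqrt(2 / 3))
      )
      bg_rows[[i]] <- data.frame(
        fish_id = f$fish_id, population = f$population,
        background = f$background, sex = f$sex, length_cm = f$length_cm,
        time_min = 0, is_background = TRUE,
        q_SW = sb$s_SW, q_MW = sb$s_MW, q_LW = sb$s_LW,
        q_dbl = pmax(bm[["luminance"]], 1e-6)
      )
    }
    out <- rbind(do.call(rbind, fish_rows), do.call(rbind, bg_rows))
    rownames(out) <- NULL
    out
  })
}
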