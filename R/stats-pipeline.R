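#' Prepare a metrics table for mixed modelling
#'
#' Drops background rows, turns `time_min` and `population` (and `sex`)
#' into factors, and validates the repeated-measures structure: at least
#' two time points and two populations, and every fish observed at two or
#' more time points.
#'
#' @param table long-format metrics table (one row per fish x time point).
#' @return Data frame with factor columns `time`, `population`, `sex`.
#' @keywords internal
build_model_data <- function(table) {
  if ("is_background" %in% names(table)) {
    table <- table[!table$is_background, , drop = FALSE]
  }
  need <- c("fish_id", "population", "sex", "length_cm", "time_min")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  table$time <- factor(table$time_min, levels = sort(unique(table$time_min)))
  table$population <- factor(table$population)
  table$sex <- factor(table$sex)
  if (nlevels(table$time) < 2L) {
    stop("need >= 2 time points to model change", call. = FALSE)
  }
  if (nlevels(table$population) < 2L) {
    stop("singular design: need >= 2 populations for an interaction model",
         call. = FALSE)
  }
  per_fish <- table(table$fish_id)
  if (any(per_fish < 2L)) {
    stop("every fish needs >= 2 time points; first offender: ",
         names(per_fish)[per_fish < 2L][1L], call. = FALSE)
  }
  table
}

transform_fun <- function(transform) {
  switch(transform,
         identity = function(x) x,
         log = log,
         sqrt = sqrt,
         stop("unknown transform: ", transform, call. = FALSE))
}

#' Choose a variance-stabilising transform for a colour metric
#'
#' Fits the repeated-measures model under each admissible candidate
#' transform (identity, log, sqrt) and keeps the one whose model residuals
#' look most normal by the Shapiro-Wilk W statistic. Log is skipped (with a
#' message) when the response contains non-positive values — JND responses
#' can legitimately be zero — and sqrt when negatives are present.
#' Deterministic given the data.
#'
#' @param table metrics table (see [build_model_data()]).
#' @param response name of the response column.
#' @param candidates transforms to consider.
#' @return List with `transform` (the winner), and `W` (named vector of
#'   Shapiro-Wilk statistics for every candidate actually fitted).
#' @export
choose_transform <- function(table, response,
                             candidates = c("identity", "log", "sqrt")) {
  dat <- build_model_data(table)
  y <- dat[[response]]
  if (is.null(y)) stop("no column `", response, "`", call. = FALSE)
  if (any(!is.finite(y))) stop("response contains non-finite values",
                               call. = FALSE)
  if (stats::var(y) == 0) {
    stop("response is constant: no variance to model", call. = FALSE)
  }
  keep <- candidates
  if ("log" %in% keep && any(y <= 0)) {
    message("log transform skipped: response has non-positive values")
    keep <- setdiff(keep, "log")
  }
  if ("sqrt" %in% keep && any(y < 0)) {
    message("sqrt transform skipped: response has negative values")
    keep <- setdiff(keep, "sqrt")
  }
  W <- vapply(keep, function(tr) {
    fit <- fit_colour_lmm(dat, response, transform = tr)
    r <- stats::residuals(fit)
    if (length(r) > 5000L) r <- r[seq(1L, length(r), length.out = 5000L)]
    stats::shapiro.test(r)$statistic
  }, numeric(1))
  names(W) <- keep
  list(transform = keep[which.max(W)], W = W)
}

#' Fit the repeated-measures colour-change model
#'
#' Fits `metric ~ time * population + length_cm + sex + (1 | fish_id)` by
#' REML (or ML), with time and population categorical and a random
#' intercept per fish to absorb the repeated measures. The optional
#' transform is applied inside the model formula (`log(metric)` /
#' `sqrt(metric)`) so that downstream marginal-means machinery can
#' back-transform.
#'
#' @inheritParams choose_transform
#' @param transform `"identity"`, `"log"` or `"sqrt"` (or `"auto"` to pick
#'   via [choose_transform()]).
#' @param reml fit by REML (default) or ML (required for AIC comparison).
#' @return A `lmerModLmerTest` fit with attributes `transform` and
#'   `response`.
#' @export
fit_colour_lmm <- function(table, response, transform = "identity",
                           reml = TRUE) {
  dat <- build_model_data(table)
  if (identical(transform, "auto")) {
    transform <- choose_transform(dat, response)$transform
  }
  y <- dat[[response]]
  if (is.null(y)) stop("no column `", response, "`", call. = FALSE)
  if (transform == "log" && any(y <= 0)) {
    stop("log transform needs a strictly positive response", call. = FALSE)
  }
  lhs <- switch(transform,
                identity = response,
                log = sprintf("log(%s)", response),
                sqrt = sprintf("sqrt(%s)", response))
  fml <- stats::as.formula(
    paste(lhs, "~ time * population + length_cm + sex + (1 | fish_id)")
  )
  fit <- lmerTest::lmer(fml, data = dat, REML = reml)
  attr(fit, "transform") <- transform
  attr(fit, "response") <- response
  fit
}

#' Joint F test of the time-by-population interaction
#'
#' The headline test of whether populations differ in their colour-change
#' trajectories. Denominator degrees of freedom come from Satterthwaite's
#' approximation; a classical between-within fallback
#' (`N - n_fish - p_within`, with `p_within` the count of within-fish fixed
#' effects: time main effects plus interaction terms) is available and
#' flagged in the output. On fully balanced designs the two agree.
#'
#' @param fit a [fit_colour_lmm()] model.
#' @param ddf `"satterthwaite"` or `"between-within"`.
#' @return List with `F`, `num_df`, `den_df`, `p`, `ddf_method`.
#' @export
test_interaction <- function(fit, ddf = c("satterthwaite", "between-within")) {
  ddf <- match.arg(ddf)
  if (ddf == "satterthwaite") {
    an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    row <- an["time:population", ]
    if (nrow(row) != 1L || anyNA(row$NumDF)) {
      stop("model contains no time:population interaction", call. = FALSE)
    }
    out <- list(F = row[["F value"]], num_df = row$NumDF, den_df = row$DenDF,
                p = row[["Pr(>F)"]], ddf_method = "satterthwaite")
  } else {
    b <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    idx <- grep("^time.+:population", names(b))
    if (!length(idx)) {
      stop("model contains no time:population interaction", call. = FALSE)
    }
    q <- length(idx)
    bb <- b[idx]
    Fv <- drop(t(bb) %*% solve(V[idx, idx]) %*% bb) / q
    dat <- stats::model.frame(fit)
    n_fish <- length(unique(dat$fish_id))
    p_within <- length(grep("^time", names(b)))  # time mains + interactions
    den <- nrow(dat) - n_fish - p_within
    out <- list(F = Fv, num_df = q, den_df = den,
                p = stats::pf(Fv, q, den, lower.tail = FALSE),
                ddf_method = "between-within")
  }
  out
}

#' Tukey-adjusted time contrasts within each population
#'
#' Estimated marginal means of the response for every time point within
#' each population, followed by all pairwise time contrasts with a Tukey
#' (studentised-range) adjustment applied within each population's family
#' of `choose(n_times, 2)` comparisons. When the model was fitted on a log
#' or sqrt scale, the marginal means are first regridded back to the
#' response scale, so estimates are differences of back-transformed means
#' with delta-method standard errors.
#'
#' @param fit a [fit_colour_lmm()] model.
#' @param adjust p-value adjustment within each family (default
#'   `"tukey"`).
#' @param regrid back-transform to the response scale before contrasting
#'   (default: yes whenever a transform was used).
#' @param family `"within"` adjusts over the time pairs inside each
#'   population (the default and the convention for within-population
#'   change); `"all"` treats every population-by-time cell pair as one
#'   family, a more conservative choice, and then reports only the
#'   within-population time pairs.
#' @return Data frame: `population`, `contrast`, `estimate`, `SE`, `df`,
#'   `t_ratio`, `p_value` (adjusted), `p_unadjusted`, `family_size`.
#' @export
time_contrasts_within_population <- function(fit, adjust = "tukey",
                                             regrid = NULL,
                                             family = c("within", "all")) {
  transform <- attr(fit, "transform")
  family <- match.arg(family)
  if (is.null(regrid)) regrid <- !identical(transform, "identity")
  spec <- if (family == "within") ~ time | population else ~ time * population
  emm <- emmeans::emmeans(fit, spec, lmer.df = "satterthwaite")
  if (regrid) emm <- emmeans::regrid(emm)
  adj <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = adjust))
  raw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  if (family == "all") {
    # keep the within-population time pairs out of the full pairwise set
    pat <- "^time(\\S+) (\\S+) - time(\\S+) \\2$"
    keep <- grepl(pat, adj$contrast)
    adj <- adj[keep, , drop = FALSE]
    raw <- raw[keep, , drop = FALSE]
    adj$population <- sub(pat, "\\2", adj$contrast)
    raw$population <- sub(pat, "\\2", raw$contrast)
    adj$contrast <- sub(pat, "time\\1 - time\\3", adj$contrast)
    raw$contrast <- sub(pat, "time\\1 - time\\3", raw$contrast)
  }
  out <- data.frame(
    population = adj$population,
    contrast = adj$contrast,
    estimate = adj$estimate,
    SE = adj$SE,
    df = adj$df,
    t_ratio = adj$t.ratio,
    p_value = adj$p.value,
    p_unadjusted = raw$p.value[match(paste(adj$population, adj$contrast),
                                     paste(raw$population, raw$contrast))]
  )
  if (family == "within") {
    fam <- table(out$population)
    out$family_size <- as.integer(fam[as.character(out$population)])
  } else {
    out$family_size <- length(keep)  # the full cell-pairwise family
  }
  miss <- is.na(out$estimate)
  if (any(miss)) {
    stop("inestimable contrast (empty cell?): ",
         paste(out$population[miss][1L], out$contrast[miss][1L]),
         call. = FALSE)
  }
  out
}

#' Rank candidate fixed-effect structures by AIC
#'
#' Fits each candidate model by maximum likelihood (REML likelihoods are
#' not comparable across fixed-effect structures) and tabulates
#' `AIC = -2 logLik + 2 k` with differences to the best model.
#'
#' @inheritParams choose_transform
#' @param rhs character vector of fixed-plus-random right-hand sides, e.g.
#'   `"time * population + length_cm + sex + (1 | fish_id)"`.
#' @param transform response transform applied to every candidate.
#' @return Data frame sorted by AIC: `model`, `k`, `logLik`, `AIC`,
#'   `delta_AIC`.
#' @export
compare_models_aic <- function(table, response, rhs, transform = "identity") {
  dat <- build_model_data(table)
  lhs <- switch(transform,
                identity = response,
                log = sprintf("log(%s)", response),
                sqrt = sprintf("sqrt(%s)", response))
  fits <- lapply(rhs, function(r) {
    lmerTest::lmer(stats::as.formula(paste(lhs, "~", r)), data = dat,
                   REML = FALSE)
  })
  out <- data.frame(
    model = rhs,
    k = vapply(fits, function(f) attr(stats::logLik(f), "df"), numeric(1)),
    logLik = vapply(fits, function(f) as.numeric(stats::logLik(f)),
                    numeric(1))
  )
  out$AIC <- -2 * out$logLik + 2 * out$k
  out <- out[order(out$AIC), , drop = FALSE]
  out$delta_AIC <- out$AIC - out$AIC[1L]
  rownames(out) <- NULL
  out
}
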