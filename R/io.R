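#' Write and read long-format experiment tables
#'
#' Tables are plain CSV with a single leading comment line recording the
#' package version and a hash of the run configuration, so every artefact
#' is traceable to the run that produced it. The reader skips comment
#' lines, types the standard columns and validates that the required ones
#' are present; rows with non-numeric cone catches are an error by default
#' or can be dropped (with a validation report) via `skip_bad`.
#'
#' @param table data frame to write.
#' @param path CSV path.
#' @param config optional run configuration list; hashed into the header
#'   comment.
#' @return `path` invisibly (writer); the typed data frame with a
#'   `validation` attribute (reader).
#' @export
write_experiment_table <- function(table, path, config = NULL) {
  header <- sprintf("# chromatch %s; config_hash %s",
                    as.character(utils::packageVersion("chromatch")),
                    config_hash(config))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @param required columns that must be present.
#' @param skip_bad drop rows with unparseable numeric fields instead of
#'   erroring.
#' @rdname write_experiment_table
#' @export
read_experiment_table <- function(path,
                                  required = c("fish_id", "population",
                                               "time_min", "q_SW", "q_MW",
                                               "q_LW", "q_dbl"),
                                  skip_bad = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines) || (length(lines) == 1L && !nzchar(lines))) {
    stop("empty table: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(text = lines, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- intersect(
    c("time_min", "length_cm", "q_SW", "q_MW", "q_LW", "q_dbl",
      "s_SW", "s_MW", "s_LW", "x", "y", "luminance", "hue", "saturation",
      "luminance_jnd", "colour_jnd"),
    names(tab)
  )
  bad <- rep(FALSE, nrow(tab))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cl]]))
    bad <- bad | (is.na(v) & !(tab[[cl]] %in% c("NA", "")))
    tab[[cl]] <- v
  }
  if ("is_background" %in% names(tab)) {
    tab$is_background <- as.logical(tab$is_background)
  }
  if (any(bad)) {
    if (!skip_bad) {
      stop("non-numeric value in numeric column, first bad row: ",
           which(bad)[1L], " (use skip_bad = TRUE to drop)", call. = FALSE)
    }
    warning("dropped ", sum(bad), " row(s) with unparseable numeric fields",
            call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
  }
  attr(tab, "validation") <- list(n_read = length(bad), n_dropped = sum(bad))
  tab
}

# polynomial rolling hash over the canonical JSON serialisation; a stable
# fingerprint for provenance headers, not a cryptographic digest
config_hash <- function(config) {
  if (is.null(config)) return("none")
  config$out_dir <- NULL  # fingerprint the science, not the output path
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  h <- 0
  for (b in utf8ToInt(txt)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Build and validate a pipeline run configuration
#'
#' A run configuration collects everything a reproducible end-to-end run
#' needs: the seed, the experiment design, the population profiles, the
#' visual system, which metrics to analyse on which backgrounds, and
#' per-metric transform overrides. Unknown keys are rejected so typos
#' cannot silently change a run.
#'
#' @param seed integer seed for the whole run.
#' @param design an [experiment_design()] (rebuilt with `seed`).
#' @param profiles named list of [population_profile()]s.
#' @param visual_system a [visual_system()].
#' @param metrics metrics to analyse.
#' @param analyse_backgrounds background labels to analyse (each treatment
#'   separately), default all in the design.
#' @param transform_overrides named character vector, e.g.
#'   `c(luminance = "log")`; metrics not named use automatic selection.
#' @param out_dir output directory.
#' @return Validated `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       design = experiment_design(seed = seed),
                       profiles = default_population_profiles(design$populations),
                       visual_system = peafowl_visual_system(),
                       metrics = c("luminance", "hue", "saturation",
                                   "luminance_jnd", "colour_jnd"),
                       analyse_backgrounds = NULL,
                       transform_overrides = character(),
                       out_dir = tempfile("chromatch_run_")) {
  design$seed <- as.integer(seed)
  cfg <- list(seed = as.integer(seed), design = design, profiles = profiles,
              visual_system = visual_system, metrics = metrics,
              analyse_backgrounds = analyse_backgrounds %||%
                design$backgrounds$background,
              transform_overrides = transform_overrides,
              out_dir = out_dir)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_run_config <- function(cfg) {
  known <- c("seed", "design", "profiles", "visual_system", "metrics",
             "analyse_backgrounds", "transform_overrides", "out_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(cfg$design, "experiment_design")) {
    stop("config `design` must be an experiment_design", call. = FALSE)
  }
  if (!inherits(cfg$visual_system, "visual_system")) {
    stop("config `visual_system` must be a visual_system (cone densities ",
         "and Weber fractions)", call. = FALSE)
  }
  check_profiles(cfg$design, cfg$profiles)
  bad_bg <- setdiff(cfg$analyse_backgrounds,
                    cfg$design$backgrounds$background)
  if (length(bad_bg)) {
    stop("analyse_backgrounds not in design: ",
         paste(bad_bg, collapse = ", "), call. = FALSE)
  }
  bad_tr <- setdiff(cfg$transform_overrides, c("identity", "log", "sqrt"))
  if (length(bad_tr)) {
    stop("unknown transform override(s): ", paste(bad_tr, collapse = ", "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Run the full simulate-to-analyse pipeline
#'
#' Executes the stages in order — simulate cone catches, compute colour
#' metrics, score fish-versus-background JNDs, fit the repeated-measures
#' models per background treatment and metric — writing every intermediate
#' table, the contrast tables, the interaction tests, a run log and the
#' resolved configuration (JSON) into `config$out_dir`. Fully
#' deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory artefacts: `catches`,
#'   `metrics`, `jnd`, `interactions` (data frame), `contrasts` (data
#'   frame), `log` (character vector of stage messages).
#' @export
run_pipeline <- function(config = run_config()) {
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    note("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  cfg_json <- config
  cfg_json$design$backgrounds <- as.list(cfg_json$design$backgrounds)
  jsonlite::write_json(cfg_json, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  catches <- stage("simulate", generate_cone_catch_table(config$design,
                                                         config$profiles))
  write_experiment_table(catches, file.path(config$out_dir, "catches.csv"),
                         config)
  metrics <- stage("metrics", add_colour_metrics(catches))
  write_experiment_table(metrics, file.path(config$out_dir, "metrics.csv"),
                         config)
  jnd <- stage("jnd", add_jnd(metrics, config$visual_system))
  write_experiment_table(jnd, file.path(config$out_dir, "jnd.csv"), config)

  interactions <- list()
  contrasts <- list()
  for (bg in config$analyse_backgrounds) {
    sub <- jnd[jnd$background == bg, , drop = FALSE]
    for (metric in config$metrics) {
      key <- paste(bg, metric, sep = "/")
      tr <- if (metric %in% names(config$transform_overrides)) {
        config$transform_overrides[[metric]]
      } else {
        choose_transform(sub, metric)$transform
      }
      fit <- stage(paste0("analyse:", key),
                   fit_colour_lmm(sub, metric, transform = tr))
      it <- test_interaction(fit)
      note("analyse %s: transform=%s ddf=%s F(%d, %.1f)=%.4f p=%.4g",
           key, tr, it$ddf_method, it$num_df, it$den_df, it$F, it$p)
      interactions[[key]] <- data.frame(
        background = bg, metric = metric, transform = tr,
        F = it$F, num_df = it$num_df, den_df = it$den_df, p = it$p,
        ddf_method = it$ddf_method
      )
      ct <- time_contrasts_within_population(fit)
      ct <- cbind(background = bg, metric = metric, ct)
      contrasts[[key]] <- ct
    }
  }
  interactions <- do.call(rbind, c(interactions, list(make.row.names = FALSE)))
  contrasts <- do.call(rbind, c(contrasts, list(make.row.names = FALSE)))
  write_experiment_table(interactions,
                         file.path(config$out_dir, "interaction_tests.csv"),
                         config)
  write_experiment_table(contrasts,
                         file.path(config$out_dir, "contrasts.csv"), config)
  note("done")
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(catches = catches, metrics = metrics, jnd = jnd,
                 interactions = interactions, contrasts = contrasts,
                 log = log_lines))
}
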