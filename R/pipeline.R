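KNOWN_STAGES <- c("simulate_evoked", "fit_control", "fcm_predict",
                  "simulate_basal_cohort", "oscillation_compare")

#' Run a configured end-to-end experiment
#'
#' Executes the configured subset of the pipeline stage graph in a fixed
#' order and writes every product as a commented CSV (or JSON for fit
#' reports) under `out_dir`:
#' \describe{
#'   \item{simulate_evoked}{synthetic evoked control trace ->
#'     `evoked_control.csv`. Options: any [mm_params()] field under
#'     `params`, plus `duration`, `noise_sd`, `stim_start_s`.}
#'   \item{fit_control}{dual-uptake fit of the evoked trace ->
#'     `control_fit.json`. Options: `frozen`, `n_starts`, `max_iter`.}
#'   \item{fcm_predict}{compartmental simulation and apparent-Km predicted
#'     traces on a dose x time grid -> `predicted_dose*_t*.csv`,
#'     `fcm_summary.csv`. Options: `rates` (six named constants, required),
#'     `doses_mg_kg`, `times_min`, other [fcm_params()] fields.}
#'   \item{simulate_basal_cohort}{per-animal pre/post basal series ->
#'     `basal_pre_<i>.csv`, `basal_post_<i>.csv`. Options: `n_animals`,
#'     `pre` and `post` lists of [basal_spec()] fields.}
#'   \item{oscillation_compare}{weighted-frequency comparison of the cohort
#'     -> `wf_comparison.csv`.}
#' }
#' Every output file opens with `# config_hash:` and `# stage:` comment
#' lines; identical config + seed reproduce byte-identical tables.
#'
#' @param config Nested list, or path to a YAML file with the same shape:
#'   `seed` (integer, required when any stochastic stage runs), optional
#'   `out_dir`, and `stages`, a named list keyed by stage name.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return A `result_bundle`: named file paths per stage, the config, its
#'   hash and a log of stage messages.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stages <- config$stages
  if (is.null(stages) || !length(stages)) {
    rlang::abort("config must define at least one stage",
                 class = "serovolt_config_error")
  }
  unknown <- setdiff(names(stages), KNOWN_STAGES)
  if (length(unknown)) {
    rlang::abort(paste("unknown stage(s):", paste(unknown, collapse = ", ")),
                 class = "serovolt_config_error")
  }
  stochastic <- c("simulate_evoked", "simulate_basal_cohort")
  needs_seed <- any(names(stages) %in% stochastic) || "fit_control" %in% names(stages)
  if (needs_seed && is.null(config$seed)) {
    rlang::abort("config must carry a seed when stochastic stages run",
                 class = "serovolt_config_error")
  }
  if ("fit_control" %in% names(stages) &&
      !"simulate_evoked" %in% names(stages)) {
    rlang::abort("fit_control requires simulate_evoked",
                 class = "serovolt_config_error")
  }
  if ("oscillation_compare" %in% names(stages) &&
      !"simulate_basal_cohort" %in% names(stages)) {
    rlang::abort("oscillation_compare requires simulate_basal_cohort",
                 class = "serovolt_config_error")
  }
  out_dir <- out_dir %||% config$out_dir %||%
    rlang::abort("an output directory is required",
                 class = "serovolt_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(config[c("seed", "stages")])
  seed <- as.integer(config$seed %||% 0L)
  files <- list()
  log <- character()
  note <- function(stage, msg) {
    log <<- c(log, sprintf("[%s] %s", stage, msg))
  }
  hdr <- function(stage) c(paste("config_hash:", hash), paste("stage:", stage))
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      rlang::abort(sprintf("stage '%s' failed: %s", stage,
                           conditionMessage(e)),
                   class = "serovolt_stage_error", parent = e)
    })
  }

  state <- new.env(parent = emptyenv())

  if (!is.null(stages$simulate_evoked)) {
    run_stage("simulate_evoked", function() {
      opt <- stages$simulate_evoked
      p <- do.call(mm_params, opt$params %||% list())
      tr <- simulate_evoked_trace(p, stim_protocol(),
                                  duration = opt$duration %||% 30,
                                  noise_sd = opt$noise_sd %||% 0,
                                  seed = seed,
                                  stim_start_s = opt$stim_start_s %||% 5)
      path <- file.path(out_dir, "evoked_control.csv")
      write_trace_csv(tr, path, hdr("simulate_evoked"))
      state$evoked <- tr
      files$simulate_evoked <<- path
      note("simulate_evoked", sprintf("%d samples written", nrow(tr)))
    })
  }

  if (!is.null(stages$fit_control)) {
    run_stage("fit_control", function() {
      opt <- stages$fit_control
      fit <- mm_fit(state$evoked, stim_protocol(),
                    init = mm_params(),
                    frozen = opt$frozen %||% c("tau_on", "tau_off"),
                    n_starts = opt$n_starts %||% 5,
                    max_iter = opt$max_iter %||% 2000,
                    seed = seed)
      path <- file.path(out_dir, "control_fit.json")
      jsonlite::write_json(
        list(config_hash = hash,
             fitted = fit$fitted[FITTABLE_MM_PARAMS],
             rmse = fit$rmse, iterations = fit$iterations,
             converged = fit$converged, frozen = fit$frozen),
        path, auto_unbox = TRUE, digits = NA)
      state$control_fit <- fit
      files$fit_control <<- path
      note("fit_control", sprintf("RMSE %.4g nM", fit$rmse))
    })
  }

  if (!is.null(stages$fcm_predict)) {
    run_stage("fcm_predict", function() {
      opt <- stages$fcm_predict
      if (is.null(opt$rates)) {
        rlang::abort("fcm_predict needs the six rate constants under 'rates'")
      }
      doses <- opt$doses_mg_kg %||% c(1, 3, 10, 30)
      times <- opt$times_min %||% c(5, 30, 60, 90, 120)
      extra <- opt[setdiff(names(opt), c("rates", "doses_mg_kg", "times_min"))]
      pbd <- purrr::map(doses, function(d) {
        do.call(fcm_params, c(opt$rates, list(dose_mg_kg = d), extra))
      })
      control <- if (!is.null(state$control_fit)) state$control_fit$fitted
                 else mm_params()
      grid <- temporo_dose_grid(control, pbd, times)
      spath <- file.path(out_dir, "fcm_summary.csv")
      write_commented_csv(as.data.frame(grid$summary), spath,
                          hdr("fcm_predict"))
      files$fcm_summary <<- spath
      tpaths <- purrr::pmap_chr(
        dplyr::distinct(grid$summary[c("dose_mg_kg", "time_min")]),
        function(dose_mg_kg, time_min) {
          sub <- grid$traces[grid$traces$dose_mg_kg == dose_mg_kg &
                               !is.na(grid$traces$time_min) &
                               grid$traces$time_min == time_min, ]
          path <- file.path(out_dir,
                            sprintf("predicted_dose%g_t%g.csv",
                                    dose_mg_kg, time_min))
          write_commented_csv(
            data.frame(time_s = sub$time_s,
                       concentration_nM = sub$concentration_nM),
            path, hdr("fcm_predict"))
          path
        })
      files$fcm_predict <<- tpaths
      note("fcm_predict", sprintf("%d predicted traces", length(tpaths)))
    })
  }

  if (!is.null(stages$simulate_basal_cohort)) {
    run_stage("simulate_basal_cohort", function() {
      opt <- stages$simulate_basal_cohort
      n <- opt$n_animals %||% 5
      pre_spec <- do.call(basal_spec, opt$pre %||% list())
      post_spec <- do.call(basal_spec, opt$post %||% list())
      state$pre <- purrr::map(seq_len(n), function(i) {
        simulate_basal_series(pre_spec, seed = seed + 1000L + i)
      })
      state$post <- purrr::map(seq_len(n), function(i) {
        simulate_basal_series(post_spec, seed = seed + 2000L + i)
      })
      paths <- character()
      for (i in seq_len(n)) {
        p1 <- file.path(out_dir, sprintf("basal_pre_%d.csv", i))
        p2 <- file.path(out_dir, sprintf("basal_post_%d.csv", i))
        write_series_csv(state$pre[[i]], p1, hdr("simulate_basal_cohort"))
        write_series_csv(state$post[[i]], p2, hdr("simulate_basal_cohort"))
        paths <- c(paths, p1, p2)
      }
      files$simulate_basal_cohort <<- paths
      note("simulate_basal_cohort", sprintf("%d animals", n))
    })
  }

  if (!is.null(stages$oscillation_compare)) {
    run_stage("oscillation_compare", function() {
      cmp <- compare_pre_post(state$pre, state$post)
      path <- file.path(out_dir, "wf_comparison.csv")
      write_commented_csv(as.data.frame(cmp), path,
                          c(hdr("oscillation_compare"),
                            sprintf("group_delta_hz: %.8g",
                                    attr(cmp, "group_delta")),
                            paste("direction:", attr(cmp, "direction"))))
      files$oscillation_compare <<- path
      note("oscillation_compare",
           sprintf("group delta %.3g Hz (%s)",
                   attr(cmp, "group_delta"), attr(cmp, "direction")))
    })
  }

  structure(list(files = files, config = config, config_hash = hash,
                 out_dir = out_dir, log = log,
                 version = as.character(utils::packageVersion("serovolt")),
                 timestamp = format(Sys.time(), tz = "UTC")),
            class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("<result_bundle> %d stage(s) in %s (config %s)\n",
              length(x$files), x$out_dir, substr(x$config_hash, 1, 8)))
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Export a long-format table for external statistics
#'
#' Flattens every tabular stage product of a bundle into one tidy table
#' (`animal`, `phase`, `time`, `value`, `stage`) suitable for downstream
#' repeated-measures ANOVA / ANCOVA tooling; the hypothesis tests themselves
#' are deliberately left to standard statistics libraries. Values are read
#' back from the written CSVs, so they round-trip the on-disk
#' representation exactly.
#'
#' @param bundle A [run_experiment()] result.
#' @param path Optional CSV output path.
#' @return A tibble; written to `path` when given.
#' @export
export_tidy_stats <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "result_bundle"))
  if (!length(bundle$files)) {
    rlang::abort("bundle contains no stage outputs",
                 class = "serovolt_export_error")
  }
  missing <- unlist(bundle$files)[!file.exists(unlist(bundle$files))]
  if (length(missing)) {
    rlang::abort(paste("missing stage outputs:",
                       paste(basename(missing), collapse = ", ")),
                 class = "serovolt_export_error")
  }
  rows <- list()
  if (!is.null(bundle$files$simulate_basal_cohort)) {
    rows$basal <- purrr::map_dfr(bundle$files$simulate_basal_cohort,
      function(f) {
        m <- regmatches(basename(f),
                        regexec("basal_(pre|post)_(\\d+)", basename(f)))[[1]]
        s <- utils::read.csv(f, comment.char = "#")
        tibble::tibble(animal = as.integer(m[3]), phase = m[2],
                       time = s$time_min, value = s$concentration_nM,
                       stage = "basal")
      })
  }
  if (!is.null(bundle$files$simulate_evoked)) {
    s <- utils::read.csv(bundle$files$simulate_evoked, comment.char = "#")
    rows$evoked <- tibble::tibble(animal = NA_integer_, phase = "control",
                                  time = s$time_s, value = s$concentration_nM,
                                  stage = "evoked")
  }
  if (!is.null(bundle$files$fcm_summary)) {
    s <- utils::read.csv(bundle$files$fcm_summary, comment.char = "#")
    rows$fcm <- tibble::tibble(animal = NA_integer_,
                               phase = paste0("dose_", s$dose_mg_kg),
                               time = s$time_min, value = s$t_half,
                               stage = "fcm_t_half")
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(path)) {
    write_commented_csv(as.data.frame(out), path,
                        paste("config_hash:", bundle$config_hash))
  }
  out
}
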