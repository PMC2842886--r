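#' Default pipeline configuration
#'
#' A complete configuration for the synthetic end-to-end run, as a nested
#' list mirroring the YAML layout: a `cohort` block (per-group generator
#' settings), `preprocess` (ectopic tolerance, detrend window), `grid`
#' (radius sweep), and `ensemble` (window geometry, thresholds and the
#' feature-set x distance grid). Scaled down from Holter scale so the default
#' run completes in seconds; pass overrides or a YAML file to change any of
#' it.
#'
#' @return Nested list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 20260101L,
    cohort = list(
      n_subjects_per_group = 6L, n_beats = 4000L, mean_rr_s = 0.8,
      n = list(sd_base_s = 0.08, succ_diff_sd_s = 0.04),
      chf = list(sd_base_s = 0.04, succ_diff_sd_s = 0.015),
      trend_amplitude_s = 0.05, ectopic_rate = 0.01
    ),
    preprocess = list(ectopic_tolerance_fraction = 0.2,
                      detrend_window_beats = 501L),
    grid = list(from = 0.005, to = 0.05, by = 0.005),
    radii = as.list(default_radii()),
    ensemble = list(window_length = 2000L, train_length = 4000L, mc = 7L,
                    realization_threshold = 0.95, group_threshold = 0.95)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Keys present in the file override [default_pipeline_config()]; missing
#' keys keep their defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("load_pipeline_config: no such file: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full synthetic pipeline
#'
#' Stages: generate the two cohorts, preprocess every series, extract the
#' feature/radius grid, select per-feature radii by t-test, and run the
#' ensemble classification grid. Artifacts written under `out_dir`:
#' `manifest.csv` + per-subject RR files, `features.csv`, `table1.csv`,
#' `report.json`, `summary.csv` and `run.log`. Every artifact records the
#' seed and the config hash, and a rerun at the same seed is byte-identical.
#'
#' @param config Nested list (see [default_pipeline_config()]) or a YAML
#'   path.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the selected radii table, the reports and
#'   the artifact paths.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- load_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  pipeline_log(con, "pipeline: seed=%d config=%s R=%s sodphrv=%s",
               config$seed, hash, as.character(getRversion()),
               as.character(utils::packageVersion("sodphrv")))

  stage <- "synth"
  result <- tryCatch({
    co <- config$cohort
    spec_n <- cohort_spec(co$n_subjects_per_group, co$n_beats, co$mean_rr_s,
                          co$n$sd_base_s, co$n$succ_diff_sd_s,
                          co$trend_amplitude_s, co$ectopic_rate, config$seed)
    spec_chf <- cohort_spec(co$n_subjects_per_group, co$n_beats, co$mean_rr_s,
                            co$chf$sd_base_s, co$chf$succ_diff_sd_s,
                            co$trend_amplitude_s, co$ectopic_rate,
                            config$seed)
    cohort <- generate_cohort(spec_n, spec_chf)
    write_rr_cohort(cohort, file.path(out_dir, "rr"))
    pipeline_log(con, "synth: %d subjects x %d beats", length(cohort),
                 co$n_beats)

    stage <- "preprocess"
    pp <- config$preprocess
    cohort <- lapply(cohort, preprocess_rr,
                     tolerance_fraction = pp$ectopic_tolerance_fraction,
                     window_beats = pp$detrend_window_beats)
    pipeline_log(con, "preprocess: tolerance=%g window=%d",
                 pp$ectopic_tolerance_fraction, pp$detrend_window_beats)

    stage <- "features"
    radii <- unlist(config$radii)[names(default_radii())]
    ftab <- cohort_feature_table(cohort, radii)
    ftab$seed <- config$seed
    ftab$config <- hash
    features_path <- file.path(out_dir, "features.csv")
    utils::write.csv(ftab, features_path, row.names = FALSE)
    pipeline_log(con, "features: %d rows -> %s", nrow(ftab), features_path)

    stage <- "select-r"
    grid <- seq(config$grid$from, config$grid$to, by = config$grid$by)
    gtab <- feature_radius_grid(cohort, grid)
    t1 <- select_radii(gtab, grid)
    t1$seed <- config$seed
    t1$config <- hash
    table1_path <- file.path(out_dir, "table1.csv")
    utils::write.csv(t1, table1_path, row.names = FALSE)
    pipeline_log(con, "select-r: grid [%g, %g] by %g -> %s",
                 config$grid$from, config$grid$to, config$grid$by,
                 table1_path)

    stage <- "classify"
    en <- config$ensemble
    configs <- table_grid_configs(
      window_length = en$window_length, train_length = en$train_length,
      mc = en$mc, realization_threshold = en$realization_threshold,
      group_threshold = en$group_threshold)
    reports <- run_experiment(cohort, configs, radii)
    summary <- do.call(rbind, lapply(reports, function(rep) {
      data.frame(
        feature_set = paste(rep$config$feature_set, collapse = "+"),
        distance = rep$config$distance,
        n_misclassified_n = rep$n_misclassified_n,
        n_misclassified_chf = rep$n_misclassified_chf,
        stringsAsFactors = FALSE)
    }))
    summary$seed <- config$seed
    summary$config <- hash
    summary_path <- file.path(out_dir, "summary.csv")
    utils::write.csv(summary, summary_path, row.names = FALSE)
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(seed = config$seed, config_hash = hash,
           per_subject = lapply(reports, function(rep) {
             list(feature_set = paste(rep$config$feature_set,
                                      collapse = "+"),
                  distance = rep$config$distance,
                  subjects = rep$per_subject, P = rep$P)
           })),
      report_path, auto_unbox = TRUE, digits = NA)
    pipeline_log(con, "classify: %d configs -> %s, %s", length(configs),
                 summary_path, report_path)

    list(radii_table = t1, reports = reports, summary = summary,
         paths = list(features = features_path, table1 = table1_path,
                      summary = summary_path, report = report_path,
                      log = log_path))
  }, error = function(e) {
    pipeline_log(con, "FAILED at stage %s: %s", stage, conditionMessage(e))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Command-line entry point
#'
#' Subcommands: `synth`, `preprocess`, `features`, `select-r`, `classify`
#' run a single stage from/to files; `all` runs [run_pipeline()]. Every
#' subcommand accepts `--config FILE` (YAML overriding the defaults) and
#' `--out DIR`.
#'
#' @param args Character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status, invisibly (0 on success).
#' @export
sodp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: sodphrv <synth|preprocess|features|select-r|classify|all>",
    "[--config FILE] [--out DIR] [--manifest FILE]")
  if (length(args) == 0L) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- list(config = NULL, out = "sodphrv-out", manifest = NULL)
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% names(opt) || i == length(rest)) {
      message("unknown or incomplete option: ", rest[i], "\n", usage)
      return(invisible(1L))
    }
    opt[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  cfg <- load_pipeline_config(opt$config)

  status <- tryCatch({
    if (cmd == "all") {
      run_pipeline(cfg, opt$out)
    } else if (cmd == "synth") {
      co <- cfg$cohort
      cohort <- generate_cohort(
        cohort_spec(co$n_subjects_per_group, co$n_beats, co$mean_rr_s,
                    co$n$sd_base_s, co$n$succ_diff_sd_s,
                    co$trend_amplitude_s, co$ectopic_rate, cfg$seed),
        cohort_spec(co$n_subjects_per_group, co$n_beats, co$mean_rr_s,
                    co$chf$sd_base_s, co$chf$succ_diff_sd_s,
                    co$trend_amplitude_s, co$ectopic_rate, cfg$seed))
      write_rr_cohort(cohort, opt$out)
    } else if (cmd %in% c("preprocess", "features", "select-r", "classify")) {
      if (is.null(opt$manifest)) stop(cmd, " needs --manifest")
      cohort <- read_rr_manifest(opt$manifest)
      pp <- cfg$preprocess
      cohort <- lapply(cohort, preprocess_rr,
                       tolerance_fraction = pp$ectopic_tolerance_fraction,
                       window_beats = pp$detrend_window_beats)
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      radii <- unlist(cfg$radii)[names(default_radii())]
      if (cmd == "preprocess") {
        write_rr_cohort(cohort, opt$out)
      } else if (cmd == "features") {
        utils::write.csv(cohort_feature_table(cohort, radii),
                         file.path(opt$out, "features.csv"),
                         row.names = FALSE)
      } else if (cmd == "select-r") {
        grid <- seq(cfg$grid$from, cfg$grid$to, by = cfg$grid$by)
        utils::write.csv(select_radii(feature_radius_grid(cohort, grid),
                                      grid),
                         file.path(opt$out, "table1.csv"), row.names = FALSE)
      } else {
        en <- cfg$ensemble
        configs <- table_grid_configs(
          window_length = en$window_length, train_length = en$train_length,
          mc = en$mc, realization_threshold = en$realization_threshold,
          group_threshold = en$group_threshold)
        reports <- run_experiment(cohort, configs, radii)
        summary <- do.call(rbind, lapply(reports, function(rep) {
          data.frame(
            feature_set = paste(rep$config$feature_set, collapse = "+"),
            distance = rep$config$distance,
            n_misclassified_n = rep$n_misclassified_n,
            n_misclassified_chf = rep$n_misclassified_chf)
        }))
        utils::write.csv(summary, file.path(opt$out, "summary.csv"),
                         row.names = FALSE)
      }
    } else {
      message("unknown subcommand: ", cmd, "\n", usage)
      return(invisible(1L))
    }
    0L
  }, error = function(e) {
    message("sodphrv ", cmd, ": ", conditionMessage(e))
    1L
  })
  invisible(status)
}
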