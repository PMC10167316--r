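# End-to-end orchestration: simulate -> preprocess -> features -> stats ->
# select -> classify -> report, with a checksummed run manifest. The
# numbered scripts under analysis/ are thin narrative drivers over these
# functions.

#' Pipeline configuration
#'
#' Every stage parameter in one validated list. The defaults describe a
#' desk-scale demonstration cohort (short recordings, reduced trial
#' counts); the full study conditions are 20+20 subjects, 300 s rest at
#' 512 Hz and 8 blocks x 90 task trials.
#'
#' @param cohort a [cohort_spec()].
#' @param task list: `n_blocks`, `trials_per_block`, `probe_rate`.
#' @param preprocess list: `low_hz`, `high_hz`, `tmin_s`, `tmax_s`,
#'   `trim_to`, `ptp_threshold_uv`, `rest_epoch_s`.
#' @param measures feature measures for the biomarker table.
#' @param bands band names for the biomarker table.
#' @param stats_q FDR level (default 0.05).
#' @param selection an [optimizer_config()] or NULL to skip selection.
#' @param models list of [model_spec()]s for classification.
#' @param split a [split_spec()].
#' @param window sequence window in samples (default 32).
#' @param seed global seed propagated to every stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(n_high = 4, n_low = 4,
                                                 rest_duration_s = 20),
                            task = list(n_blocks = 2L, trials_per_block = 30L,
                                        probe_rate = 1 / 18),
                            preprocess = list(low_hz = 0.5, high_hz = 40,
                                              tmin_s = -0.5, tmax_s = 1.3,
                                              trim_to = c(-0.2, 1.3),
                                              ptp_threshold_uv = 150,
                                              rest_epoch_s = 2),
                            measures = c("band_power", "pli"),
                            bands = c("delta"),
                            stats_q = 0.05,
                            selection = NULL,
                            models = list(model_spec("dt")),
                            split = split_spec("subject_level"),
                            window = 32L, seed = 1L) {
  bad <- setdiff(measures, feature_measures())
  if (length(bad)) stop_invalid("unknown measure(s): %s",
                                paste(bad, collapse = ", "))
  bad_b <- setdiff(bands, band_names())
  if (length(bad_b)) stop_invalid("unknown band(s): %s",
                                  paste(bad_b, collapse = ", "))
  assert_scalar_num(stats_q, "stats_q", 1e-12, 1 - 1e-12)
  stopifnot(inherits(cohort, "cohort_spec"), inherits(split, "split_spec"))
  structure(
    list(cohort = cohort, task = task, preprocess = preprocess,
         measures = measures, bands = bands, stats_q = stats_q,
         selection = selection, models = models, split = split,
         window = as.integer(window), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a synthetic cohort and writes feature tables,
#' group-statistics topographies, selection results and the classification
#' table under `out_dir`, plus a manifest with stage timings and md5
#' checksums of every output file.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return The run manifest (list), invisibly written as
#'   `manifest.yaml`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list(); files <- character(0)
  stage <- function(name, code) {
    t0 <- proc.time()[3]
    r <- tryCatch(force(code), error = function(e) {
      stop_invalid("stage '%s' failed: %s", name, conditionMessage(e))
    })
    timings[[name]] <<- round(proc.time()[3] - t0, 2)
    r
  }
  emit <- function(path) { files <<- c(files, path); path }
  cohort <- config$cohort
  cohort$seed <- derive_seed(config$seed, 1L)

  sim <- stage("simulate", {
    events <- generate_sart_events(config$task$n_blocks,
                                   config$task$trials_per_block,
                                   config$task$probe_rate,
                                   seed = derive_seed(config$seed, 2L))
    rest <- generate_cohort(cohort)
    task_spec <- cohort
    task_spec$seed <- derive_seed(config$seed, 3L)
    task <- generate_cohort(task_spec, events = events)
    write_events(events, emit(file.path(out_dir, "events.tsv")))
    write_questionnaires(rest$questionnaires,
                         emit(file.path(out_dir, "questionnaires.tsv")))
    list(events = events, rest = rest, task = task)
  })

  pp <- config$preprocess
  prep <- stage("preprocess", {
    rest_ep <- lapply(sim$rest$recordings, function(r) {
      rest_epochs(bandpass_filter(r, pp$low_hz, pp$high_hz), pp$rest_epoch_s)
    })
    task_ep <- lapply(sim$task$recordings, function(r) {
      preprocess_recording(r, sim$events, pp$low_hz, pp$high_hz,
                           pp$tmin_s, pp$tmax_s, pp$trim_to,
                           pp$ptp_threshold_uv)$epochs
    })
    list(rest = rest_ep, task = task_ep)
  })

  ft <- stage("features", {
    tab <- extract_feature_table(prep$rest, config$measures, config$bands)
    write_feature_table(tab, emit(file.path(out_dir, "features_rest.tsv")))
    tab
  })

  gs <- stage("stats", {
    qt <- questionnaire_group_table(sim$rest$questionnaires)
    utils::write.table(qt, emit(file.path(out_dir, "questionnaire_stats.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    desc <- attr(ft, "descriptors")
    mont <- build_montage()
    res <- list(questionnaires = qt)
    for (ms in intersect(config$measures, c("band_power", "relative_power",
                                            "hfd", "dfa"))) {
      for (bd in config$bands) {
        sub <- ft[, c("subject_id", "group",
                      desc$name[desc$measure == ms & desc$band == bd])]
        class(sub) <- class(ft)
        g <- channelwise_group_test(sub, config$stats_q)
        export_topography(g, mont,
                          emit(file.path(out_dir,
                                         sprintf("topo_%s_%s.tsv", ms, bd))))
        res[[paste(ms, bd, sep = "_")]] <- g
      }
    }
    res
  })

  sel <- stage("select", {
    if (is.null(config$selection)) NULL else {
      sc <- config$selection
      sc$seed <- derive_seed(config$seed, 4L)
      sr <- switch(sc$algorithm, gwo = run_gwo(ft, sc), ga = run_ga(ft, sc),
                   pso = run_pso(ft, sc))
      write_selection_result(sr, emit(file.path(out_dir, "selection.tsv")))
      sr
    }
  })

  cls <- stage("classify", {
    datasets <- list(
      rest_raw = bind_windows(lapply(prep$rest, window_sequences,
                                     window = config$window)),
      task_raw = bind_windows(lapply(prep$task, window_sequences,
                                     window = config$window))
    )
    for (bd in setdiff(config$bands, "raw")) {
      datasets[[paste0("rest_", bd)]] <-
        bind_windows(lapply(prep$rest, function(e) {
          window_sequences(band_filter(e, bd), window = config$window)
        }))
    }
    tab <- benchmark(datasets, config$models, config$split,
                     seed = derive_seed(config$seed, 5L))
    utils::write.table(tab, emit(file.path(out_dir, "classification.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    tab
  })

  manifest <- list(
    seed = config$seed,
    stage_timings_s = timings,
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(manifest = manifest, features = ft, stats = gs,
                 selection = sel, classification = cls))
}

#' Render a human-readable run summary
#'
#' Reads the tables a [run_pipeline()] call wrote and formats a text
#' report: questionnaire group statistics, per-family significant-channel
#' counts, the selection mask and the accuracy table. Regeneration is
#' idempotent.
#'
#' @param out_dir the pipeline output directory.
#' @param path file to write (default `report.txt` inside `out_dir`).
#' @return The report lines, invisibly.
#' @export
report_run <- function(out_dir, path = file.path(out_dir, "report.txt")) {
  need <- file.path(out_dir, c("questionnaire_stats.tsv",
                               "classification.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop_invalid("missing pipeline outputs: %s",
                                 paste(basename(miss), collapse = ", "))
  qt <- utils::read.table(need[1], sep = "\t", header = TRUE)
  cl <- utils::read.table(need[2], sep = "\t", header = TRUE)
  lines <- c("== Questionnaire group comparison ==")
  for (i in seq_len(nrow(qt))) {
    lines <- c(lines, sprintf(
      "%-10s high %6.2f (%5.2f, n=%d)  low %6.2f (%5.2f, n=%d)  t(%g) = %5.2f, p = %.3g",
      qt$score[i], qt$mean_high[i], qt$sd_high[i], qt$n_high[i],
      qt$mean_low[i], qt$sd_low[i], qt$n_low[i], qt$df[i], qt$t[i], qt$p[i]))
  }
  topo <- list.files(out_dir, pattern = "^topo_.*\\.tsv$", full.names = TRUE)
  if (length(topo)) {
    lines <- c(lines, "", "== Significant channels per feature family ==")
    for (f in sort(topo)) {
      tt <- utils::read.table(f, sep = "\t", header = TRUE)
      lines <- c(lines, sprintf("%-28s %d / %d channels significant",
                                sub("\\.tsv$", "", basename(f)),
                                sum(tt$rejected), nrow(tt)))
    }
  }
  selp <- file.path(out_dir, "selection.tsv")
  if (file.exists(selp)) {
    sl <- readLines(selp)
    lines <- c(lines, "", "== Feature selection ==",
               sl[seq_len(min(4, length(sl)))])
  }
  lines <- c(lines, "", "== Classification ==",
             utils::capture.output(print(cl, row.names = FALSE)))
  writeLines(lines, path)
  invisible(lines)
}
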