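# End-to-end orchestration: preprocess -> phase windows -> activation ->
# wave fronts -> repolarization -> origins & classification.

#' Pipeline configuration
#'
#' All tunables with their defaults: 60 Hz low-pass cutoff, 3 x 3 spatial and
#' 3-frame temporal kernels, 128 ms minimum phase segment, 1% false discovery
#' rate for the derivative threshold, 75% biphasic valley depth, automatic
#' conduction-block threshold and minimum ERP, APD80 with 80-400 ms limits.
#' `theta_t_cb` and `erp_min` may be `"auto"` or a value in ms.
#'
#' @param cutoff_hz,spatial_kernel,temporal_kernel preprocessing parameters.
#' @param min_segment_ms phase-segmentation floor in ms.
#' @param fdr_q derivative-threshold false discovery rate.
#' @param valley_frac biphasic split threshold.
#' @param theta_t_cb `"auto"` or ms.
#' @param n_short_stimuli short-coupled stimulus count for the automatic
#'   conduction-block estimate.
#' @param erp_min `"auto"` or ms.
#' @param repol_level,apd_min_ms,apd_max_ms,repol_method repolarization
#'   parameters.
#' @param deriv_threshold `"auto"` or a manual value (normalized units / ms).
#' @param seed RNG seed recorded with the run.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(cutoff_hz = 60, spatial_kernel = 3L,
                            temporal_kernel = 3L, min_segment_ms = 128,
                            fdr_q = 0.01, valley_frac = 0.75,
                            theta_t_cb = "auto", n_short_stimuli = 3L,
                            erp_min = "auto", repol_level = 0.8,
                            apd_min_ms = 80, apd_max_ms = 400,
                            repol_method = "amplitude_crossing",
                            deriv_threshold = "auto", seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#' @param path JSON file with any subset of [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::fromJSON(path)
  # a resolved config re-runs with its frozen automatic values
  resolved <- c(theta_t_cb_ms = "theta_t_cb", erp_min_ms = "erp_min",
                deriv_threshold_value = "deriv_threshold")
  for (from in names(resolved)) {
    if (!is.null(vals[[from]])) {
      vals[[resolved[[from]]]] <- vals[[from]]
      vals[[from]] <- NULL
    }
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing, phase windowing, activation detection, wave-front
#' labeling, repolarization mapping, repetitiveness classification and origin
#' detection, writing all artifacts plus a run log and the fully resolved
#' configuration (automatic values included) to `out_dir`.
#'
#' @param stack a [voltage_stack()] or path to a raw-binary stack.
#' @param mask optional logical matrix or path to a mask file; default all-in.
#' @param config a [pipeline_config()] or path to a config JSON.
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param reference optional `activation_events` of a short-coupled reference
#'   recording for the automatic conduction-block estimate; default: the
#'   analyzed recording itself.
#' @return (invisibly) a list with all intermediate and final results.
#' @export
run_pipeline <- function(stack, mask = NULL, config = pipeline_config(),
                         out_dir = NULL, reference = NULL) {
  t_start <- Sys.time()
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.character(stack)) stack <- read_raw_stack(stack)
  if (is.character(mask)) mask <- read_mask(mask)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  logf <- if (is.null(out_dir)) NULL else file.path(out_dir, "run.log")
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(fmt, ...))
    message(line)
    if (!is.null(logf)) cat(line, "\n", file = logf, append = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      say(stage, "FAILED: %s", conditionMessage(e))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list(config = config)

  res$stack <- run_stage("preprocess", {
    s <- precondition_stack(stack, cutoff_hz = config$cutoff_hz,
                            spatial_kernel = config$spatial_kernel,
                            temporal_kernel = config$temporal_kernel,
                            mask = mask)
    say("preprocess", "%d frames, %d masked-in pixels",
        dim(s$data)[3L], sum(s$mask))
    s
  })

  res$windows <- run_stage("phase_windows", {
    w <- stack_upstroke_windows(res$stack,
                                min_segment_ms = config$min_segment_ms)
    nwin <- sum(vapply(w$intervals_by_pixel, nrow, integer(1L)))
    say("phase_windows", "%d candidate upstroke windows", nwin)
    w
  })

  res$threshold <- run_stage("derivative_threshold", {
    th <- if (identical(config$deriv_threshold, "auto"))
      auto_derivative_threshold(res$stack, res$windows, fdr_q = config$fdr_q)
    else manual_derivative_threshold(config$deriv_threshold)
    say("derivative_threshold", "theta = %.5g /ms (%s)", th$value, th$method)
    th
  })

  res$events <- run_stage("activation", {
    ev <- build_activation_matrix(res$stack, res$windows, res$threshold,
                                  valley_frac = config$valley_frac)
    say("activation", "%d pAT events (%d secondary)", nrow(ev),
        sum(ev$component == "secondary"))
    ev
  })

  res$theta_t_cb_ms <- run_stage("conduction_block", {
    th <- if (identical(config$theta_t_cb, "auto"))
      estimate_conduction_block_threshold(reference %||% res$events,
                                          config$n_short_stimuli)
    else as.numeric(config$theta_t_cb)
    say("conduction_block", "theta_t_cb = %g ms", th)
    th
  })

  res$labeling <- run_stage("wavefronts", {
    cfg <- wavefront_config(res$theta_t_cb_ms,
                            theta_method = if (identical(config$theta_t_cb, "auto"))
                              "auto" else "manual")
    lb <- label_wavefronts(res$events, cfg)
    say("wavefronts", "%d wave fronts", nrow(lb$info))
    lb
  })

  rcfg <- repolarization_config(level_frac = config$repol_level,
                                apd_min_ms = config$apd_min_ms,
                                apd_max_ms = config$apd_max_ms,
                                method = config$repol_method)
  res$repolarization <- run_stage("repolarization", {
    out <- lapply(res$labeling$info$label, function(lb)
      front_repolarization(res$stack, res$events, res$labeling, lb, rcfg))
    names(out) <- paste0("front_", res$labeling$info$label)
    say("repolarization", "%d fronts mapped", length(out))
    out
  })

  res$erp_min_ms <- run_stage("erp_min", {
    erp <- if (identical(config$erp_min, "auto")) {
      # minimum basal APD from the earliest front with resolvable durations
      basal <- NULL
      for (fr in res$repolarization) {
        if (!all(is.na(fr$apd))) { basal <- fr$apd; break }
      }
      if (is.null(basal))
        stop("cannot auto-derive ERPmin: no front has a resolvable APD")
      default_erp_min(min(basal, na.rm = TRUE))
    } else as.numeric(config$erp_min)
    say("erp_min", "ERPmin = %g ms", erp)
    erp
  })

  res$repetitiveness <- run_stage("repetitiveness", {
    out <- lapply(res$labeling$info$label, function(lb)
      classify_repetitiveness(res$events, res$labeling, lb, res$erp_min_ms))
    names(out) <- paste0("front_", res$labeling$info$label)
    nrep <- sum(vapply(out, function(o)
      o$classification == "repetitive", logical(1L)))
    say("repetitiveness", "%d repetitive / %d fronts", nrep, length(out))
    out
  })

  res$origins <- run_stage("origins", {
    out <- lapply(res$labeling$info$label, function(lb)
      detect_activation_origins(res$events, res$labeling, lb,
                                res$erp_min_ms, res$stack$mask))
    names(out) <- paste0("front_", res$labeling$info$label)
    ncl <- sum(vapply(out, function(o) nrow(o$clusters), integer(1L)))
    say("origins", "%d origin clusters", ncl)
    out
  })

  res$resolved_config <- c(unclass(config),
                           list(theta_t_cb_ms = res$theta_t_cb_ms,
                                erp_min_ms = res$erp_min_ms,
                                deriv_threshold_value = res$threshold$value))

  if (!is.null(out_dir)) run_stage("artifacts", {
    # digits = I(17): doubles (notably the derivative threshold) must
    # round-trip exactly so that re-running the resolved config is
    # bit-identical
    jsonlite::write_json(res$resolved_config,
                         file.path(out_dir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = I(17))
    write_events_csv(res$events, file.path(out_dir, "pat_events.csv"))
    write_labels_csv(res$events, res$labeling,
                     file.path(out_dir, "wavefront_labels.csv"))
    data.table::fwrite(res$labeling$info, file.path(out_dir, "wavefronts.csv"))
    for (lb in res$labeling$info$label) {
      fr <- res$repolarization[[paste0("front_", lb)]]
      write_map_csv(fr$at, file.path(out_dir, sprintf("at_map_%03d.csv", lb)))
      write_map_csv(fr$rt, file.path(out_dir, sprintf("rt_map_%03d.csv", lb)))
      write_map_csv(fr$apd, file.path(out_dir, sprintf("apd_map_%03d.csv", lb)))
      org <- res$origins[[paste0("front_", lb)]]
      data.table::fwrite(org$clusters,
                         file.path(out_dir, sprintf("origins_%03d.csv", lb)))
    }
    cls <- data.table::data.table(
      label = res$labeling$info$label,
      classification = vapply(res$repetitiveness, function(o)
        o$classification, character(1L)))
    data.table::fwrite(cls, file.path(out_dir, "repetitiveness.csv"))
    manifest <- list(created = format(t_start), files = list.files(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    say("artifacts", "written to %s", out_dir)
  })

  say("done", "elapsed %.1f s", as.numeric(Sys.time()) - as.numeric(t_start))
  invisible(res)
}
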