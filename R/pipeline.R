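#' Pipeline configuration
#'
#' Builds (or reads from YAML) the configuration of the end-to-end pipeline:
#' simulate -> (optionally) detect -> metrics -> stats. The default demo
#' configuration simulates the awake Purkinje cohort (2 genotypes x 24 cells,
#' 71 s per cell) and analyses the ground-truth trains; trace synthesis plus
#' detection can be enabled per stage.
#'
#' @param condition study condition passed to [study_cohort_spec()].
#' @param n_per_group optional named vector overriding group sizes.
#' @param master_seed master seed; every stochastic stage derives its seed from
#'   it and records it in the outputs.
#' @param stages character vector of enabled stages among
#'   `c("simulate", "detect", "metrics", "stats")`.
#' @param unit_types spike types to analyse in the stats stage.
#' @param alpha,fdr gate level and BH false discovery rate.
#' @param noise_sd_uv,amplitude_uv,fs_hz trace-synthesis settings (used only
#'   when the detect stage is enabled).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(condition = "awake_purkinje", n_per_group = NULL,
                            master_seed = 1L,
                            stages = c("simulate", "metrics", "stats"),
                            unit_types = NULL, alpha = 0.05, fdr = 0.2,
                            noise_sd_uv = 12.5, amplitude_uv = 100,
                            fs_hz = 25000) {
  unit_types <- unit_types %||%
    (if (condition == "nuclear") "cn" else c("ss", "cs"))
  structure(list(condition = condition, n_per_group = n_per_group,
                 master_seed = as.integer(master_seed), stages = stages,
                 unit_types = unit_types, alpha = alpha, fdr = fdr,
                 noise_sd_uv = noise_sd_uv, amplitude_uv = amplitude_uv,
                 fs_hz = fs_hz),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$n_per_group <- if (!is.null(y$n_per_group)) unlist(y$n_per_group)
  do.call(pipeline_config, y)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order and writes all stage outputs under
#' `out_dir`: cohort metadata and spike-time CSVs, per-cell metrics CSV,
#' group-summary CSV, the statistical report as JSON, and a run manifest with
#' the configuration, seed and per-output MD5 checksums. Re-running with the
#' same configuration reproduces identical metrics and report files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the cohort, metrics, reports and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  put <- function(name) {
    p <- file.path(out_dir, name); outputs[[length(outputs) + 1L]] <<- p; p
  }
  res <- list()

  if ("simulate" %in% config$stages) {
    spec <- study_cohort_spec(config$condition, config$n_per_group,
                              config$master_seed)
    cohort <- tryCatch(gen_cohort(spec),
                       error = function(e) stop("stage simulate failed: ",
                                                conditionMessage(e)))
    write_metadata_csv(cohort, put("metadata.csv"))
    write_spike_csv(cohort, put("spikes.csv"))
    res$cohort <- cohort
  } else stop_invalid("pipeline requires the simulate stage (no external input configured)")

  trains_for_metrics <- res$cohort
  if ("detect" %in% config$stages) {
    seeds <- derive_seeds(config$master_seed + 1L, length(res$cohort))
    sorted <- lapply(seq_along(res$cohort), function(i) {
      tr <- tryCatch(synth_trace(res$cohort[[i]],
                                 amplitude_uv = config$amplitude_uv,
                                 noise_sd_uv = config$noise_sd_uv,
                                 fs_hz = config$fs_hz, seed = seeds[i]),
                     error = function(e) stop("stage detect failed: ",
                                              conditionMessage(e)))
      sort_spikes(tr)
    })
    res$sorted <- sorted
    trains_for_metrics <- lapply(seq_along(res$cohort), function(i) {
      cl <- res$cohort[[i]]
      cl$trains <- if (res$cohort[[i]]$cell_type == "purkinje")
        list(ss = sorted[[i]]$ss, cs = sorted[[i]]$cs)
      else list(cn = sorted[[i]]$ss)
      cl
    })
    attributes(trains_for_metrics) <- attributes(res$cohort)
  }

  if ("metrics" %in% config$stages) {
    metrics <- tryCatch(cohort_metrics(trains_for_metrics),
                        error = function(e) stop("stage metrics failed: ",
                                                 conditionMessage(e)))
    write.csv(metrics, put("metrics.csv"), row.names = FALSE)
    write.csv(cohort_summary(metrics), put("group_summary.csv"),
              row.names = FALSE)
    res$metrics <- metrics
  }

  if ("stats" %in% config$stages) {
    if (is.null(res$metrics)) stop_invalid("stats stage requires metrics stage")
    reports <- lapply(config$unit_types, function(ut)
      tryCatch(analysis_workflow(res$metrics, unit_type = ut,
                                 alpha = config$alpha, fdr = config$fdr),
               error = function(e) stop("stage stats failed: ",
                                        conditionMessage(e))))
    names(reports) <- config$unit_types
    jsonlite::write_json(report_to_list(reports), put("stat_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(report_to_table(reports), put("stat_results.csv"),
              row.names = FALSE)
    res$reports <- reports
  }

  manifest <- list(
    config = unclass(config),
    master_seed = config$master_seed,
    outputs = as.list(stats::setNames(as.character(tools::md5sum(unlist(outputs))),
                                      basename(unlist(outputs)))),
    package_version = as.character(utils::packageVersion("purkinje")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

# flat results table: one row per (unit_type, predictor, response); omnibus-
# only rows when the gate did not pass
report_to_table <- function(reports) {
  rows <- list()
  for (ut in names(reports)) {
    rep <- reports[[ut]]
    for (pred in names(rep$predictors)) {
      e <- rep$predictors[[pred]]
      base <- data.frame(unit_type = ut, predictor = pred,
                         skipped = isTRUE(e$skipped),
                         wilks_lambda = NA_real_, manova_p = NA_real_,
                         gate_passed = NA, response = NA_character_,
                         z = NA_real_, p = NA_real_,
                         bh_critical = NA_real_, rejected = NA)
      if (!isTRUE(e$skipped)) {
        base$wilks_lambda <- e$manova$wilks_lambda
        base$manova_p <- e$manova$p
        base$gate_passed <- e$gate_passed
      }
      if (!isTRUE(e$skipped) && e$gate_passed) {
        for (i in seq_len(nrow(e$pairwise))) {
          r <- base
          r[c("response", "z", "p", "bh_critical", "rejected")] <-
            e$pairwise[i, c("response", "z", "p", "bh_critical", "rejected")]
          rows[[length(rows) + 1L]] <- r
        }
      } else rows[[length(rows) + 1L]] <- base
    }
  }
  do.call(rbind, rows)
}

# serialisable view of a list of stat_reports
report_to_list <- function(reports) {
  lapply(reports, function(rep) {
    list(unit_type = rep$unit_type, alpha = rep$alpha, fdr = rep$fdr,
         n_cells = rep$n_cells, n_dropped = rep$n_dropped,
         predictors = lapply(rep$predictors, function(e) {
           if (isTRUE(e$skipped)) return(list(skipped = TRUE, reason = e$reason))
           out <- list(skipped = FALSE,
                       wilks_lambda = e$manova$wilks_lambda,
                       f_stat = e$manova$f_stat,
                       df_display = c(e$manova$df_hypothesis, e$manova$df_error),
                       df_exact_f = c(e$manova$df1, e$manova$df2),
                       p = e$manova$p, gate_passed = e$gate_passed,
                       groups = e$groups, n_per_group = e$n_per_group)
           if (e$gate_passed) out$pairwise <- e$pairwise
           out
         }))
  })
}
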