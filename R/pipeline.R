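#' Pipeline run configuration
#'
#' Collects every tunable threshold of the analysis in one place so that a
#' run is fully reproducible from its configuration: the hit-calling SD
#' multiplier, channel calibration factors, plate Z' floor, inhibition
#' amplitude floor and the master seed from which all simulation
#' randomness flows.
#'
#' @param seed Master integer seed.
#' @param k_sd Hit-calling SD multiplier (default 5).
#' @param calibration Named channel calibration factors
#'   (default `c(g_cy3 = 1.7, g_cy5 = 4.2)`).
#' @param zprime_floor Minimum acceptable plate Z' (default 0.5).
#' @param amp_floor Minimum inhibition amplitude (default 0.02 FRET units).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, k_sd = 5,
                       calibration = c(g_cy3 = 1.7, g_cy5 = 4.2),
                       zprime_floor = 0.5, amp_floor = 0.02) {
  stopifnot(k_sd > 0, all(calibration > 0), length(calibration) == 2)
  structure(list(seed = as.integer(seed), k_sd = k_sd,
                 calibration = calibration, zprime_floor = zprime_floor,
                 amp_floor = amp_floor),
            class = "run_config")
}

#' Run the analysis pipeline over prepared inputs
#'
#' Orchestrates the stages on whatever inputs are supplied: plate QC and
#' hit calling on a screening dataset, rescreen confirmation, compound-
#' corrected inhibition fits on titrations, biexponential/extent analysis
#' on annealing time courses, and ROC/AUC on a labeled score set. Every
#' threshold and the seed are echoed into the report.
#'
#' @param config A [run_config()].
#' @param screen Optional `screen_dataset`.
#' @param rescreens Optional list of rescreen `screen_dataset`s.
#' @param titrations Optional list of `titration_series`.
#' @param timecourses Optional list of `annealing_timecourse`s (grouped
#'   per compound; the zero-concentration trace is the uninhibited
#'   reference).
#' @param scores Optional `score_set`.
#' @param out_dir Optional directory; when given, a JSON report and TSV
#'   tables are written there.
#' @return A report list with one element per executed stage.
#' @export
run_pipeline <- function(config = run_config(), screen = NULL,
                         rescreens = NULL, titrations = NULL,
                         timecourses = NULL, scores = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  report <- list(
    schema_version = "1.0",
    parameters = list(
      seed = config$seed, k_sd = config$k_sd,
      calibration = as.list(config$calibration),
      zprime_floor = config$zprime_floor, amp_floor = config$amp_floor
    )
  )

  if (!is.null(screen)) {
    qc <- plate_qc(screen)
    hits <- call_hits(screen, k = config$k_sd,
                      zprime_floor = config$zprime_floor)
    report$qc <- qc
    report$hits <- hits[hits$is_hit, , drop = FALSE]
    report$n_hits <- sum(hits$is_hit)
    report$n_qc_failed_wells <- sum(hits$flags == "qc_failed")
    if (!is.null(rescreens)) {
      report$confirmation <- confirm_hits(hits, rescreens, k = config$k_sd,
                                          zprime_floor = config$zprime_floor)
    }
  }

  if (!is.null(titrations)) {
    report$dose_response <- do.call(rbind, lapply(titrations, function(s) {
      corr <- correct_for_compound(s)
      fit <- tryCatch(
        fit_inhibition(corr$conc_M, corr$fret_corrected,
                       amp_floor = config$amp_floor),
        error = function(e) NULL)
      if (is.null(fit)) {
        data.frame(compound_id = s$compound_id, condition = s$condition,
                   ic50_M = NA_real_, hill = NA_real_, f0 = NA_real_,
                   f_sat = NA_real_, status = "FIT_FAILED",
                   bound_M = NA_real_, stringsAsFactors = FALSE)
      } else {
        data.frame(compound_id = s$compound_id, condition = s$condition,
                   ic50_M = fit$ic50, hill = fit$hill, f0 = fit$f0,
                   f_sat = fit$f_sat, status = fit$status,
                   bound_M = fit$bound_value, stringsAsFactors = FALSE)
      }
    }))
  }

  if (!is.null(timecourses)) {
    fits <- lapply(timecourses, fit_biexp)
    ext_tab <- data.frame(
      compound_id = vapply(fits, `[[`, character(1), "compound_id"),
      conc_M = vapply(fits, `[[`, numeric(1), "concentration"),
      extent = vapply(fits, `[[`, numeric(1), "f_inf"),
      k1 = vapply(fits, `[[`, numeric(1), "k1"),
      k2 = vapply(fits, `[[`, numeric(1), "k2"),
      rmse = vapply(fits, `[[`, numeric(1), "rmse"),
      stringsAsFactors = FALSE
    )
    report$annealing_extents <- ext_tab
    report$annealing_ic50 <- do.call(rbind, lapply(
      split(ext_tab, ext_tab$compound_id), function(d) {
        fit <- tryCatch(
          annealing_ic50(data.frame(conc_M = d$conc_M, extent = d$extent),
                         amp_floor = config$amp_floor),
          error = function(e) NULL)
        data.frame(compound_id = d$compound_id[1],
                   ic50_M = if (is.null(fit)) NA_real_ else fit$ic50,
                   status = if (is.null(fit)) "FIT_FAILED" else fit$status,
                   stringsAsFactors = FALSE)
      }))
  }

  if (!is.null(scores)) {
    roc <- build_roc(scores)
    report$roc <- list(auc = roc$auc,
                       youden_threshold = roc$youden_threshold,
                       n_active = roc$n_active, n_decoy = roc$n_decoy)
    hist <- score_histogram(scores)
    report$score_separation <- hist$separation
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      lapply(report, function(x) if (is.data.frame(x)) x else x),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null"
    )
    tsv <- function(d, f) utils::write.table(
      d, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(report$qc)) tsv(report$qc, "qc.tsv")
    if (!is.null(report$hits)) tsv(report$hits, "hits.tsv")
    if (!is.null(report$dose_response)) tsv(report$dose_response, "dose.tsv")
    if (!is.null(report$annealing_extents)) {
      tsv(report$annealing_extents, "annealing_extents.tsv")
    }
  }
  report
}
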