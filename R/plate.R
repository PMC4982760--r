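#' Per-plate quality-control statistics
#'
#' Computes control-well summary statistics and the standard HTS assay
#' performance measures for each plate: Z'-factor
#' `1 - 3 (SDn + SDp) / (mun - mup)`, signal-to-noise
#' `(mun - mup) / SDn` and signal-to-background `mun / mup`, where the
#' "negative" control is the intact protein-DNA complex (high FRET) and
#' the "positive" control is the disrupted complex (low FRET).
#'
#' @param dataset A `screen_dataset` (from [gen_screen()] or
#'   [read_plate_csv()]), or any data frame with columns
#'   `plate_id, role, i_cy3, i_cy5`.
#' @return A `qc_report` data frame, one row per plate, with columns
#'   `plate_id, n_neg, n_pos, mu_neg, sd_neg, mu_pos, sd_pos, zprime,
#'   s2n, s2b, diagnostic`. `diagnostic` is `NA` for a healthy plate,
#'   otherwise a short message (e.g. inverted or coincident controls,
#'   in which case Z' and S/N are `NaN`).
#' @export
plate_qc <- function(dataset) {
  need <- c("plate_id", "role", "i_cy3", "i_cy5")
  stopifnot(all(need %in% names(dataset)))
  out <- lapply(split(dataset, dataset$plate_id), function(pl) {
    neg <- pl[pl$role == "neg_control", ]
    pos <- pl[pl$role == "pos_control", ]
    if (nrow(neg) < 2 || nrow(pos) < 2) {
      stop(sprintf("plate %s: need >= 2 wells of each control role",
                   pl$plate_id[1]), call. = FALSE)
    }
    fn <- fret_app_raw(neg$i_cy3, neg$i_cy5)
    fp <- fret_app_raw(pos$i_cy3, pos$i_cy5)
    mu_n <- mean(fn); sd_n <- sd(fn)
    mu_p <- mean(fp); sd_p <- sd(fp)
    dyn <- mu_n - mu_p
    diagnostic <- NA_character_
    if (dyn == 0) {
      zprime <- NaN; s2n <- NaN
      diagnostic <- "coincident controls: mu_neg == mu_pos, Z' and S/N undefined"
    } else {
      zprime <- 1 - 3 * (sd_n + sd_p) / dyn
      s2n <- dyn / sd_n
      if (dyn < 0) {
        diagnostic <- "inverted controls: mu_neg < mu_pos (negative dynamic range)"
      }
    }
    s2b <- if (mu_p == 0) NaN else mu_n / mu_p
    data.frame(plate_id = pl$plate_id[1], n_neg = nrow(neg),
               n_pos = nrow(pos), mu_neg = mu_n, sd_neg = sd_n,
               mu_pos = mu_p, sd_pos = sd_p, zprime = zprime,
               s2n = s2n, s2b = s2b, diagnostic = diagnostic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Call screening hits against the intact-complex controls
#'
#' A test well is a hit when its apparent FRET falls at least `k` negative-
#' control standard deviations below the negative-control (intact complex)
#' mean of its own plate: `FRET <= mu_neg - k * sd_neg`, boundary
#' inclusive. Control statistics are computed per plate, never pooled, so
#' plate-to-plate drift is absorbed by design. Plates whose Z'-factor falls
#' below `zprime_floor` are excluded: their wells are reported with a
#' `qc_failed` flag and `is_hit = FALSE`.
#'
#' @param dataset A `screen_dataset` or equivalent data frame.
#' @param k SD multiplier of the hit threshold (default 5).
#' @param zprime_floor Minimum acceptable plate Z' (default 0.5).
#' @return A `hit_calls` data frame with one row per test well:
#'   `plate_id, row, col, compound_id, fret_app, sd_below_neg, is_hit,
#'   flags`.
#' @export
call_hits <- function(dataset, k = 5, zprime_floor = 0.5) {
  stopifnot(k > 0)
  qc <- plate_qc(dataset)
  test <- dataset[dataset$role == "test" & !is.na(dataset$compound_id), ,
                  drop = FALSE]
  m <- match(test$plate_id, qc$plate_id)
  fret <- fret_app_raw(test$i_cy3, test$i_cy5)
  sd_below <- (qc$mu_neg[m] - fret) / qc$sd_neg[m]
  # zero-SD controls: any depression is infinitely many SDs, none is zero
  sd_below[is.nan(sd_below)] <- 0
  qc_ok <- !is.na(qc$zprime[m]) & !is.nan(qc$zprime[m]) &
    qc$zprime[m] >= zprime_floor & is.na(qc$diagnostic[m])
  out <- data.frame(
    plate_id = test$plate_id, row = test$row, col = test$col,
    compound_id = test$compound_id,
    fret_app = fret, sd_below_neg = sd_below,
    is_hit = qc_ok & sd_below >= k,
    flags = ifelse(qc_ok, "", "qc_failed"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("hit_calls", "data.frame")
  out
}

#' Confirm primary hits in cherry-pick rescreen rounds
#'
#' Primary hits are re-assembled on fresh plates and re-tested; a compound
#' is confirmed only if it passes the same `k`-SD criterion in every
#' rescreen round. Compounds failing any round are reported with reason
#' "poor reproducibility"; compounds absent from a rescreen are reported
#' as untested and not confirmed.
#'
#' @param primary_hits A `hit_calls` data frame (only rows with
#'   `is_hit = TRUE` are considered).
#' @param rescreens A list of `screen_dataset`s, one per rescreen round.
#' @param k,zprime_floor Passed to [call_hits()] for each round.
#' @return A data frame with columns `compound_id, n_rounds, n_passed,
#'   confirmed, reason`.
#' @export
confirm_hits <- function(primary_hits, rescreens, k = 5, zprime_floor = 0.5) {
  stopifnot(length(rescreens) >= 1)
  ids <- unique(primary_hits$compound_id[primary_hits$is_hit])
  round_calls <- lapply(rescreens, call_hits, k = k,
                        zprime_floor = zprime_floor)
  res <- lapply(ids, function(id) {
    passed <- vapply(round_calls, function(rc) {
      rows <- rc[rc$compound_id == id, , drop = FALSE]
      if (nrow(rows) == 0) NA else all(rows$is_hit)
    }, logical(1))
    if (anyNA(passed)) {
      status <- FALSE
      reason <- "untested in at least one rescreen round"
    } else if (all(passed)) {
      status <- TRUE
      reason <- ""
    } else {
      status <- FALSE
      reason <- "poor reproducibility"
    }
    data.frame(compound_id = id, n_rounds = length(rescreens),
               n_passed = sum(passed, na.rm = TRUE),
               confirmed = status, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Flag optical artifacts in concentration re-tests
#'
#' Distinguishes genuine inhibitors from chromogenic/fluorogenic false
#' positives using their concentration-response signature. A compound is
#' flagged `LINEAR_CONC_DEPENDENCE` when a straight-line fit of signal
#' versus concentration (the better of linear- and log-concentration
#' regressors) explains the response well (R^2 >= `r2_min`) while the
#' inhibition model does not converge to a genuine sigmoid; flagged
#' `HIGH_BACKGROUND` when compound-only background FRET exceeds
#' `background_ceiling`; flagged `UNEVALUABLE` with fewer than 3
#' concentration points.
#'
#' @param retest Data frame with columns `compound_id, conc_M, fret`
#'   (protein-present signal) and optionally `background` (compound-only
#'   FRET).
#' @param r2_min R-squared floor for the linear alternative (default 0.95).
#' @param background_ceiling Background FRET ceiling (default 0.8).
#' @return Data frame `compound_id, flags` where `flags` is a
#'   comma-separated string, empty for clean compounds.
#' @export
flag_optical_artifacts <- function(retest, r2_min = 0.95,
                                   background_ceiling = 0.8) {
  stopifnot(all(c("compound_id", "conc_M", "fret") %in% names(retest)))
  res <- lapply(split(retest, retest$compound_id), function(d) {
    flags <- character(0)
    if (nrow(d) < 3) {
      flags <- "UNEVALUABLE"
    } else {
      r2_lin <- suppressWarnings(summary(lm(fret ~ conc_M,
                                            data = d))$r.squared)
      dp <- d[d$conc_M > 0, , drop = FALSE]
      r2_log <- if (nrow(dp) >= 3) {
        suppressWarnings(summary(lm(fret ~ log10(conc_M),
                                    data = dp))$r.squared)
      } else NA_real_
      r2_best <- suppressWarnings(max(r2_lin, r2_log, na.rm = TRUE))
      inhib_ok <- tryCatch({
        fit <- fit_inhibition(d$conc_M, d$fret)
        fit$status == "CONVERGED"
      }, error = function(e) FALSE)
      if (isTRUE(r2_best >= r2_min) && !inhib_ok) {
        flags <- c(flags, "LINEAR_CONC_DEPENDENCE")
      }
      if ("background" %in% names(d) &&
          any(d$background > background_ceiling, na.rm = TRUE)) {
        flags <- c(flags, "HIGH_BACKGROUND")
      }
    }
    data.frame(compound_id = d$compound_id[1],
               flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
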