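#' Read a screening-plate CSV
#'
#' Expects a header `plate_id,row,col,role,compound_id,conc_M,i_cy3,i_cy5`
#' with rows as letters A-P, 1-based plate columns, molar concentrations
#' and one line per well. Roles are cross-checked against the standard
#' layout (controls in columns 1, 2, 23, 24; test compounds in 3-22);
#' mismatches are recorded as warnings, duplicate wells and non-numeric
#' intensities are rejected with the offending line numbers.
#'
#' @param path Path to the CSV file.
#' @return A `screen_dataset` data frame.
#' @export
read_plate_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "row", "col", "role", "compound_id", "conc_M",
            "i_cy3", "i_cy5")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("plate CSV %s is missing columns: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  raw$compound_id <- as.character(raw$compound_id)
  lineno <- seq_len(nrow(raw)) + 1L  # header is line 1
  for (col in c("conc_M", "i_cy3", "i_cy5")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad) > 0) {
      stop(sprintf("non-numeric %s at line(s) %s of %s", col,
                   paste(head(lineno[bad], 5), collapse = ", "), path),
           call. = FALSE)
    }
    raw[[col]] <- v
  }
  key <- paste(raw$plate_id, raw$row, raw$col)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(sprintf("duplicate well(s) at line(s) %s of %s",
                 paste(head(lineno[dup], 5), collapse = ", "), path),
         call. = FALSE)
  }
  expected_role <- ifelse(raw$col %in% NEG_CONTROL_COLS, "neg_control",
                   ifelse(raw$col %in% POS_CONTROL_COLS, "pos_control",
                          "test"))
  mism <- which(raw$role != expected_role)
  if (length(mism) > 0) {
    warning(sprintf(
      "%d well(s) have roles inconsistent with the standard layout (first at line %d)",
      length(mism), lineno[mism[1]]), call. = FALSE)
  }
  raw$compound_id[raw$compound_id == ""] <- NA_character_
  structure(raw, class = c("screen_dataset", "data.frame"))
}

#' Write a screening dataset to CSV
#'
#' @param dataset A `screen_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(dataset, path) {
  out <- as.data.frame(dataset)
  out$compound_id[is.na(out$compound_id)] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a titration CSV into titration series
#'
#' Expects columns `compound_id, condition, conc_M, i_cy3, i_cy5,
#' protein_present` (logical or 0/1). For each compound/condition the
#' protein-present rows form the titration and the protein-absent rows
#' the paired no-protein control.
#'
#' @param path Path to the CSV file.
#' @param calibration Named calibration factors `c(g_cy3 =, g_cy5 =)`.
#' @return A list of `titration_series` objects.
#' @export
read_titration_csv <- function(path, calibration = c(g_cy3 = 1.7,
                                                     g_cy5 = 4.2)) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "condition", "conc_M", "i_cy3", "i_cy5",
            "protein_present")
  if (!all(need %in% names(raw))) {
    stop(sprintf("titration CSV missing columns: %s",
                 paste(setdiff(need, names(raw)), collapse = ", ")),
         call. = FALSE)
  }
  raw$protein_present <- as.logical(raw$protein_present)
  groups <- split(raw, list(raw$compound_id, raw$condition), drop = TRUE)
  lapply(unname(groups), function(g) {
    pr <- g[g$protein_present, ]
    np <- g[!g$protein_present, ]
    pr <- pr[order(pr$conc_M), ]
    np <- np[order(np$conc_M), ]
    structure(list(
      compound_id = g$compound_id[1],
      condition = g$condition[1],
      concentrations = pr$conc_M,
      i_cy3 = pr$i_cy3, i_cy5 = pr$i_cy5,
      paired_no_protein = if (nrow(np) > 0) {
        list(concentrations = np$conc_M, i_cy3 = np$i_cy3, i_cy5 = np$i_cy5)
      } else NULL,
      calibration = calibration
    ), class = "titration_series")
  })
}

#' Write titration series to CSV
#'
#' @param series_list A list of `titration_series` (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series_list, path) {
  if (inherits(series_list, "titration_series")) {
    series_list <- list(series_list)
  }
  rows <- lapply(series_list, function(s) {
    pr <- data.frame(compound_id = s$compound_id, condition = s$condition,
                     conc_M = s$concentrations, i_cy3 = s$i_cy3,
                     i_cy5 = s$i_cy5, protein_present = TRUE)
    np <- if (!is.null(s$paired_no_protein)) {
      data.frame(compound_id = s$compound_id, condition = s$condition,
                 conc_M = s$paired_no_protein$concentrations,
                 i_cy3 = s$paired_no_protein$i_cy3,
                 i_cy5 = s$paired_no_protein$i_cy5,
                 protein_present = FALSE)
    }
    rbind(pr, np)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read annealing time courses from CSV
#'
#' Expects columns `compound_id, conc_M, t_s` and either a `fret` column
#' (calibrated, replicate-averaged) or raw `i_cy3, i_cy5` channels, which
#' are converted with [fret_app_calibrated()].
#'
#' @param path Path to the CSV file.
#' @param calibration Named calibration factors.
#' @return A list of `annealing_timecourse` objects.
#' @export
read_timecourse_csv <- function(path, calibration = c(g_cy3 = 1.7,
                                                      g_cy5 = 4.2)) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "conc_M", "t_s")
  if (!all(need %in% names(raw))) {
    stop(sprintf("time-course CSV missing columns: %s",
                 paste(setdiff(need, names(raw)), collapse = ", ")),
         call. = FALSE)
  }
  if (!("fret" %in% names(raw))) {
    if (!all(c("i_cy3", "i_cy5") %in% names(raw))) {
      stop("time-course CSV needs either a fret column or i_cy3/i_cy5",
           call. = FALSE)
    }
    raw$fret <- fret_app_calibrated(raw$i_cy3, raw$i_cy5,
                                    g_cy3 = calibration[["g_cy3"]],
                                    g_cy5 = calibration[["g_cy5"]])
  }
  groups <- split(raw, list(raw$compound_id, raw$conc_M), drop = TRUE)
  lapply(unname(groups), function(g) {
    g <- g[order(g$t_s), ]
    structure(list(compound_id = g$compound_id[1],
                   concentration = g$conc_M[1],
                   times = g$t_s, fret = g$fret),
              class = "annealing_timecourse")
  })
}

#' Write annealing time courses to CSV
#'
#' @param tc_list A list of `annealing_timecourse` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc_list, path) {
  if (inherits(tc_list, "annealing_timecourse")) tc_list <- list(tc_list)
  rows <- lapply(tc_list, function(tc) {
    data.frame(compound_id = tc$compound_id, conc_M = tc$concentration,
               t_s = tc$times, fret = tc$fret)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labeled docking-score CSV
#'
#' Expects columns `compound_id, pose_id, score, label` with labels
#' `active` / `decoy`.
#'
#' @param path Path to the CSV file.
#' @return A `score_set` data frame.
#' @export
read_score_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "pose_id", "score", "label")
  if (!all(need %in% names(raw))) {
    stop(sprintf("score CSV missing columns: %s",
                 paste(setdiff(need, names(raw)), collapse = ", ")),
         call. = FALSE)
  }
  structure(raw, class = c("score_set", "data.frame"))
}

#' Write a score set to CSV
#'
#' @param scores A `score_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_csv <- function(scores, path) {
  write.csv(as.data.frame(scores), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
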