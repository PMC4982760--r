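#' @importFrom stats rnorm median sd lm coef setNames predict quantile
#' @importFrom utils read.csv write.csv head
NULL

PLATE_ROWS <- LETTERS[1:16]
NEG_CONTROL_COLS <- c(1L, 24L)  # intact complex, high FRET
POS_CONTROL_COLS <- c(2L, 23L)  # poly(dT)-disrupted complex, low FRET
TEST_COLS <- 3:22

# inhibition model used throughout: f(c) = f_sat + (f0 - f_sat)/(1 + (c/ic50)^hill)
# c = 0 gives f0 exactly (0^hill = 0 for hill > 0)
inhibition_model <- function(conc, ic50, hill, f0, f_sat) {
  f_sat + (f0 - f_sat) / (1 + (conc / ic50)^hill)
}

# intensity-channel noise scaled so the induced FRET SD equals fret_sd
# (first-order propagation of independent channel noise through the ratio)
add_channel_noise <- function(fret, fret_sd, total) {
  if (fret_sd == 0) return(intensities_from_fret(fret, total))
  sd_i <- fret_sd * total / sqrt(fret^2 + (1 - fret)^2)
  base <- intensities_from_fret(fret, total)
  data.frame(
    i_cy3 = pmax(base$i_cy3 + rnorm(length(fret), 0, sd_i), 0),
    i_cy5 = pmax(base$i_cy5 + rnorm(length(fret), 0, sd_i), 0)
  )
}

#' Generate a synthetic screening dataset
#'
#' Simulates a single-concentration screening campaign on 384-well plates
#' laid out as in the original assay: intact-complex (high FRET, "negative")
#' controls in columns 1 and 24, disrupted-complex (low FRET, "positive")
#' controls in columns 2 and 23, and test compounds in columns 3-22.
#' Planted actives have their expected FRET depressed by
#' `config$active_effect`; a configurable fraction of the remaining
#' compounds receive a spurious optical FRET offset. Channel intensities
#' are emitted so that [fret_app_raw()] recovers the simulated FRET.
#'
#' @param config A [screen_sim_config()].
#' @return A `screen_dataset`: a data frame of wells with columns
#'   `plate_id, row, col, role, compound_id, conc_M, i_cy3, i_cy5` and
#'   attributes `truth` (the planted active and artifact compound ids) and
#'   `config`.
#' @export
gen_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  withr::with_seed(config$seed, {
    n_compounds <- config$n_plates * config$compounds_per_plate
    compound_ids <- sprintf("CMP%05d", seq_len(n_compounds))
    actives <- sort(sample(n_compounds, config$n_planted_actives))
    inactive_pool <- setdiff(seq_len(n_compounds), actives)
    n_art <- round(config$artifact_fraction * length(inactive_pool))
    artifacts <- sort(sample(inactive_pool, n_art))

    plates <- vector("list", config$n_plates)
    for (p in seq_len(config$n_plates)) {
      grid <- expand.grid(row = PLATE_ROWS, col = 1:24,
                          stringsAsFactors = FALSE)
      grid <- grid[order(grid$col, grid$row), ]
      role <- ifelse(grid$col %in% NEG_CONTROL_COLS, "neg_control",
              ifelse(grid$col %in% POS_CONTROL_COLS, "pos_control", "test"))
      # compounds fill test wells column-wise; unused test wells stay empty
      test_idx <- which(role == "test")
      n_this <- config$compounds_per_plate
      global <- (p - 1L) * n_this + seq_len(n_this)
      compound <- rep(NA_character_, nrow(grid))
      compound[test_idx[seq_len(n_this)]] <- compound_ids[global]

      fret <- rep(NA_real_, nrow(grid))
      fret[role == "neg_control"] <- config$fret_neg
      fret[role == "pos_control"] <- config$fret_pos
      is_filled <- !is.na(compound)
      glob_of_well <- match(compound, compound_ids)
      fret[is_filled] <- config$fret_neg
      fret[is_filled & glob_of_well %in% actives] <-
        config$fret_neg - config$active_effect
      fret[is_filled & glob_of_well %in% artifacts] <-
        config$fret_neg + config$artifact_effect
      keep <- !is.na(fret)
      grid <- grid[keep, ]
      role <- role[keep]
      compound <- compound[keep]
      fret <- pmin(pmax(fret[keep], 0), 1)

      inten <- if (config$noise_model == "fret") {
        f_obs <- pmin(pmax(fret + rnorm(length(fret), 0, config$well_noise_sd),
                           0), 1)
        intensities_from_fret(f_obs, config$total_intensity)
      } else {
        add_channel_noise(fret, config$well_noise_sd, config$total_intensity)
      }
      plates[[p]] <- data.frame(
        plate_id = sprintf("P%02d", p),
        row = grid$row, col = grid$col, role = role,
        compound_id = compound,
        conc_M = ifelse(role == "test", 15e-6, 0),
        i_cy3 = inten$i_cy3, i_cy5 = inten$i_cy5,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, plates)
    rownames(out) <- NULL
    structure(out,
              truth = list(actives = compound_ids[actives],
                           artifacts = compound_ids[artifacts]),
              config = config,
              class = c("screen_dataset", "data.frame"))
  })
}

#' Generate a synthetic compound titration
#'
#' Simulates titration of a compound into a preformed protein-DNA complex
#' together with the paired no-protein control series (free labeled DNA
#' plus compound). Protein-present FRET follows the inhibition model
#' `f_sat + (f0 - f_sat)/(1 + (c/ic50)^hill)`; the compound's optical
#' artifact (a linear-in-log-concentration FRET offset) is added to both
#' series, so the paired correction of [correct_for_compound()] removes it.
#' Both series include a zero-compound baseline point and are emitted as
#' calibrated channel intensities.
#'
#' @param config A [titration_sim_config()].
#' @param compound_id,condition Identifiers carried into the output.
#' @return A `titration_series` object (see [correct_for_compound()]).
#' @export
gen_titration <- function(config, compound_id = "CMP00001",
                          condition = "ssDNA") {
  stopifnot(inherits(config, "titration_sim_config"))
  withr::with_seed(config$seed, {
    conc <- c(0, config$concentrations)
    artifact <- ifelse(
      conc > 0,
      config$artifact_slope * log10(conc / min(config$concentrations)),
      0
    )
    f_prot <- inhibition_model(conc, config$ic50, config$hill,
                               config$f0, config$f_sat) + artifact
    f_nop <- config$f_free + artifact

    avg_noisy <- function(f_true) {
      reps <- replicate(config$n_replicates,
                        f_true + rnorm(length(f_true), 0, config$noise_sd))
      rowMeans(matrix(reps, nrow = length(f_true)))
    }
    f_prot_obs <- pmin(pmax(avg_noisy(f_prot), 0), 1)
    f_nop_obs <- pmin(pmax(avg_noisy(f_nop), 0), 1)

    ip <- intensities_from_fret(f_prot_obs, config$total_intensity,
                                calibrate = TRUE)
    inp <- intensities_from_fret(f_nop_obs, config$total_intensity,
                                 calibrate = TRUE)
    structure(list(
      compound_id = compound_id,
      condition = condition,
      concentrations = conc,
      i_cy3 = ip$i_cy3, i_cy5 = ip$i_cy5,
      paired_no_protein = list(concentrations = conc,
                               i_cy3 = inp$i_cy3, i_cy5 = inp$i_cy5),
      calibration = c(g_cy3 = 1.7, g_cy5 = 4.2),
      config = config
    ), class = "titration_series")
  })
}

#' Generate synthetic annealing time courses
#'
#' Simulates FRET-monitored annealing traces, one per compound
#' concentration, over the reaction window. Each trace follows
#' `F(t) = F_inf - A1 exp(-k1 t) - A2 exp(-k2 t)` with total amplitude
#' `F_inf - f_baseline` split between the two phases, plus pointwise
#' Gaussian noise.
#'
#' @param config An [annealing_sim_config()].
#' @param compound_id Identifier carried into the output.
#' @return A list of `annealing_timecourse` objects, one per entry of
#'   `config$extents_by_conc`, each with fields `compound_id,
#'   concentration, times, fret`.
#' @export
gen_annealing <- function(config, compound_id = "CMP00001") {
  stopifnot(inherits(config, "annealing_sim_config"))
  withr::with_seed(config$seed, {
    times <- seq(0, config$t_max, by = config$dt)
    lapply(seq_along(config$extents_by_conc), function(i) {
      conc <- as.numeric(names(config$extents_by_conc)[i])
      f_inf <- config$extents_by_conc[[i]]
      amp <- f_inf - config$f_baseline
      a1 <- config$amp_split * amp
      a2 <- amp - a1
      f <- f_inf - a1 * exp(-config$k1 * times) - a2 * exp(-config$k2 * times)
      f <- f + rnorm(length(times), 0, config$noise_sd)
      structure(list(compound_id = compound_id, concentration = conc,
                     times = times, fret = f),
                class = "annealing_timecourse")
    })
  })
}

#' Generate a synthetic labeled docking-score set
#'
#' Draws pose scores for actives and decoys from two Gaussians on a
#' lower-is-better (kcal/mol) scale, emulating the bimodal score
#' distribution of a docking run validated against property-matched
#' decoys. Poses are grouped into compounds for best-pose summaries.
#'
#' @param config A [score_sim_config()].
#' @return A `score_set`: data frame with columns
#'   `compound_id, pose_id, score, label`.
#' @export
gen_pose_scores <- function(config) {
  stopifnot(inherits(config, "score_sim_config"))
  withr::with_seed(config$seed, {
    mk <- function(n, mean, sd, label, prefix) {
      n_cmp <- ceiling(n / config$poses_per_compound)
      cmp <- rep(sprintf("%s%04d", prefix, seq_len(n_cmp)),
                 each = config$poses_per_compound)[seq_len(n)]
      data.frame(
        compound_id = cmp,
        pose_id = sprintf("%s_p%02d", cmp,
                          stats::ave(seq_len(n), cmp, FUN = seq_along)),
        score = rnorm(n, mean, sd),
        label = label,
        stringsAsFactors = FALSE
      )
    }
    out <- rbind(
      mk(config$n_active_poses, config$active_mean, config$active_sd,
         "active", "ACT"),
      mk(config$n_decoy_poses, config$decoy_mean, config$decoy_sd,
         "decoy", "DEC")
    )
    rownames(out) <- NULL
    structure(out, config = config,
              class = c("score_set", "data.frame"))
  })
}
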