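#' Configuration for the synthetic screening-plate generator
#'
#' Describes a simulated single-concentration screening campaign: plates of
#' 384 wells (16 rows x 24 columns) with intact-complex control wells in
#' columns 1-2 (high FRET, the "negative" control of this assay) and
#' disrupted-complex controls in columns 23-24 (low FRET, "positive"
#' control), and test compounds in columns 3-22 (320 per plate). A chosen
#' number of library compounds are planted as true actives whose expected
#' FRET is depressed by `active_effect`; a fraction of the inactive
#' compounds can be given a spurious optical offset to emulate fluorescent
#' or quenching compounds.
#'
#' @param n_plates Number of 384-well plates.
#' @param compounds_per_plate Test compounds per plate (default 320, the
#'   capacity of the 20 test columns).
#' @param n_planted_actives Number of compounds planted as true actives.
#' @param active_effect FRET depression of a planted active relative to the
#'   intact-complex mean. Default `fret_neg - fret_pos` (full disruption).
#' @param well_noise_sd Per-well FRET standard deviation (FRET units).
#' @param fret_neg Mean FRET of the intact protein-DNA complex control
#'   (default 0.63, a stoichiometric wrapped complex).
#' @param fret_pos Mean FRET of the disrupted-complex control (default 0.30,
#'   the complex challenged with excess unlabeled ssDNA).
#' @param artifact_fraction Fraction of inactive compounds given an optical
#'   artifact offset.
#' @param artifact_effect FRET offset applied to artifact compounds (may be
#'   negative to emulate false positives).
#' @param total_intensity Summed two-channel intensity per well (arbitrary
#'   units; only the ratio matters downstream).
#' @param noise_model `"intensity"` (additive Gaussian on each channel,
#'   scaled so the induced FRET SD equals `well_noise_sd`) or `"fret"`
#'   (Gaussian directly on the FRET value, then converted to intensities).
#' @param seed Integer seed; the same seed and config reproduce the dataset
#'   exactly.
#' @return An object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_plates = 9,
                              compounds_per_plate = 320,
                              n_planted_actives = 0,
                              active_effect = fret_neg - fret_pos,
                              well_noise_sd = 0.005,
                              fret_neg = 0.63,
                              fret_pos = 0.30,
                              artifact_fraction = 0,
                              artifact_effect = -0.1,
                              total_intensity = 1000,
                              noise_model = c("intensity", "fret"),
                              seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_plates >= 1, compounds_per_plate >= 1,
            compounds_per_plate <= 320,
            n_planted_actives >= 0, well_noise_sd >= 0,
            artifact_fraction >= 0, artifact_fraction <= 1,
            total_intensity > 0)
  if (!(fret_pos >= 0 && fret_pos < fret_neg && fret_neg <= 1)) {
    stop("require 0 <= fret_pos < fret_neg <= 1", call. = FALSE)
  }
  if (n_planted_actives > n_plates * compounds_per_plate) {
    stop("n_planted_actives exceeds the library size", call. = FALSE)
  }
  structure(list(
    n_plates = as.integer(n_plates),
    compounds_per_plate = as.integer(compounds_per_plate),
    n_planted_actives = as.integer(n_planted_actives),
    active_effect = active_effect,
    well_noise_sd = well_noise_sd,
    fret_neg = fret_neg,
    fret_pos = fret_pos,
    artifact_fraction = artifact_fraction,
    artifact_effect = artifact_effect,
    total_intensity = total_intensity,
    noise_model = noise_model,
    seed = as.integer(seed)
  ), class = "screen_sim_config")
}

#' Configuration for the synthetic titration generator
#'
#' Describes a compound titration into a preformed protein-DNA complex.
#' The protein-present FRET follows the four-parameter inhibition model
#' `f(c) = f_sat + (f0 - f_sat) / (1 + (c / ic50)^hill)`; a paired
#' no-protein series (free labeled DNA plus compound) carries the compound's
#' optical artifact, modeled as a linear-in-log-concentration FRET offset
#' that also rides on the protein series so that the standard paired
#' correction removes it.
#'
#' @param ic50 Half-maximal inhibitory concentration, molar.
#' @param hill Hill slope (> 0).
#' @param f0 FRET of the uninhibited complex (zero compound).
#' @param f_sat FRET plateau at complete inhibition.
#' @param f_free FRET of the free labeled DNA without protein (default 0.48,
#'   a 30-mer with terminal dyes).
#' @param concentrations Strictly positive, sorted molar concentrations.
#'   Default: 12 points log-spaced over `[ic50/30, 30 * ic50]`.
#' @param noise_sd FRET-level noise SD per point.
#' @param artifact_slope FRET offset per decade of concentration (0 = clean
#'   compound), anchored to 0 at the lowest tested concentration.
#' @param n_replicates Replicate readings averaged per point.
#' @param total_intensity Summed channel intensity per reading.
#' @param seed Integer seed.
#' @return An object of class `titration_sim_config`.
#' @export
titration_sim_config <- function(ic50,
                                 hill = 1,
                                 f0 = 0.63,
                                 f_sat = 0.45,
                                 f_free = 0.48,
                                 concentrations = NULL,
                                 noise_sd = 0.01,
                                 artifact_slope = 0,
                                 n_replicates = 3,
                                 total_intensity = 1000,
                                 seed = 1L) {
  stopifnot(ic50 > 0, hill > 0, noise_sd >= 0, n_replicates >= 1,
            f0 >= 0, f0 <= 1, f_sat >= 0, f_sat <= 1)
  if (is.null(concentrations)) {
    concentrations <- exp(seq(log(ic50 / 30), log(30 * ic50), length.out = 12))
  }
  if (any(concentrations <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be sorted ascending without duplicates",
         call. = FALSE)
  }
  structure(list(
    ic50 = ic50, hill = hill, f0 = f0, f_sat = f_sat, f_free = f_free,
    concentrations = concentrations, noise_sd = noise_sd,
    artifact_slope = artifact_slope,
    n_replicates = as.integer(n_replicates),
    total_intensity = total_intensity, seed = as.integer(seed)
  ), class = "titration_sim_config")
}

#' Configuration for the synthetic annealing time-course generator
#'
#' Describes FRET-monitored annealing of two complementary labeled
#' oligonucleotides over a fixed reaction window (default 500 s). Each
#' trace rises from `f_baseline` to its asymptote `F_inf` as a
#' biexponential, `F(t) = F_inf - A1 exp(-k1 t) - A2 exp(-k2 t)` with
#' `A1 + A2 = F_inf - f_baseline` and `A1 = amp_split * (F_inf -
#' f_baseline)`. Compound inhibition is expressed through the per-
#' concentration asymptotes in `extents_by_conc`.
#'
#' @param f_baseline FRET before annealing starts.
#' @param extents_by_conc Named numeric vector: names are molar compound
#'   concentrations (`"0"` allowed for the no-compound reference), values
#'   the asymptotic FRET.
#' @param k1,k2 Fast and slow phase rates, per second (> 0).
#' @param amp_split Fraction of the total amplitude in the fast phase.
#' @param t_max Reaction window, seconds (default 500).
#' @param dt Sampling interval, seconds.
#' @param noise_sd FRET-level noise SD per time point.
#' @param seed Integer seed.
#' @return An object of class `annealing_sim_config`.
#' @export
annealing_sim_config <- function(f_baseline = 0.2,
                                 extents_by_conc,
                                 k1 = 0.05,
                                 k2 = 0.005,
                                 amp_split = 0.7,
                                 t_max = 500,
                                 dt = 2,
                                 noise_sd = 0.01,
                                 seed = 1L) {
  stopifnot(k1 > 0, k2 > 0, amp_split >= 0, amp_split <= 1, noise_sd >= 0)
  if (t_max <= 0) stop("t_max must be positive", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (is.null(names(extents_by_conc)) ||
      anyNA(suppressWarnings(as.numeric(names(extents_by_conc))))) {
    stop("extents_by_conc must be named by numeric concentrations",
         call. = FALSE)
  }
  structure(list(
    f_baseline = f_baseline, extents_by_conc = extents_by_conc,
    k1 = k1, k2 = k2, amp_split = amp_split,
    t_max = t_max, dt = dt, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "annealing_sim_config")
}

#' Configuration for the synthetic docking-score generator
#'
#' Emulates the bimodal score distribution of a docking run rescored
#' against property-matched decoys: active poses drawn from one Gaussian,
#' decoy poses from another, on a lower-is-better (free energy, kcal/mol)
#' scale.
#'
#' @param n_active_poses,n_decoy_poses Pose counts (> 0).
#' @param active_mean,active_sd Score distribution of active poses.
#' @param decoy_mean,decoy_sd Score distribution of decoy poses.
#' @param poses_per_compound Poses grouped per compound id (for best-pose
#'   summaries).
#' @param seed Integer seed.
#' @return An object of class `score_sim_config`.
#' @export
score_sim_config <- function(n_active_poses = 500,
                             n_decoy_poses = 5000,
                             active_mean = -9,
                             active_sd = 0.8,
                             decoy_mean = -5.5,
                             decoy_sd = 1.0,
                             poses_per_compound = 10,
                             seed = 1L) {
  stopifnot(n_active_poses > 0, n_decoy_poses > 0,
            active_sd > 0, decoy_sd > 0, poses_per_compound >= 1)
  structure(list(
    n_active_poses = as.integer(n_active_poses),
    n_decoy_poses = as.integer(n_decoy_poses),
    active_mean = active_mean, active_sd = active_sd,
    decoy_mean = decoy_mean, decoy_sd = decoy_sd,
    poses_per_compound = as.integer(poses_per_compound),
    seed = as.integer(seed)
  ), class = "score_sim_config")
}
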