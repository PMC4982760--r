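test_that("zero-noise screen puts every well exactly at its target FRET", {
  ds <- make_screen(n_actives = 0, noise = 0)
  f <- fret_app_raw(ds$i_cy3, ds$i_cy5)
  expect_equal(unname(f[ds$role == "test"]),
               rep(0.63, sum(ds$role == "test")))
  expect_equal(unname(f[ds$role == "neg_control"]),
               rep(0.63, sum(ds$role == "neg_control")))
  expect_equal(unname(f[ds$role == "pos_control"]),
               rep(0.30, sum(ds$role == "pos_control")))
})

test_that("a full-effect active lands exactly on the disrupted-control mean", {
  ds <- gen_screen(screen_sim_config(n_plates = 1, n_planted_actives = 1,
                                     well_noise_sd = 0, seed = 11))
  truth <- attr(ds, "truth")$actives
  w <- ds[!is.na(ds$compound_id) & ds$compound_id == truth, ]
  expect_equal(fret_app_raw(w$i_cy3, w$i_cy5), 0.30)
})

test_that("plate layout matches the control design", {
  ds <- make_screen(seed = 2)
  expect_setequal(unique(ds$col[ds$role == "neg_control"]), c(1, 24))
  expect_setequal(unique(ds$col[ds$role == "pos_control"]), c(2, 23))
  expect_true(all(ds$col[ds$role == "test"] %in% 3:22))
  per_plate <- table(ds$plate_id, ds$role)
  expect_true(all(per_plate[, "neg_control"] == 32))
  expect_true(all(per_plate[, "pos_control"] == 32))
  expect_true(all(per_plate[, "test"] == 320))
})

test_that("active detection rate matches the normal tail probability", {
  # effect 10 sigma, threshold 5 sigma: pass probability Phi(5); with
  # 96 actives the expected number of misses is ~3e-5, so all must pass
  sigma <- 0.01
  ds <- gen_screen(screen_sim_config(
    n_plates = 9, n_planted_actives = 96, active_effect = 10 * sigma,
    well_noise_sd = sigma, noise_model = "fret", seed = 17))
  hits <- call_hits(ds, k = 5, zprime_floor = -Inf)
  truth <- attr(ds, "truth")$actives
  frac <- mean(hits$is_hit[hits$compound_id %in% truth])
  expect_gte(frac, pnorm(5) - 3 * sqrt(pnorm(5) * (1 - pnorm(5)) / 96))
})

test_that("titration generator obeys the inhibition-model identities", {
  cfg <- titration_sim_config(ic50 = 2e-6, f0 = 0.63, f_sat = 0.45,
                              concentrations = c(1e-8, 1e-7, 2e-6, 1e-5, 1e-4),
                              noise_sd = 0, seed = 1)
  ser <- gen_titration(cfg)
  f <- fret_app_calibrated(ser$i_cy3, ser$i_cy5)
  # midpoint identity at c = ic50
  expect_equal(f[ser$concentrations == 2e-6], (0.63 + 0.45) / 2,
               tolerance = 1e-10)
  # zero-compound baseline anchors f0; c -> 0 limit approaches f0
  expect_equal(f[ser$concentrations == 0], 0.63, tolerance = 1e-10)
  expect_equal(f[ser$concentrations == 1e-8], 0.63, tolerance = 0.006)
})

test_that("titration midpoint matches the strongest reported inhibitor class", {
  # parameters of a ~1.8 uM inhibitor with saturation FRET 0.45
  cfg <- titration_sim_config(ic50 = 1.8e-6, f0 = 0.63, f_sat = 0.45,
                              concentrations = sort(c(1.8e-6,
                                exp(seq(log(6e-8), log(5.4e-5), length.out = 9)))),
                              noise_sd = 0, seed = 1)
  ser <- gen_titration(cfg)
  f <- fret_app_calibrated(ser$i_cy3, ser$i_cy5)
  expect_equal(f[ser$concentrations == 1.8e-6], (0.63 + 0.45) / 2,
               tolerance = 1e-10)
})

test_that("annealing traces start at baseline and rise to the asymptote", {
  cfg <- annealing_sim_config(f_baseline = 0.2,
                              extents_by_conc = c("0" = 0.6),
                              k1 = 0.05, k2 = 0.005, noise_sd = 0,
                              t_max = 5000, dt = 2, seed = 1)
  tc <- gen_annealing(cfg)[[1]]
  expect_equal(tc$fret[tc$times == 0], 0.2)
  expect_equal(tail(tc$fret, 1), 0.6, tolerance = 1e-6)
})

test_that("half-rise time of a generated trace matches a numeric root-find", {
  cfg <- annealing_sim_config(f_baseline = 0.2,
                              extents_by_conc = c("0" = 0.6),
                              k1 = 0.05, k2 = 0.005, amp_split = 0.7,
                              noise_sd = 0, t_max = 500, dt = 0.1, seed = 1)
  tc <- gen_annealing(cfg)[[1]]
  half <- 0.4
  t_emp <- approx(tc$fret, tc$times, xout = half)$y
  closed <- function(t) {
    0.6 - 0.7 * 0.4 * exp(-0.05 * t) - 0.3 * 0.4 * exp(-0.005 * t) - half
  }
  t_oracle <- uniroot(closed, c(0, 500), tol = 1e-10)$root
  expect_equal(t_emp, t_oracle, tolerance = 1e-3)
})

test_that("non-overlapping score distributions give AUC 1", {
  cfg <- score_sim_config(n_active_poses = 50, n_decoy_poses = 50,
                          active_mean = -12, active_sd = 0.1,
                          decoy_mean = -2, decoy_sd = 0.1, seed = 4)
  ss <- gen_pose_scores(cfg)
  expect_true(max(ss$score[ss$label == "active"]) <
                min(ss$score[ss$label == "decoy"]))
  expect_equal(build_roc(ss)$auc, 1)
})

test_that("identical score distributions give AUC near 0.5 at large n", {
  cfg <- score_sim_config(n_active_poses = 5e4, n_decoy_poses = 5e4,
                          active_mean = -6, active_sd = 1,
                          decoy_mean = -6, decoy_sd = 1, seed = 8)
  ss <- gen_pose_scores(cfg)
  # Monte-Carlo: SE of AUC ~ 1/sqrt(12 * min(n_a, n_d)) scale
  expect_equal(build_roc(ss)$auc, 0.5, tolerance = 0.01)
})

test_that("default score config is bimodal: two separated histogram modes", {
  ss <- gen_pose_scores(score_sim_config(seed = 3))
  h <- score_histogram(ss, bin_width = 0.5)
  mode_a <- h$mids[which.max(h$counts_active)]
  mode_d <- h$mids[which.max(h$counts_decoy)]
  expect_gt(abs(mode_a - mode_d), 2 * 0.5)
  expect_gt(h$separation, 2)
})

test_that("every generator is bit-reproducible under its seed", {
  expect_identical(make_screen(n_actives = 10, seed = 42),
                   make_screen(n_actives = 10, seed = 42))
  tcfg <- function(s) titration_sim_config(ic50 = 1e-6, seed = s)
  expect_identical(gen_titration(tcfg(42)), gen_titration(tcfg(42)))
  acfg <- function(s) annealing_sim_config(
    extents_by_conc = c("0" = 0.6, "1e-05" = 0.3), seed = s)
  expect_identical(gen_annealing(acfg(42)), gen_annealing(acfg(42)))
  scfg <- function(s) score_sim_config(n_active_poses = 100,
                                       n_decoy_poses = 100, seed = s)
  expect_identical(gen_pose_scores(scfg(42)), gen_pose_scores(scfg(42)))
  # different seeds differ
  expect_false(identical(gen_pose_scores(scfg(1)), gen_pose_scores(scfg(2))))
})

test_that("noise realizations differ across seeds but share the expectation", {
  cfg <- function(s) titration_sim_config(
    ic50 = 2e-6, f0 = 0.63, f_sat = 0.45,
    concentrations = c(2e-6), noise_sd = 0.02, n_replicates = 1, seed = s)
  vals <- vapply(1:200, function(s) {
    ser <- gen_titration(cfg(s))
    fret_app_calibrated(ser$i_cy3[2], ser$i_cy5[2])
  }, numeric(1))
  se <- 0.02 / sqrt(200)
  expect_lt(abs(mean(vals) - 0.54), 3 * se)
})

test_that("intensity round trip recovers the simulated FRET", {
  ds <- make_screen(n_actives = 20, seed = 9, noise = 0.005)
  f <- fret_app_raw(ds$i_cy3, ds$i_cy5)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(ds$i_cy3 >= 0 & ds$i_cy5 >= 0))
  mu_neg <- mean(f[ds$role == "neg_control"])
  expect_equal(mu_neg, 0.63, tolerance = 0.002)
  expect_equal(sd(f[ds$role == "neg_control"]), 0.005, tolerance = 0.3)
})

test_that("config validation catches impossible simulations", {
  expect_error(screen_sim_config(fret_neg = 0.3, fret_pos = 0.6),
               "fret_pos < fret_neg")
  expect_error(screen_sim_config(n_plates = 1, n_planted_actives = 400),
               "library size")
  expect_error(titration_sim_config(ic50 = -1))
  expect_error(titration_sim_config(ic50 = 1e-6,
                                    concentrations = c(0, 1e-6)),
               "strictly positive")
  expect_error(annealing_sim_config(extents_by_conc = c("0" = 0.6),
                                    t_max = -5), "t_max")
  expect_error(annealing_sim_config(extents_by_conc = c("0" = 0.6),
                                    dt = 0), "dt")
})
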