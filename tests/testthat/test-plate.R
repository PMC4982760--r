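test_that("plate QC reproduces the hand-computed control statistics", {
  # neg controls: mean 0.6, SD 0.01; pos: mean 0.3, SD 0.01 (exact moments)
  pl <- rbind(wells_with_moments("P1", "neg_control", 1, 0.6, 0.01),
              wells_with_moments("P1", "pos_control", 2, 0.3, 0.01))
  qc <- plate_qc(pl)
  expect_equal(qc$mu_neg, 0.6)
  expect_equal(qc$sd_neg, 0.01)
  expect_equal(qc$zprime, 1 - 3 * 0.02 / 0.3)  # 0.8
  expect_equal(qc$s2n, 30)
  expect_equal(qc$s2b, 2)
  expect_true(is.na(qc$diagnostic))
})

test_that("zero-SD controls give the Z' = 1 limit", {
  pl <- rbind(wells_with_moments("P1", "neg_control", 1, 0.6, 0),
              wells_with_moments("P1", "pos_control", 2, 0.3, 0))
  expect_equal(plate_qc(pl)$zprime, 1)
})

test_that("paper-regime controls land in the high-Z' regime", {
  ds <- gen_screen(screen_sim_config(n_plates = 3, well_noise_sd = 0.005,
                                     seed = 21))
  qc <- plate_qc(ds)
  expect_true(all(qc$zprime > 0.85))
  expect_true(all(qc$zprime <= 1))
})

test_that("degenerate or swapped controls raise diagnostics", {
  pl <- rbind(wells_with_moments("P1", "neg_control", 1, 0.5, 0.01),
              wells_with_moments("P1", "pos_control", 2, 0.5, 0.01))
  qc <- plate_qc(pl)
  expect_true(is.nan(qc$zprime))
  expect_match(qc$diagnostic, "coincident")

  swapped <- rbind(wells_with_moments("P2", "neg_control", 1, 0.3, 0.01),
                   wells_with_moments("P2", "pos_control", 2, 0.6, 0.01))
  qc2 <- plate_qc(swapped)
  expect_match(qc2$diagnostic, "inverted")

  expect_error(plate_qc(wells_with_moments("P3", "neg_control", 1, 0.6, 0.01)),
               "control role")
})

test_that("the hit boundary is inclusive and anchored to the same plate", {
  pl <- rbind(wells_with_moments("P1", "neg_control", 1, 0.6, 0.01),
              wells_with_moments("P1", "pos_control", 2, 0.3, 0.002))
  boundary <- 0.6 - 5 * 0.01
  test_wells <- data.frame(
    plate_id = "P1", row = c("A", "B", "C"), col = 3, role = "test",
    compound_id = c("AT_BOUNDARY", "AT_NEG_MEAN", "BELOW"),
    conc_M = 15e-6,
    i_cy5 = c(boundary, 0.6, 0.2) * 1000,
    i_cy3 = (1 - c(boundary, 0.6, 0.2)) * 1000,
    stringsAsFactors = FALSE)
  hits <- call_hits(rbind(pl, test_wells), k = 5)
  expect_true(hits$is_hit[hits$compound_id == "AT_BOUNDARY"])
  expect_false(hits$is_hit[hits$compound_id == "AT_NEG_MEAN"])
  expect_true(hits$is_hit[hits$compound_id == "BELOW"])
  expect_equal(hits$sd_below_neg[hits$compound_id == "AT_BOUNDARY"], 5)
})

test_that("hit calling is monotone in well FRET", {
  set.seed(31)
  pl <- rbind(wells_with_moments("P1", "neg_control", 1, 0.63, 0.005),
              wells_with_moments("P1", "pos_control", 2, 0.30, 0.005))
  frets <- seq(0.2, 0.65, length.out = 30)
  wells <- data.frame(plate_id = "P1", row = rep(LETTERS[1:15], 2),
                      col = rep(3:4, each = 15), role = "test",
                      compound_id = sprintf("W%02d", 1:30), conc_M = 15e-6,
                      i_cy5 = frets * 1000, i_cy3 = (1 - frets) * 1000,
                      stringsAsFactors = FALSE)
  hits <- call_hits(rbind(pl, wells), k = 5)
  called <- hits$is_hit[order(hits$fret_app)]
  # hits form a prefix of the FRET-sorted wells: no non-hit below a hit
  expect_true(all(diff(as.integer(called)) <= 0))
})

test_that("zero-noise screens recover the planted actives exactly", {
  for (seed in c(5, 23)) {
    ds <- make_screen(n_actives = 40, seed = seed, noise = 0)
    hits <- call_hits(ds, zprime_floor = -Inf)
    expect_setequal(hits$compound_id[hits$is_hit],
                    attr(ds, "truth")$actives)
  }
})

test_that("a campaign-scale screen with planted actives yields exact recovery", {
  ds <- make_screen(n_actives = 96, seed = 7)
  hits <- call_hits(ds, k = 5)
  expect_equal(sum(hits$is_hit), 96)
  expect_setequal(hits$compound_id[hits$is_hit], attr(ds, "truth")$actives)
})

test_that("plates failing the Z' floor are excluded with a qc_failed flag", {
  ds <- gen_screen(screen_sim_config(n_plates = 2, n_planted_actives = 10,
                                     well_noise_sd = 0.08, seed = 13))
  qc <- plate_qc(ds)
  expect_true(all(qc$zprime < 0.5))  # noise this large destroys the assay
  hits <- call_hits(ds, zprime_floor = 0.5)
  expect_true(all(!hits$is_hit))
  expect_true(all(hits$flags == "qc_failed"))
})

test_that("confirmation requires passing every rescreen round", {
  primary <- make_screen(n_actives = 20, seed = 41)
  truth <- attr(primary, "truth")$actives
  hits <- call_hits(primary)
  expect_setequal(hits$compound_id[hits$is_hit], truth)

  # round 1: all actives still active; round 2: only the first 8 reproduce
  rescreen_with <- function(active_ids, seed) {
    ds <- make_screen(n_actives = 0, seed = seed)
    rows <- ds$compound_id %in% active_ids
    f <- 0.30
    ds$i_cy5[rows] <- f * 1000
    ds$i_cy3[rows] <- (1 - f) * 1000
    ds
  }
  reproducible <- truth[1:8]
  rounds <- list(rescreen_with(truth, seed = 61),
                 rescreen_with(reproducible, seed = 62))
  conf <- confirm_hits(hits, rounds)
  expect_setequal(conf$compound_id[conf$confirmed], reproducible)
  failed <- conf[!conf$confirmed & conf$compound_id %in% truth, ]
  expect_true(all(failed$reason == "poor reproducibility"))
})

test_that("compounds absent from a rescreen are untested, not confirmed", {
  primary <- make_screen(n_actives = 5, seed = 43)
  hits <- call_hits(primary)
  # rescreen plate lacks these compound ids entirely
  rescreen <- gen_screen(screen_sim_config(n_plates = 1,
                                           n_planted_actives = 0, seed = 44))
  rescreen$compound_id <- sub("^CMP", "OTH", rescreen$compound_id)
  conf <- confirm_hits(hits, list(rescreen))
  expect_true(all(!conf$confirmed))
  expect_true(all(grepl("untested", conf$reason)))
})

test_that("artifact signatures are separated from genuine inhibition", {
  conc <- exp(seq(log(1e-7), log(1e-4), length.out = 8))
  # linear concentration dependence, no saturation: classic false positive
  linear <- data.frame(compound_id = "LIN", conc_M = conc,
                       fret = 0.63 + 1500 * conc)
  # flat within noise
  set.seed(71)
  flat <- data.frame(compound_id = "FLAT", conc_M = conc,
                     fret = 0.63 + rnorm(8, 0, 0.005))
  # genuine inhibitor at 10:1 signal-to-noise
  set.seed(72)
  real <- data.frame(compound_id = "REAL", conc_M = conc,
                     fret = 0.45 + 0.18 / (1 + conc / 2e-6) +
                       rnorm(8, 0, 0.018))
  flags <- flag_optical_artifacts(rbind(linear, flat, real))
  expect_match(flags$flags[flags$compound_id == "LIN"],
               "LINEAR_CONC_DEPENDENCE")
  expect_equal(flags$flags[flags$compound_id == "FLAT"], "")
  expect_equal(flags$flags[flags$compound_id == "REAL"], "")
})

test_that("artifact flags separate planted artifact compounds from actives", {
  # ten artifact-like series (linear rise, no true effect) vs ten actives
  conc <- exp(seq(log(1e-7), log(1e-4), length.out = 10))
  set.seed(73)
  series <- do.call(rbind, c(
    lapply(1:10, function(i) data.frame(
      compound_id = sprintf("ART%02d", i), conc_M = conc,
      fret = 0.63 + 2000 * conc + rnorm(10, 0, 0.0005))),
    lapply(1:10, function(i) data.frame(
      compound_id = sprintf("ACT%02d", i), conc_M = conc,
      fret = 0.45 + 0.18 / (1 + conc / 2e-6) + rnorm(10, 0, 0.005)))
  ))
  flags <- flag_optical_artifacts(series)
  art <- grepl("^ART", flags$compound_id)
  expect_true(all(grepl("LINEAR_CONC_DEPENDENCE", flags$flags[art])))
  expect_true(all(flags$flags[!art] == ""))
})

test_that("high background and short series get their own flags", {
  short <- data.frame(compound_id = "SHORT", conc_M = c(1e-6, 1e-5),
                      fret = c(0.6, 0.6))
  expect_equal(flag_optical_artifacts(short)$flags, "UNEVALUABLE")

  conc <- exp(seq(log(1e-7), log(1e-4), length.out = 6))
  bg <- data.frame(compound_id = "BG", conc_M = conc,
                   fret = rep(0.63, 6), background = rep(0.9, 6))
  expect_match(flag_optical_artifacts(bg)$flags, "HIGH_BACKGROUND")
})
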