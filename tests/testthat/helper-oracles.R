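# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Mann-Whitney pair-counting AUC: probability a random active pose scores
# better (lower) than a random decoy pose, ties counted 1/2.
auc_pair_count <- function(scores, labels) {
  a <- scores[labels == "active"]
  d <- scores[labels == "decoy"]
  cmp <- outer(a, d, function(x, y) (x < y) + 0.5 * (x == y))
  mean(cmp)
}

# Brute-force inhibition fit: dense log grid over ic50, coarse hill set,
# linear solve of the two plateaus at each node.
grid_fit_inhibition <- function(conc, fret, n_grid = 200,
                                hills = c(0.5, 1, 2)) {
  pos <- conc[conc > 0]
  ic_grid <- exp(seq(log(min(pos) / 10), log(max(pos) * 10),
                     length.out = n_grid))
  best <- NULL
  for (h in hills) {
    for (ic in ic_grid) {
      s <- 1 / (1 + (conc / ic)^h)
      co <- stats::lm.fit(cbind(s, 1 - s), fret)$coefficients
      rss <- sum((fret - (co[1] * s + co[2] * (1 - s)))^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(ic50 = ic, hill = h, f0 = co[[1]], f_sat = co[[2]],
                     rss = rss)
      }
    }
  }
  best$log_step <- diff(log(ic_grid[1:2]))
  best
}

# Separable biexponential oracle: grid over rate pairs, linear solve of
# asymptote and amplitudes.
grid_fit_biexp <- function(t, y, n_grid = 25) {
  ks <- exp(seq(log(0.5 / max(t)), log(2 / median(diff(t))),
                length.out = n_grid))
  best <- NULL
  for (i in seq_along(ks)) {
    for (j in seq_len(i)) {
      X <- cbind(1, -exp(-ks[i] * t), -exp(-ks[j] * t))
      co <- tryCatch(stats::lm.fit(X, y)$coefficients,
                     error = function(e) NULL)
      if (is.null(co) || anyNA(co)) next
      rss <- sum((y - X %*% co)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(f_inf = co[[1]], a_fast = max(co[2:3]),
                     k1 = ks[i], k2 = ks[j], rss = rss)
      }
    }
  }
  best
}

# The inhibition model as printed in log10 form (valid for c > 0):
# FRET0 - FRETmin / (1 + 10^((logIC50 - log c) * hill)), FRETmin = f0 - f_sat
printed_log_model <- function(conc, ic50, hill, f0, f_sat) {
  f0 - (f0 - f_sat) / (1 + 10^((log10(ic50) - log10(conc)) * hill))
}

# Exact-moment control wells: n values with a prescribed mean and SD,
# converted to intensities at total 1000 so fret_app_raw round-trips.
wells_with_moments <- function(plate_id, role, col, mu, sdv, n = 4) {
  x <- scale(seq_len(n))[, 1]          # mean 0, sd 1 exactly
  fret <- mu + sdv * x
  data.frame(plate_id = plate_id,
             row = LETTERS[seq_len(n)], col = col, role = role,
             compound_id = NA_character_, conc_M = 0,
             i_cy5 = fret * 1000, i_cy3 = (1 - fret) * 1000,
             stringsAsFactors = FALSE)
}

make_screen <- function(n_actives = 0, seed = 1, noise = 0.005, ...) {
  gen_screen(screen_sim_config(n_plates = 9, n_planted_actives = n_actives,
                               well_noise_sd = noise, seed = seed, ...))
}
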