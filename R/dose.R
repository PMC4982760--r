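#' Correct a titration for compound optical artifacts
#'
#' Chromogenic or fluorogenic compounds distort the FRET readout
#' independently of any effect on the protein-DNA complex. The standard
#' correction titrates the compound into the free labeled DNA (no protein)
#' and subtracts, at each concentration, the change of that control signal
#' relative to its zero-compound baseline from the protein-present signal:
#' `corrected(c) = F_protein(c) - (F_no_protein(c) - F_no_protein(0))`.
#' FRET is computed with the calibrated formula using the series'
#' calibration factors.
#'
#' @param series A `titration_series` (from [gen_titration()] or
#'   [read_titration_csv()]) with a paired no-protein series containing a
#'   zero-compound baseline.
#' @return A data frame `conc_M, fret_raw, fret_no_protein,
#'   fret_corrected`.
#' @export
correct_for_compound <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  np <- series$paired_no_protein
  if (is.null(np)) {
    stop("series has no paired no-protein control", call. = FALSE)
  }
  if (!isTRUE(all.equal(series$concentrations, np$concentrations))) {
    stop("no-protein concentrations do not match the protein series",
         call. = FALSE)
  }
  i0 <- which(np$concentrations == 0)
  if (length(i0) != 1) {
    stop("no-protein series must contain exactly one zero-compound baseline",
         call. = FALSE)
  }
  cal <- series$calibration
  if (is.null(cal)) cal <- c(g_cy3 = 1.7, g_cy5 = 4.2)
  f_prot <- fret_app_calibrated(series$i_cy3, series$i_cy5,
                                g_cy3 = cal[["g_cy3"]], g_cy5 = cal[["g_cy5"]])
  f_np <- fret_app_calibrated(np$i_cy3, np$i_cy5,
                              g_cy3 = cal[["g_cy3"]], g_cy5 = cal[["g_cy5"]])
  data.frame(
    conc_M = series$concentrations,
    fret_raw = f_prot,
    fret_no_protein = f_np,
    fret_corrected = f_prot - (f_np - f_np[i0])
  )
}

# linear solve of the two plateaus given a fixed sigmoid shape
# s(c) = 1/(1 + (c/ic50)^hill); F = f_sat + (f0 - f_sat) s = f0 s + f_sat (1-s)
plateau_solve <- function(conc, fret, ic50, hill) {
  s <- 1 / (1 + (conc / ic50)^hill)
  fit <- stats::lm.fit(cbind(s = s, one_minus_s = 1 - s), fret)
  co <- fit$coefficients
  list(f0 = co[["s"]], f_sat = co[["one_minus_s"]],
       rss = sum(fit$residuals^2))
}

#' Fit the four-parameter inhibition model to a titration
#'
#' Fits `F(c) = f_sat + (f0 - f_sat) / (1 + (c / ic50)^hill)` by
#' Levenberg-Marquardt nonlinear least squares. `f0` is the uninhibited
#' FRET, `f_sat` the plateau at complete inhibition (the reported
#' "saturation FRET"), and the model is the familiar log-logistic
#' inhibition curve written so that the full-inhibition plateau is a
#' primary parameter; for `c > 0` it is identical to the log-form
#' `FRET0 - FRETmin / (1 + 10^((logIC50 - log c) * hill))` with
#' `FRET0 = f0` and amplitude `FRETmin = f0 - f_sat`.
#'
#' Initialization scans a coarse grid of log-spaced `ic50` candidates and
#' Hill slopes, solving the two plateaus linearly at each node, and the
#' best node seeds the refinement; two additional restarts from perturbed
#' initials guard against local minima. Zero-concentration points are
#' valid and anchor `f0` (the model evaluates to `f0` at `c = 0`).
#'
#' @param concentrations Molar concentrations (>= 0; at least 5 distinct
#'   positive values).
#' @param fret FRET values, same length.
#' @param hill_bounds Allowed Hill-slope range (default `c(0.1, 10)`).
#' @param amp_floor Minimum amplitude `f0 - f_sat` regarded as real
#'   inhibition (default 0.02 FRET units); below it (or when the
#'   amplitude is within 2 SE of zero) the fit is reported
#'   `NO_INHIBITION`.
#' @param n_restarts Perturbed restarts after the grid-seeded fit.
#' @return An `inhibition_fit` list: `ic50, hill, f0, f_sat, se` (named
#'   vector of asymptotic standard errors), `status` (`CONVERGED`,
#'   `NO_INHIBITION` or `LOWER_BOUND_ONLY`), `bound_value` (max tested
#'   concentration, for `LOWER_BOUND_ONLY`), `rss`, `n`, plus the data.
#' @export
fit_inhibition <- function(concentrations, fret,
                           hill_bounds = c(0.1, 10),
                           amp_floor = 0.02,
                           n_restarts = 2) {
  stopifnot(length(concentrations) == length(fret),
            is.numeric(concentrations), is.numeric(fret))
  if (any(concentrations < 0)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  pos <- unique(concentrations[concentrations > 0])
  if (length(pos) < 5) {
    stop("need at least 5 distinct positive concentrations", call. = FALSE)
  }
  if (length(fret) < 5) {
    stop("fewer points than parameters", call. = FALSE)
  }

  conc <- concentrations
  # grid seed: 40 log-spaced ic50 candidates x coarse hill set
  ic_grid <- exp(seq(log(min(pos) / 10), log(max(pos) * 10), length.out = 40))
  hill_grid <- c(0.5, 1, 2)
  best <- NULL
  for (h in hill_grid) {
    for (ic in ic_grid) {
      sol <- plateau_solve(conc, fret, ic, h)
      if (is.null(best) || sol$rss < best$rss) {
        best <- c(sol, list(ic50 = ic, hill = h))
      }
    }
  }

  run_nls <- function(start) {
    tryCatch({
      fit <- minpack.lm::nlsLM(
        fret ~ f_sat + (f0 - f_sat) / (1 + (conc / exp(lic))^hill),
        start = start,
        lower = c(lic = log(min(pos)) - log(1e4),
                  hill = hill_bounds[1], f0 = -0.5, f_sat = -0.5),
        upper = c(lic = log(max(pos)) + log(1e4),
                  hill = hill_bounds[2], f0 = 1.5, f_sat = 1.5),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      fit
    }, error = function(e) NULL)
  }

  start0 <- list(lic = log(best$ic50), hill = best$hill,
                 f0 = unname(best$f0), f_sat = unname(best$f_sat))
  fits <- list(run_nls(start0))
  for (r in seq_len(n_restarts)) {
    pert <- start0
    pert$lic <- pert$lic + c(-0.7, 0.7)[1 + r %% 2]
    pert$hill <- max(hill_bounds[1],
                     min(hill_bounds[2], pert$hill * c(0.6, 1.6)[1 + r %% 2]))
    fits[[r + 1]] <- run_nls(pert)
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) > 0) {
    rss_all <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
    fit <- fits[[which.min(rss_all)]]
    cf <- coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) {
                     setNames(rep(NA_real_, 4),
                              c("lic", "hill", "f0", "f_sat"))
                   })
    rss <- sum(stats::resid(fit)^2)
  } else {
    # all LM starts rejected (e.g. singular gradient at the seed):
    # fall back to a derivative-free refinement of the grid optimum
    obj <- function(p) {
      sum((fret - (p[4] + (p[3] - p[4]) /
                     (1 + (conc / exp(p[1]))^p[2])))^2)
    }
    op <- stats::optim(unlist(start0), obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    cf <- c(lic = op$par[[1]],
            hill = min(max(op$par[[2]], hill_bounds[1]), hill_bounds[2]),
            f0 = op$par[[3]], f_sat = op$par[[4]])
    se <- setNames(rep(NA_real_, 4), c("lic", "hill", "f0", "f_sat"))
    rss <- op$value
  }
  ic50 <- exp(cf[["lic"]])
  # delta method for the ic50 SE from the log-scale SE
  se_out <- c(ic50 = unname(ic50 * se[["lic"]]),
              hill = unname(se[["hill"]]),
              f0 = unname(se[["f0"]]),
              f_sat = unname(se[["f_sat"]]))
  amp <- cf[["f0"]] - cf[["f_sat"]]
  amp_se <- sqrt(sum(se[c("f0", "f_sat")]^2, na.rm = TRUE))

  status <- "CONVERGED"
  bound_value <- NA_real_
  if (amp < amp_floor || (is.finite(amp_se) && amp_se > 0 && amp / amp_se < 2)) {
    status <- "NO_INHIBITION"
  } else if (ic50 > max(pos)) {
    status <- "LOWER_BOUND_ONLY"
    bound_value <- max(pos)
  }

  structure(list(
    ic50 = unname(ic50), hill = unname(cf[["hill"]]),
    f0 = unname(cf[["f0"]]), f_sat = unname(cf[["f_sat"]]),
    se = se_out, status = status, bound_value = bound_value,
    rss = rss, n = length(fret),
    concentrations = conc, fret = fret
  ), class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat("Inhibition-model fit (", x$status, ")\n", sep = "")
  if (x$status == "LOWER_BOUND_ONLY") {
    cat(sprintf("  IC50 > %s (max tested concentration)\n",
                format_molar(x$bound_value)))
  } else {
    cat(sprintf("  IC50: %s (SE %s)\n", format_molar(x$ic50),
                format_molar(x$se[["ic50"]])))
  }
  cat(sprintf("  Hill slope: %.3g\n", x$hill))
  cat(sprintf("  FRET0 (f0): %.3f   saturation FRET (f_sat): %.3f\n",
              x$f0, x$f_sat))
  cat(sprintf("  n = %d points, RSS = %.3g\n", x$n, x$rss))
  invisible(x)
}

# report molar values at a readable scale (M -> mM/uM/nM)
format_molar <- function(x) {
  if (!is.finite(x)) return(as.character(x))
  a <- abs(x)
  if (a >= 1e-3) sprintf("%.3g mM", x * 1e3)
  else if (a >= 1e-6) sprintf("%.3g µM", x * 1e6)
  else sprintf("%.3g nM", x * 1e9)
}

#' Evaluate the fitted inhibition curve
#'
#' @param object An `inhibition_fit`.
#' @param newdata Optional numeric concentrations (molar).
#' @param ... Unused.
#' @return Fitted FRET values.
#' @export
predict.inhibition_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$concentrations else newdata
  inhibition_model(conc, object$ic50, object$hill, object$f0, object$f_sat)
}

#' Summarize inhibition across binding conditions
#'
#' Builds a specificity profile from per-condition inhibition fits: each
#' condition is marked `+` when the fit converged to genuine inhibition,
#' `-` when it reported no inhibition (or only a lower bound within the
#' tested range), and `?` when untested. A compound specific for the
#' protein-ssDNA interaction shows e.g. `ssDNA+, ssDNA_RPA+, dsDNA-,
#' RPA_only-`.
#'
#' @param fits Named list of `inhibition_fit` objects, names drawn from
#'   `ssDNA, ssDNA_RPA, dsDNA, RPA_only`.
#' @param conditions Conditions to report (default the four standard ones).
#' @return List with `profile` (single string) and `calls` (named
#'   character vector of `+`, `-`, `?`).
#' @export
classify_specificity <- function(fits,
                                 conditions = c("ssDNA", "ssDNA_RPA",
                                                "dsDNA", "RPA_only")) {
  if (!("ssDNA" %in% names(fits))) {
    stop("at least the ssDNA condition must be fitted", call. = FALSE)
  }
  calls <- vapply(conditions, function(cond) {
    f <- fits[[cond]]
    if (is.null(f)) return("?")
    if (f$status == "CONVERGED") "+" else "-"
  }, character(1))
  list(profile = paste0(conditions, calls, collapse = ", "),
       calls = calls)
}
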