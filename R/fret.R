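#' Apparent FRET from raw two-channel intensities
#'
#' Computes the apparent FRET as the acceptor's fraction of the total
#' emission, `i_cy5 / (i_cy5 + i_cy3)`. This is the plate-reader statistic
#' used during primary screening; it is a proximity proxy, not a true
#' transfer efficiency.
#'
#' @param i_cy3 Donor (Cy3) emission intensity, arbitrary units, >= 0.
#'   Vectorized.
#' @param i_cy5 Acceptor (Cy5) emission intensity, arbitrary units, >= 0.
#' @return Numeric vector of apparent FRET values in `[0, 1]`.
#' @examples
#' fret_app_raw(300, 700)  # 0.7
#' @seealso [fret_app_calibrated()] for the instrument-calibrated form used
#'   in cuvette titrations.
#' @export
fret_app_raw <- function(i_cy3, i_cy5) {
  stopifnot(is.numeric(i_cy3), is.numeric(i_cy5))
  if (any(i_cy3 < 0, na.rm = TRUE) || any(i_cy5 < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  total <- i_cy3 + i_cy5
  if (any(total <= 0, na.rm = TRUE)) {
    stop("total intensity must be positive in every well", call. = FALSE)
  }
  i_cy5 / total
}

#' Calibrated apparent FRET for spectrofluorimeter titrations
#'
#' Computes `g_cy5 * i_cy5 / (g_cy5 * i_cy5 + g_cy3 * i_cy3)`, weighting the
#' two channels by instrument calibration factors that compensate for the
#' different detection efficiencies of the donor and acceptor channels.
#' The default factors (4.2 for Cy5, 1.7 for Cy3) are the calibration of the
#' cuvette instrument used in the original titration assays.
#'
#' @inheritParams fret_app_raw
#' @param g_cy3,g_cy5 Positive calibration factors for the donor and acceptor
#'   channels.
#' @return Numeric vector of calibrated FRET values in `[0, 1]`.
#' @examples
#' fret_app_calibrated(1, 1)  # 4.2 / 5.9
#' @export
fret_app_calibrated <- function(i_cy3, i_cy5, g_cy3 = 1.7, g_cy5 = 4.2) {
  stopifnot(is.numeric(i_cy3), is.numeric(i_cy5),
            length(g_cy3) == 1, length(g_cy5) == 1,
            g_cy3 > 0, g_cy5 > 0)
  if (any(i_cy3 < 0, na.rm = TRUE) || any(i_cy5 < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  wtot <- g_cy5 * i_cy5 + g_cy3 * i_cy3
  if (any(wtot <= 0, na.rm = TRUE)) {
    stop("weighted total intensity must be positive", call. = FALSE)
  }
  g_cy5 * i_cy5 / wtot
}

# Invert a FRET value to an (i_cy3, i_cy5) pair with the given total
# intensity. With calibrate = FALSE the raw ratio is inverted; otherwise the
# weighted form. Used by the generators so that round-tripping through the
# forward formula reproduces the target FRET exactly.
intensities_from_fret <- function(fret, total = 1000, calibrate = FALSE,
                                  g_cy3 = 1.7, g_cy5 = 4.2) {
  fret <- pmin(pmax(fret, 0), 1)
  if (!calibrate) {
    i_cy5 <- fret * total
    i_cy3 <- total - i_cy5
  } else {
    # solve g5*i5/(g5*i5 + g3*i3) = f with i3 + i5 = total
    a5 <- fret / g_cy5
    a3 <- (1 - fret) / g_cy3
    i_cy5 <- total * a5 / (a5 + a3)
    i_cy3 <- total - i_cy5
  }
  data.frame(i_cy3 = i_cy3, i_cy5 = i_cy5)
}
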