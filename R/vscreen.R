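#' Build a ROC curve from labeled pose scores
#'
#' Constructs the receiver-operating-characteristic curve of a docking
#' score list validated against decoys, at pose level: every pose is an
#' instance, ranked by score with lower (more negative) meaning better
#' predicted binding (set `lower_is_better = FALSE` to invert). A cutoff
#' `t` predicts a pose active when its score is strictly better than `t`;
#' tied scores are processed as a block so each distinct score contributes
#' a single curve vertex. The AUC is the trapezoidal area, which equals
#' the Mann-Whitney probability that a random active pose outscores a
#' random decoy pose, ties counted 1/2.
#'
#' @param scores A `score_set` or data frame with columns `score` and
#'   `label` (values `"active"` / `"decoy"`).
#' @param lower_is_better Score direction (default `TRUE`, free energies).
#' @return A `roc_curve` list: `thresholds` (cutoff realizing each
#'   vertex), `fpr`, `tpr`, `auc`, `youden_threshold`, `n_active`,
#'   `n_decoy`.
#' @export
build_roc <- function(scores, lower_is_better = TRUE) {
  stopifnot(all(c("score", "label") %in% names(scores)))
  s <- scores$score
  lab <- scores$label
  if (any(!is.finite(s))) stop("scores must be finite", call. = FALSE)
  if (!all(lab %in% c("active", "decoy"))) {
    stop("labels must be 'active' or 'decoy'", call. = FALSE)
  }
  n_a <- sum(lab == "active")
  n_d <- sum(lab == "decoy")
  if (n_a == 0 || n_d == 0) {
    stop("both an active and a decoy label are required", call. = FALSE)
  }
  if (!lower_is_better) s <- -s

  # block-tie processing: one vertex per distinct score
  o <- order(s)
  s_o <- s[o]; a_o <- lab[o] == "active"
  blocks <- split(seq_along(s_o), match(s_o, unique(s_o)))
  tp <- cumsum(vapply(blocks, function(i) sum(a_o[i]), numeric(1)))
  fp <- cumsum(vapply(blocks, function(i) sum(!a_o[i]), numeric(1)))
  distinct <- unique(s_o)
  # vertex k is realized by the cutoff "score < next distinct score";
  # the final vertex (1,1) by a cutoff beyond the worst score
  thr <- c(distinct[-1], Inf)
  tpr <- unname(c(0, tp / n_a))
  fpr <- unname(c(0, fp / n_d))
  thr <- c(distinct[1], thr)
  if (!lower_is_better) thr <- -thr

  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)

  roc <- structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                        youden_threshold = NA_real_,
                        n_active = n_a, n_decoy = n_d,
                        lower_is_better = lower_is_better),
                   class = "roc_curve")
  roc$youden_threshold <- pick_threshold(roc)
  roc
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d active / %d decoy poses, %d vertices\n",
              x$n_active, x$n_decoy, length(x$tpr)))
  cat(sprintf("  AUC = %.4f\n", x$auc))
  cat(sprintf("  Youden-optimal cutoff: %.4g\n", x$youden_threshold))
  invisible(x)
}

#' Choose the optimal score cutoff from a ROC curve
#'
#' Returns the cutoff maximizing Youden's J statistic `TPR - FPR` over the
#' curve vertices; ties are broken toward the more stringent (better,
#' i.e. lower for free-energy scores) cutoff. The cutoff is interpreted
#' as in [build_roc()]: a pose with score strictly better than the cutoff
#' is predicted active.
#'
#' @param roc A `roc_curve`.
#' @return The chosen score cutoff (scalar).
#' @export
pick_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$tpr - roc$fpr
  best <- which(j == max(j))
  # vertex thresholds are ascending in stringency order for
  # lower-is-better; the first maximizer is the most stringent
  roc$thresholds[best[1]]
}

#' Select library compounds scoring better than a reference
#'
#' Ranks virtual-screening candidates relative to a reference inhibitor:
#' compounds whose best pose score is strictly better (lower) than the
#' reference compound's best pose are returned in ascending score order.
#'
#' @param library_scores Named numeric vector of best-pose scores per
#'   compound, or a `score_set`/data frame with `compound_id` and `score`
#'   (the per-compound minimum is taken).
#' @param reference_best Best pose score of the reference compound.
#' @return Data frame `compound_id, best_score`, ranked ascending.
#' @export
select_candidates <- function(library_scores, reference_best) {
  if (is.data.frame(library_scores)) {
    best <- tapply(library_scores$score, library_scores$compound_id, min)
  } else {
    if (is.null(names(library_scores))) {
      stop("library_scores must be named by compound", call. = FALSE)
    }
    best <- library_scores
  }
  if (length(best) == 0) stop("library is empty", call. = FALSE)
  keep <- best < reference_best
  out <- data.frame(compound_id = names(best)[keep],
                    best_score = as.numeric(best[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$best_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram and bimodality summary of a labeled score set
#'
#' Bins active and decoy pose scores on a shared grid and summarizes
#' their separation as `|mean_active - mean_decoy| / pooled SD` — a
#' bimodal score distribution (well-separated active and decoy modes)
#' gives a separation statistic well above 2.
#'
#' @param scores A `score_set` or data frame with `score` and `label`.
#' @param bin_width Bin width, same units as the scores (> 0).
#' @return List with `breaks`, `mids`, `counts_active`, `counts_decoy`,
#'   `separation`.
#' @export
score_histogram <- function(scores, bin_width = 0.5) {
  stopifnot(all(c("score", "label") %in% names(scores)))
  if (bin_width <= 0) stop("bin width must be positive", call. = FALSE)
  s <- scores$score
  lo <- floor(min(s) / bin_width) * bin_width
  hi <- ceiling(max(s) / bin_width) * bin_width
  if (hi == lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  cnt <- function(x) {
    h <- hist(x, breaks = breaks, plot = FALSE)
    h$counts
  }
  a <- s[scores$label == "active"]
  d <- s[scores$label == "decoy"]
  pooled <- sqrt(((length(a) - 1) * stats::var(a) +
                    (length(d) - 1) * stats::var(d)) /
                   (length(a) + length(d) - 2))
  list(breaks = breaks,
       mids = breaks[-1] - bin_width / 2,
       counts_active = cnt(a),
       counts_decoy = cnt(d),
       separation = abs(mean(a) - mean(d)) / pooled)
}
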