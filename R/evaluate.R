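#' Evaluate predicted DMRs against a simulated truth
#'
#' Computes the benchmark metrics at two levels.
#' \describe{
#'   \item{segment-wise}{a predicted DMR is a true positive when it
#'     overlaps some truth DMR of the same direction by more than
#'     `overlap_fraction` of its own length (the denominator is
#'     configurable); precision is the fraction of predicted DMRs that are
#'     true positives, recall the fraction of truth DMRs matched by at
#'     least one such prediction, F1 their harmonic mean.}
#'   \item{site-wise}{every simulated CpG site is labelled by the truth
#'     (`gain`/`loss`/`none`) and by the predictions (inside a predicted
#'     DMR or not, direction-aware); precision, recall and F1 follow from
#'     the per-site confusion, and specificity is the fraction of
#'     truth-negative sites outside every predicted DMR.}
#' }
#'
#' @param predicted DMR tibble with `chrom`, `start`, `end` and a
#'   direction (either a `direction` column with `gain`/`loss` or a
#'   `state` column with `hyper`/`hypo`/`hypo_block`).
#' @param truth A `rocker_sim` object from [simulate_dataset()], or a
#'   truth DMR tibble (`chrom`, `start`, `end`, `direction`) with the
#'   per-site labels supplied via `sites`.
#' @param overlap_fraction Required overlap (strict inequality), default
#'   0.30.
#' @param denominator Length used for the overlap fraction:
#'   `"predicted"` (default; the sentence subject of the matching rule),
#'   `"truth"`, or `"either"` (matched if either fraction qualifies).
#' @param sites Optional per-site truth tibble (`chrom`, `pos`, `truth`)
#'   when `truth` is a plain tibble.
#' @return A tibble with columns `level` (`segment`/`site`), `precision`,
#'   `recall`, `f1`, `specificity` (site level only), `n_predicted`,
#'   `n_truth`.
#' @export
evaluate_predictions <- function(predicted, truth,
                                 overlap_fraction = 0.30,
                                 denominator = c("predicted", "truth", "either"),
                                 sites = NULL) {
  denominator <- match.arg(denominator)
  if (inherits(truth, "rocker_sim")) {
    sites <- truth$sites
    truth <- truth$truth
  }
  predicted <- as_tibble(predicted)
  pred_dir <- pred_direction(predicted)
  if (!"direction" %in% names(truth)) abort("truth table lacks a 'direction' column")

  # --- segment-wise -----------------------------------------------------
  np <- nrow(predicted)
  nt <- nrow(truth)
  tp_pred <- logical(np)
  truth_hit <- logical(nt)
  for (i in seq_len(np)) {
    same <- which(truth$chrom == predicted$chrom[i] &
      truth$direction == pred_dir[i])
    if (length(same) == 0) next
    ov <- pmin(truth$end[same], predicted$end[i]) -
      pmax(truth$start[same], predicted$start[i]) + 1
    ov <- pmax(ov, 0)
    frac_p <- ov / (predicted$end[i] - predicted$start[i] + 1)
    frac_t <- ov / (truth$end[same] - truth$start[same] + 1)
    ok <- switch(denominator,
      predicted = frac_p > overlap_fraction,
      truth = frac_t > overlap_fraction,
      either = frac_p > overlap_fraction | frac_t > overlap_fraction
    )
    if (any(ok)) {
      tp_pred[i] <- TRUE
      truth_hit[same[ok]] <- TRUE
    }
  }
  seg_prec <- if (np > 0) mean(tp_pred) else NA_real_
  seg_rec <- if (nt > 0) mean(truth_hit) else NA_real_
  seg <- tibble(
    level = "segment",
    precision = seg_prec, recall = seg_rec,
    f1 = harmonic_f1(seg_prec, seg_rec),
    specificity = NA_real_,
    n_predicted = np, n_truth = nt
  )

  # --- site-wise --------------------------------------------------------
  site <- NULL
  if (!is.null(sites)) {
    lab <- rep("none", nrow(sites))
    for (i in seq_len(np)) {
      hit <- sites$chrom == predicted$chrom[i] &
        sites$pos >= predicted$start[i] & sites$pos <= predicted$end[i]
      lab[hit] <- pred_dir[i]
    }
    pos_truth <- sites$truth != "none"
    pos_pred <- lab != "none"
    tp <- sum(pos_truth & pos_pred & sites$truth == lab)
    prec <- if (any(pos_pred)) tp / sum(pos_pred) else NA_real_
    rec <- if (any(pos_truth)) tp / sum(pos_truth) else NA_real_
    spec <- if (any(!pos_truth)) {
      sum(!pos_truth & !pos_pred) / sum(!pos_truth)
    } else {
      NA_real_
    }
    site <- tibble(
      level = "site",
      precision = prec, recall = rec, f1 = harmonic_f1(prec, rec),
      specificity = spec,
      n_predicted = sum(pos_pred), n_truth = sum(pos_truth)
    )
  }
  bind_rows(seg, site)
}

pred_direction <- function(predicted) {
  if ("direction" %in% names(predicted)) {
    d <- predicted$direction
  } else if ("state" %in% names(predicted)) {
    d <- ifelse(predicted$state == "hyper", "gain",
      ifelse(predicted$state %in% c("hypo", "hypo_block"), "loss",
        NA_character_
      )
    )
  } else {
    abort("predicted DMRs need a 'direction' or 'state' column")
  }
  if (anyNA(d)) abort("prediction direction missing or unrecognized")
  d
}

harmonic_f1 <- function(p, r) {
  if (is.na(p) || is.na(r) || p + r == 0) {
    return(if (identical(r, 0) || identical(p, 0)) 0 else NA_real_)
  }
  2 * p * r / (p + r)
}
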