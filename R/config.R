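#' Pipeline configuration
#'
#' Collects all tunable parameters of the DMR pipeline with their default
#' values and validates them. The defaults correspond to the settings the
#' method was designed around: `p = 0.05`, `f = 0.4`, `mu = 0.25`,
#' `d_norm = 1e5`, a minimum of 6 CpG sites per DMR and an FDR cutoff of
#' 0.05.
#'
#' @param p Baseline probability of a state change between adjacent sites in
#'   the homogeneous limit of the transition model; larger values favour
#'   shorter segments. Must lie in (0, 1).
#' @param f Variance-split factor dividing the total AUC standard deviation
#'   between the neutral state (`f * sigma_tot`) and the two differential
#'   states (`(1 - f) * sigma_tot`). Must lie in (0, 1).
#' @param mu Offset of the differential state means from the null AUC value
#'   of 0.5, so the state means are `0.5 - mu`, `0.5`, `0.5 + mu`. Must lie
#'   in (0, 0.5).
#' @param d_norm Distance normalization in base pairs for the
#'   distance-dependent transition probabilities; larger values make jumps
#'   between states less likely at a given genomic gap.
#' @param min_sites Minimum number of CpG sites for a segment to be retained
#'   as a DMR (segments with fewer sites are discarded).
#' @param fdr_alpha Benjamini-Hochberg FDR threshold; segments with
#'   `fdr >= fdr_alpha` are discarded.
#' @param max_distance Optional gap threshold in base pairs: segments are
#'   split wherever two adjacent CpG sites are farther apart than this value
#'   (useful for sparse array designs). `NULL` disables splitting.
#' @param hypo_block_len Length threshold in base pairs separating short
#'   hypomethylated DMRs from hypo-blocks (loss-of-methylation regions
#'   longer than this are labelled `hypo_block`).
#' @param score_threshold Absolute sample-score threshold used by
#'   [psfse()] to count a DMR as supported in a sample (strict exceedance).
#' @param min_normals Minimum control-group size below which
#'   [compute_auc_track()] emits a warning (the per-site AUC becomes noisy
#'   with small control sets).
#' @param mad_type Dispersion estimator used for the normal reference in
#'   [score_samples()]: `"scaled_mad"` (median absolute deviation with the
#'   1.4826 consistency constant, the default), `"raw_mad"` (unscaled
#'   median absolute deviation) or `"max_abs_dev"` (maximum absolute
#'   deviation from the median).
#'
#' @return A named list of class `rocker_config`.
#' @examples
#' cfg <- rocker_config()
#' cfg$p
#' @export
rocker_config <- function(p = 0.05,
                          f = 0.4,
                          mu = 0.25,
                          d_norm = 1e5,
                          min_sites = 6L,
                          fdr_alpha = 0.05,
                          max_distance = NULL,
                          hypo_block_len = 1e4,
                          score_threshold = 3,
                          min_normals = 10L,
                          mad_type = c("scaled_mad", "raw_mad", "max_abs_dev")) {
  mad_type <- match.arg(mad_type)
  stopifnot(
    is.numeric(p), length(p) == 1, p > 0, p < 1,
    is.numeric(f), length(f) == 1, f > 0, f < 1,
    is.numeric(mu), length(mu) == 1, mu > 0, mu < 0.5,
    is.numeric(d_norm), length(d_norm) == 1, d_norm > 0,
    is.numeric(min_sites), length(min_sites) == 1, min_sites >= 1,
    is.numeric(fdr_alpha), length(fdr_alpha) == 1, fdr_alpha > 0, fdr_alpha <= 1,
    is.null(max_distance) ||
      (is.numeric(max_distance) && length(max_distance) == 1 && max_distance > 0),
    is.numeric(hypo_block_len), length(hypo_block_len) == 1, hypo_block_len > 0,
    is.numeric(score_threshold), length(score_threshold) == 1, score_threshold > 0,
    is.numeric(min_normals), length(min_normals) == 1, min_normals >= 1
  )
  structure(
    list(
      p = p, f = f, mu = mu, d_norm = d_norm,
      min_sites = as.integer(min_sites), fdr_alpha = fdr_alpha,
      max_distance = max_distance, hypo_block_len = hypo_block_len,
      score_threshold = score_threshold, min_normals = as.integer(min_normals),
      mad_type = mad_type
    ),
    class = "rocker_config"
  )
}

#' @export
print.rocker_config <- function(x, ...) {
  cat("<rocker_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-15s %s\n", nm, if (is.null(val)) "NULL" else format(val)))
  }
  invisible(x)
}
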