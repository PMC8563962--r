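#' Robust Z-score of one sample against the normal reference of a DMR
#'
#' The score is `(beta_med - median(normal_meds)) / dispersion`, where
#' `beta_med` is the sample's median beta (percentage points) over the CpG
#' sites of the DMR, `normal_meds` are the corresponding per-sample medians
#' in the control group, and the dispersion is a robust spread of
#' `normal_meds` floored at 1 percentage point to avoid inflating scores
#' when the controls are nearly constant.
#'
#' @param beta_med Median beta of the scored sample within the DMR
#'   (percentage units).
#' @param normal_meds Numeric vector of per-control-sample median betas
#'   within the DMR.
#' @param mad_type Dispersion estimator: `"scaled_mad"` (median absolute
#'   deviation times 1.4826, the default), `"raw_mad"`, or
#'   `"max_abs_dev"` (maximum absolute deviation from the median).
#' @return A single Z-score (`NA` if `beta_med` is missing).
#' @examples
#' rocker_sample_score(80, c(40, 50, 60), mad_type = "raw_mad") # 3
#' @export
rocker_sample_score <- function(beta_med, normal_meds,
                                mad_type = c("scaled_mad", "raw_mad", "max_abs_dev")) {
  mad_type <- match.arg(mad_type)
  normal_meds <- normal_meds[!is.na(normal_meds)]
  if (length(normal_meds) == 0 || is.na(beta_med)) {
    return(NA_real_)
  }
  ctr <- median(normal_meds)
  disp <- switch(mad_type,
    scaled_mad = mad(normal_meds),
    raw_mad = mad(normal_meds, constant = 1),
    max_abs_dev = max(abs(normal_meds - ctr))
  )
  disp <- max(disp, 1) # floor: one percentage point of methylation
  (beta_med - ctr) / disp
}

#' Score samples against a DMR catalog
#'
#' For every DMR and every test sample, computes the robust Z-score of the
#' sample's median beta within the DMR against the control-group reference
#' ([rocker_sample_score()]). Samples with no non-missing site in a DMR
#' get a missing score; the per-(DMR, sample) fraction of missing sites is
#' reported alongside.
#'
#' @param dmrs DMR tibble (columns `chrom`, `start`, `end`, `state`), e.g.
#'   [tidy()] output or a catalog read with [read_dmr_bed()].
#' @param tumor Beta table of the samples (or cells) to score.
#' @param normal Beta table of the control group (same site list).
#' @param config A [rocker_config()]; `mad_type` selects the reference
#'   dispersion estimator.
#' @return A long tibble of class `rocker_scores` with columns `dmr_id`,
#'   `chrom`, `start`, `end`, `state`, `sample`, `score`, `frac_missing`,
#'   `ref_median`, `ref_disp`.
#' @export
score_samples <- function(dmrs, tumor, normal, config = rocker_config()) {
  tumor <- validate_beta_table(tumor, convert = FALSE, what = "test table")
  normal <- validate_beta_table(normal, convert = FALSE, what = "control table")
  tv <- beta_values(tumor)
  nv <- beta_values(normal)
  smp <- beta_samples(tumor)
  out <- lapply(seq_len(nrow(dmrs)), function(z) {
    in_dmr <- tumor$chrom == dmrs$chrom[z] &
      tumor$pos >= dmrs$start[z] & tumor$pos <= dmrs$end[z]
    tz <- tv[in_dmr, , drop = FALSE]
    nz <- nv[in_dmr, , drop = FALSE]
    t_med <- apply(tz, 2, median, na.rm = TRUE)
    t_med[colSums(!is.na(tz)) == 0] <- NA_real_
    n_med <- apply(nz, 2, median, na.rm = TRUE)
    n_med <- n_med[colSums(!is.na(nz)) > 0]
    ref <- if (length(n_med)) median(n_med) else NA_real_
    disp <- if (length(n_med)) {
      max(switch(config$mad_type,
        scaled_mad = mad(n_med),
        raw_mad = mad(n_med, constant = 1),
        max_abs_dev = max(abs(n_med - median(n_med)))
      ), 1)
    } else {
      NA_real_
    }
    tibble(
      dmr_id = z,
      chrom = dmrs$chrom[z], start = dmrs$start[z], end = dmrs$end[z],
      state = dmrs$state[z],
      sample = smp,
      score = unname(vapply(
        t_med, rocker_sample_score, numeric(1),
        normal_meds = n_med, mad_type = config$mad_type
      )),
      frac_missing = unname(
        if (nrow(tz)) colMeans(is.na(tz)) else rep(1, length(smp))
      ),
      ref_median = ref,
      ref_disp = disp
    )
  })
  structure(bind_rows(out), class = c("rocker_scores", class(tibble())))
}

#' Per-sample fraction of supporting events
#'
#' For each sample and DMR class, the fraction of catalog DMRs whose
#' sample score exceeds the support threshold in the direction of the
#' class: scores strictly above `+threshold` support hyper DMRs, scores
#' strictly below `-threshold` support hypo DMRs and hypo-blocks (a score
#' exactly at the threshold does not count). Missing scores are excluded
#' from the numerator but kept in the denominator, so the fraction is
#' conservative under missingness.
#'
#' @param scores A `rocker_scores` tibble from [score_samples()].
#' @param score_threshold Support threshold (default 3).
#' @return A tibble with columns `sample`, `state`, `n_dmrs`,
#'   `n_supporting`, `psfse`.
#' @export
psfse <- function(scores, score_threshold = 3) {
  scores |>
    group_by(.data$sample, .data$state) |>
    summarise(
      n_dmrs = dplyr::n(),
      n_supporting = sum(
        ifelse(.data$state == "hyper",
          .data$score > score_threshold,
          .data$score < -score_threshold
        ),
        na.rm = TRUE
      ),
      .groups = "drop"
    ) |>
    mutate(psfse = .data$n_supporting / .data$n_dmrs) |>
    arrange(.data$sample, .data$state)
}

#' Per-cell fraction of supporting events with a missingness gate
#'
#' Single-cell version of [psfse()]: cells whose fraction of DMRs without
#' a score (no covered CpG site) reaches `missing_cap` in any DMR class
#' are excluded, mirroring sparse single-cell assays where poorly covered
#' cells yield unreliable fractions; remaining cells get one fraction per
#' class.
#'
#' @param scores A `rocker_scores` tibble from [score_samples()] on cells.
#' @param missing_cap Maximum tolerated fraction of scoreless DMRs per
#'   class (default 0.5; a cell is kept only if *below* the cap in every
#'   class).
#' @param score_threshold Support threshold (default 3).
#' @return A tibble as in [psfse()], restricted to retained cells. Emits a
#'   warning and returns an empty table when every cell is gated out.
#' @export
pcfse <- function(scores, missing_cap = 0.5, score_threshold = 3) {
  miss <- scores |>
    group_by(.data$sample, .data$state) |>
    summarise(frac_na = mean(is.na(.data$score)), .groups = "drop") |>
    group_by(.data$sample) |>
    summarise(worst = max(.data$frac_na), .groups = "drop")
  keep <- miss$sample[miss$worst < missing_cap]
  if (length(keep) == 0) {
    warn("pcfse: all cells exceed the missingness cap")
    return(tibble(
      sample = character(), state = character(),
      n_dmrs = integer(), n_supporting = integer(), psfse = numeric()
    ))
  }
  psfse(
    filter(scores, .data$sample %in% keep),
    score_threshold = score_threshold
  )
}
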