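#' Per-site ROC AUC of test versus control beta values
#'
#' The AUC is computed as the normalized Mann-Whitney U statistic with
#' midranks for ties: `(#{t > n} + 0.5 * #{t = n}) / (n_t * n_n)` over all
#' (test, control) pairs, which equals the trapezoidal area under the ROC
#' curve. Values near 1 indicate hypermethylation in the test group, values
#' near 0 hypomethylation, 0.5 no separation.
#'
#' @param tumor_betas Numeric vector of test-group beta values (any
#'   monotone scale; missing values are dropped).
#' @param normal_betas Numeric vector of control-group beta values.
#' @return A single AUC in \[0, 1\], or `NA` when either group has fewer
#'   than two non-missing values.
#' @examples
#' compute_site_auc(c(90, 80), c(10, 20)) # 1
#' compute_site_auc(c(50, 50), c(50, 50)) # 0.5
#' @export
compute_site_auc <- function(tumor_betas, normal_betas) {
  t <- tumor_betas[!is.na(tumor_betas)]
  n <- normal_betas[!is.na(normal_betas)]
  nt <- length(t)
  nn <- length(n)
  if (nt < 2 || nn < 2) {
    return(NA_real_)
  }
  r <- rank(c(t, n))
  u <- sum(r[seq_len(nt)]) - nt * (nt + 1) / 2
  u / (nt * nn)
}

#' Genome-ordered AUC track for two matched beta tables
#'
#' Computes one ROC AUC per CpG site shared by the test and control tables
#' (the two tables must have identical site lists). Sites where either
#' group has fewer than two non-missing values are dropped from the track
#' (a count is reported): they carry no rank information and would corrupt
#' the downstream segmentation. The sample standard deviation of all
#' retained AUC values, pooled across chromosomes, is attached as the
#' `sigma_tot` attribute and drives the emission variances of the
#' segmentation model.
#'
#' @param tumor,normal Beta tables with identical `(chrom, pos)` site lists
#'   (see [read_beta_matrix()]).
#' @param config A [rocker_config()]; only `min_normals` is used here (a
#'   warning is emitted when the control group is smaller, since per-site
#'   AUC values become unstable with few controls).
#' @return A tibble with columns `chrom`, `pos` (and `site_id` when
#'   present), `auc`, `n_tumor`, `n_normal`, sorted along the genome, with
#'   attribute `sigma_tot`.
#' @export
compute_auc_track <- function(tumor, normal, config = rocker_config()) {
  tumor <- validate_beta_table(tumor, convert = FALSE, what = "test table")
  normal <- validate_beta_table(normal, convert = FALSE, what = "control table")
  check_matched_sites(tumor, normal)
  tv <- beta_values(tumor)
  nv <- beta_values(normal)
  if (ncol(nv) < config$min_normals) {
    warn(sprintf(
      "control group has %d samples (< %d): per-site AUC values will be noisy",
      ncol(nv), config$min_normals
    ))
  }
  auc <- vapply(
    seq_len(nrow(tv)),
    function(i) compute_site_auc(tv[i, ], nv[i, ]),
    numeric(1)
  )
  track <- tibble(
    chrom = tumor$chrom,
    pos = tumor$pos,
    auc = auc,
    n_tumor = rowSums(!is.na(tv)),
    n_normal = rowSums(!is.na(nv))
  )
  if ("site_id" %in% names(tumor)) {
    track <- mutate(track, site_id = tumor$site_id, .after = "pos")
  }
  dropped <- sum(is.na(track$auc))
  if (dropped > 0) {
    inform(sprintf(
      "compute_auc_track: %d site(s) with < 2 usable values per group dropped",
      dropped
    ))
    track <- filter(track, !is.na(.data$auc))
  }
  attr(track, "sigma_tot") <- sd(track$auc)
  track
}

#' Call differentially methylated sites from an AUC track
#'
#' Labels each site `hyper`, `hypo` or `neutral` from its AUC alone, using
#' strict inequalities at the thresholds: lenient mode calls `hypo` below
#' 0.2 and `hyper` above 0.8; stringent mode uses 0.1 and 0.9.
#'
#' @param track An AUC track from [compute_auc_track()].
#' @param mode `"lenient"` or `"stringent"`.
#' @return The track with an added `dms` character column.
#' @export
call_dms <- function(track, mode = c("lenient", "stringent")) {
  mode <- match.arg(mode)
  lo <- if (mode == "lenient") 0.2 else 0.1
  hi <- if (mode == "lenient") 0.8 else 0.9
  mutate(track, dms = dplyr::case_when(
    .data$auc < lo ~ "hypo",
    .data$auc > hi ~ "hyper",
    TRUE ~ "neutral"
  ))
}
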