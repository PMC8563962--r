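#' Detect differentially methylated regions between two groups
#'
#' Runs the full pipeline: per-site ROC AUC of test versus control beta
#' values, segmentation of the genome-ordered AUC track with a
#' heterogeneous three-state hidden Markov model (distance-dependent
#' transitions, truncated-Gaussian emissions), optional splitting at large
#' inter-site gaps, a Wilcoxon-Mann-Whitney test of the per-site group
#' means within each non-neutral segment, Benjamini-Hochberg correction,
#' and filtering by FDR and site support. Loss-of-methylation DMRs longer
#' than `hypo_block_len` are labelled `hypo_block`.
#'
#' @param tumor,normal Beta tables with identical site lists (see
#'   [read_beta_matrix()]); `tumor` is the test group, `normal` the
#'   control group.
#' @param config A [rocker_config()] with all tuning parameters.
#' @param auc_track Optional precomputed AUC track (from
#'   [compute_auc_track()] or [read_auc_track()]); when supplied, the AUC
#'   step is skipped but the beta tables are still needed for the
#'   segment-level test and effect sizes.
#' @return An object of class `rocker_fit`: a list with elements
#'   \describe{
#'     \item{auc}{the AUC track tibble (attribute `sigma_tot`),}
#'     \item{segments}{all segments (the three states, with `p_value`,
#'       `fdr` and `mean_beta_diff`; neutral segments are untested),}
#'     \item{dmrs}{the filtered, classified DMR tibble,}
#'     \item{params}{the fitted [hmm_params()],}
#'     \item{config}{the configuration used.}
#'   }
#'   Use [tidy()] for the DMR table, [glance()] for a one-row summary and
#'   [autoplot()] for a track plot.
#' @examples
#' sim <- simulate_dataset("wgbs",
#'   class_label = 1, n_sites = 600, n_dmrs = 4,
#'   n_tumor = 10, n_normal = 10, seed = 7
#' )
#' fit <- detect_dmrs(sim$tumor, sim$normal)
#' tidy(fit)
#' @export
detect_dmrs <- function(tumor, normal, config = rocker_config(),
                        auc_track = NULL) {
  tumor <- validate_beta_table(tumor, convert = FALSE, what = "test table")
  normal <- validate_beta_table(normal, convert = FALSE, what = "control table")
  check_matched_sites(tumor, normal)
  track <- auc_track %||% compute_auc_track(tumor, normal, config)
  sigma_tot <- attr(track, "sigma_tot") %||% sd(track$auc)
  params <- hmm_params(config, sigma_tot)
  states <- viterbi_decode(track, params)
  segments <- states_to_segments(states, track)
  segments <- split_by_max_distance(segments, track, config$max_distance)

  # per-site group means, aligned with the track rows
  key_track <- paste(track$chrom, track$pos)
  idx <- match(key_track, paste(tumor$chrom, tumor$pos))
  t_mean <- rowMeans(beta_values(tumor), na.rm = TRUE)[idx]
  n_mean <- rowMeans(beta_values(normal), na.rm = TRUE)[idx]
  diff_site <- t_mean - n_mean

  seg_stats <- vapply(seq_len(nrow(segments)), function(i) {
    rng <- segments$start_index[i]:segments$end_index[i]
    p <- if (segments$state[i] == "neutral") {
      NA_real_ # neutral segments are never DMR candidates; keep them out
      # of the BH family so they do not dilute the correction
    } else {
      wmw_p(t_mean[rng], n_mean[rng])
    }
    c(p, mean(diff_site[rng], na.rm = TRUE))
  }, numeric(2))
  segments$p_value <- seg_stats[1, ]
  segments$mean_beta_diff <- seg_stats[2, ]
  segments$fdr <- adjust_fdr(segments$p_value)

  dmrs <- filter_segments(segments, config)
  structure(
    list(
      auc = track, segments = segments, dmrs = dmrs,
      params = params, config = config,
      n_tumor = length(beta_samples(tumor)),
      n_normal = length(beta_samples(normal))
    ),
    class = "rocker_fit"
  )
}

#' @export
print.rocker_fit <- function(x, ...) {
  cat(sprintf(
    "<rocker_fit> %d sites, %d segments, %d DMRs (sigma_tot = %.4f)\n",
    nrow(x$auc), nrow(x$segments), nrow(x$dmrs),
    attr(x$auc, "sigma_tot")
  ))
  if (nrow(x$dmrs) > 0) print(table(x$dmrs$state))
  invisible(x)
}

#' Tidy the DMR table of a fit
#'
#' @param x A `rocker_fit` from [detect_dmrs()].
#' @param ... Unused.
#' @return The DMR tibble (`chrom`, `start`, `end`, `state`, `n_sites`,
#'   `mean_auc`, `mean_beta_diff`, `p_value`, `fdr`, `length_bp`).
#' @method tidy rocker_fit
#' @export
tidy.rocker_fit <- function(x, ...) {
  select(
    x$dmrs, "chrom", "start", "end", "state", "direction", "n_sites",
    "mean_auc", "mean_beta_diff", "p_value", "fdr", "length_bp"
  )
}

#' One-row summary of a fit
#'
#' @param x A `rocker_fit` from [detect_dmrs()].
#' @param ... Unused.
#' @return A one-row tibble with site, segment and DMR counts, the AUC
#'   dispersion `sigma_tot`, and the gain/loss DMR burden.
#' @method glance rocker_fit
#' @export
glance.rocker_fit <- function(x, ...) {
  b <- dmr_burden(x$dmrs, x$segments)
  tibble(
    n_sites = nrow(x$auc),
    n_segments = nrow(x$segments),
    n_dmrs = nrow(x$dmrs),
    n_hyper = sum(x$dmrs$state == "hyper"),
    n_hypo = sum(x$dmrs$state == "hypo"),
    n_hypo_block = sum(x$dmrs$state == "hypo_block"),
    sigma_tot = attr(x$auc, "sigma_tot"),
    burden_gain = b$burden[b$direction == "gain"],
    burden_loss = b$burden[b$direction == "loss"]
  )
}
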