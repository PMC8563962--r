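#' Wilcoxon-Mann-Whitney test of intra-segment differential methylation
#'
#' For one segment, the per-site beta values are averaged within each group
#' ("CpG-wise averaged beta values") and the two resulting vectors -- one
#' entry per CpG site -- are compared with a two-sided two-sample rank-sum
#' test. The exact null distribution is used when the segment has at most
#' 25 sites and no ties; otherwise the normal approximation with tie and
#' continuity correction applies.
#'
#' @param segment One-row segment tibble (columns `chrom`, `start`, `end`),
#'   e.g. a row of [states_to_segments()] output.
#' @param tumor,normal Beta tables with matched site lists.
#' @return A two-sided p-value, or `NA` if the segment contains no site
#'   with non-missing averages in both groups.
#' @export
segment_wmw_test <- function(segment, tumor, normal) {
  in_seg <- tumor$chrom == segment$chrom &
    tumor$pos >= segment$start & tumor$pos <= segment$end
  a <- rowMeans(beta_values(tumor)[in_seg, , drop = FALSE], na.rm = TRUE)
  b <- rowMeans(beta_values(normal)[in_seg, , drop = FALSE], na.rm = TRUE)
  wmw_p(a, b)
}

# Two-sided rank-sum p-value with the exact/approximate policy above.
wmw_p <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) {
    return(NA_real_)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= 25 && length(b) <= 25
  suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg adjustment of segment p-values
#'
#' Standard BH step-up applied jointly over all tested segments of one run
#' (all chromosomes together). Missing p-values are excluded from the
#' family and stay missing.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Vector of FDR values of the same length.
#' @export
adjust_fdr <- function(pvalues) {
  out <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Split segments at large inter-site gaps
#'
#' Cuts every segment at gaps between adjacent CpG sites larger than
#' `max_distance` base pairs. Intended for sparse designs (e.g. arrays)
#' where a single state run can otherwise bridge unassayed genomic space.
#' Sub-segments inherit the parent state and re-enter testing and
#' filtering. With `max_distance = NULL` the input is returned unchanged.
#'
#' @param segments Segment tibble from [states_to_segments()] (must carry
#'   `start_index`/`end_index` into `track`).
#' @param track The AUC track the segments were derived from.
#' @param max_distance Gap threshold in base pairs, or `NULL`.
#' @return A segment tibble of the same shape, possibly with more rows;
#'   the union of sub-segment sites equals the original sites.
#' @export
split_by_max_distance <- function(segments, track, max_distance) {
  if (is.null(max_distance) || nrow(segments) == 0) {
    return(segments)
  }
  pieces <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    idx <- seg$start_index:seg$end_index
    pos <- track$pos[idx]
    cut <- which(diff(pos) > max_distance)
    if (length(cut) == 0) {
      return(seg)
    }
    bounds <- cbind(c(1, cut + 1), c(cut, length(idx)))
    auc <- if ("auc" %in% names(track)) track$auc[idx] else rep(NA_real_, length(idx))
    tibble(
      chrom = seg$chrom,
      start = pos[bounds[, 1]],
      end = pos[bounds[, 2]],
      state = seg$state,
      n_sites = bounds[, 2] - bounds[, 1] + 1L,
      start_index = idx[bounds[, 1]],
      end_index = idx[bounds[, 2]],
      mean_auc = vapply(
        seq_len(nrow(bounds)),
        function(j) mean(auc[bounds[j, 1]:bounds[j, 2]]), numeric(1)
      )
    )
  })
  bind_rows(pieces)
}

#' Classify DMR candidates by direction and genomic length
#'
#' Gain-of-methylation segments are `hyper` regardless of size;
#' loss-of-methylation segments are `hypo` up to `hypo_block_len` base
#' pairs and `hypo_block` beyond it. The length of an interval is
#' `end - start + 1` (1-based inclusive bounds).
#'
#' @param state Character vector of underlying states (`"hypo"` for loss,
#'   `"hyper"` for gain).
#' @param length_bp Integer vector of segment lengths in base pairs.
#' @param hypo_block_len Length threshold in base pairs (default 10 kb).
#' @return Character vector of labels `hyper`, `hypo` or `hypo_block`.
#' @export
classify_dmr <- function(state, length_bp, hypo_block_len = 1e4) {
  dplyr::case_when(
    state == "hyper" ~ "hyper",
    state == "hypo" & length_bp > hypo_block_len ~ "hypo_block",
    state == "hypo" ~ "hypo",
    TRUE ~ NA_character_
  )
}

#' Filter tested segments into the final DMR set
#'
#' Keeps non-neutral segments with `fdr < fdr_alpha` and at least
#' `min_sites` CpG sites (segments with FDR at or above the cutoff, or
#' with fewer sites, are discarded), then classifies the survivors with
#' [classify_dmr()].
#'
#' @param segments Segment tibble with columns `state`, `n_sites`, `fdr`
#'   (plus coordinates and statistics).
#' @param config A [rocker_config()].
#' @return A DMR tibble with added `length_bp` and the classified `state`
#'   (`hyper`, `hypo`, `hypo_block`); the raw direction is kept as
#'   `direction` (`gain`/`loss`).
#' @export
filter_segments <- function(segments, config = rocker_config()) {
  kept <- filter(
    segments,
    .data$state != "neutral",
    !is.na(.data$fdr),
    .data$fdr < config$fdr_alpha,
    .data$n_sites >= config$min_sites
  )
  kept <- mutate(kept,
    length_bp = .data$end - .data$start + 1L,
    direction = ifelse(.data$state == "hyper", "gain", "loss"),
    state = classify_dmr(.data$state, .data$length_bp, config$hypo_block_len)
  )
  arrange(kept, .data$chrom, .data$start)
}

#' DMR burden of a segmentation
#'
#' Fraction of the segmented genomic span covered by DMRs of each
#' direction: the denominator is the summed length of all segments
#' (including neutral ones), the numerators the summed lengths of gain and
#' loss DMRs.
#'
#' @param dmrs DMR tibble from [filter_segments()].
#' @param segments Full segment tibble (all states) from the same run.
#' @return A tibble with columns `direction` (`gain`, `loss`) and `burden`.
#' @export
dmr_burden <- function(dmrs, segments) {
  if (nrow(segments) == 0) abort("empty segmentation")
  span <- sum(segments$end - segments$start + 1)
  len <- function(d) {
    if (nrow(d) == 0) 0 else sum(d$end - d$start + 1)
  }
  tibble(
    direction = c("gain", "loss"),
    burden = c(
      len(dmrs[dmrs$state == "hyper", ]),
      len(dmrs[dmrs$state %in% c("hypo", "hypo_block"), ])
    ) / span
  )
}
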