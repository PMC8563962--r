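#' Write DMRs as a BED6+ file
#'
#' Internally all intervals are 1-based and inclusive; BED output uses the
#' conventional 0-based half-open coordinates. The six standard columns are
#' followed by `n_sites`, `mean_auc`, `mean_beta_diff`, `p_value` and `fdr`.
#' The BED score is `-10 * log10(fdr)` capped at 1000 (0 when the FDR is
#' missing).
#'
#' @param dmrs A DMR tibble as returned by [tidy()] on a [detect_dmrs()]
#'   fit: columns `chrom`, `start`, `end`, `state`, `n_sites`, `mean_auc`,
#'   `mean_beta_diff`, `p_value`, `fdr`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  score <- ifelse(
    is.na(dmrs$fdr), 0,
    pmin(1000, -10 * log10(pmax(dmrs$fdr, 1e-100)))
  )
  bed <- tibble(
    chrom = dmrs$chrom,
    start = dmrs$start - 1L,
    end = dmrs$end,
    name = paste0(dmrs$state, "_", seq_len(nrow(dmrs))),
    score = round(score, 2),
    strand = ".",
    n_sites = dmrs$n_sites,
    mean_auc = signif(dmrs$mean_auc, 6),
    mean_beta_diff = signif(dmrs$mean_beta_diff, 6),
    p_value = signif(dmrs$p_value, 6),
    fdr = signif(dmrs$fdr, 6)
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a DMR BED6+ file
#'
#' Reads BED files written by [write_dmr_bed()] (or any BED with at least
#' chrom/start/end and, when available, a `state_index` name column) back
#' into the package's 1-based inclusive interval convention.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present
#'   in the file, `state`, `n_sites`, `mean_auc`, `mean_beta_diff`,
#'   `p_value`, `fdr`.
#' @export
read_dmr_bed <- function(path) {
  cols <- c(
    "chrom", "start", "end", "name", "score", "strand",
    "n_sites", "mean_auc", "mean_beta_diff", "p_value", "fdr"
  )
  x <- readr::read_tsv(path,
    col_names = FALSE, show_col_types = FALSE, progress = FALSE,
    comment = "#"
  )
  if (nrow(x) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      state = character()
    ))
  }
  names(x) <- cols[seq_len(ncol(x))]
  out <- tibble(
    chrom = as.character(x$chrom),
    start = as.integer(x$start) + 1L,
    end = as.integer(x$end)
  )
  if ("name" %in% names(x)) {
    out$state <- sub("_[0-9]+$", "", as.character(x$name))
  }
  for (nm in c("n_sites", "mean_auc", "mean_beta_diff", "p_value", "fdr")) {
    if (nm %in% names(x)) out[[nm]] <- x[[nm]]
  }
  out
}

#' Write / read an AUC track as TSV
#'
#' @param track An AUC track tibble from [compute_auc_track()].
#' @param path File path.
#' @return `path` (write) or the track tibble with the `sigma_tot`
#'   attribute restored from the data (read).
#' @export
write_auc_track <- function(track, path) {
  readr::write_tsv(track, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_auc_track
#' @export
read_auc_track <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("chrom", "pos", "auc") %in% names(x)))
  attr(x, "sigma_tot") <- sd(x$auc)
  x
}
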