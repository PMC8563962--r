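#' Partition multiple DMR sets into atomic intervals
#'
#' Computes the multi-set interval partition (in the style of
#' `bedtools multiinter`): the genome is cut at the union of all DMR
#' boundaries so that every atomic interval is either fully inside or
#' fully outside each input DMR. Each atom is annotated with the state it
#' carries in every covering dataset. Concatenating the atoms of one
#' dataset reconstructs its DMRs exactly.
#'
#' @param dmr_sets Named list of per-dataset DMR tibbles (columns `chrom`,
#'   `start`, `end`, `state`; 1-based inclusive intervals, internally
#'   non-overlapping).
#' @return A tibble of atoms with columns `chrom`, `start`, `end`,
#'   `n_datasets` (number of covering datasets) and one state column per
#'   dataset (`NA` where the dataset does not cover the atom).
#' @export
partition_multi <- function(dmr_sets) {
  stopifnot(is.list(dmr_sets), length(dmr_sets) >= 1, !is.null(names(dmr_sets)))
  chroms <- sort(unique(unlist(lapply(dmr_sets, function(d) d$chrom))))
  grs <- lapply(names(dmr_sets), function(nm) {
    d <- arrange(dmr_sets[[nm]], .data$chrom, .data$start)
    if (nrow(d) > 1) {
      same <- d$chrom[-1] == d$chrom[-nrow(d)]
      if (any(same & d$start[-1] <= d$end[-nrow(d)])) {
        abort(sprintf("overlapping DMRs within input set '%s'", nm))
      }
    }
    GenomicRanges::GRanges(
      factor(d$chrom, levels = chroms),
      IRanges::IRanges(d$start, d$end),
      state = d$state
    )
  })
  names(grs) <- names(dmr_sets)
  atoms <- GenomicRanges::disjoin(Reduce(c, grs))
  atoms <- GenomicRanges::sort(atoms)
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(atoms)),
    start = GenomicRanges::start(atoms),
    end = GenomicRanges::end(atoms)
  )
  for (nm in names(grs)) {
    hit <- GenomicRanges::findOverlaps(atoms, grs[[nm]], type = "within")
    st <- rep(NA_character_, length(atoms))
    st[S4Vectors::queryHits(hit)] <- grs[[nm]]$state[S4Vectors::subjectHits(hit)]
    out[[nm]] <- st
  }
  st_cols <- as.matrix(out[, names(grs), drop = FALSE])
  out <- mutate(out, n_datasets = rowSums(!is.na(st_cols)), .after = "end")
  out
}

#' Refine a multi-dataset atom partition into a harmonized catalog
#'
#' Applies the catalog quality filters to each atom, per supporting
#' dataset: at least `min_sites` probes inside the atom; a two-sided
#' Wilcoxon-Mann-Whitney test of the per-sample median betas (tumors vs
#' normals), corrected by Benjamini-Hochberg within each dataset, must
#' give FDR < `fdr_alpha`; the mean beta difference must exceed 5
#' percentage points in magnitude; and at least 3 CpG sites must show a
#' concordant per-site signal (AUC < 0.25 for loss, AUC > 0.75 for gain).
#' Atoms retained in several datasets must have a dominant direction
#' (strict majority among supporting datasets; ties are discarded), and
#' the 10 kb hypo/hypo-block split is re-applied to the consensus. Atoms
#' that are adjacent, identically supported and identically labelled are
#' merged back to undo boundary fragmentation.
#'
#' @param atoms Atom tibble from [partition_multi()].
#' @param datasets Named list matching the dataset columns of `atoms`;
#'   each element a list with `tumor`, `normal` (beta tables) and `auc`
#'   (the dataset's AUC track).
#' @param config A [rocker_config()].
#' @return A catalog tibble with columns `chrom`, `start`, `end`,
#'   `length_bp`, `consensus_state`, `n_supporting`, and one per-dataset
#'   state column (supporting datasets only; others `NA`).
#' @export
refine_catalog <- function(atoms, datasets, config = rocker_config()) {
  ds_names <- intersect(names(datasets), names(atoms))
  missing_ds <- setdiff(setdiff(names(atoms), c("chrom", "start", "end", "n_datasets")), names(datasets))
  if (length(missing_ds)) {
    abort(sprintf("no beta data supplied for dataset(s): %s", paste(missing_ds, collapse = ", ")))
  }
  n_atom <- nrow(atoms)
  support <- matrix(NA_character_, n_atom, length(ds_names),
    dimnames = list(NULL, ds_names)
  )
  for (nm in ds_names) {
    ds <- datasets[[nm]]
    tv <- beta_values(ds$tumor)
    nv <- beta_values(ds$normal)
    member <- which(!is.na(atoms[[nm]]))
    stats <- lapply(member, function(i) {
      in_atom <- ds$tumor$chrom == atoms$chrom[i] &
        ds$tumor$pos >= atoms$start[i] & ds$tumor$pos <= atoms$end[i]
      n_probes <- sum(in_atom)
      if (n_probes == 0) {
        return(list(p = NA_real_, diff = NA_real_, n = 0L, conc = 0L))
      }
      t_med <- apply(tv[in_atom, , drop = FALSE], 2, median, na.rm = TRUE)
      n_med <- apply(nv[in_atom, , drop = FALSE], 2, median, na.rm = TRUE)
      loss <- atoms[[nm]][i] %in% c("hypo", "hypo_block")
      in_auc <- ds$auc$chrom == atoms$chrom[i] &
        ds$auc$pos >= atoms$start[i] & ds$auc$pos <= atoms$end[i]
      conc <- if (loss) {
        sum(ds$auc$auc[in_auc] < 0.25)
      } else {
        sum(ds$auc$auc[in_auc] > 0.75)
      }
      list(
        p = wmw_p(t_med, n_med),
        diff = mean(t_med, na.rm = TRUE) - mean(n_med, na.rm = TRUE),
        n = n_probes, conc = conc
      )
    })
    p <- vapply(stats, `[[`, numeric(1), "p")
    fdr <- adjust_fdr(p) # BH within this dataset's atom tests
    ok <- !is.na(fdr) & fdr < config$fdr_alpha &
      abs(vapply(stats, `[[`, numeric(1), "diff")) > 5 &
      vapply(stats, `[[`, integer(1), "n") >= config$min_sites &
      vapply(stats, `[[`, integer(1), "conc") >= 3
    support[member[ok], nm] <- atoms[[nm]][member[ok]]
  }

  direction <- ifelse(support == "hyper", "gain",
    ifelse(is.na(support), NA, "loss")
  )
  n_gain <- rowSums(direction == "gain", na.rm = TRUE)
  n_loss <- rowSums(direction == "loss", na.rm = TRUE)
  n_sup <- n_gain + n_loss
  dominant <- dplyr::case_when(
    n_sup == 0 ~ NA_character_,
    n_gain > n_loss ~ "gain",
    n_loss > n_gain ~ "loss",
    TRUE ~ NA_character_ # tie: no dominant state
  )
  keep <- which(!is.na(dominant))
  out <- tibble(
    chrom = atoms$chrom[keep],
    start = atoms$start[keep],
    end = atoms$end[keep]
  )
  out$length_bp <- out$end - out$start + 1L
  out$consensus_state <- ifelse(
    dominant[keep] == "gain", "hyper",
    ifelse(out$length_bp > config$hypo_block_len, "hypo_block", "hypo")
  )
  out$n_supporting <- n_sup[keep]
  for (nm in ds_names) out[[nm]] <- support[keep, nm]

  # merge back adjacent atoms with identical support pattern and label
  if (nrow(out) > 1) {
    sig <- apply(out[, c("consensus_state", ds_names), drop = FALSE], 1,
      paste,
      collapse = "|"
    )
    new_run <- c(TRUE, !(out$chrom[-1] == out$chrom[-nrow(out)] &
      out$start[-1] == out$end[-nrow(out)] + 1L &
      sig[-1] == sig[-length(sig)]))
    run <- cumsum(new_run)
    out <- out |>
      mutate(.run = run) |>
      group_by(.data$.run) |>
      summarise(across(
        c("chrom", "consensus_state", "n_supporting", all_of(ds_names)),
        dplyr::first
      ), start = min(.data$start), end = max(.data$end), .groups = "drop") |>
      mutate(length_bp = .data$end - .data$start + 1L) |>
      # re-apply the length split to merged loss entries
      mutate(consensus_state = ifelse(
        .data$consensus_state == "hyper", "hyper",
        ifelse(.data$length_bp > config$hypo_block_len, "hypo_block", "hypo")
      )) |>
      select(
        "chrom", "start", "end", "length_bp", "consensus_state",
        "n_supporting", all_of(ds_names)
      ) |>
      arrange(.data$chrom, .data$start)
  }
  out
}

#' Cumulative sharing profile of a catalog
#'
#' For each DMR class, the fraction of catalog entries supported by at
#' least `k` datasets, for `k = 1 .. n_datasets`. The curve is monotone
#' nonincreasing in `k`; its value at `k = 1` is 1 by construction.
#'
#' @param catalog Catalog tibble from [refine_catalog()] (columns
#'   `consensus_state` and `n_supporting`).
#' @param n_datasets Total number of datasets merged.
#' @return A tibble with columns `state`, `k`, `fraction`.
#' @export
sharedness_profile <- function(catalog, n_datasets) {
  tidyr::crossing(
    state = unique(catalog$consensus_state),
    k = seq_len(n_datasets)
  ) |>
    dplyr::rowwise() |>
    mutate(fraction = {
      cls <- catalog$n_supporting[catalog$consensus_state == .data$state]
      mean(cls >= .data$k)
    }) |>
    ungroup()
}
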