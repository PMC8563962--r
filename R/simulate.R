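#' Simulate a benchmark methylation dataset with implanted DMRs
#'
#' Generates a pair of beta tables (test "tumor" group and control
#' "normal" group) over a synthetic genome with known, non-overlapping
#' implanted DMRs, emulating three assay layouts:
#' \describe{
#'   \item{wgbs}{densely spaced CpG sites (exponential gaps, ~120 bp on
#'     average) on one synthetic chromosome;}
#'   \item{rrbs}{clusters of 10-40 sites at 10-100 bp spacing separated by
#'     2-20 kb gaps;}
#'   \item{hm450}{a sparse array-like design on a single chromosome:
#'     promoter clusters of 8-20 probes at 100-500 bp spacing interleaved
#'     with open-sea probes at 5-50 kb spacing, carrying exactly 60
#'     promoter DMRs (8-20 probes each) and 20 non-promoter DMRs (5-10
#'     probes each).}
#' }
#'
#' Background methylation is bimodal: each site's baseline mean is drawn
#' around a low (unmethylated, CpG-island-like) or high (methylated,
#' open-sea-like) mode. Within an implanted DMR, the test-group signal
#' mean is the baseline reflected toward the opposite mode, so
#' low-methylation regions gain methylation (`gain`) and high-methylation
#' regions lose it (`loss`). Per sample and site, a test-group value is
#' drawn from the shifted signal component with probability `c` (the
#' mixture factor) and from the baseline otherwise: smaller `c` means a
#' lower signal-to-noise ratio. Class labels 1-5 map to
#' `c = 1.0, 0.85, 0.7, 0.6, 0.55`. All values additionally carry a
#' per-sample offset (e.g. purity differences) and per-observation
#' biological/technical noise on the logit scale, then beta-distributed
#' measurement noise.
#'
#' @param platform `"wgbs"`, `"rrbs"` or `"hm450"`.
#' @param class_label Signal-to-noise class 1 (easiest) to 5 (hardest).
#' @param n_tumor,n_normal Group sizes (at least 2 each).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param n_sites Approximate number of CpG sites (ignored for `hm450`,
#'   whose layout is probe-count driven).
#' @param n_dmrs Number of implanted DMRs (ignored for `hm450`; 0 gives a
#'   null dataset with no differential signal).
#' @param dmr_sites Integer vector from which implanted DMR site counts
#'   are sampled (wgbs/rrbs only); the default long-tailed range includes
#'   DMRs below the default `min_sites` filter, as short DMRs are a
#'   realistic part of the benchmark.
#' @param sample_offset_sd Logit-scale SD of the per-sample global offset.
#' @param site_noise_sd Logit-scale SD of per-(site, sample) biological
#'   noise.
#' @param precision Beta-distribution precision of measurement noise
#'   (read-depth-like; smaller is noisier). Defaults: 12 for
#'   sequencing-like layouts, 40 for the array layout.
#' @param mode_concentration Beta concentration of per-site baseline means
#'   around their mode centre; larger values give a tighter bimodal
#'   baseline.
#' @return An object of class `rocker_sim`: a list with beta tables
#'   `tumor` and `normal` (percent units), `truth` (implanted DMRs:
#'   `chrom`, `start`, `end`, `direction`, `n_sites`, `type`), `sites`
#'   (per-site truth labels `gain`/`loss`/`none`), and the generator
#'   settings.
#' @examples
#' sim <- simulate_dataset("hm450", class_label = 1, seed = 1)
#' table(sim$truth$type)
#' @export
simulate_dataset <- function(platform = c("wgbs", "rrbs", "hm450"),
                             class_label = 5,
                             n_tumor = 6, n_normal = 6,
                             seed = 1,
                             n_sites = 20000,
                             n_dmrs = NULL,
                             dmr_sites = NULL,
                             sample_offset_sd = 0.4,
                             site_noise_sd = 1.0,
                             precision = NULL,
                             mode_concentration = 30) {
  platform <- match.arg(platform)
  if (!class_label %in% 1:5) abort("class_label must be 1, 2, 3, 4 or 5")
  stopifnot(n_tumor >= 2, n_normal >= 2)
  mixture_factor <- c(1.0, 0.85, 0.7, 0.6, 0.55)[class_label]
  precision <- precision %||% if (platform == "hm450") 40 else 12
  if (platform == "hm450") {
    site_noise_sd <- min(site_noise_sd, 0.5)
  }
  set.seed(as.integer(seed))

  lay <- switch(platform,
    wgbs = layout_wgbs(n_sites, n_dmrs %||% 150L, dmr_sites %||% 2:14),
    rrbs = layout_rrbs(n_sites, n_dmrs %||% 150L, dmr_sites %||% 2:14),
    hm450 = layout_hm450()
  )
  n <- length(lay$pos)

  # bimodal baseline site means; implanted runs get a coherent mode
  low <- runif(n) < 0.35
  low[lay$force_low] <- TRUE
  low[lay$force_high] <- FALSE
  center <- ifelse(low, 0.2, 0.8)
  m_base <- rbeta(n, center * mode_concentration, (1 - center) * mode_concentration)
  m_sig <- 1 - m_base # reflection toward the opposite mode
  direction <- ifelse(low, "gain", "loss")

  in_dmr <- rep(FALSE, n)
  truth_rows <- lapply(seq_along(lay$dmr_from), function(k) {
    rng <- lay$dmr_from[k]:lay$dmr_to[k]
    in_dmr[rng] <<- TRUE
    tibble(
      chrom = lay$chrom[lay$dmr_from[k]],
      start = lay$pos[lay$dmr_from[k]],
      end = lay$pos[lay$dmr_to[k]],
      direction = direction[lay$dmr_from[k]],
      n_sites = length(rng),
      type = lay$dmr_type[k]
    )
  })
  truth <- if (length(truth_rows)) bind_rows(truth_rows) else {
    tibble(
      chrom = character(), start = integer(), end = integer(),
      direction = character(), n_sites = integer(), type = character()
    )
  }

  draw_group <- function(n_samp, with_signal) {
    u <- rnorm(n_samp, 0, sample_offset_sd)
    vals <- matrix(NA_real_, n, n_samp)
    for (s in seq_len(n_samp)) {
      mu <- m_base
      if (with_signal && any(in_dmr)) {
        z <- in_dmr & (runif(n) < mixture_factor)
        mu[z] <- m_sig[z]
      }
      eta <- qlogis(pmin(pmax(mu, 0.001), 0.999)) + u[s] +
        rnorm(n, 0, site_noise_sd)
      pm <- plogis(eta)
      vals[, s] <- rbeta(n, pm * precision, (1 - pm) * precision) * 100
    }
    vals
  }
  tv <- draw_group(n_tumor, with_signal = TRUE)
  nv <- draw_group(n_normal, with_signal = FALSE)

  mk_table <- function(vals, prefix) {
    colnames(vals) <- paste0(prefix, seq_len(ncol(vals)))
    dplyr::bind_cols(
      tibble(chrom = lay$chrom, pos = lay$pos),
      as_tibble(vals)
    )
  }
  structure(
    list(
      tumor = mk_table(tv, "T"),
      normal = mk_table(nv, "N"),
      truth = truth,
      sites = tibble(
        chrom = lay$chrom, pos = lay$pos,
        truth = ifelse(in_dmr, direction, "none")
      ),
      platform = platform, class_label = class_label,
      mixture_factor = mixture_factor, seed = seed
    ),
    class = "rocker_sim"
  )
}

#' @export
print.rocker_sim <- function(x, ...) {
  cat(sprintf(
    "<rocker_sim> %s class %d (c = %.2f): %d sites, %d/%d samples, %d implanted DMRs\n",
    x$platform, x$class_label, x$mixture_factor,
    nrow(x$sites), ncol(x$tumor) - 2, ncol(x$normal) - 2, nrow(x$truth)
  ))
  invisible(x)
}

# -- layouts -----------------------------------------------------------------
# Each layout returns chrom/pos plus implanted DMR index ranges and, where
# the direction is dictated by genomic context, masks forcing the baseline
# mode of implanted runs.

# Non-overlapping implants: one candidate slot per DMR along the site index.
place_dmrs <- function(n, n_dmrs, dmr_sites) {
  if (n_dmrs == 0) {
    return(list(from = integer(0), to = integer(0)))
  }
  slot <- floor(n / n_dmrs)
  len <- sample(dmr_sites, n_dmrs, replace = TRUE)
  len <- pmin(len, slot - 2L)
  from <- (seq_len(n_dmrs) - 1L) * slot +
    vapply(len, function(l) sample.int(slot - l - 1L, 1), integer(1))
  list(from = from, to = from + len - 1L)
}

layout_wgbs <- function(n_sites, n_dmrs, dmr_sites) {
  gaps <- pmax(2, round(rexp(n_sites - 1, 1 / 120)))
  pos <- cumsum(c(1000L, gaps))
  dmr <- place_dmrs(n_sites, n_dmrs, dmr_sites)
  # coherent direction per implant: force a single baseline mode
  force_low <- force_high <- rep(FALSE, n_sites)
  for (k in seq_along(dmr$from)) {
    rng <- dmr$from[k]:dmr$to[k]
    if (runif(1) < 0.5) force_low[rng] <- TRUE else force_high[rng] <- TRUE
  }
  list(
    chrom = rep("chrS", n_sites), pos = as.integer(pos),
    dmr_from = dmr$from, dmr_to = dmr$to,
    dmr_type = rep("generic", length(dmr$from)),
    force_low = force_low, force_high = force_high
  )
}

layout_rrbs <- function(n_sites, n_dmrs, dmr_sites) {
  pos <- integer(0)
  cur <- 1000L
  while (length(pos) < n_sites) {
    k <- sample(10:40, 1)
    gaps <- sample(10:100, k - 1, replace = TRUE)
    pos <- c(pos, cumsum(c(cur, gaps)))
    cur <- pos[length(pos)] + sample(2000:20000, 1)
  }
  pos <- pos[seq_len(n_sites)]
  dmr <- place_dmrs(n_sites, n_dmrs, dmr_sites)
  force_low <- force_high <- rep(FALSE, n_sites)
  for (k in seq_along(dmr$from)) {
    rng <- dmr$from[k]:dmr$to[k]
    if (runif(1) < 0.5) force_low[rng] <- TRUE else force_high[rng] <- TRUE
  }
  list(
    chrom = rep("chrS", n_sites), pos = as.integer(pos),
    dmr_from = dmr$from, dmr_to = dmr$to,
    dmr_type = rep("generic", length(dmr$from)),
    force_low = force_low, force_high = force_high
  )
}

layout_hm450 <- function() {
  n_prom <- 120L # 60 carry DMRs
  n_prom_dmr <- 60L
  n_opensea_dmr <- 20L
  pos <- integer(0)
  chrom <- character(0)
  prom_runs <- list() # index ranges of promoter clusters
  sea_runs <- list() # index ranges of open-sea stretches
  cur <- 10000L
  for (i in seq_len(n_prom)) {
    k <- sample(8:20, 1)
    p <- cumsum(c(cur, sample(100:500, k - 1, replace = TRUE)))
    prom_runs[[i]] <- length(pos) + seq_len(k)
    pos <- c(pos, p)
    cur <- pos[length(pos)] + sample(5000:50000, 1)
    k2 <- sample(15:30, 1)
    p2 <- cumsum(c(cur, sample(5000:50000, k2 - 1, replace = TRUE)))
    sea_runs[[i]] <- length(pos) + seq_len(k2)
    pos <- c(pos, p2)
    cur <- pos[length(pos)] + sample(5000:50000, 1)
  }
  n <- length(pos)
  force_low <- force_high <- rep(FALSE, n)
  for (r in prom_runs) force_low[r] <- TRUE # promoters: unmethylated baseline
  for (r in sea_runs) force_high[r] <- TRUE # open sea: methylated baseline

  prom_pick <- sample.int(n_prom, n_prom_dmr)
  dmr_from <- dmr_to <- integer(0)
  for (i in prom_pick) {
    r <- prom_runs[[i]]
    sizes <- 8:min(20, length(r))
    l <- sizes[sample.int(length(sizes), 1)] # safe when length(sizes) == 1
    s <- sample.int(length(r) - l + 1L, 1)
    dmr_from <- c(dmr_from, r[s])
    dmr_to <- c(dmr_to, r[s + l - 1L])
  }
  sea_pick <- sample.int(length(sea_runs), n_opensea_dmr)
  for (i in sea_pick) {
    r <- sea_runs[[i]]
    l <- sample(5:10, 1)
    s <- sample.int(length(r) - l + 1L, 1)
    dmr_from <- c(dmr_from, r[s])
    dmr_to <- c(dmr_to, r[s + l - 1L])
  }
  ord <- order(dmr_from)
  list(
    chrom = rep("chr10", n), pos = as.integer(pos),
    dmr_from = dmr_from[ord], dmr_to = dmr_to[ord],
    dmr_type = c(
      rep("promoter", n_prom_dmr),
      rep("non_promoter", n_opensea_dmr)
    )[ord],
    force_low = force_low, force_high = force_high
  )
}

#' Simulate an AUC track directly from the segmentation HMM
#'
#' Draws a hidden state path from the heterogeneous Markov chain (with the
#' distance-dependent transition matrix evaluated at the given site gaps)
#' and emits AUC observations from the truncated-Gaussian emission
#' distributions. Useful for checking that decoding recovers the states
#' that generated the data.
#'
#' @param params An [hmm_params()] object.
#' @param n Number of sites.
#' @param gap Inter-site gap in base pairs (scalar or length `n - 1`).
#' @param chrom Chromosome name for the track.
#' @return A list with `track` (an AUC track tibble with `sigma_tot`
#'   attribute) and `states` (the true state path).
#' @export
simulate_hmm_track <- function(params, n, gap = 1000, chrom = "chrS") {
  gaps <- rep_len(gap, n - 1)
  pos <- cumsum(c(1L, gaps))
  states <- integer(n)
  states[1] <- sample.int(3, 1, prob = params$pi)
  for (i in 2:n) {
    a <- transition_matrix(gaps[i - 1], params$p, params$d_norm)
    states[i] <- sample.int(3, 1, prob = a[states[i - 1], ])
  }
  rtrunc <- function(k) {
    m <- params$mu[k]
    s <- params$sd[k]
    lo <- pnorm((params$l - m) / s)
    hi <- pnorm((params$u - m) / s)
    qnorm(runif(sum(states == k), lo, hi)) * s + m
  }
  auc <- numeric(n)
  for (k in 1:3) auc[states == k] <- rtrunc(k)
  track <- tibble(chrom = chrom, pos = as.integer(pos), auc = auc)
  attr(track, "sigma_tot") <- sd(auc)
  list(track = track, states = states)
}
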