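#' Parameters of the three-state segmentation HMM
#'
#' Builds the full parameter set of the heterogeneous hidden Markov model
#' from the run configuration and the observed AUC dispersion. The three
#' hidden states are hypomethylated (state 1), neutral (state 2) and
#' hypermethylated (state 3), with truncated-Gaussian emissions on \[0, 1\]
#' centred at `0.5 - mu`, `0.5` and `0.5 + mu`. The total AUC standard
#' deviation `sigma_tot` is split by the factor `f`: the neutral state gets
#' `f * sigma_tot`, the two differential states `(1 - f) * sigma_tot`.
#' State means are fixed parameters rather than estimated by EM: they are
#' pinned to the known null value of the AUC and to the intended
#' differential resolution. The initial state distribution is uniform.
#'
#' @param config A [rocker_config()].
#' @param sigma_tot Standard deviation of all retained AUC values (the
#'   `sigma_tot` attribute of [compute_auc_track()] output).
#' @return A list of class `hmm_params` with elements `mu` (length 3),
#'   `sd` (length 3), `p`, `d_norm`, `pi`, `l`, `u`.
#' @examples
#' hmm_params(rocker_config(), sigma_tot = 0.2)
#' @export
hmm_params <- function(config = rocker_config(), sigma_tot) {
  stopifnot(is.numeric(sigma_tot), length(sigma_tot) == 1, sigma_tot > 0)
  mu <- c(0.5 - config$mu, 0.5, 0.5 + config$mu)
  sds <- c(
    (1 - config$f) * sigma_tot,
    config$f * sigma_tot,
    (1 - config$f) * sigma_tot
  )
  if (any(sds <= 0)) abort("state standard deviations must be positive")
  structure(
    list(
      mu = mu, sd = sds,
      p = config$p, d_norm = config$d_norm,
      pi = rep(1 / 3, 3), l = 0, u = 1
    ),
    class = "hmm_params"
  )
}

#' Truncated-Gaussian emission log-density
#'
#' Log-density of the AUC observation under one hidden state: a Gaussian
#' with the state's mean and standard deviation, truncated to \[0, 1\] (the
#' support of the AUC). Results are floored at -745 so that decoding never
#' propagates `-Inf`.
#'
#' @param auc Numeric vector of AUC values in \[0, 1\].
#' @param state State index 1 (hypo), 2 (neutral) or 3 (hyper).
#' @param params An [hmm_params()] object.
#' @return Numeric vector of log-densities.
#' @export
emission_logdensity <- function(auc, state, params) {
  if (any(auc < 0 | auc > 1, na.rm = TRUE)) {
    abort("AUC values must lie in [0, 1]")
  }
  stopifnot(state %in% 1:3)
  m <- params$mu[state]
  s <- params$sd[state]
  z <- pnorm((params$u - m) / s) - pnorm((params$l - m) / s)
  pmax(dnorm(auc, m, s, log = TRUE) - log(z), -745)
}

#' Distance-dependent transition matrix
#'
#' Transition probabilities between adjacent CpG sites separated by `d_i`
#' base pairs. With `f_i = d_i / d_norm`, every off-diagonal entry is
#' `p * (1 - exp(-f_i)) / 2` and each diagonal entry is
#' `1 - p * (1 - exp(-f_i))`: state changes become more likely the farther
#' apart two sites are, saturating at the homogeneous jump probability `p`.
#' At `d_i = 0` the matrix is the identity.
#'
#' @param d_i Genomic distance in base pairs (non-negative scalar).
#' @param p Homogeneous jump probability in (0, 1).
#' @param d_norm Distance normalization in base pairs.
#' @return A 3 x 3 row-stochastic matrix.
#' @examples
#' transition_matrix(1e5, p = 0.05, d_norm = 1e5)
#' @export
transition_matrix <- function(d_i, p, d_norm) {
  stopifnot(length(d_i) == 1, is.finite(d_i))
  if (d_i < 0) abort("distance must be non-negative")
  q <- p * (1 - exp(-d_i / d_norm))
  a <- matrix(q / 2, 3, 3)
  diag(a) <- 1 - q
  a
}

#' Viterbi decoding of an AUC track
#'
#' Finds the maximum a posteriori state path of the heterogeneous HMM for
#' each chromosome independently (no transition is modelled across
#' chromosome boundaries; the first site of every chromosome uses the
#' initial distribution). The recursion runs in log space with the
#' distance-dependent transition matrix recomputed at every inter-site gap.
#'
#' @param track An AUC track from [compute_auc_track()] (columns `chrom`,
#'   `pos`, `auc`, sorted along the genome).
#' @param params An [hmm_params()] object.
#' @return Integer vector of decoded states (1 = hypo, 2 = neutral,
#'   3 = hyper), one per track row.
#' @export
viterbi_decode <- function(track, params) {
  states <- integer(nrow(track))
  for (chr in unique(track$chrom)) {
    idx <- which(track$chrom == chr)
    states[idx] <- viterbi_chrom(track$auc[idx], track$pos[idx], params)
  }
  states
}

viterbi_chrom <- function(x, pos, params) {
  n <- length(x)
  if (n == 0) {
    return(integer(0))
  }
  e <- vapply(1:3, function(k) emission_logdensity(x, k, params), numeric(n))
  e <- matrix(e, nrow = n)
  delta <- log(params$pi) + e[1, ]
  if (n == 1) {
    return(which.max(delta))
  }
  d <- diff(pos)
  q <- params$p * (1 - exp(-d / params$d_norm))
  l_same <- pmax(log1p(-q), -745)
  l_diff <- pmax(log(q / 2), -745)
  psi <- matrix(0L, n, 3)
  for (i in 2:n) {
    new_delta <- numeric(3)
    for (k in 1:3) {
      cand <- delta + l_diff[i - 1]
      cand[k] <- delta[k] + l_same[i - 1]
      j <- which.max(cand)
      psi[i, k] <- j
      new_delta[k] <- cand[j] + e[i, k]
    }
    delta <- new_delta
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  for (i in n:2) path[i - 1] <- psi[i, path[i]]
  path
}

#' Log-likelihood of a given state path
#'
#' Joint log-probability (up to the observation measure) of a state path
#' and the AUC observations under the heterogeneous HMM, per chromosome
#' with no cross-chromosome transitions. Mainly useful to compare candidate
#' paths against the Viterbi optimum.
#'
#' @inheritParams viterbi_decode
#' @param states Integer vector of states (1..3), one per track row.
#' @return A single log-likelihood value.
#' @export
hmm_path_loglik <- function(track, params, states) {
  stopifnot(length(states) == nrow(track))
  ll <- 0
  for (chr in unique(track$chrom)) {
    idx <- which(track$chrom == chr)
    x <- track$auc[idx]
    pos <- track$pos[idx]
    s <- states[idx]
    ll <- ll + log(params$pi[s[1]]) +
      sum(vapply(seq_along(s), function(i) {
        emission_logdensity(x[i], s[i], params)
      }, numeric(1)))
    if (length(s) > 1) {
      q <- params$p * (1 - exp(-diff(pos) / params$d_norm))
      same <- s[-length(s)] == s[-1]
      ll <- ll + sum(pmax(ifelse(same, log1p(-q), log(q / 2)), -745))
    }
  }
  ll
}

#' Collapse a per-site state sequence into segments
#'
#' Run-length encodes the decoded state path into maximal runs of a single
#' state, never merging across chromosome boundaries. Segment bounds are
#' the genomic positions of the first and last CpG site of the run (no
#' extension beyond assayed sites).
#'
#' @param states Integer (1..3) or character (`"hypo"`, `"neutral"`,
#'   `"hyper"`) state vector, one entry per track row.
#' @param track The AUC track (or any site table with `chrom` and `pos`;
#'   `auc` is used for the segment mean when present).
#' @return A tibble with columns `chrom`, `start`, `end`, `state`,
#'   `n_sites`, `start_index`, `end_index`, `mean_auc`.
#' @export
states_to_segments <- function(states, track) {
  stopifnot(length(states) == nrow(track))
  if (nrow(track) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      state = character(), n_sites = integer(),
      start_index = integer(), end_index = integer(), mean_auc = numeric()
    ))
  }
  lab <- if (is.numeric(states)) c("hypo", "neutral", "hyper")[states] else states
  brk <- c(TRUE, lab[-1] != lab[-length(lab)] |
    track$chrom[-1] != track$chrom[-nrow(track)])
  run <- cumsum(brk)
  auc <- if ("auc" %in% names(track)) track$auc else rep(NA_real_, nrow(track))
  tibble(
    chrom = track$chrom, pos = track$pos, state = lab,
    auc = auc, idx = seq_along(run), run = run
  ) |>
    group_by(.data$run) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$pos),
      end = max(.data$pos),
      state = .data$state[1],
      n_sites = dplyr::n(),
      start_index = min(.data$idx),
      end_index = max(.data$idx),
      mean_auc = mean(.data$auc),
      .groups = "drop"
    ) |>
    select(-"run")
}
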