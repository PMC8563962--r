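# Independent oracles used to check the package implementations.
# These are deliberately naive (enumeration / closed form / sweep line) and
# share no code with the package internals.

# ROC AUC by exhaustive pair counting.
auc_pair_oracle <- function(t, n) {
  t <- t[!is.na(t)]
  n <- n[!is.na(n)]
  wins <- sum(outer(t, n, ">")) + 0.5 * sum(outer(t, n, "=="))
  wins / (length(t) * length(n))
}

# Truncated-normal log-density on [0, 1], coded from the phi / (Phi - Phi) form.
truncnorm_log_oracle <- function(x, mean, sd, lo = 0, hi = 1) {
  num <- exp(-((x - mean) / sd)^2 / 2) / (sd * sqrt(2 * pi))
  den <- pnorm((hi - mean) / sd) - pnorm((lo - mean) / sd)
  log(num / den)
}

# All state paths of length n over 3 states (rows).
all_paths <- function(n) {
  as.matrix(expand.grid(rep(list(1:3), n)))
}

# Joint log-probability of every path for a single-chromosome track; returns
# the index of the best path. Vectorized over paths, naive over structure.
brute_force_viterbi <- function(auc, pos, params) {
  n <- length(auc)
  paths <- all_paths(n)
  e <- sapply(1:3, function(k) {
    z <- pnorm((1 - params$mu[k]) / params$sd[k]) -
      pnorm((0 - params$mu[k]) / params$sd[k])
    pmax(dnorm(auc, params$mu[k], params$sd[k], log = TRUE) - log(z), -745)
  })
  ll <- log(params$pi)[paths[, 1]]
  for (i in seq_len(n)) ll <- ll + e[cbind(i, paths[, i])]
  if (n > 1) {
    q <- params$p * (1 - exp(-diff(pos) / params$d_norm))
    for (i in seq_len(n - 1)) {
      same <- paths[, i] == paths[, i + 1]
      ll <- ll + pmax(ifelse(same, log(1 - q[i]), log(q[i] / 2)), -745)
    }
  }
  paths[which.max(ll), ]
}

# Exact two-sided rank-sum p-value by enumerating all C(n1+n2, n1) labelings.
wmw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(length(pooled), n1)
  u_all <- apply(labelings, 2, function(idx) {
    sum(ranks[idx]) - n1 * (n1 + 1) / 2
  })
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Benjamini-Hochberg by the textbook step-up with explicit cumulative min.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Sweep-line partition of 1-based closed intervals on one chromosome:
# returns atoms as a data frame with a membership string per atom.
partition_sweep_oracle <- function(sets) {
  # sets: named list of data.frames with start / end
  events <- sort(unique(unlist(lapply(sets, function(d) c(d$start, d$end + 1)))))
  atoms <- NULL
  for (i in seq_len(length(events) - 1)) {
    s <- events[i]
    e <- events[i + 1] - 1
    cover <- names(sets)[vapply(sets, function(d) {
      any(d$start <= s & d$end >= e)
    }, logical(1))]
    if (length(cover) > 0) {
      atoms <- rbind(atoms, data.frame(
        start = s, end = e, members = paste(sort(cover), collapse = ",")
      ))
    }
  }
  # merge adjacent atoms with identical membership (matches disjoin output)
  if (!is.null(atoms) && nrow(atoms) > 1) {
    keep <- c(TRUE, !(atoms$start[-1] == atoms$end[-nrow(atoms)] + 1 &
      atoms$members[-1] == atoms$members[-nrow(atoms)]))
    grp <- cumsum(keep)
    atoms <- do.call(rbind, lapply(split(atoms, grp), function(d) {
      data.frame(start = min(d$start), end = max(d$end), members = d$members[1])
    }))
    rownames(atoms) <- NULL
  }
  atoms
}
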