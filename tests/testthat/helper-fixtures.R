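# Small in-code fixtures shared by several test files.

# Beta table constructor: positions + one numeric vector per sample.
make_beta <- function(chrom, pos, ..., site_id = NULL) {
  x <- tibble::tibble(chrom = chrom, pos = as.integer(pos))
  if (!is.null(site_id)) x$site_id <- site_id
  smp <- list(...)
  for (nm in names(smp)) x[[nm]] <- smp[[nm]]
  x
}

# Matched tumor/normal pair with a clean hyper block in the middle:
# 30 sites on chr1, sites 11-20 shifted +40 points in the tumor group.
toy_pair <- function(n_tumor = 8, n_normal = 8, seed = 42) {
  withr::with_seed(seed, {
    pos <- cumsum(sample(50:150, 30, replace = TRUE))
    base <- runif(30, 20, 40)
    shift <- c(rep(0, 10), rep(40, 10), rep(0, 10))
    mk <- function(k, prefix, shifted) {
      vals <- sapply(seq_len(k), function(i) {
        pmin(pmax(base + if (shifted) shift else 0 + 0, 0), 100) +
          rnorm(30, 0, 2)
      })
      vals <- pmin(pmax(vals, 0), 100)
      colnames(vals) <- paste0(prefix, seq_len(k))
      dplyr::bind_cols(tibble::tibble(chrom = "chr1", pos = as.integer(pos)), tibble::as_tibble(vals))
    }
    list(tumor = mk(n_tumor, "T", TRUE), normal = mk(n_normal, "N", FALSE))
  })
}

quiet_detect <- function(tumor, normal, config = rockermeth::rocker_config()) {
  suppressMessages(suppressWarnings(
    rockermeth::detect_dmrs(tumor, normal, config)
  ))
}
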