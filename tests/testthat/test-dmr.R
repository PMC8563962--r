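test_that("segment rank-sum p-values match hand-worked and enumerated values", {
  # identical vectors: no separation
  seg <- tibble::tibble(chrom = "chr1", start = 100L, end = 300L)
  t <- make_beta("chr1", c(100, 200, 300), T1 = c(10, 20, 30), T2 = c(10, 20, 30))
  n <- make_beta("chr1", c(100, 200, 300), N1 = c(10, 20, 30), N2 = c(10, 20, 30))
  expect_gte(segment_wmw_test(seg, t, n), 0.99)

  # complete separation at n = 3 vs 3: exact two-sided p = 2 / C(6,3) = 0.1
  t2 <- make_beta("chr1", c(100, 200, 300), T1 = c(10, 20, 30))
  n2 <- make_beta("chr1", c(100, 200, 300), N1 = c(40, 50, 60))
  p <- segment_wmw_test(seg, t2, n2)
  expect_equal(p, wmw_enum_oracle(c(10, 20, 30), c(40, 50, 60)))
  expect_equal(p, 0.1)
})

test_that("the exact rank-sum p equals labeling enumeration for small segments", {
  withr::with_seed(9, {
    for (trial in 1:60) {
      m <- sample(3:8, 1)
      a <- runif(m, 0, 100) # continuous: ties almost surely absent
      b <- runif(m, 0, 100) + runif(1, -30, 30)
      expect_equal(
        suppressWarnings(stats::wilcox.test(a, b, exact = TRUE)$p.value),
        wmw_enum_oracle(a, b)
      )
      # and the package path agrees on the same data
      pos <- seq_len(m) * 100L
      seg <- tibble::tibble(chrom = "chr1", start = 100L, end = m * 100L)
      tt <- make_beta("chr1", pos, T1 = a)
      nn <- make_beta("chr1", pos, N1 = b)
      expect_equal(segment_wmw_test(seg, tt, nn), wmw_enum_oracle(a, b))
    }
  })
})

test_that("a large shift across many sites yields an overwhelming p-value", {
  withr::with_seed(10, {
    m <- 200
    pos <- seq_len(m) * 100L
    base <- runif(m, 20, 60)
    tt <- make_beta("chr1", pos, T1 = base + 20 + rnorm(m), T2 = base + 20 + rnorm(m))
    nn <- make_beta("chr1", pos, N1 = base + rnorm(m), N2 = base + rnorm(m))
    seg <- tibble::tibble(chrom = "chr1", start = 100L, end = m * 100L)
    expect_lt(segment_wmw_test(seg, tt, nn), 1e-10)
  })
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  withr::with_seed(11, {
    p <- runif(50)^2
    expect_equal(adjust_fdr(p), bh_oracle(p))
  })
  # missing p-values are excluded from the family and stay missing
  expect_equal(adjust_fdr(c(0.02, NA, 0.04)), c(0.04, NA, 0.04))
})

test_that("segment filtering applies the quoted boundary semantics", {
  seg <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 2000L, 4000L, 6000L, 8000L),
    end = c(1000L, 3000L, 5000L, 7000L, 9000L),
    state = c("hyper", "hyper", "hyper", "neutral", "hypo"),
    n_sites = c(5L, 6L, 6L, 50L, 6L),
    start_index = 1L, end_index = 1L, mean_auc = 0.9,
    p_value = 1e-4, mean_beta_diff = 10,
    fdr = c(1e-9, 0.049, 0.05, 1e-9, 0.01)
  )
  dmrs <- filter_segments(seg, rocker_config())
  # 5 sites discarded; fdr = 0.049 kept; fdr = 0.05 discarded; neutral never kept
  expect_equal(dmrs$start, c(2000L, 8000L))
  expect_equal(dmrs$state, c("hyper", "hypo"))
})

test_that("filtering is monotone in min_sites and fdr_alpha", {
  withr::with_seed(12, {
    seg <- tibble::tibble(
      chrom = "chr1",
      start = seq(1L, by = 1000L, length.out = 40),
      end = seq(900L, by = 1000L, length.out = 40),
      state = sample(c("hyper", "hypo", "neutral"), 40, replace = TRUE),
      n_sites = sample(1:15, 40, replace = TRUE),
      start_index = 1L, end_index = 1L, mean_auc = 0.5,
      p_value = runif(40), mean_beta_diff = 0
    )
    seg$fdr <- adjust_fdr(ifelse(seg$state == "neutral", NA, seg$p_value))
    base_ids <- filter_segments(seg, rocker_config(fdr_alpha = 0.5))$start
    stricter_sites <- filter_segments(
      seg, rocker_config(fdr_alpha = 0.5, min_sites = 9)
    )$start
    stricter_fdr <- filter_segments(
      seg, rocker_config(fdr_alpha = 0.1)
    )$start
    expect_true(all(stricter_sites %in% base_ids))
    expect_true(all(stricter_fdr %in% base_ids))
  })
})

test_that("segments split at gaps above max_distance and only there", {
  track <- tibble::tibble(
    chrom = "chr1",
    pos = c(1L, 100L, 200000L, 200100L),
    auc = c(0.9, 0.9, 0.95, 0.9)
  )
  seg <- states_to_segments(rep(3L, 4), track)
  out <- split_by_max_distance(seg, track, 1e5)
  expect_equal(nrow(out), 2)
  expect_equal(out$start, c(1L, 200000L))
  expect_equal(out$end, c(100L, 200100L))
  expect_equal(sum(out$n_sites), 4)
  # all gaps small: unchanged; single site: unchanged; NULL: no-op
  expect_equal(split_by_max_distance(seg, track, 1e6), seg)
  one <- states_to_segments(3L, track[1, ])
  expect_equal(nrow(split_by_max_distance(one, track[1, ], 10)), 1)
  expect_identical(split_by_max_distance(seg, track, NULL), seg)
  # no retained sub-segment keeps an internal gap above the threshold
  expect_true(all(vapply(seq_len(nrow(out)), function(i) {
    p <- track$pos[out$start_index[i]:out$end_index[i]]
    length(p) == 1 || max(diff(p)) <= 1e5
  }, logical(1))))
})

test_that("DMR class labels follow direction and the 10 kb length rule", {
  expect_equal(classify_dmr("hypo", 12000), "hypo_block")
  expect_equal(classify_dmr("hypo", 10000), "hypo")
  expect_equal(classify_dmr("hyper", 2e6), "hyper")
  expect_equal(
    classify_dmr(c("hypo", "hyper"), c(10001, 10001)),
    c("hypo_block", "hyper")
  )
})

test_that("DMR burden is the covered fraction of the segmented span", {
  segments <- tibble::tibble(
    chrom = "chr1", start = c(1L, 1001L, 3001L), end = c(1000L, 3000L, 4000L),
    state = c("hypo", "neutral", "hyper")
  )
  dmrs <- tibble::tibble(
    chrom = "chr1", start = c(1L, 3001L), end = c(1000L, 4000L),
    state = c("hypo_block", "hyper")
  )
  b <- dmr_burden(dmrs, segments)
  expect_equal(b$burden[b$direction == "loss"], 1000 / 4000)
  expect_equal(b$burden[b$direction == "gain"], 1000 / 4000)
  # a loss DMR covering half the span
  half <- dmr_burden(
    tibble::tibble(chrom = "chr1", start = 1L, end = 2000L, state = "hypo"),
    segments
  )
  expect_equal(half$burden[half$direction == "loss"], 0.5)
  expect_equal(half$burden[half$direction == "gain"], 0)
  expect_equal(dmr_burden(dmrs[0, ], segments)$burden, c(0, 0))
  expect_error(dmr_burden(dmrs, segments[0, ]), "empty")
})

test_that("DMRs from one run never overlap and carry consistent labels", {
  pair <- toy_pair(n_tumor = 10, n_normal = 10)
  fit <- quiet_detect(pair$tumor, pair$normal)
  d <- fit$dmrs
  if (nrow(d) > 1) {
    d <- dplyr::arrange(d, chrom, start)
    same_chr <- d$chrom[-1] == d$chrom[-nrow(d)]
    expect_true(all(!same_chr | d$start[-1] > d$end[-nrow(d)]))
  }
  expect_true(all(d$fdr < 0.05))
  expect_true(all(d$n_sites >= 6))
  expect_true(all(d$state %in% c("hyper", "hypo", "hypo_block")))
  # the toy pair has one implanted gain block
  expect_true(any(d$state == "hyper" & d$mean_beta_diff > 20))
})
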