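test_that("the multi-set partition cuts at all boundaries with correct membership", {
  sets <- list(
    A = tibble::tibble(chrom = "chr1", start = 100L, end = 300L, state = "hyper"),
    B = tibble::tibble(chrom = "chr1", start = 200L, end = 400L, state = "hyper")
  )
  atoms <- partition_multi(sets)
  expect_equal(atoms$start, c(100L, 200L, 301L))
  expect_equal(atoms$end, c(199L, 300L, 400L))
  expect_equal(atoms$A, c("hyper", "hyper", NA))
  expect_equal(atoms$B, c(NA, "hyper", "hyper"))
  expect_equal(atoms$n_datasets, c(1, 2, 1))

  # one dataset: atoms are its DMRs
  one <- partition_multi(sets["A"])
  expect_equal(one[, c("start", "end")], sets$A[, c("start", "end")])

  # disjoint inputs: union with singleton membership
  disj <- partition_multi(list(
    A = tibble::tibble(chrom = "chr1", start = 1L, end = 10L, state = "hypo"),
    B = tibble::tibble(chrom = "chr2", start = 5L, end = 20L, state = "hyper")
  ))
  expect_equal(nrow(disj), 2)
  expect_equal(disj$n_datasets, c(1, 1))

  # overlapping intervals inside one input set are rejected
  bad <- list(A = tibble::tibble(
    chrom = "chr1", start = c(1L, 5L), end = c(10L, 20L), state = "hyper"
  ))
  expect_error(partition_multi(bad), "overlapping DMRs within input set 'A'")
})

test_that("the partition agrees with a brute-force sweep line on random sets", {
  withr::with_seed(16, {
    for (trial in 1:25) {
      sets <- lapply(1:3, function(i) {
        k <- sample(1:5, 1)
        start <- sort(sample(seq(1, 500, by = 1), k)) * 10L
        width <- sample(10:80, k) * 1L
        # enforce internal non-overlap
        d <- tibble::tibble(start = start, end = start + width)
        keep <- rep(TRUE, k)
        if (k > 1) {
          for (j in 2:k) keep[j] <- d$start[j] > max(d$end[seq_len(j - 1)][keep[seq_len(j - 1)]])
        }
        d <- d[keep, ]
        tibble::tibble(
          chrom = "chr1", start = d$start, end = d$end,
          state = sample(c("hyper", "hypo"), nrow(d), replace = TRUE)
        )
      })
      names(sets) <- c("A", "B", "C")
      atoms <- partition_multi(sets)
      oracle <- partition_sweep_oracle(lapply(sets, as.data.frame))
      members <- apply(!is.na(as.matrix(atoms[, c("A", "B", "C")])), 1, function(z) {
        paste(c("A", "B", "C")[z], collapse = ",")
      })
      expect_equal(atoms$start, oracle$start)
      expect_equal(atoms$end, oracle$end)
      expect_equal(members, oracle$members)
      # atoms are disjoint and sorted
      if (nrow(atoms) > 1) {
        expect_true(all(atoms$start[-1] > atoms$end[-nrow(atoms)]))
      }
    }
  })
})

# A two-dataset fixture with controllable signal per atom region.
catalog_fixture <- function() {
  withr::with_seed(17, {
    pos <- seq(100L, by = 100L, length.out = 60)
    region <- function(lo, hi) pos >= lo & pos <= hi
    mk_ds <- function(shift_mask, shift, n_probe_mask = NULL) {
      base <- runif(60, 30, 40)
      tum <- sapply(1:8, function(i) base + ifelse(shift_mask, shift, 0) + rnorm(60, 0, 1.5))
      nor <- sapply(1:8, function(i) base + rnorm(60, 0, 1.5))
      tum <- pmin(pmax(tum, 0), 100)
      nor <- pmin(pmax(nor, 0), 100)
      colnames(tum) <- paste0("T", 1:8)
      colnames(nor) <- paste0("N", 1:8)
      tumor <- dplyr::bind_cols(tibble::tibble(chrom = "chr1", pos = pos), tibble::as_tibble(tum))
      normal <- dplyr::bind_cols(tibble::tibble(chrom = "chr1", pos = pos), tibble::as_tibble(nor))
      if (!is.null(n_probe_mask)) {
        tumor <- tumor[n_probe_mask, ]
        normal <- normal[n_probe_mask, ]
      }
      auc <- suppressMessages(suppressWarnings(compute_auc_track(tumor, normal)))
      list(tumor = tumor, normal = normal, auc = auc)
    }
    # strong gain at 100-2000 in both datasets; weak gain at 3000-4000 in A
    strong <- region(100, 2000)
    weak <- region(3000, 4000)
    list(
      A = mk_ds(strong | weak, 30) |>
        (\(d) {
          # overwrite the weak region with a sub-threshold 4-point shift
          idx <- which(weak)
          for (cn in paste0("T", 1:8)) {
            d$tumor[[cn]][idx] <- d$tumor[[cn]][idx] - 30 + 4
          }
          d$auc <- suppressMessages(suppressWarnings(compute_auc_track(d$tumor, d$normal)))
          d
        })(),
      B = mk_ds(strong, 30)
    )
  })
}

test_that("catalog refinement enforces probes, FDR, effect size and concordance", {
  ds <- catalog_fixture()
  sets <- list(
    A = tibble::tibble(
      chrom = "chr1", start = c(100L, 3000L), end = c(2000L, 4000L),
      state = "hyper"
    ),
    B = tibble::tibble(chrom = "chr1", start = 100L, end = 2000L, state = "hyper")
  )
  atoms <- partition_multi(sets)
  cat_out <- refine_catalog(atoms, ds, rocker_config())
  # the strong shared region survives with 2 supporting datasets
  expect_true(any(cat_out$start == 100 & cat_out$n_supporting == 2))
  # the weak region (4-point shift <= 5) is gone
  expect_false(any(cat_out$start == 3000))
  expect_true(all(cat_out$consensus_state %in% c("hyper", "hypo", "hypo_block")))

  # an atom with fewer than 6 probes is dropped even with perfect signal
  sets_small <- list(
    A = tibble::tibble(chrom = "chr1", start = 100L, end = 450L, state = "hyper")
  )
  atoms_small <- partition_multi(sets_small) # spans probes at 100..400 only
  expect_equal(nrow(refine_catalog(atoms_small, ds["A"], rocker_config())), 0)

  # a dataset named in the atoms but absent from the data is an error
  expect_error(refine_catalog(atoms, ds["A"], rocker_config()), "no beta data")
})

test_that("atoms with no dominant direction across datasets are discarded", {
  ds <- catalog_fixture()
  # fabricate opposite claimed states for the same strong region: the beta
  # signal supports gain in both datasets, so the loss claim fails its
  # concordance check and the region keeps a gain majority
  sets <- list(
    A = tibble::tibble(chrom = "chr1", start = 100L, end = 2000L, state = "hyper"),
    B = tibble::tibble(chrom = "chr1", start = 100L, end = 2000L, state = "hypo")
  )
  atoms <- partition_multi(sets)
  out <- refine_catalog(atoms, ds, rocker_config())
  expect_true(nrow(out) == 0 || all(out$consensus_state == "hyper"))
})

test_that("retained catalog entries satisfy every refinement predicate", {
  ds <- catalog_fixture()
  sets <- list(
    A = tibble::tibble(
      chrom = "chr1", start = c(100L, 3000L), end = c(2000L, 4000L),
      state = "hyper"
    ),
    B = tibble::tibble(chrom = "chr1", start = 100L, end = 2000L, state = "hyper")
  )
  atoms <- partition_multi(sets)
  cat_out <- refine_catalog(atoms, ds, rocker_config())
  for (i in seq_len(nrow(cat_out))) {
    for (nm in c("A", "B")) {
      if (is.na(cat_out[[nm]][i])) next
      d <- ds[[nm]]
      in_atom <- d$tumor$pos >= cat_out$start[i] & d$tumor$pos <= cat_out$end[i]
      expect_gte(sum(in_atom), 6)
      t_med <- apply(beta_values(d$tumor)[in_atom, ], 2, median)
      n_med <- apply(beta_values(d$normal)[in_atom, ], 2, median)
      expect_gt(abs(mean(t_med) - mean(n_med)), 5)
      in_auc <- d$auc$pos >= cat_out$start[i] & d$auc$pos <= cat_out$end[i]
      expect_gte(sum(d$auc$auc[in_auc] > 0.75), 3)
    }
  }
  # refinement never invents coordinates outside the partition
  expect_true(all(cat_out$start %in% atoms$start | cat_out$start %in% (atoms$end + 1L) |
    cat_out$start %in% atoms$start))
  expect_true(all(cat_out$end <= max(atoms$end)))
})

test_that("sharing curves count multi-dataset support cumulatively", {
  cat_tbl <- tibble::tibble(
    consensus_state = c(rep("hyper", 6), rep("hypo", 4)),
    n_supporting = c(3, 3, 3, 1, 1, 1, 1, 1, 1, 1)
  )
  prof <- sharedness_profile(cat_tbl, n_datasets = 6)
  get <- function(st, k) prof$fraction[prof$state == st & prof$k == k]
  expect_equal(get("hyper", 1), 1)
  expect_equal(get("hyper", 3), 0.5)
  expect_equal(get("hyper", 4), 0)
  expect_equal(get("hypo", 2), 0) # all private
  # monotone nonincreasing in k for every class
  for (st in unique(prof$state)) {
    expect_true(all(diff(prof$fraction[prof$state == st]) <= 0))
  }
})
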