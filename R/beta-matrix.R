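#' Beta-value tables
#'
#' Throughout the package a methylation dataset is an ordinary data frame
#' ("beta table") with the site coordinate columns `chrom` and `pos`
#' (1-based), an optional `site_id`, and one numeric column per sample
#' holding beta values in percentage units (0 = unmethylated, 100 = fully
#' methylated). Missing values are allowed. Rows are sorted by
#' `(chrom, pos)` and positions are unique within a chromosome.
#'
#' @name beta-table
#' @keywords internal
NULL

.coord_cols <- c("chrom", "pos", "site_id")

#' Sample columns of a beta table
#'
#' @param x A beta table (see [read_beta_matrix()]).
#' @return Character vector of sample column names.
#' @export
beta_samples <- function(x) {
  setdiff(names(x), .coord_cols)
}

#' Extract the numeric beta matrix (sites x samples) from a beta table
#'
#' @param x A beta table.
#' @return A numeric matrix with one row per site and one column per sample.
#' @export
beta_values <- function(x) {
  as.matrix(x[, beta_samples(x), drop = FALSE])
}

# Validate and normalize a beta table: sort, check invariants.
# `convert` rescales fraction-unit input ([0,1]) to percentages.
validate_beta_table <- function(x, units_hint = NULL, convert = TRUE,
                                what = "beta table") {
  x <- as_tibble(x)
  if (!all(c("chrom", "pos") %in% names(x))) {
    abort(sprintf("%s must have 'chrom' and 'pos' columns", what))
  }
  smp <- beta_samples(x)
  if (length(smp) == 0) abort(sprintf("%s has no sample columns", what))
  if (any(x$pos < 1)) abort("positions must be >= 1")
  x <- arrange(x, .data$chrom, .data$pos)
  dup <- duplicated(x[, c("chrom", "pos")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("duplicate site at %s:%d", x$chrom[i], x$pos[i]))
  }
  if ("site_id" %in% names(x)) {
    ids <- x$site_id[!is.na(x$site_id)]
    if (anyDuplicated(ids)) abort("site_id values must be unique")
  }
  vals <- beta_values(x)
  if (!is.numeric(vals)) abort(sprintf("sample columns of %s must be numeric", what))
  if (convert) {
    mx <- suppressWarnings(max(vals, na.rm = TRUE))
    units <- units_hint %||% if (is.finite(mx) && mx <= 1) "fraction" else "percent"
    if (identical(units, "fraction")) {
      vals <- vals * 100
      x[, smp] <- as.data.frame(vals)
    }
  }
  bad <- which(!is.na(vals) & (vals < 0 | vals > 100))
  if (length(bad)) {
    abort(sprintf("%d beta value(s) outside [0, 100] after unit conversion", length(bad)))
  }
  x
}

#' Read a beta-value table from delimited text
#'
#' Reads a TSV file with columns `chrom`, `pos`, optional `site_id`, and one
#' column per sample. Values may be stored as fractions in \[0, 1\] or as
#' percentages in \[0, 100\]; fraction input is rescaled to percentages
#' (auto-detected when `units_hint` is absent: a maximum value of at most 1
#' is taken to mean fractions). Non-numeric cells are treated as missing
#' (a count is reported); duplicated `(chrom, pos)` rows and values outside
#' the valid range are errors.
#'
#' @param path Path to a tab-delimited text file.
#' @param units_hint Optional `"fraction"` or `"percent"` to override unit
#'   auto-detection.
#' @return A beta table: a tibble sorted by `(chrom, pos)` with beta values
#'   in percentage units.
#' @export
read_beta_matrix <- function(path, units_hint = NULL) {
  if (!is.null(units_hint)) {
    units_hint <- match.arg(units_hint, c("fraction", "percent"))
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  smp <- beta_samples(x)
  n_bad <- 0L
  for (s in smp) {
    if (!is.numeric(x[[s]])) {
      v <- suppressWarnings(as.numeric(x[[s]]))
      n_bad <- n_bad + sum(is.na(v) & !is.na(x[[s]]) & x[[s]] != "NA")
      x[[s]] <- v
    }
  }
  if (n_bad > 0) {
    inform(sprintf("read_beta_matrix: %d non-numeric cell(s) treated as missing", n_bad))
  }
  validate_beta_table(x, units_hint = units_hint, what = basename(path))
}

#' Write a beta-value table to delimited text
#'
#' @param x A beta table (percent units).
#' @param path Output file path.
#' @param units `"percent"` (as stored) or `"fraction"` (divided by 100).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, units = c("percent", "fraction")) {
  units <- match.arg(units)
  x <- validate_beta_table(x, convert = FALSE)
  if (units == "fraction") {
    smp <- beta_samples(x)
    x[, smp] <- as.data.frame(beta_values(x) / 100)
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

# Check that two beta tables share an identical site list.
check_matched_sites <- function(tumor, normal) {
  if (nrow(tumor) != nrow(normal)) {
    abort(sprintf(
      "site lists differ: %d sites in test group, %d in control group",
      nrow(tumor), nrow(normal)
    ))
  }
  same <- tumor$chrom == normal$chrom & tumor$pos == normal$pos
  if (!all(same)) {
    i <- which(!same)[1]
    abort(sprintf(
      "site lists differ at row %d: %s:%d vs %s:%d",
      i, tumor$chrom[i], tumor$pos[i], normal$chrom[i], normal$pos[i]
    ))
  }
  invisible(TRUE)
}
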