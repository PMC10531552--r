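# Size standardization and pooled z-normalization.
#
# Tumors differ in volume by orders of magnitude between patients and across
# a therapy course; every dataset is therefore brought to the same 1000-voxel
# size before mixture fitting, so each tumor/timepoint contributes equal
# weight. "Extrapolation" of small tumors is bootstrap resampling with
# replacement: it preserves the empirical (ADC, SUV) distribution without
# inventing values.

#' Standardize a voxel table to a fixed size
#'
#' Larger tables are uniformly subsampled without replacement; smaller ones
#' are bootstrap-resampled with replacement; a table already at the target is
#' returned unchanged. Metadata columns travel with the rows.
#'
#' @param table A non-empty [voxel_table].
#' @param n_target target record count (default 1000).
#' @param seed RNG seed for reproducibility; the caller's RNG state is left
#'   untouched.
#' @return A [voxel_table] with exactly `n_target` rows.
#' @export
standardize_size <- function(table, n_target = 1000, seed = NULL) {
  stopifnot(inherits(table, "voxel_table"))
  n <- nrow(table)
  if (n == 0L) stop("cannot standardize an empty voxel table")
  if (n_target < 1L) stop("`n_target` must be at least 1")
  if (n == n_target) return(table)
  rows <- with_seed(seed, {
    if (n > n_target) sample.int(n, n_target, replace = FALSE)
    else sample.int(n, n_target, replace = TRUE)
  })
  vt_keep(table, rows)
}

#' Pooled z-normalization
#'
#' Centers and scales one pooled value vector to mean 0 and standard
#' deviation 1 exactly, using the population (divide-by-n) standard
#' deviation. ADC and SUV are normalized separately but each pooled across
#' all patients and timepoints in one cohort pass, so inter-patient offsets
#' remain comparable in normalized units.
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return List with `values` (normalized vector), `mean` and `sd` (the
#'   constants used, for exact inversion).
#' @export
znormalize <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to normalize")
  if (any(!is.finite(values))) stop("values must be finite")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) stop("zero variance: cannot z-normalize a constant input")
  list(values = (values - m) / s, mean = m, sd = s)
}
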