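# The flat per-voxel record set every downstream stage consumes.

#' Construct a voxel table
#'
#' A data frame of per-voxel records with at least `adc` (1e-6 mm^2/s) and
#' `suv` (unitless) columns, optionally `patient_id`, `timepoint`
#' (`"baseline"` or `"post"`), `tissue_group` and `cluster` labels, and
#' 0-based voxel indices. The MR grid spacing rides along as an attribute so
#' volumes can be computed from record counts.
#'
#' @param df data frame with numeric `adc` and `suv` columns.
#' @param spacing mm per axis of the grid the records came from, or `NULL`.
#' @return An object of class `voxel_table` (a data frame).
#' @export
voxel_table <- function(df, spacing = NULL) {
  if (!is.data.frame(df)) stop("`df` must be a data frame")
  if (!all(c("adc", "suv") %in% names(df)))
    stop("voxel table needs `adc` and `suv` columns")
  if (any(df$suv < 0, na.rm = TRUE)) stop("SUV must be non-negative")
  if ("timepoint" %in% names(df) &&
      !all(df$timepoint %in% c("baseline", "post")))
    stop("`timepoint` must be 'baseline' or 'post'")
  out <- as.data.frame(df)
  class(out) <- c("voxel_table", "data.frame")
  if (!is.null(spacing)) {
    spacing <- as.double(spacing)
    if (length(spacing) != 3L || any(spacing <= 0))
      stop("`spacing` must be 3 strictly positive numbers")
    attr(out, "spacing") <- spacing
  }
  out
}

vt_spacing <- function(table) attr(table, "spacing")

# rebuild a voxel_table after row subsetting, keeping metadata
vt_keep <- function(table, rows) {
  out <- as.data.frame(table)[rows, , drop = FALSE]
  rownames(out) <- NULL
  voxel_table(out, spacing = vt_spacing(table))
}

#' Volume of a single voxel
#'
#' @param spacing mm per axis (length 3, strictly positive).
#' @return List with `mm3` and `ml`; the MR analysis grid of
#'   0.7 x 0.7 x 5 mm gives 2.45 mm^3 = 0.00245 mL.
#' @export
voxel_volume <- function(spacing) {
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  mm3 <- prod(spacing)
  list(mm3 = mm3, ml = mm3 * 1e-3)
}

#' Remove ADC outlier voxels
#'
#' Voxels with ADC at or below the outlier cut (default 50 x 1e-6 mm^2/s,
#' i.e. essentially no measurable diffusion — air, artifact or fit failure)
#' are excluded before any classification. Survivor order is preserved.
#'
#' @param table A [voxel_table].
#' @param adc_outlier Exclusive lower bound on retained ADC values; records
#'   with `adc <= adc_outlier` are dropped.
#' @return The filtered [voxel_table]; the number of removed records is in
#'   `attr(x, "n_removed")`.
#' @export
filter_outliers <- function(table, adc_outlier = 50) {
  stopifnot(inherits(table, "voxel_table"))
  keep <- table$adc > adc_outlier
  n_removed <- sum(!keep)
  out <- vt_keep(table, keep)
  if (nrow(out) == 0L) warning("all voxels removed by the ADC outlier filter")
  if (n_removed > 0)
    message(n_removed, " outlier voxel(s) removed (ADC <= ", adc_outlier, ")")
  attr(out, "n_removed") <- n_removed
  out
}

#' Total volume of a voxel table
#'
#' Record count times single-voxel volume; reporting code rounds to the
#' nearest mL, this function never does.
#'
#' @param table A [voxel_table] carrying grid spacing metadata.
#' @return Volume in mL.
#' @export
total_volume <- function(table) {
  stopifnot(inherits(table, "voxel_table"))
  sp <- vt_spacing(table)
  if (is.null(sp)) stop("voxel table has no grid spacing metadata")
  nrow(table) * voxel_volume(sp)$ml
}

#' Summary statistics of a voxel table
#'
#' Mean, median and 5th/95th percentiles of ADC and SUV over retained
#' records, plus count and volume. Percentiles use linear interpolation
#' between order statistics (`stats::quantile` type 7).
#'
#' @param table A non-empty [voxel_table].
#' @return An object of class `voxel_summary`: `n_voxels`, `volume_ml`
#'   (`NA` without spacing metadata), and per-quantity `mean`, `median`,
#'   `p5`, `p95`.
#' @export
voxel_summary <- function(table) {
  stopifnot(inherits(table, "voxel_table"))
  if (nrow(table) == 0L) stop("cannot summarize an empty voxel table")
  one <- function(x) {
    q <- stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
    list(mean = mean(x), median = q[2], p5 = q[1], p95 = q[3])
  }
  sp <- vt_spacing(table)
  structure(list(
    n_voxels = nrow(table),
    volume_ml = if (is.null(sp)) NA_real_ else total_volume(table),
    adc = one(table$adc),
    suv = one(table$suv)), class = "voxel_summary")
}

#' @export
print.voxel_summary <- function(x, ...) {
  cat(sprintf("voxels: %d  volume: %s mL\n", x$n_voxels,
              ifelse(is.na(x$volume_ml), "?", format(round(x$volume_ml)))))
  for (q in c("adc", "suv"))
    cat(sprintf("  %s: mean %.3g  median %.3g  p5 %.3g  p95 %.3g\n",
                toupper(q), x[[q]]$mean, x[[q]]$median, x[[q]]$p5, x[[q]]$p95))
  invisible(x)
}
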