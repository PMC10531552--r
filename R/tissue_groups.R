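# Virtual tissue groups by fixed SUV/ADC thresholds.
#
# The quadrant rule: high tracer uptake with restricted diffusion marks
# highly vital (cellular, metabolically active) tissue; low uptake with free
# diffusion marks low-vital (necrotic/matured) tissue; the two discordant
# quadrants are equivocal. Exact threshold equality maps to equivocal.

TISSUE_LEVELS <- c("vital", "equivocal", "low_vital")

#' Fixed tissue-classification thresholds
#'
#' @param suv_cut SUV cutoff between high and low uptake (default 2.5).
#' @param adc_cut ADC cutoff between restricted and free diffusion, in
#'   1e-6 mm^2/s (default 1250).
#' @param adc_outlier ADC outlier bound (default 50); must be below
#'   `adc_cut`.
#' @return An object of class `tissue_thresholds`.
#' @export
tissue_thresholds <- function(suv_cut = 2.5, adc_cut = 1250,
                              adc_outlier = 50) {
  if (any(c(suv_cut, adc_cut, adc_outlier) <= 0))
    stop("all thresholds must be positive")
  if (adc_outlier >= adc_cut) stop("`adc_outlier` must be below `adc_cut`")
  structure(list(suv_cut = suv_cut, adc_cut = adc_cut,
                 adc_outlier = adc_outlier), class = "tissue_thresholds")
}

#' Classify voxels into virtual tissue groups
#'
#' Vectorized quadrant rule: `vital` iff SUV > suv_cut and ADC < adc_cut;
#' `low_vital` iff SUV < suv_cut and ADC > adc_cut; `equivocal` otherwise,
#' including exact equality with either threshold. Input must already be
#' outlier-filtered.
#'
#' @param adc,suv numeric vectors (recycled against each other must match).
#' @param thresholds A [tissue_thresholds].
#' @return factor with levels `vital`, `equivocal`, `low_vital`.
#' @export
classify_voxel <- function(adc, suv, thresholds = tissue_thresholds()) {
  stopifnot(inherits(thresholds, "tissue_thresholds"),
            length(adc) == length(suv))
  if (any(adc <= thresholds$adc_outlier))
    stop("ADC values at or below the outlier cut must be filtered upstream")
  lab <- ifelse(suv > thresholds$suv_cut & adc < thresholds$adc_cut, "vital",
         ifelse(suv < thresholds$suv_cut & adc > thresholds$adc_cut,
                "low_vital", "equivocal"))
  factor(lab, levels = TISSUE_LEVELS)
}

#' Add tissue-group labels to a voxel table
#'
#' @param table A filtered [voxel_table].
#' @param thresholds A [tissue_thresholds].
#' @return The table with a `tissue_group` factor column; the thresholds are
#'   attached as `attr(x, "thresholds")`.
#' @export
classify_voxels <- function(table, thresholds = tissue_thresholds()) {
  stopifnot(inherits(table, "voxel_table"))
  table$tissue_group <- classify_voxel(table$adc, table$suv, thresholds)
  attr(table, "thresholds") <- thresholds
  table
}

#' Subvolume proportions per group
#'
#' Counts, volume (count x voxel volume) and fractions of total for each of
#' the three labels of `column`.
#'
#' @param table A labeled [voxel_table].
#' @param column `"tissue_group"` (default) or `"cluster"`.
#' @return An object of class `group_proportions`: data frame with `group`,
#'   `n`, `fraction`, `volume_ml` rows in the fixed level order.
#' @export
group_proportions <- function(table, column = "tissue_group") {
  stopifnot(inherits(table, "voxel_table"))
  if (nrow(table) == 0L) stop("empty voxel table")
  if (!column %in% names(table))
    stop("no `", column, "` column; classify or cluster first")
  lab <- factor(table[[column]], levels = TISSUE_LEVELS)
  if (any(is.na(lab))) stop("unlabeled records present")
  n <- as.integer(table(lab))
  sp <- vt_spacing(table)
  vml <- if (is.null(sp)) rep(NA_real_, 3) else n * voxel_volume(sp)$ml
  out <- data.frame(group = TISSUE_LEVELS, n = n,
                    fraction = n / sum(n), volume_ml = vml)
  structure(out, class = c("group_proportions", "data.frame"),
            thresholds = attr(table, "thresholds"))
}

#' Compare group proportions across timepoints
#'
#' @param pre,post [group_proportions] computed with identical thresholds.
#' @param dead_band absolute fraction change below which a group is labeled
#'   `unchanged` (default 0).
#' @return data frame with `group`, `pre`, `post`, `delta`, `direction`.
#' @export
compare_timepoints <- function(pre, post, dead_band = 0) {
  stopifnot(inherits(pre, "group_proportions"),
            inherits(post, "group_proportions"))
  th_pre <- attr(pre, "thresholds"); th_post <- attr(post, "thresholds")
  if (!is.null(th_pre) && !is.null(th_post) && !identical(th_pre, th_post))
    stop("pre and post proportions were computed with different thresholds")
  stopifnot(identical(pre$group, post$group))
  delta <- post$fraction - pre$fraction
  direction <- ifelse(abs(delta) <= dead_band, "unchanged",
                      ifelse(delta > 0, "increase", "decrease"))
  data.frame(group = pre$group, pre = pre$fraction, post = post$fraction,
             delta = delta, direction = direction)
}
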