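# Scalar volumes, masks, grids, resampling, masked-pair extraction.
#
# Conventions (fixed once, to prevent silent transposition):
#   * arrays are indexed (x, y, z) in NIfTI header order;
#   * voxel indices are 0-based in all tabular outputs;
#   * world coordinate of voxel (i, j, k) is origin + (i, j, k) * spacing
#     (axis-aligned affine; inputs are assumed co-registered in world space).

#' Construct a scalar volume
#'
#' A 3D grid of one physical quantity with spacing/origin metadata. SUV is
#' unitless; ADC is carried in the canonical unit 1e-6 mm^2/s, so the
#' conventional viability cutoff is the number 1250.
#'
#' @param values 3D numeric array; `NA` marks missing voxels.
#' @param spacing mm per axis (length 3, strictly positive).
#' @param quantity `"suv"` or `"adc"`.
#' @param origin world position of voxel (0,0,0) in mm.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, spacing, quantity = c("suv", "adc"),
                          origin = c(0, 0, 0)) {
  quantity <- match.arg(quantity)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  if (any(is.infinite(values))) stop("`values` must be finite or NA")
  structure(list(values = values, spacing = spacing,
                 origin = as.double(origin), quantity = quantity),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume %s> %s voxels, spacing %s mm, %d missing\n",
              x$quantity, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(is.na(x$values))))
  invisible(x)
}

#' Construct a tumor VOI mask
#'
#' Binary volume-of-interest mask on the MR analysis grid. The mask is the
#' contract boundary for everything upstream of the voxel table: exclusions
#' (vessels, hematomas) are assumed already applied by whoever drew it.
#'
#' @param values 3D logical (or 0/1 numeric) array.
#' @param spacing mm per axis.
#' @param origin world position of voxel (0,0,0) in mm.
#' @param provenance free-text note on where the mask came from.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(values, spacing, origin = c(0, 0, 0),
                     provenance = "unspecified") {
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  vals <- array(as.logical(values), dim = dim(values))
  if (any(is.na(vals))) stop("mask may not contain NA")
  structure(list(values = vals, spacing = as.double(spacing),
                 origin = as.double(origin), provenance = provenance),
            class = "voi_mask")
}

#' Describe a sampling grid
#'
#' @param shape voxel counts per axis.
#' @param spacing mm per axis.
#' @param origin world position of voxel (0,0,0) in mm.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing, origin = c(0, 0, 0)) {
  spacing <- as.double(spacing)
  if (any(spacing <= 0)) stop("`spacing` must be strictly positive")
  structure(list(shape = as.integer(shape), spacing = spacing,
                 origin = as.double(origin)), class = "grid_spec")
}

as_grid_spec <- function(x) {
  if (inherits(x, "grid_spec")) return(x)
  if (inherits(x, c("scalar_volume", "voi_mask")))
    return(grid_spec(dim(x$values), x$spacing, x$origin))
  stop("cannot interpret target as a grid")
}

#' Read a scalar volume from NIfTI
#'
#' ADC maps are converted to the canonical unit 1e-6 mm^2/s on read: files
#' stored in mm^2/s (median of positive voxels < 0.1) are multiplied by 1e6
#' and the conversion is reported via `message()`.
#'
#' @param path NIfTI-1 file.
#' @param quantity `"suv"` or `"adc"`.
#' @return A [scalar_volume].
#' @export
read_volume <- function(path, quantity = c("suv", "adc")) {
  quantity <- match.arg(quantity)
  nii <- read_nifti(path)
  vals <- nii$data
  if (quantity == "adc") {
    pos <- vals[!is.na(vals) & vals > 0]
    if (length(pos) && stats::median(pos) < 0.1) {
      vals <- vals * 1e6
      message("ADC volume detected in mm^2/s; converted to 1e-6 mm^2/s")
    }
  }
  scalar_volume(vals, nii$spacing, quantity, nii$origin)
}

#' Write a scalar volume to NIfTI
#'
#' @param volume A [scalar_volume].
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  vals <- volume$values
  vals[is.na(vals)] <- NaN
  write_nifti(vals, path, volume$spacing, volume$origin, "float64")
}

#' Read a VOI mask from NIfTI
#'
#' Nonzero voxels are foreground.
#'
#' @param path NIfTI-1 file.
#' @param provenance note carried on the mask.
#' @return A [voi_mask].
#' @export
read_mask <- function(path, provenance = NULL) {
  nii <- read_nifti(path)
  voi_mask(nii$data != 0, nii$spacing, nii$origin,
           provenance = provenance %||% path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a volume onto a target grid
#'
#' Samples the source volume at the world coordinates of the target grid's
#' voxel centers. Target voxels falling outside the source extent (beyond the
#' outermost voxel centers) are marked missing, never extrapolated.
#'
#' @param volume A [scalar_volume].
#' @param target A [grid_spec], or a volume/mask whose grid is reused.
#' @param interpolation `"trilinear"` for continuous fields, `"nearest"` for
#'   categorical ones.
#' @return A [scalar_volume] on the target grid.
#' @export
resample_to_grid <- function(volume, target,
                             interpolation = c("trilinear", "nearest")) {
  stopifnot(inherits(volume, "scalar_volume"))
  interpolation <- match.arg(interpolation)
  tg <- as_grid_spec(target)
  src_dim <- dim(volume$values)

  # fractional source indices of target voxel centers, per axis
  ax_idx <- lapply(1:3, function(a) {
    world <- tg$origin[a] + (seq_len(tg$shape[a]) - 1) * tg$spacing[a]
    (world - volume$origin[a]) / volume$spacing[a]
  })
  fx <- rep(ax_idx[[1]], times = tg$shape[2] * tg$shape[3])
  fy <- rep(rep(ax_idx[[2]], each = tg$shape[1]), times = tg$shape[3])
  fz <- rep(ax_idx[[3]], each = tg$shape[1] * tg$shape[2])

  eps <- 1e-9
  inside <- fx >= -eps & fx <= src_dim[1] - 1 + eps &
            fy >= -eps & fy <= src_dim[2] - 1 + eps &
            fz >= -eps & fz <= src_dim[3] - 1 + eps
  if (!any(inside))
    stop("no overlap between source volume and target grid")

  out <- rep(NA_real_, length(fx))
  src <- volume$values
  if (interpolation == "nearest") {
    i <- pmin(pmax(round(fx[inside]), 0), src_dim[1] - 1)
    j <- pmin(pmax(round(fy[inside]), 0), src_dim[2] - 1)
    k <- pmin(pmax(round(fz[inside]), 0), src_dim[3] - 1)
    out[inside] <- src[cbind(i + 1, j + 1, k + 1)]
  } else {
    x <- pmin(pmax(fx[inside], 0), src_dim[1] - 1)
    y <- pmin(pmax(fy[inside], 0), src_dim[2] - 1)
    z <- pmin(pmax(fz[inside], 0), src_dim[3] - 1)
    x0 <- pmin(floor(x), src_dim[1] - 2 + (src_dim[1] == 1))
    y0 <- pmin(floor(y), src_dim[2] - 2 + (src_dim[2] == 1))
    z0 <- pmin(floor(z), src_dim[3] - 2 + (src_dim[3] == 1))
    dx <- x - x0; dy <- y - y0; dz <- z - z0
    g <- function(i, j, k) src[cbind(i + 1, j + 1, k + 1)]
    x1 <- pmin(x0 + 1, src_dim[1] - 1)
    y1 <- pmin(y0 + 1, src_dim[2] - 1)
    z1 <- pmin(z0 + 1, src_dim[3] - 1)
    out[inside] <-
      g(x0, y0, z0) * (1 - dx) * (1 - dy) * (1 - dz) +
      g(x1, y0, z0) * dx       * (1 - dy) * (1 - dz) +
      g(x0, y1, z0) * (1 - dx) * dy       * (1 - dz) +
      g(x1, y1, z0) * dx       * dy       * (1 - dz) +
      g(x0, y0, z1) * (1 - dx) * (1 - dy) * dz +
      g(x1, y0, z1) * dx       * (1 - dy) * dz +
      g(x0, y1, z1) * (1 - dx) * dy       * dz +
      g(x1, y1, z1) * dx       * dy       * dz
  }
  scalar_volume(array(out, dim = tg$shape), tg$spacing, volume$quantity,
                tg$origin)
}

#' Extract per-voxel (ADC, SUV) pairs under a mask
#'
#' All three inputs must share the MR analysis grid. One record is produced
#' per foreground mask voxel whose ADC and SUV are both non-missing; dropped
#' voxels are counted and reported.
#'
#' @param suv_on_mr SUV [scalar_volume] resampled onto the MR grid.
#' @param adc ADC [scalar_volume] on the MR grid.
#' @param mask A [voi_mask] on the MR grid.
#' @return A [voxel_table] with columns `adc`, `suv`, `i`, `j`, `k`
#'   (0-based voxel indices); the number of dropped voxels is available as
#'   `attr(x, "n_dropped")`.
#' @export
extract_masked_pairs <- function(suv_on_mr, adc, mask) {
  stopifnot(inherits(suv_on_mr, "scalar_volume"),
            inherits(adc, "scalar_volume"), inherits(mask, "voi_mask"))
  d <- dim(mask$values)
  if (!identical(dim(suv_on_mr$values), d) || !identical(dim(adc$values), d))
    stop("SUV, ADC and mask must share the same grid shape")
  if (!isTRUE(all.equal(suv_on_mr$spacing, adc$spacing, tolerance = 1e-6)) ||
      !isTRUE(all.equal(adc$spacing, mask$spacing, tolerance = 1e-6)))
    stop("SUV, ADC and mask must share the same grid spacing")
  fg <- which(mask$values)
  if (!length(fg)) stop("mask has no foreground voxels")
  av <- adc$values[fg]
  sv <- suv_on_mr$values[fg]
  keep <- !is.na(av) & !is.na(sv)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " mask voxel(s) dropped (missing ADC or SUV)")
  idx <- arrayInd(fg[keep], d) - 1L
  tab <- voxel_table(
    data.frame(adc = av[keep], suv = sv[keep],
               i = idx[, 1], j = idx[, 2], k = idx[, 3]),
    spacing = mask$spacing)
  attr(tab, "n_dropped") <- n_dropped
  tab
}
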