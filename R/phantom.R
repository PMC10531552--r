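# Synthetic phantom cohorts: paired SUV/ADC volumes with a known latent
# three-compartment structure and therapy-course transforms.
#
# The phantom emulates what the analysis assumes about real tumors: an
# ellipsoidal VOI on the MR grid; spatially contiguous ("blobby") tissue
# compartments rather than i.i.d. voxels, so averaging onto the coarser PET
# grid is meaningful; bivariate Gaussian (ADC, SUV) emission per compartment
# straddling the classification thresholds; inverse ADC-SUV coupling inside
# the vital compartment; additive measurement noise; and physical
# non-negativity enforced by rejection sampling.

.default_compartment_params <- function(vital_coupling) {
  list(
    vital     = list(mean = c(adc = 850,  suv = 4.0),
                     sd = c(adc = 200, suv = 0.7), coupling = vital_coupling),
    equivocal = list(mean = c(adc = 1100, suv = 1.8),
                     sd = c(adc = 200, suv = 0.7), coupling = 0),
    low_vital = list(mean = c(adc = 1700, suv = 1.2),
                     sd = c(adc = 200, suv = 0.7), coupling = 0))
}

#' Phantom generator configuration
#'
#' Defaults encode the analysis grid (MR 0.7 x 0.7 x 5 mm, PET
#' 2.8 x 2.8 x 2 mm), baseline compartment fractions of
#' 26.3/37.9/35.8 percent (vital/equivocal/low-vital), emission
#' distributions straddling the SUV 2.5 / ADC 1250 cutoffs, and a negative
#' ADC-SUV coupling of -0.4 inside the vital compartment.
#'
#' @param grid_shape MR voxel counts per axis.
#' @param mr_spacing MR grid spacing, mm.
#' @param pet_spacing PET grid spacing, mm.
#' @param compartment_fractions named or ordered proportions of
#'   vital/equivocal/low-vital tissue; non-negative, summing to 1.
#' @param compartment_params per-compartment list with `mean` (adc, suv),
#'   `sd` (adc, suv) and optional `coupling`; `NULL` for defaults.
#' @param vital_coupling ADC-SUV correlation inside the vital compartment;
#'   non-positive (0 is allowed for null simulations).
#' @param noise_sd additive measurement-noise SD per channel (adc, suv).
#' @param background background (adc, suv) level outside the tumor.
#' @param blob_voxels target voxels per contiguous compartment blob.
#' @param radius_frac ellipsoid semi-axes as a fraction of the half-extent.
#' @param seed integer seed; identical config implies identical phantom.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48, 48, 16),
                           mr_spacing = c(0.7, 0.7, 5),
                           pet_spacing = c(2.8, 2.8, 2),
                           compartment_fractions =
                             c(vital = 0.263, equivocal = 0.379,
                               low_vital = 0.358),
                           compartment_params = NULL,
                           vital_coupling = -0.4,
                           noise_sd = c(adc = 20, suv = 0.1),
                           background = c(adc = 1400, suv = 0.2),
                           blob_voxels = 250,
                           radius_frac = 0.7,
                           seed = 1L) {
  f <- as.double(compartment_fractions)
  if (length(f) != 3L || any(f < 0) || any(f > 1))
    stop("compartment_fractions must be 3 proportions in [0, 1]")
  if (abs(sum(f) - 1) > 1e-12)
    stop("compartment_fractions must sum to 1 (within 1e-12)")
  if (any(mr_spacing <= 0) || any(pet_spacing <= 0))
    stop("spacings must be strictly positive")
  if (vital_coupling > 0 || vital_coupling <= -1)
    stop("vital_coupling must be in (-1, 0]")
  if (is.null(compartment_params))
    compartment_params <- .default_compartment_params(vital_coupling)
  for (nm in TISSUE_LEVELS) {
    cp <- compartment_params[[nm]]
    if (is.null(cp) || length(cp$mean) != 2L || length(cp$sd) != 2L)
      stop("compartment_params must define mean and sd for ", nm)
    if (any(cp$sd <= 0)) stop("emission SDs must be positive")
  }
  vm <- compartment_params$vital$mean
  lm <- compartment_params$low_vital$mean
  if (!(vm[2] > 2.5 && vm[1] < 1250))
    stop("vital compartment mean must have SUV > 2.5 and ADC < 1250")
  if (!(lm[2] < 2.5 && lm[1] > 1250))
    stop("low-vital compartment mean must have SUV < 2.5 and ADC > 1250")
  structure(list(grid_shape = as.integer(grid_shape),
                 mr_spacing = as.double(mr_spacing),
                 pet_spacing = as.double(pet_spacing),
                 compartment_fractions = stats::setNames(f, TISSUE_LEVELS),
                 compartment_params = compartment_params,
                 vital_coupling = vital_coupling,
                 noise_sd = noise_sd, background = background,
                 blob_voxels = blob_voxels, radius_frac = radius_frac,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# nearest-seed blob id for each mask voxel, chunked to bound memory
.nearest_seed <- function(coords, seeds) {
  n <- nrow(coords)
  out <- integer(n)
  chunk <- max(1L, floor(4e6 / nrow(seeds)))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    d2 <- outer(rowSums(coords[idx, , drop = FALSE]^2),
                rowSums(seeds^2), `+`) -
      2 * coords[idx, , drop = FALSE] %*% t(seeds)
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}

# bivariate Gaussian emission truncated to adc > 0, suv >= 0 by rejection
.draw_emission <- function(n, cp) {
  rho <- cp$coupling %||% 0
  adc <- numeric(n); suv <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    z1 <- stats::rnorm(length(todo))
    z2 <- stats::rnorm(length(todo))
    a <- cp$mean[1] + cp$sd[1] * z1
    s <- cp$mean[2] + cp$sd[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
    adc[todo] <- a; suv[todo] <- s
    todo <- todo[!(a > 0 & s >= 0)]
  }
  cbind(adc = adc, suv = suv)
}

#' Generate a phantom tumor
#'
#' Builds an ellipsoidal VOI on the MR grid, partitions it into contiguous
#' compartment blobs matching the configured fractions, draws per-voxel
#' (ADC, SUV) emissions, adds measurement noise, and grids SUV onto the
#' coarser PET grid by averaging the MR-grid values falling into each PET
#' voxel. Identical configuration yields a bit-identical phantom.
#'
#' @param config A [phantom_config].
#' @return An object of class `phantom` with elements `suv` (PET-grid
#'   [scalar_volume]), `adc` (MR grid), `suv_mr` (MR-grid SUV before PET
#'   gridding — the latent measured emission, used as ground truth in
#'   recovery tests), `mask` ([voi_mask]), `labels` (integer array:
#'   0 outside, 1 vital, 2 equivocal, 3 low-vital), `config`, `timepoint`,
#'   `mode`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, .generate_phantom_impl(config))
}

.generate_phantom_impl <- function(config) {
  dims <- config$grid_shape
  sp <- config$mr_spacing
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * sp[a])
  ext <- (dims - 1) * sp
  center <- ext / 2
  semi <- config$radius_frac * ext / 2
  if (any(semi <= 0)) stop("degenerate ellipsoid")
  u <- lapply(1:3, function(a) ((ax[[a]] - center[a]) / semi[a])^2)
  mask_arr <- outer(outer(u[[1]], u[[2]], `+`), u[[3]], `+`) <= 1
  fg <- which(mask_arr)
  n_mask <- length(fg)
  if (n_mask == 0L) stop("phantom mask is empty")

  idx <- arrayInd(fg, dims)
  coords <- cbind(ax[[1]][idx[, 1]], ax[[2]][idx[, 2]], ax[[3]][idx[, 3]])

  # contiguous compartments: nearest-seed partition, cells assigned to
  # compartments along a random order so cell-count fractions match targets
  n_blobs <- max(3L, as.integer(round(n_mask / config$blob_voxels)))
  seeds <- coords[sample.int(n_mask, min(n_blobs, n_mask)), , drop = FALSE]
  cell <- .nearest_seed(coords, seeds)
  sizes <- tabulate(cell, nbins = nrow(seeds))
  perm <- sample.int(nrow(seeds))
  cum <- cumsum(sizes[perm]) / n_mask
  mid <- cum - sizes[perm] / (2 * n_mask)
  bounds <- cumsum(config$compartment_fractions)[1:2]
  comp_of_cell <- integer(nrow(seeds))
  comp_of_cell[perm] <- findInterval(mid, bounds) + 1L
  comp <- comp_of_cell[cell]

  emission <- matrix(NA_real_, n_mask, 2)
  for (g in 1:3) {
    sel <- which(comp == g)
    if (length(sel))
      emission[sel, ] <-
        .draw_emission(length(sel), config$compartment_params[[g]])
  }

  adc_arr <- array(config$background[["adc"]], dim = dims)
  suv_arr <- array(config$background[["suv"]], dim = dims)
  adc_arr <- adc_arr + stats::rnorm(prod(dims), 0, config$noise_sd[["adc"]])
  suv_arr <- suv_arr + stats::rnorm(prod(dims), 0, config$noise_sd[["suv"]])
  adc_arr[fg] <- emission[, 1] +
    stats::rnorm(n_mask, 0, config$noise_sd[["adc"]])
  suv_arr[fg] <- emission[, 2] +
    stats::rnorm(n_mask, 0, config$noise_sd[["suv"]])
  adc_arr[adc_arr <= 0] <- 1
  suv_arr[suv_arr < 0] <- 0

  labels <- array(0L, dim = dims)
  labels[fg] <- comp

  # SUV onto the PET grid: average MR-grid values per covering PET voxel
  psp <- config$pet_spacing
  pdims <- as.integer(floor(ext / psp)) + 2L
  pax <- lapply(1:3, function(a)
    pmin(pmax(round(ax[[a]] / psp[a]), 0), pdims[a] - 1L))
  pi_ <- rep(pax[[1]], times = dims[2] * dims[3])
  pj <- rep(rep(pax[[2]], each = dims[1]), times = dims[3])
  pk <- rep(pax[[3]], each = dims[1] * dims[2])
  plin <- 1L + pi_ + pdims[1] * (pj + pdims[2] * pk)
  sums <- rowsum(as.vector(suv_arr), plin)
  counts <- rowsum(rep(1, length(plin)), plin)
  pet_arr <- array(config$background[["suv"]], dim = pdims)
  pet_arr[as.integer(rownames(sums))] <- sums / counts
  pet_arr[pet_arr < 0] <- 0

  structure(list(
    suv = scalar_volume(pet_arr, psp, "suv"),
    adc = scalar_volume(adc_arr, sp, "adc"),
    suv_mr = scalar_volume(suv_arr, sp, "suv"),
    mask = voi_mask(mask_arr, sp, provenance = "synthetic ellipsoid"),
    labels = labels,
    config = config, timepoint = "baseline", mode = NULL),
    class = "phantom")
}

#' Empirical compartment fractions of a phantom
#'
#' @param phantom A [generate_phantom] result.
#' @return Named numeric vector of truth-label fractions inside the mask.
#' @export
phantom_truth_fractions <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  lab <- phantom$labels[phantom$labels > 0L]
  stats::setNames(tabulate(lab, nbins = 3L) / length(lab), TISSUE_LEVELS)
}

.therapy_defaults <- list(
  response = list(volume_factor = 0.2,
                  fractions = c(vital = 0.0003, equivocal = 0.343,
                                low_vital = 0.657),
                  adc_shift = 200, suv_shift = -0.4),
  progression = list(volume_factor = 0.5,
                     fractions = c(vital = 0.418, equivocal = 0.333,
                                   low_vital = 0.249),
                     adc_shift = -150, suv_shift = 0.5))

#' Apply a therapy course to a phantom
#'
#' Produces the post-therapy phantom of the same patient: the tumor shrinks
#' by `volume_factor`, compartment fractions are re-drawn (response:
#' near-zero vital, mostly low-vital; progression: vital fraction up), and
#' compartment means shift so that under response the cohort mean ADC rises
#' and mean SUV falls, and the reverse under progression.
#'
#' @param phantom A baseline [generate_phantom] result.
#' @param mode `"response"` or `"progression"`.
#' @param volume_factor,fractions,adc_shift,suv_shift overrides of the
#'   per-mode defaults (response: factor 0.2, fractions
#'   0.03/34.3/65.7 percent, ADC +200, SUV -0.4; progression: factor 0.5,
#'   fractions 41.8/33.3/24.9 percent, ADC -150, SUV +0.5).
#' @return A [generate_phantom]-shaped object with `timepoint = "post"`.
#' @export
apply_therapy_course <- function(phantom,
                                 mode = c("response", "progression"),
                                 volume_factor = NULL, fractions = NULL,
                                 adc_shift = NULL, suv_shift = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  mode <- match.arg(mode)
  def <- .therapy_defaults[[mode]]
  volume_factor <- volume_factor %||% def$volume_factor
  fractions <- fractions %||% def$fractions
  adc_shift <- adc_shift %||% def$adc_shift
  suv_shift <- suv_shift %||% def$suv_shift
  if (volume_factor <= 0) stop("volume_factor must be positive")

  cfg <- phantom$config
  params <- cfg$compartment_params
  for (nm in TISSUE_LEVELS) {
    params[[nm]]$mean[1] <- max(100, params[[nm]]$mean[1] + adc_shift)
    params[[nm]]$mean[2] <- max(0.1, params[[nm]]$mean[2] + suv_shift)
  }
  post_cfg <- cfg
  post_cfg$compartment_fractions <-
    stats::setNames(as.double(fractions) / sum(fractions), TISSUE_LEVELS)
  post_cfg$compartment_params <- params
  post_cfg$radius_frac <- cfg$radius_frac * volume_factor^(1 / 3)
  post_cfg$seed <- derive_seed(cfg$seed,
                               if (mode == "response") 101L else 211L)
  out <- with_seed(post_cfg$seed, .generate_phantom_impl(post_cfg))
  out$timepoint <- "post"
  out$mode <- mode
  out
}

#' Write a phantom to NIfTI files
#'
#' @param phantom A [generate_phantom] result.
#' @param directory output directory (created if missing).
#' @return Named character vector of paths (`suv`, `adc`, `mask`,
#'   `labels`), invisibly.
#' @export
write_phantom <- function(phantom, directory) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- c(suv = file.path(directory, "suv.nii.gz"),
             adc = file.path(directory, "adc.nii.gz"),
             mask = file.path(directory, "mask.nii.gz"),
             labels = file.path(directory, "labels.nii.gz"))
  write_volume(phantom$suv, paths[["suv"]])
  write_volume(phantom$adc, paths[["adc"]])
  write_nifti(phantom$mask$values + 0L, paths[["mask"]],
              phantom$mask$spacing, phantom$mask$origin, "uint8")
  write_nifti(phantom$labels, paths[["labels"]],
              phantom$adc$spacing, phantom$adc$origin, "int16")
  invisible(paths)
}

#' Voxel table of a phantom
#'
#' Two routes onto the per-voxel record set: `"latent"` reads the MR-grid
#' values directly under the mask (ground truth for recovery tests, with the
#' true compartment as `tissue_truth`); `"pipeline"` resamples the PET-grid
#' SUV back onto the MR grid trilinearly and extracts masked pairs, i.e. what
#' the analysis of real data would see.
#'
#' @param phantom A [generate_phantom] result.
#' @param use `"latent"` or `"pipeline"`.
#' @param patient_id optional id carried into the table.
#' @return A [voxel_table]; the latent route adds a `tissue_truth` column.
#' @export
phantom_table <- function(phantom, use = c("latent", "pipeline"),
                          patient_id = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  use <- match.arg(use)
  if (use == "latent") {
    fg <- which(phantom$mask$values)
    idx <- arrayInd(fg, dim(phantom$mask$values)) - 1L
    tab <- voxel_table(
      data.frame(adc = phantom$adc$values[fg],
                 suv = phantom$suv_mr$values[fg],
                 i = idx[, 1], j = idx[, 2], k = idx[, 3],
                 tissue_truth = factor(TISSUE_LEVELS[phantom$labels[fg]],
                                       levels = TISSUE_LEVELS)),
      spacing = phantom$adc$spacing)
  } else {
    suv_on_mr <- resample_to_grid(phantom$suv, phantom$adc, "trilinear")
    tab <- extract_masked_pairs(suv_on_mr, phantom$adc, phantom$mask)
  }
  if (!is.null(patient_id)) tab$patient_id <- patient_id
  tab$timepoint <- phantom$timepoint
  tab
}
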