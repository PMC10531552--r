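# Phantom generator: fractions, coupling, determinism, therapy transforms,
# file round trips.

test_that("config invariants are enforced", {
  expect_error(phantom_config(compartment_fractions = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(phantom_config(mr_spacing = c(0.7, 0, 5)), "positive")
  expect_error(phantom_config(vital_coupling = 0.3), "vital_coupling")
  bad <- tight_params()
  bad$vital$mean <- c(adc = 1400, suv = 4) # vital on the wrong ADC side
  expect_error(phantom_config(compartment_params = bad), "vital compartment")
})

test_that("truth fractions approach the configured fractions", {
  ph <- big_phantom(seed = 41) # ~17k mask voxels
  truth <- phantom_truth_fractions(ph)
  target <- c(vital = 0.263, equivocal = 0.379, low_vital = 0.358)
  expect_lt(max(abs(truth - target)), 0.02)
  expect_gt(sum(ph$mask$values), 0.05 * prod(dim(ph$mask$values)))
  # labels defined exactly on mask voxels
  expect_true(all((ph$labels > 0) == ph$mask$values))
  expect_setequal(unique(ph$labels[ph$labels > 0]), 1:3)
})

test_that("identical config yields a bit-identical phantom", {
  a <- small_phantom(seed = 42)
  b <- small_phantom(seed = 42)
  expect_identical(a$adc$values, b$adc$values)
  expect_identical(a$suv$values, b$suv$values)
  expect_identical(a$labels, b$labels)
  c <- small_phantom(seed = 43)
  expect_false(identical(a$adc$values, c$adc$values))
})

test_that("a pure-vital phantom stays in the vital quadrant", {
  # tail-bound oracle: with mean (900, 4.0) and tiny SD, the normal CDF puts
  # >= 99% of mass at SUV > 2.5 and ADC < 1250 per channel
  params <- list(
    vital = list(mean = c(adc = 900, suv = 4), sd = c(adc = 50, suv = 0.2),
                 coupling = 0),
    equivocal = list(mean = c(adc = 1100, suv = 1.8),
                     sd = c(adc = 50, suv = 0.2), coupling = 0),
    low_vital = list(mean = c(adc = 1700, suv = 1.2),
                     sd = c(adc = 50, suv = 0.2), coupling = 0))
  p_ok <- stats::pnorm(1250, 900, sqrt(50^2 + 5^2)) *
    stats::pnorm(2.5, 4, sqrt(0.2^2 + 0.02^2), lower.tail = FALSE)
  expect_gt(p_ok, 0.99)
  ph <- small_phantom(seed = 44,
                      compartment_fractions = c(1, 0, 0),
                      compartment_params = params,
                      noise_sd = c(adc = 5, suv = 0.02))
  tab <- phantom_table(ph, "latent")
  expect_gt(mean(tab$suv > 2.5 & tab$adc < 1250), 0.99)
})

test_that("vital-compartment coupling is recovered at scale", {
  ph <- big_phantom(seed = 45, noise_sd = c(adc = 1e-6, suv = 1e-6))
  tab <- phantom_table(ph, "latent")
  vital <- tab[tab$tissue_truth == "vital", ]
  expect_gt(nrow(vital), 3000)
  r <- pearson_cor(vital$adc, vital$suv)$r
  expect_lt(abs(r - (-0.4)), 0.05)
  expect_lt(r, 0)
})

test_that("therapy transforms move fractions and intensities as configured", {
  base <- big_phantom(seed = 46)
  resp <- apply_therapy_course(base, "response")
  expect_equal(resp$timepoint, "post")
  expect_lt(phantom_truth_fractions(resp)[["vital"]], 0.01)
  expect_lt(sum(resp$mask$values), sum(base$mask$values))

  prog <- apply_therapy_course(base, "progression")
  expect_gt(phantom_truth_fractions(prog)[["vital"]],
            phantom_truth_fractions(base)[["vital"]])

  # identity transform keeps the mask voxel count
  ident <- apply_therapy_course(base, "response", volume_factor = 1,
                                fractions = c(0.263, 0.379, 0.358),
                                adc_shift = 0, suv_shift = 0)
  expect_equal(sum(ident$mask$values), sum(base$mask$values))
  expect_error(apply_therapy_course(base, "remission"), "arg")
})

test_that("phantom files round-trip through NIfTI", {
  ph <- small_phantom(seed = 47)
  dir <- withr::local_tempdir()
  paths <- write_phantom(ph, dir)
  expect_true(all(file.exists(paths)))
  adc <- read_nifti(paths[["adc"]])
  expect_identical(adc$data, ph$adc$values)
  expect_equal(adc$spacing, c(0.7, 0.7, 5.0), tolerance = 1e-6)
  suv <- read_nifti(paths[["suv"]])
  expect_equal(suv$spacing, c(2.8, 2.8, 2.0), tolerance = 1e-6)
  lab <- read_nifti(paths[["labels"]])
  msk <- read_nifti(paths[["mask"]])
  expect_setequal(unique(lab$data[msk$data > 0]), c(1, 2, 3))
  expect_true(all(lab$data[msk$data == 0] == 0))
})
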