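# EM mixture fitting, density intersections, demarcation thresholds,
# cluster assignment and within-cluster correlation.

sim_mixture_2d <- function(n, weights, means, sd = 0.4, seed = 1) {
  set.seed(seed)
  z <- sample(seq_along(weights), n, TRUE, weights)
  x <- t(vapply(z, function(g) means[[g]] + rnorm(2, 0, sd), numeric(2)))
  list(x = x, z = z)
}

test_that("EM recovers parameters of a separated 2D mixture", {
  means <- list(c(-3, 3), c(0, 0), c(3, -3))
  sim <- sim_mixture_2d(1e4, c(0.3, 0.4, 0.3), means, sd = 0.5, seed = 71)
  m <- fit_gmm(sim$x, 3, seed = 7)
  perm <- match_components(m, means)
  for (j in 1:3) {
    cm <- m$components[[perm[j]]]
    expect_lt(sqrt(sum((cm$mean - means[[j]])^2)), 0.1)
  }
  w <- vapply(m$components, `[[`, numeric(1), "weight")[perm]
  expect_lt(max(abs(w - c(0.3, 0.4, 0.3))), 0.03)
  expect_true(m$converged)
})

test_that("the log-likelihood trace is non-decreasing on varied fixtures", {
  set.seed(72)
  fixtures <- list(
    rnorm(200),
    c(rnorm(150, -2), rnorm(150, 2)),
    cbind(rnorm(300), rnorm(300)),
    sim_mixture_2d(500, c(0.5, 0.3, 0.2),
                   list(c(-2, 0), c(0, 2), c(2, 0)), seed = 73)$x)
  for (x in fixtures) {
    m <- fit_gmm(x, 3, seed = 5, n_init = 2)
    tr <- m$loglik_trace
    expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-length(tr)]))))
  }
})

test_that("k = 1 reproduces the closed-form Gaussian MLE", {
  set.seed(74)
  x <- rnorm(500, 3, 2)
  m <- fit_gmm(x, k = 1, seed = 1, n_init = 1)
  expect_equal(m$components[[1]]$mean, mean(x), tolerance = 1e-6)
  expect_equal(as.double(m$components[[1]]$cov),
               mean((x - mean(x))^2), tolerance = 1e-6)
  expect_equal(m$components[[1]]$weight, 1)
})

test_that("fit is reproducible under a fixed seed and guards degeneracy", {
  set.seed(75)
  x <- c(rnorm(200, -1), rnorm(200, 1))
  a <- fit_gmm(x, 3, seed = 11)
  b <- fit_gmm(x, 3, seed = 11)
  expect_identical(a$loglik, b$loglik)
  expect_error(fit_gmm(x[1:20], 3), "at least")
  expect_error(fit_gmm(rep(1, 100), 3), "identical")
  # single true component: extra components must collapse benignly
  y <- rnorm(600)
  expect_no_error(m <- fit_gmm(y, 3, seed = 3))
  w <- sort(vapply(m$components, `[[`, numeric(1), "weight"))
  vars <- vapply(m$components, function(cm) as.double(cm$cov), numeric(1))
  expect_true(w[1] < 0.05 || min(vars) <= 1e-3)
  expect_true(is.finite(m$loglik))
})

test_that("density intersections solve the defining equation", {
  g <- function(w, mu, sd) gaussian_component(w, mu, matrix(sd^2))
  wdens <- function(cm, x)
    cm$weight * dnorm(x, cm$mean, sqrt(as.double(cm$cov)))

  # symmetric equal-variance case: single root at the midpoint
  expect_equal(gaussian_intersections(g(.5, 0, 1), g(.5, 2, 1)), 1,
               tolerance = 1e-12)

  # equal means, different variances: two symmetric roots
  c1 <- g(.5, 0, 1); c2 <- g(.5, 0, 2)
  roots <- gaussian_intersections(c1, c2)
  expect_length(roots, 2)
  expect_equal(roots[1], -roots[2], tolerance = 1e-9)
  oracle <- oracle_intersections(c1, c2, -8, 8)
  expect_equal(roots, oracle, tolerance = 1e-6)

  # unequal weights shift the root toward the lighter component
  c3 <- g(.9, 0, 1); c4 <- g(.1, 2, 1)
  r <- gaussian_intersections(c3, c4)
  expect_length(r, 1)
  expect_gt(r, 1)
  expect_lt(abs(wdens(c3, r) - wdens(c4, r)), 1e-9)

  # every root satisfies the weighted-density equality to 1e-9
  set.seed(76)
  for (i in 1:20) {
    a <- g(runif(1, .1, .9), rnorm(1), runif(1, .5, 2))
    b <- g(runif(1, .1, .9), rnorm(1), runif(1, .5, 2))
    for (r in gaussian_intersections(a, b))
      expect_lt(abs(wdens(a, r) - wdens(b, r)), 1e-9)
  }
  expect_error(gaussian_intersections(g(.5, 0, 1), g(.5, 0, 1)),
               "identical")
})

test_that("demarcation thresholds sit between adjacent means", {
  mk_model <- function(ws, mus, sds) {
    comps <- Map(function(w, m, s) gaussian_component(w, m, matrix(s^2)),
                 ws, mus, sds)
    structure(list(components = comps, k = length(ws), d = 1L),
              class = "mixture_model")
  }
  m <- mk_model(c(1, 1, 1) / 3, c(-2, 0, 2), c(1, 1, 1))
  expect_equal(demarcation_thresholds(m), c(-1, 1), tolerance = 1e-9)

  m2 <- mk_model(c(.2, .5, .3), c(-2, 0.5, 3), c(0.8, 1.2, 0.6))
  th <- demarcation_thresholds(m2)
  expect_length(th, 2)
  expect_true(all(diff(th) > 0))
  # grid-scan oracle on each adjacent pair, restricted between the means
  o1 <- oracle_intersections(m2$components[[1]], m2$components[[2]], -2, 0.5)
  o2 <- oracle_intersections(m2$components[[2]], m2$components[[3]], 0.5, 3)
  expect_equal(th, c(o1[1], o2[1]), tolerance = 1e-6)

  expect_error(demarcation_thresholds(
    structure(list(d = 2L), class = "mixture_model")), "1D")
})

test_that("semantic relabeling is invariant to component permutation", {
  means <- list(c(-1.5, 1.5), c(0, 0), c(1.5, -1.5)) # (adc_norm, suv_norm)
  sim <- sim_mixture_2d(3000, c(1, 1, 1) / 3, means, sd = 0.3, seed = 77)
  tab <- voxel_table(data.frame(adc = 1000 + 200 * sim$x[, 1],
                                suv = pmax(0, 2 + 0.5 * sim$x[, 2])))
  tab$adc_norm <- sim$x[, 1]; tab$suv_norm <- sim$x[, 2]
  m <- fit_gmm(sim$x, 3, seed = 9)
  out <- assign_clusters(m, tab)
  # permute components: labels must not change
  for (perm in list(c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))) {
    mp <- m; mp$components <- m$components[perm]
    expect_identical(assign_clusters(mp, tab)$cluster, out$cluster)
  }
  # truth component 1 has lowest ADC / highest SUV -> vital
  expect_gt(mean(out$cluster[sim$z == 1] == "vital"), 0.95)
  expect_gt(mean(out$cluster[sim$z == 3] == "low_vital"), 0.95)
  # a voxel at a dominant component mean goes to that component
  at_mean <- tab[1, ]; at_mean$adc_norm <- -1.5; at_mean$suv_norm <- 1.5
  expect_equal(as.character(assign_clusters(m, at_mean)$cluster), "vital")
  expect_equal(sum(group_proportions(out, "cluster")$fraction), 1,
               tolerance = 1e-12)
})

test_that("1D assignment cuts at the demarcation thresholds", {
  set.seed(78)
  x <- c(rnorm(400, -2, .4), rnorm(400, 0, .4), rnorm(400, 2, .4))
  tab <- voxel_table(data.frame(adc = rep(1000, 1200),
                                suv = rep(1, 1200)))
  tab$suv_norm <- x
  m <- fit_gmm(x, 3, seed = 12)
  th <- demarcation_thresholds(m)
  out <- assign_clusters(m, tab, var = "suv")
  expected <- cut(x, c(-Inf, th, Inf),
                  labels = c("low_vital", "equivocal", "vital"))
  expect_identical(as.character(out$cluster), as.character(expected))
  expect_error(assign_clusters(m, tab, var = "both"), "2D")
})

test_that("within-cluster correlations recover the configured coupling", {
  ph <- big_phantom(seed = 79, compartment_params = tight_params(-0.4),
                    noise_sd = c(adc = 1e-6, suv = 1e-6))
  tab <- phantom_table(ph, "latent")
  tab$cluster <- tab$tissue_truth
  cw <- correlate_within_clusters(tab)
  r_vital <- cw$r[cw$cluster == "vital"]
  expect_lt(abs(r_vital - (-0.4)), 0.1)
  expect_lt(abs(cw$r[cw$cluster == "equivocal"]), 0.05)

  tiny <- voxel_table(data.frame(adc = c(1, 2), suv = c(1, 2)))
  tiny$cluster <- factor(c("vital", "vital"),
                         levels = c("vital", "equivocal", "low_vital"))
  expect_warning(cw2 <- correlate_within_clusters(tiny), "fewer than 3")
  expect_true(is.na(cw2$r[cw2$cluster == "vital"]))
})

test_that("null coupling gives near-zero correlation in every cluster", {
  ph <- big_phantom(seed = 80, vital_coupling = 0,
                    compartment_params = tight_params(0),
                    noise_sd = c(adc = 1e-6, suv = 1e-6))
  tab <- phantom_table(ph, "latent")
  tab$cluster <- tab$tissue_truth
  cw <- correlate_within_clusters(tab)
  expect_true(all(abs(cw$r) < 0.05))
})
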