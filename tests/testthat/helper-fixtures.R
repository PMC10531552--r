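# Shared fixtures, built in code.

# small phantom for fast tests (~1.5k mask voxels)
small_phantom <- function(seed = 11, ...) {
  generate_phantom(phantom_config(grid_shape = c(32, 32, 10),
                                  seed = seed, ...))
}

# well-separated emission: every compartment mean sits >= ~2 effective SDs
# (emission + default measurement noise in quadrature) from both thresholds,
# so analytic cross-threshold leakage is < 3% per channel by the normal CDF
tight_params <- function(coupling = -0.4) {
  list(vital     = list(mean = c(adc = 850,  suv = 4.0),
                        sd = c(adc = 100, suv = 0.3), coupling = coupling),
       equivocal = list(mean = c(adc = 1050, suv = 1.7),
                        sd = c(adc = 100, suv = 0.3), coupling = 0),
       low_vital = list(mean = c(adc = 1700, suv = 1.2),
                        sd = c(adc = 100, suv = 0.3), coupling = 0))
}

# a large phantom whose mask holds >= n voxels (grid sized accordingly)
big_phantom <- function(seed = 13, ...) {
  generate_phantom(phantom_config(grid_shape = c(64, 64, 24),
                                  seed = seed, ...))
}

# brute-force summary oracle: direct formulas on the raw vectors
oracle_summary <- function(x) {
  list(mean = sum(x) / length(x),
       median = stats::median(x),
       p5 = unname(stats::quantile(x, 0.05, type = 7)),
       p95 = unname(stats::quantile(x, 0.95, type = 7)))
}

# grid-scan oracle for weighted-density intersections: sign changes of the
# difference of the two weighted densities on a dense grid
oracle_intersections <- function(c1, c2, lo, hi, n = 2e5) {
  wd <- function(cm, x) cm$weight * stats::dnorm(x, cm$mean[1],
                                                 sqrt(as.double(cm$cov)))
  x <- seq(lo, hi, length.out = n)
  d <- wd(c1, x) - wd(c2, x)
  sc <- which(d[-1] * d[-length(d)] < 0)
  vapply(sc, function(i) {
    uniroot(function(z) wd(c1, z) - wd(c2, z), c(x[i], x[i + 1]),
            tol = 1e-13)$root
  }, numeric(1))
}

# match fitted components to truth by best permutation of mean distances
match_components <- function(model, true_means) {
  k <- model$k
  perms <- if (k == 3L) list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                             c(3,1,2), c(3,2,1))
           else stop("k must be 3")
  fitted <- lapply(model$components, `[[`, "mean")
  cost <- vapply(perms, function(p)
    sum(vapply(seq_len(k), function(j)
      sum((fitted[[p[j]]] - true_means[[j]])^2), numeric(1))), numeric(1))
  perms[[which.min(cost)]]
}
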