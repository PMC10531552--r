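# Three-component Gaussian mixture clustering of normalized (ADC, SUV)
# voxel data, fitted by expectation-maximization implemented here (log-space
# E-step, weighted-moment M-step, eigenvalue-floored covariances, seeded
# k-means++-style restarts). For 1D fits, subregion boundaries are the
# intersection points of adjacent weighted component densities.

#' @rdname fit_gmm
#' @export
gaussian_component <- function(weight, mean, cov) {
  mean <- as.double(mean)
  cov <- as.matrix(cov)
  if (weight <= 0) stop("component weight must be positive")
  if (nrow(cov) != length(mean) || ncol(cov) != length(mean))
    stop("covariance dimension must match the mean")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("covariance must be positive-definite")
  structure(list(weight = weight, mean = mean, cov = cov),
            class = "gaussian_component")
}

# n x k matrix of log N(x; mean_j, cov_j)
.log_gauss <- function(x, comps) {
  n <- nrow(x); d <- ncol(x)
  out <- matrix(NA_real_, n, length(comps))
  for (j in seq_along(comps)) {
    cm <- comps[[j]]
    ch <- chol(cm$cov)
    centered <- sweep(x, 2, cm$mean)
    z <- backsolve(ch, t(centered), transpose = TRUE)
    out[, j] <- -0.5 * d * log(2 * pi) - sum(log(diag(ch))) -
      0.5 * colSums(z^2)
  }
  out
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

.floor_cov <- function(cov, floor) {
  e <- eigen(cov, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  e$vectors %*% (vals * t(e$vectors))
}

# k-means++-style center seeding followed by one hard-assignment moment step
.gmm_init <- function(x, k, floor) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k)[-1]) {
    pr <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1L, prob = pr), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  dist2 <- sapply(seq_len(k), function(j)
    rowSums(sweep(x, 2, centers[j, ])^2))
  assign <- max.col(-dist2, ties.method = "first")
  lapply(seq_len(k), function(j) {
    sel <- assign == j
    if (sum(sel) < 2L) {
      gaussian_component(1 / k, centers[j, ],
                         .floor_cov(stats::cov(x) / k + diag(floor, ncol(x)),
                                    floor))
    } else {
      xs <- x[sel, , drop = FALSE]
      cv <- stats::cov(xs) * (nrow(xs) - 1) / nrow(xs)
      gaussian_component(sum(sel) / n, colMeans(xs), .floor_cov(cv, floor))
    }
  })
}

.gmm_em_once <- function(x, k, tol, max_iter, floor) {
  n <- nrow(x)
  comps <- .gmm_init(x, k, floor)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lw <- log(vapply(comps, `[[`, numeric(1), "weight"))
    lp <- sweep(.log_gauss(x, comps), 2, lw, `+`)
    lse <- .logsumexp_rows(lp)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(lp - lse)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * abs(ll_old)) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    for (j in seq_len(k)) {
      mu <- colSums(resp[, j] * x) / nk[j]
      centered <- sweep(x, 2, mu)
      cv <- crossprod(centered * sqrt(resp[, j])) / nk[j]
      comps[[j]] <- gaussian_component(nk[j] / n, mu, .floor_cov(cv, floor))
    }
  }
  list(components = comps, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, iterations = iter, converged = converged)
}

#' Fit a Gaussian mixture model by EM
#'
#' Expectation-maximization with responsibilities computed via log-sum-exp,
#' weighted-moment M-steps, covariance eigenvalues floored at `cov_floor`,
#' and the best of `n_init` seeded k-means++-style restarts kept. The
#' log-likelihood trace is stored and is non-decreasing up to numerical
#' round-off.
#'
#' @param x numeric matrix (rows = observations) or vector for 1D data.
#' @param k number of components (default 3).
#' @param seed RNG seed controlling initialization.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @param n_init number of restarts.
#' @param cov_floor eigenvalue floor for component covariances.
#' @return An object of class `mixture_model`: `components` (list of
#'   [gaussian_component]), `k`, `d`, `loglik`, `loglik_trace`,
#'   `iterations`, `converged`.
#' @export
fit_gmm <- function(x, k = 3L, seed = NULL, tol = 1e-6, max_iter = 500L,
                    n_init = 5L, cov_floor = 1e-6) {
  if (is.null(dim(x))) x <- matrix(as.double(x), ncol = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("data must be finite")
  if (nrow(x) < 10L * k)
    stop("need at least ", 10L * k, " points to fit ", k, " components")
  if (nrow(unique(x)) == 1L) stop("all points identical; mixture undefined")
  fits <- lapply(seq_len(n_init), function(i) {
    with_seed(if (is.null(seed)) NULL else derive_seed(seed, i),
              .gmm_em_once(x, k, tol, max_iter, cov_floor))
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  structure(c(best, list(k = as.integer(k), d = ncol(x))),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model> k = %d, d = %d, loglik = %.4f (%s, %d iter)\n",
              x$k, x$d, x$loglik,
              if (x$converged) "converged" else "not converged",
              x$iterations))
  for (j in seq_len(x$k)) {
    cm <- x$components[[j]]
    cat(sprintf("  comp %d: w = %.3f, mean = (%s)\n", j, cm$weight,
                paste(sprintf("%.3f", cm$mean), collapse = ", ")))
  }
  invisible(x)
}

.comp_1d <- function(cm) {
  mu <- cm$mean
  if (length(mu) != 1L) stop("component is not one-dimensional")
  list(w = cm$weight, mu = as.double(mu), sd = sqrt(as.double(cm$cov)))
}

#' Intersection points of two weighted Gaussian densities
#'
#' Solves w1 * phi(x; mu1, sd1) = w2 * phi(x; mu2, sd2) through the
#' quadratic obtained from the log-densities; 0, 1 or 2 real roots are
#' returned in ascending order. At each root the two weighted densities
#' agree to near machine precision.
#'
#' @param c1,c2 one-dimensional [gaussian_component]s (or lists with
#'   `weight`, `mean`, `cov`).
#' @return numeric vector of 0-2 abscissae.
#' @export
gaussian_intersections <- function(c1, c2) {
  a1 <- .comp_1d(c1); a2 <- .comp_1d(c2)
  if (isTRUE(all.equal(c(a1$w, a1$mu, a1$sd), c(a2$w, a2$mu, a2$sd),
                       tolerance = 1e-12)))
    stop("identical components intersect everywhere")
  # quadratic A x^2 + B x + C = 0 from equating log weighted densities
  A <- 1 / (2 * a2$sd^2) - 1 / (2 * a1$sd^2)
  B <- a1$mu / a1$sd^2 - a2$mu / a2$sd^2
  C <- a2$mu^2 / (2 * a2$sd^2) - a1$mu^2 / (2 * a1$sd^2) +
    log((a1$w * a2$sd) / (a2$w * a1$sd))
  if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) return(numeric(0)) # parallel: no crossing
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(numeric(0))
  sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
}

#' Demarcation thresholds of a 1D mixture
#'
#' Components are ordered by mean; for each adjacent pair the density
#' intersection lying between the two means is the demarcation threshold.
#' If no intersection falls between the means (possible with extreme weight
#' or variance imbalance), the midpoint of the means is substituted with a
#' warning. The k - 1 thresholds are strictly increasing.
#'
#' @param model a 1D [fit_gmm] result.
#' @return numeric vector of k - 1 ascending thresholds.
#' @export
demarcation_thresholds <- function(model) {
  stopifnot(inherits(model, "mixture_model"))
  if (model$d != 1L) stop("demarcation thresholds are defined for 1D models")
  mus <- vapply(model$components, function(cm) cm$mean[1], numeric(1))
  ord <- order(mus)
  comps <- model$components[ord]
  mus <- mus[ord]
  th <- numeric(model$k - 1L)
  for (j in seq_len(model$k - 1L)) {
    roots <- gaussian_intersections(comps[[j]], comps[[j + 1L]])
    between <- roots[roots > mus[j] & roots < mus[j + 1L]]
    if (length(between)) {
      th[j] <- between[1L]
    } else {
      warning("no density intersection between adjacent component means; ",
              "using their midpoint")
      th[j] <- (mus[j] + mus[j + 1L]) / 2
    }
  }
  if (any(diff(th) <= 0)) stop("demarcation thresholds are not increasing")
  th
}

# semantic names from component means: highest SUV / lowest ADC -> vital,
# lowest SUV / highest ADC -> low_vital, remainder -> equivocal
.semantic_order <- function(model, var) {
  mus <- do.call(rbind, lapply(model$components, `[[`, "mean"))
  score <- switch(var,
    both = mus[, 2] - mus[, 1], # suv_norm minus adc_norm
    suv = mus[, 1],
    adc = -mus[, 1])
  ranks <- rank(score, ties.method = "first")
  labels <- character(model$k)
  labels[which.max(ranks)] <- "vital"
  labels[which.min(ranks)] <- "low_vital"
  labels[labels == ""] <- "equivocal"
  labels
}

#' Assign voxels to mixture clusters
#'
#' 2D mode assigns each voxel to the maximum-responsibility component of a
#' model fitted on `(adc_norm, suv_norm)`; 1D mode cuts the chosen variable
#' at the demarcation thresholds. Components are then relabeled to semantic
#' names from their means: highest normalized SUV / lowest ADC becomes
#' `vital`, the opposite extreme `low_vital`, the remainder `equivocal` —
#' a deterministic rule invariant to component permutation.
#'
#' @param model a [fit_gmm] result (d = 2 with `var = "both"`, d = 1
#'   otherwise).
#' @param table a [voxel_table] with `adc_norm` and `suv_norm` columns from
#'   the same normalization the model was fitted on.
#' @param var `"both"` (2D, default), `"suv"` or `"adc"` (1D).
#' @return The table with a `cluster` factor column (levels `vital`,
#'   `equivocal`, `low_vital`).
#' @export
assign_clusters <- function(model, table, var = c("both", "suv", "adc")) {
  stopifnot(inherits(model, "mixture_model"), inherits(table, "voxel_table"))
  var <- match.arg(var)
  if (var == "both" && model$d != 2L)
    stop("2D assignment requires a 2D model")
  if (var != "both" && model$d != 1L)
    stop("1D assignment requires a 1D model")
  need <- if (var == "both") c("adc_norm", "suv_norm")
          else paste0(var, "_norm")
  if (!all(need %in% names(table)))
    stop("table lacks normalized column(s): ", paste(need, collapse = ", "))
  labels <- .semantic_order(model, var)
  if (var == "both") {
    x <- as.matrix(table[, c("adc_norm", "suv_norm")])
    lw <- log(vapply(model$components, `[[`, numeric(1), "weight"))
    lp <- sweep(.log_gauss(x, model$components), 2, lw, `+`)
    comp <- max.col(lp, ties.method = "first")
  } else {
    th <- demarcation_thresholds(model)
    mus <- vapply(model$components, function(cm) cm$mean[1], numeric(1))
    ord <- order(mus)
    comp <- ord[findInterval(table[[need]], th) + 1L]
  }
  table$cluster <- factor(labels[comp], levels = TISSUE_LEVELS)
  attr(table, "cluster_model") <- model
  table
}

#' Within-cluster correlation of ADC and SUV
#'
#' Pearson correlation of the raw (ADC, SUV) pairs inside each cluster.
#' Clusters with fewer than 3 voxels or constant values get a missing R
#' with a warning.
#'
#' @param table a clustered [voxel_table].
#' @param column label column to stratify by (default `"cluster"`).
#' @return data frame with `cluster`, `n`, `r`, `p`.
#' @export
correlate_within_clusters <- function(table, column = "cluster") {
  stopifnot(inherits(table, "voxel_table"))
  if (!column %in% names(table)) stop("no `", column, "` column")
  lab <- factor(table[[column]], levels = TISSUE_LEVELS)
  out <- data.frame(cluster = TISSUE_LEVELS, n = NA_integer_,
                    r = NA_real_, p = NA_real_)
  for (g in seq_along(TISSUE_LEVELS)) {
    sel <- which(lab == TISSUE_LEVELS[g])
    out$n[g] <- length(sel)
    if (length(sel) < 3L) {
      if (length(sel) > 0L)
        warning("cluster '", TISSUE_LEVELS[g],
                "' has fewer than 3 voxels; correlation undefined")
      next
    }
    a <- table$adc[sel]; s <- table$suv[sel]
    if (stats::sd(a) == 0 || stats::sd(s) == 0) {
      warning("cluster '", TISSUE_LEVELS[g],
              "' has constant values; correlation undefined")
      next
    }
    pc <- pearson_cor(a, s)
    out$r[g] <- pc$r; out$p[g] <- pc$p
  }
  out
}
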