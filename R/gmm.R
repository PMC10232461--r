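#' Bayesian information criterion
#'
#' `BIC = -2 ln(L) + k ln(n)` for a fitted model with log-likelihood
#' `ln(L)`, `k_params` free parameters and `n` observations. Smaller is
#' better.
#'
#' @param log_likelihood maximized log-likelihood.
#' @param k_params number of free parameters.
#' @param n number of observations (>= 1).
#' @return The BIC value.
#' @export
bic <- function(log_likelihood, k_params, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  -2 * log_likelihood + k_params * log(n)
}

# free-parameter count for a k-component mixture in d dimensions with full
# covariances: k*d means + k*d*(d+1)/2 covariance terms + (k-1) weights
gmm_k_params <- function(k, d) {
  k * d + k * d * (d + 1) / 2 + (k - 1)
}

# One EM fit initialized from a randomly started k-means partition (the
# RNG state supplies the start). Hard-assignment responsibilities from a
# random partition alone would put every initial mean at the grand mean --
# an unstable symmetric point EM escapes too slowly -- so the k-means step
# is what makes independent repeats explore distinct local optima.
gmm_fit_once <- function(X, k, var_floor = 1e-4, max_iter = 500L,
                         tol = 1e-4) {
  n <- nrow(X)
  if (k == 1L) {
    resp0 <- matrix(1, n, 1)
  } else {
    assign <- tryCatch(
      suppressWarnings(kmeans(X, centers = k, iter.max = 10,
                              nstart = 1))$cluster,
      error = function(e) sample.int(k, n, replace = TRUE))
    resp0 <- matrix(1e-6, n, k)
    resp0[cbind(seq_len(n), assign)] <- 1
    resp0 <- resp0 / rowSums(resp0)
  }
  # `tol` is per sample: EM stops when the total log-likelihood changes by
  # less than tol * n between iterations
  fit <- em_gmm_cpp(X, resp0, var_floor, as.integer(max_iter), tol * n)
  fit$bic <- bic(fit$loglik, gmm_k_params(k, ncol(X)), n)
  fit$k <- k
  fit
}

#' Select the Gaussian-mixture component count by repeated EM and mean BIC
#'
#' For each candidate component count, the EM algorithm is run `repeats`
#' times from random initializations (randomly started k-means partitions)
#' and the BIC of each repeat is recorded; the chosen component count is
#' the one with the minimum mean BIC over repeats, and the reported fit is
#' the best-likelihood repeat at that count. Averaging the BIC over random
#' restarts penalizes over-parameterized mixtures whose extra components
#' frequently collapse into poor local optima. A variance floor guards EM
#' against collapsing components; floored repeats are counted in
#' `n_degenerate`.
#'
#' @param samples numeric vector (1D) or two-column matrix (2D) of
#'   observations (latencies in ms).
#' @param k_range candidate component counts (default 1 to 5).
#' @param repeats EM repeats per component count (default 1000).
#' @param seed RNG seed for the random initializations.
#' @param var_floor,max_iter EM controls.
#' @param tol convergence threshold on the per-sample log-likelihood
#'   change between EM iterations (default 1e-4).
#' @return A `gmm_selection` list: `chosen_k`, `mean_bic` (per k),
#'   `best_fits` (per k), `fit` (best fit at `chosen_k`: weights, means,
#'   covs, loglik), `n_degenerate`, `monotone_ok` (best likelihood never
#'   decreases with k), `repeats`, `seed`.
#' @export
gmm_select <- function(samples, k_range = 1:5, repeats = 1000L, seed = 1L,
                       var_floor = 1e-4, max_iter = 500L, tol = 1e-4) {
  X <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  if (nrow(X) < 2 * max(k_range))
    stop("need at least 2*max(k_range) samples", call. = FALSE)
  with_seed(seed, {
    mean_bic <- setNames(numeric(length(k_range)), k_range)
    best_fits <- vector("list", length(k_range))
    n_degen <- 0L
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      bics <- numeric(repeats)
      best <- NULL
      for (r in seq_len(repeats)) {
        f <- gmm_fit_once(X, k, var_floor, max_iter, tol)
        bics[r] <- f$bic
        if (f$n_floored > 0) n_degen <- n_degen + 1L
        if (is.null(best) || f$loglik > best$loglik) best <- f
      }
      mean_bic[ki] <- mean(bics)
      best_fits[[ki]] <- best
    }
    chosen <- k_range[which.min(mean_bic)]
    best_ll <- vapply(best_fits, function(f) f$loglik, numeric(1))
    structure(list(
      chosen_k = chosen, mean_bic = mean_bic, best_fits = best_fits,
      fit = best_fits[[which.min(mean_bic)]],
      n_degenerate = n_degen,
      monotone_ok = all(diff(best_ll) >= -1e-6),
      repeats = repeats, k_range = k_range, seed = seed),
      class = "gmm_selection")
  })
}

#' X-means cross-check of the cluster count
#'
#' BIC-driven k-means splitting: starting from a single cluster, each
#' cluster is tentatively split in two by k-means and the split is kept
#' when it improves the BIC of a spherical-Gaussian model of that
#' cluster's points; splitting continues until no split helps or `k_max`
#' is reached. Used as an independent confirmation of the mixture-model
#' component count.
#'
#' @param samples numeric vector or matrix of observations.
#' @param k_max maximum number of clusters.
#' @param seed RNG seed (k-means initialization).
#' @return Chosen number of clusters.
#' @export
xmeans_check <- function(samples, k_max = 5L, seed = 1L) {
  X <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  n <- nrow(X); d <- ncol(X)
  if (n < 2) return(1L)
  # BIC of a spherical-Gaussian model of one point set (k centres)
  bic_subset <- function(pts, centers, assign) {
    m <- nrow(pts); kk <- nrow(centers)
    rss <- sum((pts - centers[assign, , drop = FALSE])^2)
    sig2 <- max(rss / (d * max(m - kk, 1)), 1e-12)
    ll <- -0.5 * m * d * log(2 * pi * sig2) - rss / (2 * sig2) +
      sum(tabulate(assign, kk) * log(pmax(tabulate(assign, kk) / m, 1e-12)))
    bic(ll, kk * d + kk - 1 + 1, m)
  }
  with_seed(seed, {
    clusters <- list(seq_len(n))
    repeat {
      if (length(clusters) >= k_max) break
      improved <- FALSE
      new_clusters <- list()
      for (cl in clusters) {
        pts <- X[cl, , drop = FALSE]
        if (length(cl) < 4 || nrow(unique(pts)) < 2) {
          new_clusters <- c(new_clusters, list(cl)); next
        }
        ctr1 <- matrix(colMeans(pts), 1)
        b1 <- bic_subset(pts, ctr1, rep(1L, length(cl)))
        km <- suppressWarnings(kmeans(pts, centers = 2, nstart = 5))
        b2 <- bic_subset(pts, km$centers, km$cluster)
        if (b2 < b1 && length(clusters) + length(new_clusters) + 1 <= k_max &&
            min(km$size) > 0) {
          new_clusters <- c(new_clusters, list(cl[km$cluster == 1]),
                            list(cl[km$cluster == 2]))
          improved <- TRUE
        } else new_clusters <- c(new_clusters, list(cl))
      }
      clusters <- new_clusters
      if (!improved) break
    }
    length(clusters)
  })
}
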