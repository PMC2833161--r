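#' Spherical k-means: k-means clustering under cosine distance
#'
#' Coarse partitioning of microenvironment vectors on the unit sphere.
#' Rows are unit-normalized internally, distance to a center is
#' `1 - cosine similarity`, and each centroid is the normalized mean of its
#' members (the direction maximizing the mean cosine to them). Iteration
#' alternates assignment and centroid update until the assignment reaches a
#' fixed point, the objective improves by less than `tol`, or `max_iter`
#' iterations. Initialization is k-means++-style seeding adapted to cosine
#' distance, so runs are deterministic given `seed`. An empty cluster is
#' repaired by reseeding it with the point farthest (in cosine distance)
#' from its current centroid.
#'
#' @param ms a `microenv_set` (any space tag); rows must be non-zero.
#' @param k number of clusters, `1 <= k <= n_sites`.
#' @param seed RNG seed for the initialization.
#' @param max_iter iteration cap (default 300).
#' @param tol minimum objective improvement to continue (default 1e-6).
#' @return An object of class `spherical_kmeans`: `cluster` (1-based
#'   assignments), `centers` (k x D unit-norm matrix), `objective`
#'   (sum over sites of 1 - cosine to the assigned center), `n_iter`,
#'   `seed`, `k`.
#' @export
kmeans_cosine <- function(ms, k, seed = 1L, max_iter = 300L, tol = 1e-6) {
  x <- if (inherits(ms, "microenv_set")) ms$features else as.matrix(ms)
  n <- nrow(x)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k = ", k, " exceeds the number of sites (", n, ")")
  u <- unit_rows(x, "input to kmeans_cosine")

  set.seed(seed)
  centers <- u[kmeanspp_cosine(u, k), , drop = FALSE]

  assign_old <- rep(-1L, n)
  obj_prev <- Inf
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    sims <- u %*% t(centers)                   # n x k cosines
    lab <- max.col(sims, ties.method = "first")
    # repair empty clusters: reseed with the point farthest from its centroid
    repeat {
      cnt <- tabulate(lab, nbins = k)
      empty <- which(cnt == 0)
      if (!length(empty)) break
      far <- which.min(sims[cbind(seq_len(n), lab)])
      lab[far] <- empty[1]
      centers[empty[1], ] <- u[far, ]
      sims <- u %*% t(centers)
      lab2 <- max.col(sims, ties.method = "first")
      lab2[far] <- empty[1]
      lab <- lab2
    }
    obj <- sum(1 - sims[cbind(seq_len(n), lab)])
    stopifnot(obj <= obj_prev + 1e-8)          # objective never increases
    converged_assign <- identical(lab, assign_old)
    converged_obj <- (obj_prev - obj) < tol
    assign_old <- lab
    # update step: normalized member means
    for (j in seq_len(k)) {
      m <- colSums(u[lab == j, , drop = FALSE])
      nm <- sqrt(sum(m^2))
      if (nm > 0) centers[j, ] <- m / nm
    }
    if (converged_assign || converged_obj || n_iter >= max_iter) {
      obj_prev <- obj
      break
    }
    obj_prev <- obj
  }
  structure(list(k = as.integer(k), cluster = assign_old, centers = centers,
                 objective = obj_prev, n_iter = n_iter, seed = as.integer(seed)),
            class = "spherical_kmeans")
}

# k-means++ seeding under cosine distance: each next seed drawn with
# probability proportional to its distance to the closest chosen seed.
kmeanspp_cosine <- function(u, k) {
  n <- nrow(u)
  chosen <- integer(k)
  chosen[1] <- sample.int(n, 1)
  if (k == 1) return(chosen)
  d <- 1 - drop(u %*% u[chosen[1], ])
  d[d < 0] <- 0
  for (i in 2:k) {
    d[chosen[seq_len(i - 1)]] <- 0
    if (sum(d) == 0) {
      cand <- setdiff(seq_len(n), chosen[seq_len(i - 1)])
      chosen[i] <- cand[1]
    } else {
      chosen[i] <- sample.int(n, 1, prob = d / sum(d))
    }
    d <- pmin(d, pmax(1 - drop(u %*% u[chosen[i], ]), 0))
  }
  chosen
}

#' @export
print.spherical_kmeans <- function(x, ...) {
  cat("Spherical k-means: k = ", x$k, ", n = ", length(x$cluster),
      ", objective = ", signif(x$objective, 6),
      ", iterations = ", x$n_iter, "\n", sep = "")
  cat("  cluster sizes: ",
      paste(tabulate(x$cluster, nbins = x$k), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Best of several spherical k-means restarts
#'
#' Runs [kmeans_cosine()] with seeds `base_seed, base_seed + 1, ...` and
#' returns the run with the lowest objective; ties go to the lowest seed.
#'
#' @inheritParams kmeans_cosine
#' @param n_restarts number of restarts (default 10).
#' @param base_seed seed of the first restart.
#' @return The best `spherical_kmeans` fit.
#' @export
kmeans_restarts <- function(ms, k, n_restarts = 10L, base_seed = 1L,
                            max_iter = 300L, tol = 1e-6) {
  stopifnot(n_restarts >= 1)
  best <- NULL
  for (s in base_seed + seq_len(n_restarts) - 1L) {
    fit <- kmeans_cosine(ms, k, seed = s, max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best
}

#' Write coarse-cluster assignments and centroids
#'
#' Assignments go to a TSV (site id columns plus `coarse_cluster`),
#' centroids to a JSON file.
#'
#' @param fit a `spherical_kmeans`.
#' @param ms the clustered `microenv_set`.
#' @param assignments_path,centroids_path output paths (NULL to skip one).
#' @return invisibly, the written paths.
#' @export
write_coarse <- function(fit, ms, assignments_path, centroids_path = NULL) {
  df <- cbind(ms$sites[c("structure_id", "chain", "residue_number", "residue_name")],
              coarse_cluster = fit$cluster)
  utils::write.table(df, assignments_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(centroids_path)) {
    jsonlite::write_json(list(k = fit$k, objective = fit$objective,
                              seed = fit$seed, centers = fit$centers),
                         centroids_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(c(assignments_path, centroids_path))
}
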