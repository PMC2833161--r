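#' Random protein clusters from a background pool
#'
#' Uniform sampling without replacement, seeded; used as the null
#' comparison for the functional-coherence statistic.
#'
#' @param pool character vector of candidate protein ids.
#' @param sizes cluster sizes to draw.
#' @param n_per_size clusters per size (default 1).
#' @param seed RNG seed.
#' @return list of character vectors (length `length(sizes) * n_per_size`),
#'   each with attribute `size`.
#' @export
make_random_clusters <- function(pool, sizes, n_per_size = 1L, seed = 1L) {
  if (any(sizes > length(pool))) {
    stop("requested size exceeds the pool (", length(pool), ")")
  }
  set.seed(seed)
  out <- list()
  for (sz in sizes) {
    for (r in seq_len(n_per_size)) {
      cl <- sample(pool, sz)
      attr(cl, "size") <- sz
      out[[length(out) + 1L]] <- cl
    }
  }
  out
}

#' Dilution series of a protein cluster
#'
#' Progressively destroys the biological signal of a base cluster, either
#' by replacing members with pool proteins at fixed cluster size
#' (`"fixed"`) or by adding pool proteins while keeping all base members
#' (`"additive"`, cluster size `ceiling(base / fraction)`). Fraction 1.0
#' returns the base unchanged. Percent signal is the proportion of
#' retained base members in each realized cluster.
#'
#' @param base character vector: the coherent base cluster.
#' @param pool character vector of replacement proteins, disjoint from
#'   `base`.
#' @param mode `"fixed"` or `"additive"`.
#' @param fractions signal fractions in (0, 1].
#' @param n_replicates independent realizations per fraction.
#' @param seed RNG seed.
#' @param pool_tag label of the pool (`"random"` or `"similar"`).
#' @return object of class `dilution_series`: `mode`, `fractions`,
#'   `clusters` (list over fractions of lists over replicates),
#'   `percent_signal`, `pool_tag`.
#' @export
make_dilution_series <- function(base, pool, mode = c("fixed", "additive"),
                                 fractions = c(1, 0.8, 0.6, 0.4, 0.2),
                                 n_replicates = 1L, seed = 1L,
                                 pool_tag = "random") {
  mode <- match.arg(mode)
  if (length(intersect(base, pool))) stop("pool must be disjoint from base")
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  set.seed(seed)
  nb <- length(base)
  clusters <- vector("list", length(fractions))
  pct <- numeric(length(fractions))
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      if (f == 1) {
        cl <- base
        kept <- nb
      } else if (mode == "fixed") {
        kept <- round(f * nb)
        n_repl <- nb - kept
        if (n_repl > length(pool)) stop("pool too small for replacement")
        cl <- c(sample(base, kept), sample(pool, n_repl))
      } else {
        total <- ceiling(nb / f)
        n_add <- total - nb
        if (n_add > length(pool)) stop("pool too small for addition")
        kept <- nb
        cl <- c(base, sample(pool, n_add))
      }
      reps[[r]] <- cl
    }
    clusters[[i]] <- reps
    pct[i] <- kept / length(clusters[[i]][[1]])
  }
  structure(list(mode = mode, fractions = fractions, clusters = clusters,
                 percent_signal = pct, n_replicates = n_replicates,
                 pool_tag = pool_tag),
            class = "dilution_series")
}

#' Median functional coherence along a dilution series
#'
#' @param series a `dilution_series`.
#' @param index a `document_index`.
#' @param corpus a `knowledge_corpus`.
#' @return data.frame(fraction, median_F, n_scored, n_unscorable);
#'   unscorable clusters are recorded as missing, not fatal.
#' @export
coherence_curve <- function(series, index, corpus) {
  stopifnot(inherits(series, "dilution_series"))
  rows <- lapply(seq_along(series$fractions), function(i) {
    fs <- vapply(series$clusters[[i]], function(cl) {
      res <- tryCatch(functional_coherence(cl, index, corpus),
                      error = function(e) NULL)
      if (is.null(res)) NA_real_ else res$F
    }, numeric(1))
    data.frame(fraction = series$fractions[i],
               median_F = stats::median(fs, na.rm = TRUE),
               n_scored = sum(!is.na(fs)),
               n_unscorable = sum(is.na(fs)))
  })
  do.call(rbind, rows)
}

#' Partition agreement metrics
#'
#' Purity (precision-like: each predicted cluster votes for its dominant
#' truth class), inverse purity (recall-like, roles swapped) and the
#' adjusted Rand index.
#'
#' @param predicted,truth label vectors of equal length.
#' @return list(purity, inverse_purity, ari).
#' @export
partition_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("label vectors differ in length")
  ct <- table(predicted, truth)
  n <- length(predicted)
  list(purity = sum(apply(ct, 1, max)) / n,
       inverse_purity = sum(apply(ct, 2, max)) / n,
       ari = mclust::adjustedRandIndex(predicted, truth))
}

#' Silhouette widths under cosine distance
#'
#' Standard silhouette analysis on the pairwise `1 - cosine` distance
#' matrix, delegated to [cluster::silhouette()] (which assigns width 0 to
#' observations in singleton clusters).
#'
#' @param ms a `microenv_set` or numeric matrix.
#' @param labels cluster labels (at least 2 distinct).
#' @return list(widths, mean).
#' @export
silhouette_cosine <- function(ms, labels) {
  x <- if (inherits(ms, "microenv_set")) ms$features else as.matrix(ms)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  d <- cosine_dist_matrix(x)
  sil <- cluster::silhouette(labels, dmatrix = d)
  w <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, length(labels))
  list(widths = as.numeric(w), mean = mean(w))
}

#' Sweep k and the number of principal components
#'
#' For every (k, n_pc) combination, fits PCA on the standardized set,
#' reduces, runs spherical k-means, and reports: the mean over truth
#' classes of the best (smallest) hypergeometric enrichment p-value
#' attained by any cluster for that class, the mean cosine silhouette
#' width, and the purity against the truth labels.
#'
#' @param ms a standardized `microenv_set`.
#' @param k_values,pc_values parameter grids.
#' @param truth reference labels, one per site.
#' @param seed base seed for k-means restarts.
#' @param n_restarts restarts per k-means run.
#' @return data.frame with one row per combination.
#' @export
parameter_sweep <- function(ms, k_values, pc_values, truth, seed = 1L,
                            n_restarts = 3L) {
  stopifnot(inherits(ms, "microenv_set"))
  rows <- list()
  for (npc in pc_values) {
    model <- fit_pca(ms, npc)
    red <- predict(model, ms)
    for (k in k_values) {
      fit <- kmeans_restarts(red, k, n_restarts = n_restarts, base_seed = seed)
      lab <- fit$cluster
      n <- length(lab)
      best_p <- vapply(unique(truth), function(tc) {
        Kc <- sum(truth == tc)
        min(vapply(seq_len(fit$k), function(cl) {
          nn <- sum(lab == cl)
          if (nn == 0) return(1)
          hypergeom_pvalue(sum(lab == cl & truth == tc), nn, Kc, n)
        }, numeric(1)))
      }, numeric(1))
      sil <- if (k >= 2 && length(unique(lab)) >= 2) {
        silhouette_cosine(red, lab)$mean
      } else NA_real_
      pm <- partition_metrics(lab, truth)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, n_pc = npc,
        mean_best_enrichment_p = mean(best_p),
        mean_silhouette = sil,
        purity = pm$purity,
        inverse_purity = pm$inverse_purity,
        ari = pm$ari)
    }
  }
  do.call(rbind, rows)
}
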