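#' Fractional reference of a document with respect to a cluster
#'
#' The proportion of the proteins mapped to a document that belong to the
#' cluster under evaluation.
#'
#' @param doc_id document id.
#' @param cluster_proteins character vector of cluster protein ids.
#' @param corpus a `knowledge_corpus`.
#' @return numeric in [0, 1].
#' @export
fractional_reference <- function(doc_id, cluster_proteins, corpus) {
  mapped <- corpus$doc_proteins[[doc_id]]
  if (is.null(mapped) || !length(mapped)) {
    stop("document '", doc_id, "' maps to no proteins")
  }
  mean(mapped %in% cluster_proteins)
}

#' Score of a document with respect to a cluster
#'
#' Sum of the fractional references of the document's semantic neighbors.
#' Neighbors that map to no proteins contribute 0. With `m` neighbors the
#' score lies in `[0, m]`.
#'
#' @param doc_id document id present in the index.
#' @param cluster_proteins character vector of cluster protein ids.
#' @param index a `document_index`.
#' @param corpus a `knowledge_corpus`.
#' @return numeric score `>= 0`.
#' @export
document_score <- function(doc_id, cluster_proteins, index, corpus) {
  nb <- index$neighbors[[doc_id]]
  if (is.null(nb)) stop("document '", doc_id, "' is not in the index")
  in_cluster <- stats::setNames(rep(FALSE, length(corpus$proteins)), corpus$proteins)
  in_cluster[intersect(cluster_proteins, corpus$proteins)] <- TRUE
  s <- 0
  for (d in nb) {
    mapped <- corpus$doc_proteins[[d]]
    if (!is.null(mapped) && length(mapped)) s <- s + mean(in_cluster[mapped])
  }
  s
}

# KL divergence of the binned observed score distribution against a Poisson
# reference with rate lambda, evaluated over the occupied bins. Because the
# Poisson mass over a subset of bins sums to <= 1, this quantity is always
# >= 0 (Gibbs' inequality).
kl_vs_poisson <- function(scores, lambda_floor = 1e-6) {
  bins <- floor(scores)
  tab <- table(bins)
  p_obs <- as.numeric(tab) / length(bins)
  b <- as.numeric(names(tab))
  lambda <- max(mean(scores), lambda_floor)
  log_pois <- stats::dpois(b, lambda, log = TRUE)
  sum(p_obs * (log(p_obs) - log_pois))
}

#' Functional coherence of a protein cluster (NDPG)
#'
#' The neighbor-divergence-per-gene statistic: for every cluster protein,
#' each of its documents receives a [document_score()]; the scores are
#' floored into integer bins to form an observed distribution, which is
#' compared by Kullback-Leibler divergence to a Poisson reference whose
#' rate is the protein's mean observed score (floored at `1e-6`). The
#' functional coherence `F` is the mean KL divergence over the cluster
#' proteins that have at least one document; proteins without documents are
#' excluded from the mean and tallied. High `F` indicates that the
#' cluster's literature is shared and specific.
#'
#' @param cluster_proteins character vector of cluster protein ids.
#' @param index a `document_index` over the corpus documents.
#' @param corpus a `knowledge_corpus`.
#' @return An object of class `coherence_result`: `F` (mean KL, `>= 0`),
#'   `per_protein_kl` (named), `n_scored`, `n_excluded`,
#'   `proteins`.
#' @export
functional_coherence <- function(cluster_proteins, index, corpus) {
  cluster_proteins <- unique(as.character(cluster_proteins))
  in_cluster <- stats::setNames(rep(FALSE, length(corpus$proteins)), corpus$proteins)
  in_cluster[intersect(cluster_proteins, corpus$proteins)] <- TRUE

  # fractional reference of every document wrt this cluster, computed once
  frac <- vapply(corpus$doc_proteins,
                 function(mapped) mean(in_cluster[mapped]), numeric(1))

  kl <- c()
  n_excluded <- 0L
  for (p in cluster_proteins) {
    docs <- corpus$protein_docs[[p]]
    if (is.null(docs) || !length(docs)) {
      n_excluded <- n_excluded + 1L
      next
    }
    scores <- vapply(docs, function(d) {
      nb <- index$neighbors[[d]]
      if (is.null(nb)) return(NA_real_)
      f <- frac[nb]
      sum(f[!is.na(f)])
    }, numeric(1))
    scores <- scores[!is.na(scores)]
    if (!length(scores)) {
      n_excluded <- n_excluded + 1L
      next
    }
    kl[p] <- kl_vs_poisson(scores)
  }
  if (!length(kl)) stop("cluster is unscorable: no protein has any document")
  structure(list(F = mean(kl), per_protein_kl = kl,
                 n_scored = length(kl), n_excluded = n_excluded,
                 proteins = cluster_proteins),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat("Functional coherence F = ", signif(x$F, 5), " (", x$n_scored,
      " proteins scored, ", x$n_excluded, " without documents)\n", sep = "")
  invisible(x)
}

#' Write a coherence result to JSON
#' @param result a `coherence_result`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_coherence_json <- function(result, path) {
  jsonlite::write_json(
    list(F = result$F, n_scored = result$n_scored,
         n_excluded = result$n_excluded,
         per_protein_kl = as.list(result$per_protein_kl)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
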