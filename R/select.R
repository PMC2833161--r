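#' Scoring weights for tree-node selection
#'
#' The combined node score balances internal coherence (node correlation
#' `C`, bounded in [0, 1]) against external coherence (functional coherence
#' `F`, unbounded above), weighting the two approximately equally by
#' capping and normalizing `F`:
#'
#'   `S = N^n_exponent * (w_C * C + w_F * min(F, F_cap) / F_cap)`
#'
#' With the defaults `w_C = w_F = 0.5`, `F_cap = 10`, `n_exponent = 1`, the
#' score is linear in the cluster size `N` and strictly increasing in `C`
#' and in `F` below the cap.
#'
#' @param w_C,w_F weights of the two coherence terms.
#' @param F_cap value at which functional coherence saturates.
#' @param n_exponent exponent on the member count.
#' @return list of class `score_weights`.
#' @export
score_weights <- function(w_C = 0.5, w_F = 0.5, F_cap = 10, n_exponent = 1) {
  stopifnot(w_C >= 0, w_F >= 0, F_cap > 0)
  structure(list(w_C = w_C, w_F = w_F, F_cap = F_cap,
                 n_exponent = n_exponent), class = "score_weights")
}

#' Combined score of a tree node
#'
#' @param C node correlation in [0, 1] (vectorized).
#' @param F_coh functional coherence, `>= 0` (vectorized).
#' @param N member count, `>= 1` (vectorized).
#' @param weights a [score_weights()] configuration.
#' @return numeric score(s).
#' @export
score_node <- function(C, F_coh, N, weights = score_weights()) {
  if (any(C < -1e-9 | C > 1 + 1e-9)) stop("C must lie in [0, 1]")
  if (any(F_coh < 0)) stop("functional coherence must be >= 0")
  if (any(N < 1)) stop("N must be >= 1")
  C <- pmin(pmax(C, 0), 1)
  N^weights$n_exponent *
    (weights$w_C * C + weights$w_F * pmin(F_coh, weights$F_cap) / weights$F_cap)
}

#' Score every internal node of a merge tree
#'
#' Computes, for each internal node, the node correlation `C`, the
#' functional coherence `F` of the node's member proteins (0 when no corpus
#' is supplied — the external-knowledge off-switch — or when none of the
#' node's proteins has documents, with a warning), the member count `N`,
#' and the combined score `S`.
#'
#' @param tree a `merge_tree`.
#' @param ms the `microenv_set` the tree was built on.
#' @param corpus optional `knowledge_corpus`.
#' @param index optional `document_index` (required with `corpus`).
#' @param site_proteins character vector mapping each row of `ms` to a
#'   protein id; defaults to the site's structure_id.
#' @param weights a [score_weights()] configuration.
#' @return data.frame(node, C, F, N, S), one row per internal node.
#' @export
score_tree <- function(tree, ms, corpus = NULL, index = NULL,
                       site_proteins = NULL, weights = score_weights()) {
  stopifnot(inherits(tree, "merge_tree"))
  if (!is.null(corpus) && is.null(index)) {
    stop("a document index is required to score functional coherence")
  }
  if (is.null(site_proteins)) site_proteins <- ms$sites$structure_id
  n_nodes <- nrow(tree$merge)
  C <- numeric(n_nodes); Fv <- numeric(n_nodes); N <- integer(n_nodes)
  n_unscorable <- 0L
  for (nd in seq_len(n_nodes)) {
    C[nd] <- node_correlation(ms, tree, nd)
    idx <- tree_members(tree, nd)
    N[nd] <- length(idx)
    if (!is.null(corpus)) {
      prots <- unique(site_proteins[idx])
      res <- tryCatch(functional_coherence(prots, index, corpus),
                      error = function(e) NULL)
      if (is.null(res)) n_unscorable <- n_unscorable + 1L else Fv[nd] <- res$F
    }
  }
  if (n_unscorable > 0) {
    warning(n_unscorable, " node(s) had no protein with documents; ",
            "their functional coherence was scored 0")
  }
  data.frame(node = seq_len(n_nodes), C = C, F = Fv, N = N,
             S = score_node(C, Fv, N, weights))
}

#' Select an optimal disjoint set of tree nodes
#'
#' Bottom-up dynamic pass over the merge tree: a node becomes selected when
#' its score is strictly greater than the sum of the best selections in its
#' two branches, in which case all its descendants are deselected; on ties
#' the descendant selection is kept. Leaves score 0 unless scores are
#' provided for them. The result is a disjoint antichain of nodes
#' maximizing total score under this rule.
#'
#' @param tree a `merge_tree`.
#' @param node_scores data.frame with columns `node` and `S` covering every
#'   internal node (as from [score_tree()]).
#' @param leaf_scores optional numeric vector of per-leaf scores
#'   (default all 0).
#' @return integer vector of selected internal node ids (attribute
#'   `total` = attained total score; attribute `leaves` = selected leaf
#'   positions, normally empty).
#' @export
select_clusters <- function(tree, node_scores, leaf_scores = NULL) {
  stopifnot(inherits(tree, "merge_tree"))
  n_nodes <- nrow(tree$merge)
  S <- rep(NA_real_, n_nodes)
  S[node_scores$node] <- node_scores$S
  if (anyNA(S)) stop("unscored internal node(s): ",
                     paste(which(is.na(S)), collapse = ", "))
  if (is.null(leaf_scores)) leaf_scores <- numeric(tree$n_leaves)

  best <- numeric(n_nodes)
  sel <- vector("list", n_nodes)        # selected node ids below (and incl.)
  sel_leaves <- vector("list", n_nodes)
  child_val <- function(ch) {
    if (ch < 0) leaf_scores[-ch] else best[ch]
  }
  child_sel <- function(ch) {
    if (ch < 0) {
      if (leaf_scores[-ch] > 0) list(nodes = integer(0), leaves = -ch)
      else list(nodes = integer(0), leaves = integer(0))
    } else list(nodes = sel[[ch]], leaves = sel_leaves[[ch]])
  }
  for (nd in seq_len(n_nodes)) {        # merge order: children precede parents
    l <- tree$merge[nd, 1]; r <- tree$merge[nd, 2]
    below <- child_val(l) + child_val(r)
    if (S[nd] > below) {                # strictly greater: take the node
      best[nd] <- S[nd]
      sel[[nd]] <- nd
      sel_leaves[[nd]] <- integer(0)
    } else {                            # keep the descendant selection
      best[nd] <- below
      ls <- child_sel(l); rs <- child_sel(r)
      sel[[nd]] <- c(ls$nodes, rs$nodes)
      sel_leaves[[nd]] <- c(ls$leaves, rs$leaves)
    }
  }
  root <- n_nodes
  out <- sort(sel[[root]])
  # selected nodes must be pairwise disjoint
  memb <- lapply(out, function(nd) tree$members[[nd]])
  if (length(memb) > 1) {
    all_m <- unlist(memb)
    stopifnot(!anyDuplicated(all_m))
  }
  attr(out, "total") <- best[root]
  attr(out, "leaves") <- sort(sel_leaves[[root]])
  out
}

#' Assemble cluster records for selected nodes
#'
#' @param tree a `merge_tree`.
#' @param selected integer vector of selected node ids.
#' @param node_scores data.frame from [score_tree()].
#' @param ms the underlying `microenv_set`.
#' @param site_proteins per-site protein ids (defaults to structure_id).
#' @param coarse_id coarse-cluster id used in the cluster name
#'   `Clust<coarse>-Sub<node>`.
#' @return data.frame with one row per cluster: `cluster_id`, `coarse_id`,
#'   `node`, `C`, `F`, `N`, `S`, and list columns `site_idx` (row indices
#'   into `ms`), `sites` (site keys) and `proteins`.
#' @export
cluster_records <- function(tree, selected, node_scores, ms,
                            site_proteins = NULL, coarse_id = 1L) {
  if (is.null(site_proteins)) site_proteins <- ms$sites$structure_id
  keys <- site_key(ms$sites)
  rows <- lapply(selected, function(nd) {
    idx <- tree_members(tree, nd)
    sc <- node_scores[node_scores$node == nd, ]
    data.frame(cluster_id = sprintf("Clust%s-Sub%d", coarse_id, nd),
               coarse_id = as.character(coarse_id), node = nd,
               C = sc$C, F = sc$F, N = length(idx), S = sc$S,
               site_idx = I(list(idx)),
               sites = I(list(keys[idx])),
               proteins = I(list(sort(unique(site_proteins[idx])))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cluster_id = character(), coarse_id = character(),
                      node = integer(), C = numeric(), F = numeric(),
                      N = integer(), S = numeric(),
                      site_idx = I(list()), sites = I(list()),
                      proteins = I(list()), stringsAsFactors = FALSE)
  }
  out
}

#' Filter cluster records by size and functional coherence
#'
#' Keeps clusters with at least `min_size` microenvironments and functional
#' coherence strictly greater than `fc_cutoff`. With `complement = TRUE`
#' the clusters that meet the size requirement but fail the coherence
#' cutoff are returned instead (the "high internal correlation, low
#' functional coherence" list).
#'
#' @param records data.frame of cluster records with columns `N` and `F`.
#' @param min_size minimum member count (default 5).
#' @param fc_cutoff functional-coherence cutoff, strict (default 3.0).
#' @param complement return the size-passing, coherence-failing records.
#' @return filtered data.frame.
#' @export
filter_clusters <- function(records, min_size = 5L, fc_cutoff = 3.0,
                            complement = FALSE) {
  size_ok <- records$N >= min_size
  fc_ok <- records$F > fc_cutoff
  keep <- if (complement) size_ok & !fc_ok else size_ok & fc_ok
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-clustering stability check
#'
#' Pools the member sites of a set of selected clusters (possibly from
#' different coarse clusters), rebuilds a single tree over the pooled set,
#' re-runs scoring and selection, and reports how faithfully the original
#' clusters are reproduced. A site is a "singleton" when it is not covered
#' by any newly selected cluster; an original cluster is recovered exactly
#' when some new cluster has the identical member set, and recovered up to
#' singletons when a new cluster equals the original minus its singleton
#' sites.
#'
#' @param records data.frame of cluster records (with `site_idx`).
#' @param ms the underlying `microenv_set`.
#' @param corpus,index optional literature evidence (as in [score_tree()]).
#' @param site_proteins per-site protein ids.
#' @param weights a [score_weights()] configuration.
#' @return list with `per_cluster` (data.frame: cluster_id,
#'   exact, up_to_singletons, n_singletons), counts `recovered`, `changed`,
#'   `singletons` (site counts summing to the pooled total), and the new
#'   selection's member sets.
#' @export
recluster_stability <- function(records, ms, corpus = NULL, index = NULL,
                                site_proteins = NULL,
                                weights = score_weights()) {
  if (nrow(records) < 1) stop("no clusters to pool")
  pooled <- sort(unique(unlist(records$site_idx)))
  if (length(pooled) < 2) stop("pooled set has fewer than 2 sites")
  tree <- hac_cosine(ms, members = pooled)
  scores <- score_tree(tree, ms, corpus = corpus, index = index,
                       site_proteins = site_proteins, weights = weights)
  sel <- select_clusters(tree, scores)
  new_sets <- lapply(sel, function(nd) sort(tree_members(tree, nd)))
  covered <- unlist(new_sets)
  singleton_sites <- setdiff(pooled, covered)

  per <- lapply(seq_len(nrow(records)), function(i) {
    orig <- sort(records$site_idx[[i]])
    exact <- any(vapply(new_sets, function(s) identical(s, orig), logical(1)))
    lost <- intersect(orig, singleton_sites)
    trimmed <- setdiff(orig, lost)
    upto <- exact || (length(trimmed) > 0 &&
      any(vapply(new_sets, function(s) identical(s, sort(trimmed)), logical(1))))
    data.frame(cluster_id = records$cluster_id[i], exact = exact,
               up_to_singletons = upto, n_singletons = length(lost),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  recovered_sites <- length(setdiff(
    unique(unlist(records$site_idx[which(per$up_to_singletons)])),
    singleton_sites))
  changed <- length(pooled) - recovered_sites - length(singleton_sites)
  list(per_cluster = per,
       recovered = recovered_sites,
       changed = changed,
       singletons = length(singleton_sites),
       total = length(pooled),
       new_member_sets = new_sets)
}

#' Write selected cluster records to TSV and JSON
#' @param records cluster records data.frame.
#' @param tsv_path,json_path output paths (NULL to skip one).
#' @return invisibly, the written paths.
#' @export
write_records <- function(records, tsv_path = NULL, json_path = NULL) {
  flat <- records
  flat$site_idx <- NULL
  flat$sites <- vapply(records$sites, paste, character(1), collapse = ",")
  flat$proteins <- vapply(records$proteins, paste, character(1), collapse = ",")
  if (!is.null(tsv_path)) {
    utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    j <- lapply(seq_len(nrow(records)), function(i) {
      list(cluster_id = records$cluster_id[i], C = records$C[i],
           F = records$F[i], N = records$N[i], S = records$S[i],
           sites = records$sites[[i]], proteins = records$proteins[[i]])
    })
    jsonlite::write_json(j, json_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(c(tsv_path, json_path))
}
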