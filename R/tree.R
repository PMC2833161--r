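#' Agglomerative hierarchical clustering under cosine distance
#'
#' Builds the exact agglomeration tree for a subset of microenvironment
#' vectors, merging the closest pair of clusters at each step under the
#' chosen linkage (single by default, the configuration used throughout the
#' pipeline; complete and average are available for parameter sweeps).
#' Distances are `1 - cosine similarity` between unit-normalized rows.
#'
#' Ties are broken deterministically: every active cluster is represented
#' by its smallest leaf index, and among all pairs at the minimum distance
#' the pair whose (smaller representative, larger representative) is
#' lexicographically smallest is merged.
#'
#' @param ms a `microenv_set` (or plain matrix).
#' @param members indices of the rows to cluster (default all). At least 2.
#' @param linkage one of `"single"`, `"complete"`, `"average"`.
#' @return An object of class `merge_tree`: `n_leaves`; `leaf_sites`
#'   (row indices into `ms`, leaf order = input order of `members`);
#'   `merge` ((n-1) x 2, negative entries are leaves, positive entries
#'   earlier merge nodes, as in [stats::hclust()]); `height`
#'   (merge distance per node); `members` (per node, sorted leaf
#'   positions); `linkage`. The root is node `n_leaves - 1`.
#' @export
hac_cosine <- function(ms, members = NULL,
                       linkage = c("single", "complete", "average")) {
  linkage <- match.arg(linkage)
  x <- if (inherits(ms, "microenv_set")) ms$features else as.matrix(ms)
  if (is.null(members)) members <- seq_len(nrow(x))
  n <- length(members)
  if (n < 2) stop("need at least 2 members to build a tree")
  d <- cosine_dist_matrix(x[members, , drop = FALSE])
  diag(d) <- Inf

  active <- rep(TRUE, n)
  rep_leaf <- seq_len(n)          # smallest leaf index in each active slot
  node_of <- -seq_len(n)          # hclust coding: leaf i is -i
  size <- rep(1L, n)
  memb <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members_out <- vector("list", n - 1L)

  for (s in seq_len(n - 1L)) {
    act <- which(active)
    sub <- d[act, act, drop = FALSE]
    m <- min(sub)
    hit <- which(sub == m, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    # deterministic tie-break on representative leaf indices
    ra <- rep_leaf[act[hit[, 1]]]; rb <- rep_leaf[act[hit[, 2]]]
    lo <- pmin(ra, rb); hi <- pmax(ra, rb)
    pick <- order(lo, hi)[1]
    i <- act[hit[pick, 1]]; j <- act[hit[pick, 2]]
    if (rep_leaf[j] < rep_leaf[i]) { tmp <- i; i <- j; j <- tmp }

    merge[s, ] <- sort_merge_pair(node_of[i], node_of[j])
    height[s] <- m
    members_out[[s]] <- sort(c(memb[[i]], memb[[j]]))

    # Lance-Williams update into slot i
    di <- d[i, ]; dj <- d[j, ]
    newd <- switch(linkage,
                   single = pmin(di, dj),
                   complete = pmax(di, dj),
                   average = (size[i] * di + size[j] * dj) / (size[i] + size[j]))
    d[i, ] <- newd; d[, i] <- newd
    d[i, i] <- Inf
    active[j] <- FALSE
    d[j, ] <- Inf; d[, j] <- Inf
    size[i] <- size[i] + size[j]
    memb[[i]] <- members_out[[s]]
    node_of[i] <- s
  }
  if (linkage == "single") {
    # single linkage heights are non-decreasing by construction
    stopifnot(all(diff(height) >= -1e-12))
  }
  structure(list(n_leaves = n, leaf_sites = members, merge = merge,
                 height = height, members = members_out, linkage = linkage),
            class = "merge_tree")
}

# hclust convention: leaves (negative) before internal nodes; leaves by
# ascending leaf index, nodes by ascending node id
sort_merge_pair <- function(a, b) {
  if (a < 0 && b < 0) return(c(-min(-a, -b), -max(-a, -b)))
  if (a < 0) return(c(a, b))
  if (b < 0) return(c(b, a))
  c(min(a, b), max(a, b))
}

#' @export
print.merge_tree <- function(x, ...) {
  cat("Agglomeration tree (", x$linkage, " linkage, cosine distance): ",
      x$n_leaves, " leaves, ", nrow(x$merge), " nodes\n", sep = "")
  cat("  merge distance range: ", signif(min(x$height), 4), " .. ",
      signif(max(x$height), 4), "\n", sep = "")
  invisible(x)
}

#' Leaf sites below a tree node
#'
#' @param tree a `merge_tree`.
#' @param node positive internal node id (1-based merge order) or a
#'   negative leaf id `-i` for leaf position `i`.
#' @return site row indices (into the original set) in leaf order.
#' @export
tree_members <- function(tree, node) {
  stopifnot(inherits(tree, "merge_tree"))
  if (node < 0) {
    i <- -node
    if (i > tree$n_leaves) stop("unknown leaf ", i)
    return(tree$leaf_sites[i])
  }
  if (node < 1 || node > nrow(tree$merge)) stop("unknown node ", node)
  tree$leaf_sites[tree$members[[node]]]
}

#' Node correlation: similarity of the two branches at a node
#'
#' The internal coherence of an internal node is measured as the cosine
#' similarity between the unit-normalized mean vectors of its left-branch
#' and right-branch members, clamped to [0, 1].
#'
#' @param ms the `microenv_set` the tree was built on.
#' @param tree a `merge_tree`.
#' @param node internal node id (positive).
#' @return numeric in [0, 1].
#' @export
node_correlation <- function(ms, tree, node) {
  stopifnot(inherits(tree, "merge_tree"))
  if (node < 1 || node > nrow(tree$merge)) {
    stop("node_correlation is defined for internal nodes only")
  }
  x <- if (inherits(ms, "microenv_set")) ms$features else as.matrix(ms)
  branch_mean <- function(child) {
    idx <- if (child < 0) tree$leaf_sites[-child] else
      tree$leaf_sites[tree$members[[child]]]
    u <- unit_rows(x[idx, , drop = FALSE])
    colMeans(u)
  }
  cl <- cosine_sim(branch_mean(tree$merge[node, 1]),
                   branch_mean(tree$merge[node, 2]))
  min(max(cl, 0), 1)
}

#' Export a merge tree in a Cluster-3.0-like .gtr tab format
#'
#' One row per internal node: node id, left child, right child, similarity
#' (`1 - merge distance`). Children are written as `NODEk` / `LEAFi`.
#'
#' @param tree a `merge_tree`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_tree_tsv <- function(tree, path) {
  lab <- function(v) ifelse(v < 0, paste0("LEAF", -v), paste0("NODE", v))
  df <- data.frame(node = paste0("NODE", seq_len(nrow(tree$merge))),
                   left = lab(tree$merge[, 1]),
                   right = lab(tree$merge[, 2]),
                   similarity = 1 - tree$height)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
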