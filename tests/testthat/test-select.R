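test_that("node scoring follows the capped-normalized combination", {
  expect_equal(score_node(0, 0, 5), 0)
  expect_equal(score_node(0, 0, 100), 0)
  # linear in N
  expect_equal(score_node(0.7, 2, 10), 2 * score_node(0.7, 2, 5))
  # C = 1 and F at/above the cap saturate at S = N under the defaults
  expect_equal(score_node(1, 10, 5), 5)
  expect_equal(score_node(1, 25, 5), 5)
  # strictly increasing in C and in F below the cap
  expect_gt(score_node(0.6, 2, 5), score_node(0.5, 2, 5))
  expect_gt(score_node(0.5, 3, 5), score_node(0.5, 2, 5))
  expect_equal(score_node(0.5, 11, 5), score_node(0.5, 12, 5))
  expect_error(score_node(0.5, -1, 5), "coherence")
  expect_error(score_node(1.5, 0, 5), "\\[0, 1\\]")
  # configurable weights
  w <- score_weights(w_C = 1, w_F = 0, F_cap = 5, n_exponent = 0)
  expect_equal(score_node(0.3, 99, 7, w), 0.3)
})

test_that("a dominant root or dominant children decide selection", {
  x <- rbind(c(1, 0), c(0.9, 0.1), c(0, 1), c(0.1, 0.9))
  tree <- hac_cosine(ms_from_matrix(x))
  n_nodes <- nrow(tree$merge)
  # root strictly above the children's sum -> root alone
  sc <- data.frame(node = 1:n_nodes, S = c(1, 1, 3))
  expect_equal(as.integer(select_clusters(tree, sc)), n_nodes)
  # root not strictly greater -> children kept (tie goes to descendants)
  sc$S <- c(1, 1, 2)
  expect_equal(as.integer(select_clusters(tree, sc)), c(1, 2))
  expect_error(select_clusters(tree, sc[-1, ]), "unscored")
})

test_that("selection total matches exhaustive antichain enumeration", {
  set.seed(51)
  for (rep in 1:30) {
    n <- sample(5:8, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    tree <- hac_cosine(ms_from_matrix(x))
    S <- round(runif(nrow(tree$merge), 0, 10), 2)
    sel <- select_clusters(tree, data.frame(node = seq_along(S), S = S))
    expect_equal(attr(sel, "total"), best_antichain_total(tree, S),
                 tolerance = 1e-12)
    # selected nodes are pairwise disjoint
    memb <- unlist(tree$members[as.integer(sel)])
    expect_equal(anyDuplicated(memb), 0)
  }
})

test_that("selection is invariant to the order nodes are listed", {
  set.seed(52)
  x <- matrix(rnorm(8 * 3), 8, 3)
  tree <- hac_cosine(ms_from_matrix(x))
  sc <- data.frame(node = seq_len(nrow(tree$merge)),
                   S = runif(nrow(tree$merge), 0, 5))
  sel1 <- select_clusters(tree, sc)
  sel2 <- select_clusters(tree, sc[sample(nrow(sc)), ])
  expect_equal(as.integer(sel1), as.integer(sel2))
})

test_that("with coherence off, selection is driven by C and N alone", {
  gen <- gen_vectors(sizes = c(20, 20), dim = 10, separation_deg = 70,
                     noise = 0.1, seed = 55)
  tree <- hac_cosine(gen$ms)
  sc <- score_tree(tree, gen$ms)            # no corpus: F is identically 0
  expect_true(all(sc$F == 0))
  sel <- select_clusters(tree, sc)
  sets <- lapply(as.integer(sel), function(nd) sort(tree_members(tree, nd)))
  expect_true(any(vapply(sets, identical, logical(1), y = 1:20)))
  expect_true(any(vapply(sets, identical, logical(1), y = 21:40)))
})

test_that("size and coherence filters apply strict thresholds", {
  rec <- data.frame(N = c(4, 5, 5, 10, 12, 6, 7, 9, 5, 3),
                    F = c(9, 3.0, 3.01, 2.9, 8, 0, 3.5, 2, 4, 9))
  kept <- filter_clusters(rec)
  # manual count: rows with N >= 5 and F > 3.0 -> rows 3, 5, 7, 9
  expect_equal(nrow(kept), 4)
  expect_equal(kept$F, c(3.01, 8, 3.5, 4))
  # N = 4 dropped; F = 3.0 exactly dropped (strict)
  expect_false(any(kept$N < 5))
  expect_false(any(kept$F == 3.0))
  # complementary high-C low-F list: size passes, coherence fails
  comp <- filter_clusters(rec, complement = TRUE)
  expect_equal(nrow(comp), 4)
  expect_true(all(comp$F <= 3.0 & comp$N >= 5))
  # thresholds configurable
  expect_equal(nrow(filter_clusters(rec, min_size = 1, fc_cutoff = -1)), 10)
})

test_that("cluster records carry the naming convention and member sets", {
  gen <- gen_vectors(sizes = c(10, 10), dim = 8, separation_deg = 70,
                     noise = 0.1, seed = 57)
  tree <- hac_cosine(gen$ms)
  sc <- score_tree(tree, gen$ms)
  sel <- select_clusters(tree, sc)
  rec <- cluster_records(tree, sel, sc, gen$ms, coarse_id = 7)
  expect_true(all(grepl("^Clust7-Sub[0-9]+$", rec$cluster_id)))
  expect_equal(rec$N, lengths(rec$site_idx))
  expect_equal(rec$N, lengths(rec$sites))
})

test_that("pooling well-separated clusters reproduces them exactly", {
  gen <- gen_vectors(sizes = c(25, 25), dim = 20, separation_deg = 70,
                     noise = 0.1, seed = 58)
  # select within each planted cluster separately, then pool
  recs <- list()
  for (g in 1:2) {
    tree <- hac_cosine(gen$ms, members = which(gen$labels == g))
    sc <- score_tree(tree, gen$ms)
    sel <- select_clusters(tree, sc)
    recs[[g]] <- cluster_records(tree, sel, sc, gen$ms, coarse_id = g)
  }
  records <- do.call(rbind, recs)
  rep <- recluster_stability(records, gen$ms)
  expect_true(all(rep$per_cluster$exact))
  expect_equal(rep$singletons, 0)
  expect_equal(rep$recovered + rep$changed + rep$singletons, rep$total)
})

test_that("pooling a cluster with itself recovers it unchanged", {
  gen <- gen_vectors(sizes = c(12), dim = 8, separation_deg = 0,
                     noise = 0.1, seed = 59)
  tree <- hac_cosine(gen$ms)
  sc <- score_tree(tree, gen$ms)
  sel <- select_clusters(tree, sc)
  rec <- cluster_records(tree, sel, sc, gen$ms, coarse_id = 1)
  rep <- recluster_stability(rbind(rec, rec), gen$ms)
  expect_true(all(rep$per_cluster$exact))
  expect_equal(rep$recovered, rep$total)
})
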