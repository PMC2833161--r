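test_that("corpus construction validates and excludes large-scale documents", {
  docs <- data.frame(document_id = c("d1", "d2", "d3"),
                     title = c("x", "y", "z"), abstract = c("", "", ""),
                     large_scale = c(0, 0, 1))
  map <- data.frame(protein_id = c("A", "A", "B"),
                    document_id = c("d1", "d3", "d2"))
  corpus <- knowledge_corpus(docs, map)
  expect_equal(corpus$n_large_scale_excluded, 1)
  expect_false("d3" %in% corpus$documents$document_id)
  expect_equal(corpus$protein_docs$A, "d1")
  # maps are mutually consistent
  for (p in names(corpus$protein_docs)) {
    for (d in corpus$protein_docs[[p]]) {
      expect_true(p %in% corpus$doc_proteins[[d]])
    }
  }
  expect_error(knowledge_corpus(docs[1, ], map), "unknown document")
})

test_that("corpus files round-trip through the TSV/JSONL adapters", {
  corpus <- tiny_corpus()
  map_p <- tempfile(fileext = ".tsv"); doc_p <- tempfile(fileext = ".jsonl")
  write_corpus(corpus, map_p, doc_p)
  back <- read_corpus(map_p, doc_p)
  expect_equal(back$protein_docs, corpus$protein_docs)
  expect_equal(back$documents$abstract, corpus$documents$abstract)
})

test_that("a two-document corpus has each document as the other's neighbor", {
  docs <- data.frame(document_id = c("d1", "d2"),
                     title = c("alpha beta", "alpha gamma"),
                     abstract = c("", ""))
  map <- data.frame(protein_id = c("A", "B"), document_id = c("d1", "d2"))
  idx <- build_index(knowledge_corpus(docs, map), m = 20)
  expect_equal(idx$m, 1)
  expect_equal(idx$neighbors$d1, "d2")
  expect_equal(idx$neighbors$d2, "d1")
})

test_that("identical documents are mutual top neighbors at similarity 1", {
  docs <- data.frame(document_id = c("d1", "d2", "d3"),
                     title = c("copper binding protein",
                               "copper binding protein",
                               "ribosome maturation factor"),
                     abstract = c("", "", ""))
  map <- data.frame(protein_id = c("A", "B", "C"),
                    document_id = c("d1", "d2", "d3"))
  idx <- build_index(knowledge_corpus(docs, map), m = 2)
  expect_equal(idx$neighbors$d1[1], "d2")
  expect_equal(idx$neighbor_sims$d1[1], 1, tolerance = 1e-12)
})

test_that("neighbor ranking matches an independent tf-idf computation", {
  corpus <- tiny_corpus()
  idx <- build_index(corpus, m = 5)
  for (i in c(1, 4, 6)) {
    ord <- naive_doc_ranking(corpus, i)
    expect_equal(idx$neighbors[[corpus$documents$document_id[i]]],
                 corpus$documents$document_id[ord[1:5]])
  }
})

test_that("semantic neighbors stay within topic on a two-topic corpus", {
  gc <- gen_corpus(6, c(1, 1, 1, 2, 2, 2), vocab_size = 500,
                   docs_per_protein = 5, offtopic_fraction = 0,
                   overlap_across = 0, seed = 9)
  idx <- build_index(gc$corpus, m = 5)
  topic_of_doc <- gc$truth$topic[
    vapply(idx$doc_ids, function(d) gc$corpus$doc_proteins[[d]][1], "")]
  agree <- vapply(seq_along(idx$doc_ids), function(i) {
    nb_topics <- topic_of_doc[match(idx$neighbors[[i]], idx$doc_ids)]
    mean(nb_topics == topic_of_doc[i])
  }, numeric(1))
  expect_gte(mean(agree), 0.9)
})

test_that("fractional reference is the in-cluster share of mapped proteins", {
  docs <- data.frame(document_id = "d1", title = "t", abstract = "a")
  map <- data.frame(protein_id = c("A", "B", "C", "D"), document_id = "d1")
  corpus <- knowledge_corpus(docs, map)
  expect_equal(fractional_reference("d1", c("A"), corpus), 0.25)
  expect_equal(fractional_reference("d1", c("A", "B", "C", "D"), corpus), 1)
  expect_equal(fractional_reference("d1", c("Z"), corpus), 0)
  expect_error(fractional_reference("dX", "A", corpus), "maps to no")
})

test_that("document score sums neighbor fractional references", {
  # 5 documents; d1's neighbors and their protein maps are fully known
  docs <- data.frame(
    document_id = sprintf("d%d", 1:5),
    title = c("zinc finger motif", "zinc finger domain", "zinc motif",
              "calcium channel", "calcium pump"),
    abstract = "")
  map <- data.frame(
    protein_id = c("A", "B", "B", "C", "C", "D", "E"),
    document_id = c("d1", "d2", "d3", "d3", "d4", "d4", "d5"))
  corpus <- knowledge_corpus(docs, map)
  idx <- build_index(corpus, m = 2)
  cl <- c("A", "B")
  nb <- idx$neighbors$d1
  hand <- sum(vapply(nb, function(d) {
    mapped <- corpus$doc_proteins[[d]]
    mean(mapped %in% cl)
  }, numeric(1)))
  expect_equal(document_score("d1", cl, idx, corpus), hand)
  # all neighbors outside the cluster contribute 0
  expect_equal(document_score("d5", c("Z"), idx, corpus), 0)
})

test_that("KL kernel is non-negative and vanishes in the degenerate limit", {
  # all scores 0: single bin at 0, Poisson rate at floor -> KL ~ 0
  expect_lt(foresite:::kl_vs_poisson(c(0, 0, 0)), 1e-3)
  set.seed(41)
  for (i in 1:20) {
    scores <- rpois(10, sample(1:8, 1)) + runif(10)
    expect_gte(foresite:::kl_vs_poisson(scores), 0)
  }
})

test_that("functional coherence averages per-protein KL and tallies exclusions", {
  corpus <- tiny_corpus()
  idx <- build_index(corpus, m = 3)
  res <- functional_coherence(c("A", "B", "C"), idx, corpus)
  expect_s3_class(res, "coherence_result")
  expect_gte(res$F, 0)
  expect_equal(res$F, mean(res$per_protein_kl))
  expect_equal(res$n_scored, 3)
  # a protein absent from the corpus is excluded, not scored
  res2 <- functional_coherence(c("A", "B", "NOPE"), idx, corpus)
  expect_equal(res2$n_excluded, 1)
  expect_equal(res2$n_scored, 2)
  expect_error(functional_coherence("NOPE", idx, corpus), "unscorable")
})

test_that("coherence is invariant to protein and document order", {
  gc <- gen_corpus(12, rep(c(1, 2, 0), each = 4), vocab_size = 500, seed = 6)
  idx <- build_index(gc$corpus, m = 10)
  cl <- names(gc$truth$topic)[gc$truth$topic == 1]
  f1 <- functional_coherence(cl, idx, gc$corpus)$F
  f2 <- functional_coherence(rev(cl), idx, gc$corpus)$F
  expect_identical(f1, f2)
})

test_that("planted coherent clusters outscore random clusters", {
  gc <- gen_corpus(40, rep(c(1, 2, 3, 4, 0), each = 8), vocab_size = 1000,
                   seed = 13)
  idx <- build_index(gc$corpus, m = 10)
  prots <- names(gc$truth$topic)
  coherent <- vapply(1:4, function(t) {
    functional_coherence(prots[gc$truth$topic == t], idx, gc$corpus)$F
  }, numeric(1))
  rnd <- make_random_clusters(prots, sizes = rep(8, 40), seed = 14)
  random_f <- vapply(rnd, function(cl) {
    functional_coherence(cl, idx, gc$corpus)$F
  }, numeric(1))
  expect_gt(median(coherent), quantile(random_f, 0.95))
})

test_that("median coherence does not increase as signal is diluted", {
  gc <- gen_corpus(30, c(rep(1, 10), rep(0, 20)), vocab_size = 800, seed = 17)
  idx <- build_index(gc$corpus, m = 10)
  prots <- names(gc$truth$topic)
  base <- prots[gc$truth$topic == 1]
  pool <- prots[gc$truth$topic == 0]
  series <- make_dilution_series(base, pool, mode = "fixed",
                                 fractions = c(1, 0.8, 0.6, 0.4, 0.2),
                                 n_replicates = 15, seed = 18)
  curve <- coherence_curve(series, idx, gc$corpus)
  expect_true(all(diff(curve$median_F) <= 0.1))   # small replicate noise
  expect_equal(curve$fraction, c(1, 0.8, 0.6, 0.4, 0.2))
})
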