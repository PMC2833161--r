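test_that("tokenizer lowercases, keeps hyphens and strips stop words", {
  expect_equal(tokenize("Zinc-binding in proteins"),
               c("zinc-binding", "proteins"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("Copper binding, blue copper proteins."),
               c("copper", "binding", "blue", "copper", "proteins"))
  # punctuation splits; leading/trailing hyphens do not survive
  expect_equal(tokenize("beta-barrel (trans-membrane)!"),
               c("beta-barrel", "trans-membrane"))
  expect_equal(tokenize("- the --- of -"), character(0))
})

test_that("ngrams yields distinct unigrams and consecutive bigrams", {
  expect_equal(ngrams(c("a", "b", "c"))$bigrams, c("a b", "b c"))
  expect_equal(ngrams("solo")$bigrams, character(0))
  toks <- tokenize("Copper binding, blue copper proteins.")
  ng <- ngrams(toks)
  expect_setequal(ng$unigrams, c("copper", "binding", "blue", "proteins"))
  expect_setequal(ng$bigrams,
                  c("copper binding", "binding blue", "blue copper",
                    "copper proteins"))
})

test_that("hypergeometric tail agrees with exact enumeration", {
  expect_equal(hypergeom_pvalue(0, 4, 5, 10), 1)
  expect_equal(hypergeom_pvalue(3, 7, 10, 10), 1)   # K = M
  expect_equal(hypergeom_pvalue(3, 4, 5, 10), 55 / 210, tolerance = 1e-12)
  set.seed(61)
  for (i in 1:50) {
    M <- sample(2:25, 1); K <- sample(0:M, 1); n <- sample(1:M, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_pvalue(k, n, K, M), hyper_upper_enum(k, n, K, M),
                 tolerance = 1e-10)
  }
  expect_error(hypergeom_pvalue(5, 4, 10, 20), "exceed")
  expect_error(hypergeom_pvalue(1, 30, 10, 20), "exceed")
})


test_that("entropy score rewards terms spread across proteins", {
  corpus <- entropy_fixture()
  idx <- build_index(corpus, m = 3)
  tab <- cluster_term_entropy(c("A", "B", "C"), corpus, idx,
                              which = "unigram")
  # alpha: cluster docs containing it = d1,d2,d5,d6 -> D = (0.5, 0.25, 0.25)
  h_alpha <- -(0.5 * log(0.5) + 2 * 0.25 * log(0.25))
  expect_equal(tab$H[tab$term == "alpha"], h_alpha, tolerance = 1e-10)
  expect_equal(h_alpha, 1.0397, tolerance = 1e-4)
  # beta: all four docs belong to protein A -> H = 0 -> score 0
  expect_equal(tab$H[tab$term == "beta"], 0)
  expect_equal(tab$score[tab$term == "beta"], 0)
  # normalization is by the maximum pre-idf entropy over cluster terms
  expect_equal(max(tab$H_norm), 1)
  idf_alpha <- log(8 / 4)
  expect_equal(tab$score[tab$term == "alpha"],
               (h_alpha / max(tab$H)) * idf_alpha, tolerance = 1e-10)
  expect_equal(entropy_score("beta", c("A", "B", "C"), corpus, idx), 0)
  expect_error(entropy_score("nonexistent", c("A", "B"), corpus, idx),
               "does not occur")
})

test_that("a term spread uniformly over 4 proteins has entropy ln 4", {
  docs <- data.frame(document_id = sprintf("d%d", 1:8),
                     title = c(rep("shared motif", 4), "p", "q", "r", "s"),
                     abstract = "")
  map <- data.frame(protein_id = c("A", "B", "C", "D", "A", "B", "C", "D"),
                    document_id = sprintf("d%d", 1:8))
  corpus <- knowledge_corpus(docs, map)
  idx <- build_index(corpus, m = 3)
  tab <- cluster_term_entropy(c("A", "B", "C", "D"), corpus, idx,
                              which = "unigram")
  expect_equal(tab$H[tab$term == "shared"], log(4), tolerance = 1e-10)
  expect_equal(log(4), 1.3863, tolerance = 1e-4)
})

test_that("entropy score is invariant to protein order", {
  corpus <- entropy_fixture()
  idx <- build_index(corpus, m = 3)
  t1 <- cluster_term_entropy(c("A", "B", "C"), corpus, idx)
  t2 <- cluster_term_entropy(c("C", "A", "B"), corpus, idx)
  t2 <- t2[match(t1$term, t2$term), ]
  expect_equal(t1$score, t2$score)
})

test_that("an implanted keyword is recovered with corrected significance", {
  n_prot <- 200L
  implant <- data.frame(protein_id = sprintf("P%04d", 1:8),
                        category = "keyword", term = "implanted-motif")
  extra <- data.frame(protein_id = sprintf("P%04d", 1:60),
                      category = "keyword",
                      term = rep(sprintf("common%d", 1:3), 20))
  gc <- gen_corpus(n_prot, c(rep(1, 8), rep(0, 192)), vocab_size = 1500,
                   implant = rbind(implant, extra), seed = 71)
  cl <- sprintf("P%04d", 1:8)
  ann <- annotate_cluster(cl, gc$corpus, categories = "keyword")
  expect_equal(ann$term[1], "implanted-motif")
  expect_equal(ann$k[1], 8); expect_equal(ann$K[1], 8)
  expect_equal(ann$M[1], 200)
  expect_lt(ann$p_corrected[1], 0.01)
  # exact value: p_raw = 1 / choose(200, 8) corrected by terms in cluster
  expect_equal(ann$p_raw[1], 1 / choose(200, 8) *
                 choose(192, 0) * choose(8, 8), tolerance = 1e-12)
})

test_that("ubiquitous terms are never significant and correction is sane", {
  docs <- data.frame(document_id = c("d1", "d2"), title = c("x", "y"),
                     abstract = "")
  map <- data.frame(protein_id = c("A", "B"), document_id = c("d1", "d2"))
  terms <- data.frame(protein_id = c("A", "B", "C", "D"),
                      category = "keyword", term = "everywhere")
  corpus <- knowledge_corpus(docs, map, terms,
                             proteins = c("A", "B", "C", "D"))
  ann <- annotate_cluster(c("A", "B"), corpus, categories = "keyword",
                          keep_all = TRUE)
  expect_equal(ann$p_raw, 1)           # K = M
  expect_false(any(ann$significant))
  # single tested term: correction factor 1
  expect_equal(ann$p_corrected, ann$p_raw)
  expect_true(all(ann$p_corrected >= ann$p_raw))
})

test_that("background-only proteins affect annotation only through M and K", {
  terms <- data.frame(protein_id = c("A", "B", "C"),
                      category = "keyword", term = c("kw", "kw", "other"))
  docs <- data.frame(document_id = "d1", title = "t", abstract = "")
  map <- data.frame(protein_id = "A", document_id = "d1")
  c1 <- knowledge_corpus(docs, map, terms, proteins = c("A", "B", "C"))
  c2 <- knowledge_corpus(docs, map, terms, proteins = c("A", "B", "C", "D"))
  a1 <- annotate_cluster(c("A", "B"), c1, categories = "keyword",
                         keep_all = TRUE)
  a2 <- annotate_cluster(c("A", "B"), c2, categories = "keyword",
                         keep_all = TRUE)
  expect_equal(a1$k, a2$k)
  expect_equal(a2$M, a1$M + 1)
  expect_equal(a1$p_raw, hypergeom_pvalue(a1$k, a1$n, a1$K, a1$M))
})

test_that("literature annotation counts a protein once per term", {
  corpus <- entropy_fixture()
  idx <- build_index(corpus, m = 3)
  ann <- annotate_cluster(c("A", "B", "C"), corpus, index = idx,
                          keep_all = TRUE)
  uni <- ann[ann$category == "unigram", ]
  # "beta" occurs in 4 docs but all of protein A: k = 1
  expect_equal(uni$k[uni$term == "beta"], 1)
  expect_equal(uni$k[uni$term == "alpha"], 3)
  expect_true(all(ann$p_corrected >= ann$p_raw - 1e-15))
  expect_true(all(ann$p_raw >= 0 & ann$p_raw <= 1))
  # entropy attached to literature terms only
  expect_true(all(is.finite(uni$entropy_score)))
})
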