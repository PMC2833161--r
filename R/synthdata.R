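#' Generate microenvironment vectors with planted cluster structure
#'
#' Draws unit-norm cluster centers with pairwise angular separation of at
#' least `separation_deg` degrees (rejection sampling; an error is raised
#' if the requested separation is infeasible in the given dimension), then
#' places each member at `center + noise * z / sqrt(dim)` with
#' `z ~ N(0, I)`, re-normalized to the unit sphere. The `noise` parameter
#' is therefore the expected Euclidean norm of the perturbation, and the
#' expected cosine of a member to its center is about
#' `1 / sqrt(1 + noise^2)`. Optional background points are uniform on the
#' sphere and labeled `-1`.
#'
#' Generators are pure functions of their arguments: the same settings
#' and seed always produce identical output.
#'
#' @param sizes integer vector of planted-cluster sizes.
#' @param dim vector dimension (default 264, i.e. 44 properties x 6
#'   shells).
#' @param separation_deg minimum pairwise angle between centers (degrees).
#' @param noise perturbation scale (see above).
#' @param background_fraction fraction of all points that are unstructured
#'   background.
#' @param seed RNG seed.
#' @return list: `ms` (a raw-space `microenv_set` with synthetic site
#'   ids), `labels` (planted cluster per site, `-1` for background),
#'   `centers` (n_clusters x dim).
#' @export
gen_vectors <- function(sizes, dim = 264L, separation_deg = 60,
                        noise = 0.1, background_fraction = 0, seed = 1L) {
  stopifnot(all(sizes > 0), dim >= 2, background_fraction >= 0,
            background_fraction < 1)
  g <- length(sizes)
  set.seed(seed)
  min_cos <- cos(separation_deg * pi / 180)
  centers <- matrix(0, g, dim)
  tries <- 0L
  i <- 1L
  while (i <= g) {
    tries <- tries + 1L
    if (tries > 1000L * g) {
      stop("could not place ", g, " centers at >= ", separation_deg,
           " degrees separation in dimension ", dim)
    }
    cand <- stats::rnorm(dim)
    cand <- cand / sqrt(sum(cand^2))
    if (i == 1 || all(centers[seq_len(i - 1), , drop = FALSE] %*% cand <= min_cos)) {
      centers[i, ] <- cand
      i <- i + 1L
    }
  }
  n_sig <- sum(sizes)
  n_bg <- round(n_sig * background_fraction / (1 - background_fraction))
  n <- n_sig + n_bg
  x <- matrix(0, n, dim)
  labels <- integer(n)
  row <- 1L
  for (gi in seq_len(g)) {
    for (j in seq_len(sizes[gi])) {
      v <- centers[gi, ] + noise * stats::rnorm(dim) / sqrt(dim)
      x[row, ] <- v / sqrt(sum(v^2))
      labels[row] <- gi
      row <- row + 1L
    }
  }
  if (n_bg > 0) {
    for (j in seq_len(n_bg)) {
      v <- stats::rnorm(dim)
      x[row, ] <- v / sqrt(sum(v^2))
      labels[row] <- -1L
      row <- row + 1L
    }
  }
  sites <- data.frame(structure_id = "SYNT", chain = "A",
                      residue_number = seq_len(n), residue_name = "CYS",
                      stringsAsFactors = FALSE)
  colnames(x) <- paste0("f", seq_len(dim))
  list(ms = microenv_set(sites, x), labels = labels, centers = centers)
}

#' Generate a topic-structured knowledge corpus with planted coherence
#'
#' Emulates a protein-literature corpus in which functionally related
#' proteins share vocabulary. Each planted topic owns a topic vocabulary;
#' a fraction `overlap_across` of every topic vocabulary is drawn from a
#' pool shared by all topics, the rest is topic-exclusive. Every document
#' of a protein assigned to topic `t` draws a fraction `overlap_within` of
#' its tokens from topic `t`'s vocabulary and the remainder from a large
#' background vocabulary; documents of unassigned (background) proteins
#' draw all tokens from the background vocabulary. Each protein receives
#' exactly `docs_per_protein` documents. Categorical terms can be
#' implanted into chosen proteins and are recorded as ground truth.
#'
#' @param n_proteins number of proteins (ids `P0001`, ...).
#' @param topic_assignments integer vector of length `n_proteins`; topic
#'   index per protein, 0 for background proteins.
#' @param vocab_size total vocabulary size.
#' @param topic_vocab_size words per topic vocabulary.
#' @param overlap_within fraction of a document's tokens drawn from its
#'   topic vocabulary (default 0.8).
#' @param overlap_across fraction of each topic vocabulary shared across
#'   topics (default 0.05).
#' @param docs_per_protein documents per protein (default 5).
#' @param offtopic_fraction fraction of each topic protein's documents
#'   that are off-topic, i.e. drawn entirely from the background
#'   vocabulary (default 0.2). Real protein literatures are mixed: only
#'   part of a protein's publications concern the function it shares with
#'   its cluster, and the coherence statistic is designed around exactly
#'   this heterogeneity of document scores.
#' @param doc_length tokens per document (default 50).
#' @param implant optional data.frame(protein_id, category, term) of
#'   categorical terms to attach.
#' @param seed RNG seed.
#' @return list: `corpus` (a `knowledge_corpus`), `truth` (list with
#'   `topic` per protein, `implant`).
#' @export
gen_corpus <- function(n_proteins, topic_assignments,
                       vocab_size = 2000L, topic_vocab_size = 50L,
                       overlap_within = 0.8, overlap_across = 0.05,
                       docs_per_protein = 5L, offtopic_fraction = 0.2,
                       doc_length = 50L, implant = NULL, seed = 1L) {
  stopifnot(length(topic_assignments) == n_proteins,
            overlap_within >= 0, overlap_within <= 1,
            overlap_across >= 0, overlap_across < 1)
  topics <- sort(unique(topic_assignments[topic_assignments > 0]))
  n_topics <- length(topics)
  n_shared <- round(overlap_across * topic_vocab_size)
  n_own <- topic_vocab_size - n_shared
  n_topic_words <- n_shared + n_topics * n_own
  if (vocab_size < n_topic_words + 50L) {
    stop("vocab_size too small for ", n_topics, " topics of ",
         topic_vocab_size, " words (need >= ", n_topic_words + 50L, ")")
  }
  set.seed(seed)
  words <- sprintf("w%05d", seq_len(vocab_size))
  shared <- if (n_shared > 0) words[seq_len(n_shared)] else character(0)
  topic_vocab <- list()
  off <- n_shared
  for (t in topics) {
    topic_vocab[[as.character(t)]] <- c(shared, words[off + seq_len(n_own)])
    off <- off + n_own
  }
  background <- words[(n_topic_words + 1):vocab_size]

  proteins <- sprintf("P%04d", seq_len(n_proteins))
  doc_rows <- list()
  map_rows <- list()
  doc_i <- 0L
  n_topic_tok <- round(overlap_within * doc_length)
  n_offtopic <- round(offtopic_fraction * docs_per_protein)
  for (p in seq_len(n_proteins)) {
    tv <- if (topic_assignments[p] > 0) {
      topic_vocab[[as.character(topic_assignments[p])]]
    } else NULL
    for (d in seq_len(docs_per_protein)) {
      doc_i <- doc_i + 1L
      id <- sprintf("D%05d", doc_i)
      # the last n_offtopic documents of a topic protein are off-topic
      toks <- if (is.null(tv) || d > docs_per_protein - n_offtopic) {
        sample(background, doc_length, replace = TRUE)
      } else {
        c(sample(tv, n_topic_tok, replace = TRUE),
          sample(background, doc_length - n_topic_tok, replace = TRUE))
      }
      doc_rows[[doc_i]] <- data.frame(
        document_id = id, title = sprintf("t%05d", doc_i),
        abstract = paste(toks, collapse = " "), stringsAsFactors = FALSE)
      map_rows[[doc_i]] <- data.frame(protein_id = proteins[p],
                                      document_id = id, large_scale = 0L,
                                      stringsAsFactors = FALSE)
    }
  }
  documents <- do.call(rbind, doc_rows)
  protein_docs <- do.call(rbind, map_rows)
  term_tables <- NULL
  if (!is.null(implant)) {
    term_tables <- implant[c("protein_id", "category", "term")]
  }
  corpus <- knowledge_corpus(documents, protein_docs, term_tables,
                             proteins = proteins)
  list(corpus = corpus,
       truth = list(topic = stats::setNames(topic_assignments, proteins),
                    implant = implant))
}

#' Generate a matched study: planted vectors, proteins and corpus
#'
#' Convenience generator tying the two synthetic inputs together: sites of
#' planted vector cluster `g` are assigned round-robin to the proteins of
#' corpus topic `g`, so vector structure and literature structure agree.
#' Background sites map to background proteins.
#'
#' @param sizes planted vector-cluster sizes.
#' @param proteins_per_cluster proteins per planted cluster.
#' @param n_background_proteins extra unassigned proteins.
#' @param dim,separation_deg,noise,background_fraction see [gen_vectors()].
#' @param seed RNG seed (vectors use `seed`, corpus `seed + 1`).
#' @param ... further arguments to [gen_corpus()].
#' @return list: `ms`, `labels`, `centers`, `site_proteins` (protein id
#'   per site), `corpus`, `truth`.
#' @export
gen_study <- function(sizes = c(50, 50, 50), proteins_per_cluster = 10L,
                      n_background_proteins = 20L, dim = 264L,
                      separation_deg = 60, noise = 0.1,
                      background_fraction = 0, seed = 1L, ...) {
  vec <- gen_vectors(sizes, dim = dim, separation_deg = separation_deg,
                     noise = noise, background_fraction = background_fraction,
                     seed = seed)
  g <- length(sizes)
  n_proteins <- g * proteins_per_cluster + n_background_proteins
  topic <- c(rep(seq_len(g), each = proteins_per_cluster),
             rep(0L, n_background_proteins))
  corp <- gen_corpus(n_proteins, topic, seed = seed + 1L, ...)
  proteins <- names(corp$truth$topic)
  site_proteins <- character(length(vec$labels))
  for (gi in seq_len(g)) {
    idx <- which(vec$labels == gi)
    pg <- proteins[topic == gi]
    site_proteins[idx] <- pg[((seq_along(idx) - 1L) %% length(pg)) + 1L]
  }
  bg_sites <- which(vec$labels == -1L)
  if (length(bg_sites)) {
    pb <- proteins[topic == 0L]
    if (!length(pb)) stop("background sites require background proteins")
    site_proteins[bg_sites] <- pb[((seq_along(bg_sites) - 1L) %% length(pb)) + 1L]
  }
  list(ms = vec$ms, labels = vec$labels, centers = vec$centers,
       site_proteins = site_proteins, corpus = corp$corpus,
       truth = corp$truth)
}
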