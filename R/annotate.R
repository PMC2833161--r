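.foresite_env <- new.env(parent = emptyenv())

#' Packaged stop-word list
#' @return character vector of stop words.
#' @export
stopwords <- function() {
  if (is.null(.foresite_env$stopwords)) {
    path <- system.file("extdata", "stopwords.txt", package = "foresite")
    .foresite_env$stopwords <- readLines(path, warn = FALSE)
  }
  .foresite_env$stopwords
}

#' Tokenize free text for literature-term extraction
#'
#' Lowercases, splits on whitespace and punctuation while keeping
#' intra-word hyphens ("zinc-binding" stays one token), and removes stop
#' words from the packaged list. Token order is preserved.
#'
#' @param text a character string (empty input gives an empty result).
#' @return character vector of surviving tokens.
#' @export
tokenize <- function(text) {
  if (length(text) == 0 || !nzchar(text)) return(character(0))
  t <- tolower(text)
  t <- gsub("[^a-z0-9-]+", " ", t)
  toks <- strsplit(trimws(t), "\\s+")[[1]]
  toks <- gsub("^-+|-+$", "", toks)       # hyphen only survives word-internally
  toks <- toks[nzchar(toks)]
  toks[!(toks %in% stopwords())]
}

#' Unigram and bigram term sets from a token sequence
#'
#' Bigrams are consecutive pairs of the post-filter token sequence, joined
#' by a single space.
#'
#' @param tokens character vector as produced by [tokenize()].
#' @return list with `unigrams` and `bigrams` (each distinct, order of
#'   first appearance).
#' @export
ngrams <- function(tokens) {
  uni <- unique(tokens)
  bi <- if (length(tokens) >= 2) {
    unique(paste(tokens[-length(tokens)], tokens[-1]))
  } else character(0)
  list(unigrams = uni, bigrams = bi)
}

#' Upper-tail hypergeometric p-value for term enrichment
#'
#' Probability of observing `k` or more annotated entities in a cluster of
#' size `n`, when `K` of the `M` background entities carry the term
#' (enrichment only; depletion is not tested). Delegates to
#' [stats::phyper()], which works on log scale internally.
#'
#' @param k cluster entities with the term.
#' @param n cluster size.
#' @param K background count of the term.
#' @param M background universe size.
#' @return `P(X >= k)` in [0, 1].
#' @export
hypergeom_pvalue <- function(k, n, K, M) {
  if (any(k < 0 | n < 0 | K < 0 | M < 0)) stop("counts must be non-negative")
  if (any(n > M | K > M)) stop("n and K cannot exceed M")
  if (any(k > pmin(n, K))) stop("k cannot exceed min(n, K)")
  stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

#' Background term universe over a corpus
#'
#' For categorical categories the entities are all corpus proteins; for
#' the literature categories (`unigram`, `bigram`) the entities are the
#' proteins with at least one document, and a protein counts once per term
#' no matter how many of its documents contain it.
#'
#' @param corpus a `knowledge_corpus`.
#' @param category category name (a categorical table name, `"unigram"`,
#'   or `"bigram"`).
#' @param index a `document_index` (required for literature categories).
#' @return list of class `term_universe`: `category`, `counts` (named),
#'   `M`.
#' @export
term_universe <- function(corpus, category, index = NULL) {
  if (category %in% c("unigram", "bigram")) {
    if (is.null(index)) stop("literature universes need a document index")
    slot <- if (category == "unigram") "doc_unigrams" else "doc_bigrams"
    with_docs <- names(corpus$protein_docs)[lengths(corpus$protein_docs) > 0]
    counts <- new.env(parent = emptyenv())
    for (p in with_docs) {
      terms <- unique(unlist(index[[slot]][corpus$protein_docs[[p]]]))
      for (t in terms) {
        counts[[t]] <- (counts[[t]] %||% 0L) + 1L
      }
    }
    cn <- ls(counts)
    structure(list(category = category,
                   counts = stats::setNames(
                     vapply(cn, function(t) counts[[t]], integer(1)), cn),
                   M = length(with_docs)),
              class = "term_universe")
  } else {
    tt <- corpus$term_tables
    if (is.null(tt) || !category %in% tt$category) {
      stop("unknown categorical category '", category, "'")
    }
    sub <- unique(tt[tt$category == category, c("protein_id", "term")])
    structure(list(category = category,
                   counts = table_to_counts(sub$term),
                   M = length(corpus$proteins)),
              class = "term_universe")
  }
}

table_to_counts <- function(x) {
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

#' Entropy-based score of literature terms within a cluster
#'
#' For a term `t` and cluster protein `p`, `D_tp` is the ratio of the
#' number of the protein's documents containing the term to the number of
#' documents containing the term in the entire cluster. The Shannon
#' entropy `H_t = -sum_p D_tp * ln(D_tp)` rewards terms whose supporting
#' documents are spread evenly across the cluster proteins; it is
#' normalized by the maximum entropy over all cluster terms (prior to idf
#' weighting) and multiplied by `idf_t = ln(n_docs / df_t)` computed over
#' the whole corpus. A term confined to one protein's documents scores 0.
#'
#' @param cluster_proteins character vector of cluster protein ids.
#' @param corpus a `knowledge_corpus`.
#' @param index a `document_index`.
#' @param which one or both of `"unigram"`, `"bigram"`.
#' @return data.frame(category, term, H, H_norm, idf, score) for every
#'   term occurring in the cluster's documents.
#' @export
cluster_term_entropy <- function(cluster_proteins, corpus, index,
                                 which = c("unigram", "bigram")) {
  which <- match.arg(which, several.ok = TRUE)
  cluster_proteins <- intersect(unique(cluster_proteins), corpus$proteins)
  cl_docs <- unique(unlist(corpus$protein_docs[cluster_proteins]))
  if (!length(cl_docs)) stop("cluster has no documents")
  n_docs_total <- nrow(corpus$documents)
  out <- list()
  for (cat in which) {
    slot <- if (cat == "unigram") "doc_unigrams" else "doc_bigrams"
    doc_terms <- index[[slot]]
    # documents containing each term, within the cluster
    cl_term_docs <- split(
      rep(cl_docs, lengths(doc_terms[cl_docs])),
      unlist(doc_terms[cl_docs]))
    if (!length(cl_term_docs)) next
    df_all <- table_to_counts(unlist(lapply(doc_terms, unique)))
    terms <- names(cl_term_docs)
    H <- vapply(terms, function(t) {
      tdocs <- cl_term_docs[[t]]
      total <- length(tdocs)
      d_tp <- vapply(cluster_proteins, function(p) {
        length(intersect(corpus$protein_docs[[p]], tdocs)) / total
      }, numeric(1))
      d_tp <- d_tp[d_tp > 0]
      -sum(d_tp * log(d_tp))
    }, numeric(1))
    hmax <- max(H)
    h_norm <- if (hmax > 0) H / hmax else H * 0
    idf <- log(n_docs_total / df_all[terms])
    out[[cat]] <- data.frame(category = cat, term = terms, H = unname(H),
                             H_norm = unname(h_norm), idf = unname(idf),
                             score = unname(h_norm * idf),
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Entropy score of a single term
#'
#' @inheritParams cluster_term_entropy
#' @param term the term (unigram or bigram).
#' @return numeric score `>= 0`.
#' @export
entropy_score <- function(term, cluster_proteins, corpus, index) {
  cat <- if (grepl(" ", term)) "bigram" else "unigram"
  tab <- cluster_term_entropy(cluster_proteins, corpus, index, which = cat)
  hit <- tab[tab$term == term, ]
  if (nrow(hit) == 0) stop("term '", term, "' does not occur in the cluster")
  hit$score
}

#' Annotate a cluster with enriched terms from all sources
#'
#' Per category, counts how many cluster entities carry each term observed
#' in the cluster (entities are proteins; for literature terms a protein
#' counts once per term if any of its documents contains it), computes the
#' upper-tail hypergeometric p-value against the category's background
#' universe, applies a Bonferroni correction by the number of distinct
#' terms observed in the cluster for that category, and keeps terms with
#' corrected p below `p_cutoff`. Literature terms additionally carry the
#' entropy score with its own cutoff flag.
#'
#' @param cluster_proteins character vector of cluster protein ids (or a
#'   1-row cluster record, from which `proteins` is taken).
#' @param corpus a `knowledge_corpus`.
#' @param index optional `document_index`; literature categories are
#'   skipped without it.
#' @param categories categories to test (default: all categorical tables
#'   plus `unigram` and `bigram` when an index is given).
#' @param p_cutoff corrected p-value cutoff, strict (default 0.01).
#' @param entropy_cutoff entropy-score significance cutoff (default 2.7).
#' @param keep_all keep all tested terms, flagging significance, instead
#'   of only significant ones.
#' @return data.frame(category, term, k, n, K, M, p_raw, p_corrected,
#'   entropy_score, entropy_significant, contributors), sorted by
#'   `p_corrected` then term.
#' @export
annotate_cluster <- function(cluster_proteins, corpus, index = NULL,
                             categories = NULL, p_cutoff = 0.01,
                             entropy_cutoff = 2.7, keep_all = FALSE) {
  if (is.data.frame(cluster_proteins)) {
    cluster_proteins <- cluster_proteins$proteins[[1]]
  }
  cluster_proteins <- intersect(unique(as.character(cluster_proteins)),
                                corpus$proteins)
  if (!length(cluster_proteins)) stop("empty cluster (no proteins in corpus)")
  if (is.null(categories)) {
    categories <- character(0)
    if (!is.null(corpus$term_tables)) {
      categories <- sort(unique(corpus$term_tables$category))
    }
    if (!is.null(index)) categories <- c(categories, "unigram", "bigram")
  }

  ent_tab <- NULL
  if (!is.null(index) && any(c("unigram", "bigram") %in% categories)) {
    has_docs <- lengths(corpus$protein_docs[cluster_proteins]) > 0
    if (any(has_docs)) {
      ent_tab <- cluster_term_entropy(cluster_proteins, corpus, index)
    }
  }

  res <- list()
  for (cat in categories) {
    uni <- term_universe(corpus, cat, index)
    if (cat %in% c("unigram", "bigram")) {
      slot <- if (cat == "unigram") "doc_unigrams" else "doc_bigrams"
      ents <- cluster_proteins[lengths(corpus$protein_docs[cluster_proteins]) > 0]
      if (!length(ents)) next
      ent_terms <- lapply(ents, function(p) {
        unique(unlist(index[[slot]][corpus$protein_docs[[p]]]))
      })
    } else {
      tt <- corpus$term_tables[corpus$term_tables$category == cat, ]
      ents <- cluster_proteins
      ent_terms <- lapply(ents, function(p) unique(tt$term[tt$protein_id == p]))
    }
    names(ent_terms) <- ents
    k_tab <- table_to_counts(unlist(ent_terms))
    if (!length(k_tab)) next
    n <- length(ents)
    n_terms <- length(k_tab)
    terms <- names(k_tab)
    K <- uni$counts[terms]
    K[is.na(K)] <- k_tab[is.na(K)]       # guard: term unseen in universe
    p_raw <- hypergeom_pvalue(as.integer(k_tab), n, as.integer(K), uni$M)
    p_corr <- pmin(1, p_raw * n_terms)
    contrib <- vapply(terms, function(t) {
      paste(ents[vapply(ent_terms, function(ts) t %in% ts, logical(1))],
            collapse = ",")
    }, character(1))
    df <- data.frame(category = cat, term = terms,
                     k = as.integer(k_tab), n = n,
                     K = as.integer(K), M = uni$M,
                     p_raw = unname(p_raw), p_corrected = unname(p_corr),
                     entropy_score = NA_real_, entropy_significant = NA,
                     contributors = unname(contrib),
                     stringsAsFactors = FALSE, row.names = NULL)
    if (cat %in% c("unigram", "bigram") && !is.null(ent_tab)) {
      e <- ent_tab[ent_tab$category == cat, ]
      df$entropy_score <- e$score[match(df$term, e$term)]
      df$entropy_significant <- !is.na(df$entropy_score) &
        df$entropy_score >= entropy_cutoff
    }
    df$significant <- df$p_corrected < p_cutoff
    if (!keep_all) df <- df[df$significant, , drop = FALSE]
    res[[cat]] <- df
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(invisible(NULL))
  out <- out[order(out$p_corrected, out$term), ]
  rownames(out) <- NULL
  out
}

#' Write term scores to TSV and JSON
#' @param scores data.frame from [annotate_cluster()].
#' @param tsv_path,json_path output paths (NULL to skip one).
#' @return invisibly, the written paths.
#' @export
write_term_scores <- function(scores, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(scores, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(scores, json_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(c(tsv_path, json_path))
}
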