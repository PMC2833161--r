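#' Knowledge corpus: proteins, documents and their annotations
#'
#' Container for the literature and annotation evidence the pipeline uses:
#' a set of protein ids, a table of documents (title + abstract text), a
#' many-to-many protein-to-document mapping, and optional per-protein
#' categorical term tables (keywords, GO-like terms, ligand codes, ...).
#' Documents flagged as "large scale" studies are dropped on construction
#' (they reference so many proteins that they carry no specific functional
#' signal); the number dropped is recorded in `n_large_scale_excluded`.
#'
#' @param documents data.frame with columns `document_id`, `title`,
#'   `abstract` (and optionally logical/0-1 `large_scale`).
#' @param protein_docs data.frame with columns `protein_id`, `document_id`
#'   (and optionally `large_scale`, flagging the document).
#' @param term_tables optional data.frame with columns `protein_id`,
#'   `category`, `term`.
#' @param proteins optional explicit protein universe; defaults to the
#'   proteins appearing in `protein_docs` and `term_tables`.
#' @return An object of class `knowledge_corpus` with consistent
#'   `protein_docs` and `doc_proteins` maps (named lists of character
#'   vectors).
#' @export
knowledge_corpus <- function(documents, protein_docs, term_tables = NULL,
                             proteins = NULL) {
  stopifnot(is.data.frame(documents), is.data.frame(protein_docs))
  need <- setdiff(c("document_id", "title", "abstract"), names(documents))
  if (length(need)) stop("documents missing column(s): ", paste(need, collapse = ", "))
  need <- setdiff(c("protein_id", "document_id"), names(protein_docs))
  if (length(need)) stop("protein_docs missing column(s): ", paste(need, collapse = ", "))

  documents$document_id <- as.character(documents$document_id)
  protein_docs$protein_id <- as.character(protein_docs$protein_id)
  protein_docs$document_id <- as.character(protein_docs$document_id)
  if (anyDuplicated(documents$document_id)) stop("duplicate document ids")

  large <- rep(FALSE, nrow(documents))
  if ("large_scale" %in% names(documents)) {
    large <- as.logical(as.integer(documents$large_scale))
  }
  if ("large_scale" %in% names(protein_docs)) {
    flagged <- unique(protein_docs$document_id[
      as.logical(as.integer(protein_docs$large_scale))])
    large <- large | documents$document_id %in% flagged
  }
  unknown <- setdiff(protein_docs$document_id, documents$document_id)
  if (length(unknown)) {
    stop("protein_docs references unknown document(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  n_excluded <- sum(large)
  documents <- documents[!large, c("document_id", "title", "abstract"),
                         drop = FALSE]
  rownames(documents) <- NULL
  protein_docs <- protein_docs[protein_docs$document_id %in%
                                 documents$document_id, , drop = FALSE]

  if (is.null(proteins)) {
    proteins <- unique(c(protein_docs$protein_id,
                         if (!is.null(term_tables)) as.character(term_tables$protein_id)))
  }
  proteins <- sort(unique(as.character(proteins)))

  pd <- split(protein_docs$document_id, protein_docs$protein_id)
  pd <- lapply(pd, function(v) sort(unique(v)))
  dp <- split(protein_docs$protein_id, protein_docs$document_id)
  dp <- lapply(dp, function(v) sort(unique(v)))

  if (!is.null(term_tables)) {
    need <- setdiff(c("protein_id", "category", "term"), names(term_tables))
    if (length(need)) stop("term_tables missing column(s): ", paste(need, collapse = ", "))
    term_tables$protein_id <- as.character(term_tables$protein_id)
    term_tables$category <- as.character(term_tables$category)
    term_tables$term <- as.character(term_tables$term)
    term_tables <- unique(term_tables[c("protein_id", "category", "term")])
    rownames(term_tables) <- NULL
  }

  structure(list(proteins = proteins, documents = documents,
                 protein_docs = pd, doc_proteins = dp,
                 term_tables = term_tables,
                 n_large_scale_excluded = n_excluded),
            class = "knowledge_corpus")
}

#' @export
print.knowledge_corpus <- function(x, ...) {
  cat("Knowledge corpus: ", length(x$proteins), " proteins, ",
      nrow(x$documents), " documents (", x$n_large_scale_excluded,
      " large-scale excluded)\n", sep = "")
  if (!is.null(x$term_tables)) {
    cat("  term categories: ",
        paste(sort(unique(x$term_tables$category)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read a knowledge corpus from disk
#'
#' @param map_path TSV with columns protein_id, document_id, large_scale (0/1).
#' @param docs_path JSON-lines file, one object per line with fields
#'   `id`, `title`, `abstract`.
#' @param terms_path optional TSV with columns protein_id, category, term.
#' @return A `knowledge_corpus`.
#' @export
read_corpus <- function(map_path, docs_path, terms_path = NULL) {
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  lines <- readLines(docs_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- do.call(rbind, lapply(lines, function(l) {
    j <- jsonlite::fromJSON(l)
    data.frame(document_id = as.character(j$id), title = j$title %||% "",
               abstract = j$abstract %||% "", stringsAsFactors = FALSE)
  }))
  terms <- if (!is.null(terms_path)) {
    utils::read.delim(terms_path, stringsAsFactors = FALSE)
  }
  knowledge_corpus(docs, map, terms)
}

#' Write the corpus protein-document map and documents to disk
#' @param corpus a `knowledge_corpus`.
#' @param map_path,docs_path,terms_path output paths (NULL to skip).
#' @return invisibly, the written paths.
#' @export
write_corpus <- function(corpus, map_path, docs_path, terms_path = NULL) {
  map <- data.frame(
    protein_id = rep(names(corpus$protein_docs),
                     lengths(corpus$protein_docs)),
    document_id = unlist(corpus$protein_docs, use.names = FALSE),
    large_scale = 0L, stringsAsFactors = FALSE)
  utils::write.table(map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(docs_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus$documents))) {
    writeLines(jsonlite::toJSON(
      list(id = corpus$documents$document_id[i],
           title = corpus$documents$title[i],
           abstract = corpus$documents$abstract[i]), auto_unbox = TRUE), con)
  }
  if (!is.null(terms_path) && !is.null(corpus$term_tables)) {
    utils::write.table(corpus$term_tables, terms_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(map_path, docs_path, terms_path))
}

#' Build a document similarity index over a corpus
#'
#' Each document (title + abstract) is tokenized (lowercased, stop words
#' removed, intra-word hyphens preserved), represented as a weighted word
#' vector with weights `log(1 + tf) * idf`, `idf = ln(n_docs / df)`, and
#' unit-normalized. For every document the `m` most cosine-similar other
#' documents are recorded as its semantic neighbors (`m` is capped at
#' `n_docs - 1`; similarity ties are broken by ascending document id; a
#' document is never its own neighbor).
#'
#' @param corpus a `knowledge_corpus` with at least 2 documents.
#' @param m neighbors per document (default 20).
#' @return An object of class `document_index`: `doc_ids`, `m`,
#'   `neighbors` (list of character vectors, similarity-descending),
#'   `neighbor_sims`, `vocabulary`, and per-document distinct unigram /
#'   bigram term sets (used for literature-term annotation).
#' @export
build_index <- function(corpus, m = 20L) {
  stopifnot(inherits(corpus, "knowledge_corpus"))
  docs <- corpus$documents
  n <- nrow(docs)
  if (n < 2) stop("need at least 2 documents to build an index")
  m <- min(as.integer(m), n - 1L)

  toks <- lapply(seq_len(n), function(i) {
    tokenize(paste(docs$title[i], docs$abstract[i]))
  })
  vocab <- sort(unique(unlist(toks)))
  tf <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) {
    t <- table(toks[[i]])
    tf[i, names(t)] <- as.numeric(t)
  }
  df <- colSums(tf > 0)
  idf <- log(n / df)
  w <- log1p(tf) * rep(idf, each = n)
  nrm <- sqrt(rowSums(w^2))
  nrm[nrm == 0] <- 1
  w <- w / nrm

  sims <- tcrossprod(w)
  ids <- docs$document_id
  neighbors <- vector("list", n)
  neighbor_sims <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sims[i, ]
    s[i] <- -Inf
    ord <- order(-s, ids)[seq_len(m)]
    neighbors[[i]] <- ids[ord]
    neighbor_sims[[i]] <- unname(s[ord])
  }
  names(neighbors) <- ids
  names(neighbor_sims) <- ids

  grams <- lapply(toks, ngrams)
  doc_unigrams <- lapply(grams, `[[`, "unigrams")
  doc_bigrams <- lapply(grams, `[[`, "bigrams")
  names(doc_unigrams) <- ids
  names(doc_bigrams) <- ids

  structure(list(doc_ids = ids, m = m, neighbors = neighbors,
                 neighbor_sims = neighbor_sims, vocabulary = vocab,
                 doc_unigrams = doc_unigrams, doc_bigrams = doc_bigrams),
            class = "document_index")
}

#' @export
print.document_index <- function(x, ...) {
  cat("Document index: ", length(x$doc_ids), " documents, ",
      length(x$vocabulary), " vocabulary terms, m = ", x$m,
      " neighbors\n", sep = "")
  invisible(x)
}
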