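# Fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (enumeration / brute force) and share no code with the
# implementation paths they check.

# small microenv_set from a plain matrix
ms_from_matrix <- function(x, space_tag = "raw") {
  x <- as.matrix(x)
  sites <- data.frame(structure_id = sprintf("S%03d", seq_len(nrow(x))),
                      chain = "A", residue_number = seq_len(nrow(x)),
                      residue_name = "CYS", stringsAsFactors = FALSE)
  microenv_set(sites, x, space_tag = space_tag)
}

# minimal PDB-format ATOM line (fixed columns)
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          record = "ATOM") {
  name_field <- if (nchar(name) >= 4) substr(name, 1, 4) else
    sprintf(" %-3s", name)
  elem <- substr(gsub("[0-9]", "", name), 1, 1)
  sprintf("%-6s%5d %s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_field, " ", resid, chain, resno,
          x, y, z, 1.00, 0.00, elem)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# hand-built corpus: proteins A..D; A/B/C share "copper" literature, D is
# unrelated background
tiny_corpus <- function() {
  docs <- data.frame(
    document_id = sprintf("d%d", 1:6),
    title = c("copper transport", "copper binding", "blue copper protein",
              "copper oxidase", "ribosome assembly", "ribosome biogenesis"),
    abstract = c("copper uptake system", "copper site geometry",
                 "blue copper electron transfer", "copper enzyme catalysis",
                 "ribosomal subunit maturation", "ribosome export factor"),
    stringsAsFactors = FALSE)
  map <- data.frame(
    protein_id = c("A", "A", "B", "C", "D", "D"),
    document_id = c("d1", "d2", "d3", "d4", "d5", "d6"),
    large_scale = 0L, stringsAsFactors = FALSE)
  knowledge_corpus(docs, map)
}

# naive O(n^3) single-linkage oracle: at every step rescan all pairs of
# active groups against the raw distance matrix; identical tie-break rule
# (lexicographically smallest pair of smallest-leaf representatives)
naive_single_linkage <- function(d) {
  n <- nrow(d)
  groups <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  members <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (i >= j) next
        dij <- min(d[groups[[i]], groups[[j]]])
        ri <- min(groups[[i]]); rj <- min(groups[[j]])
        key <- c(dij, min(ri, rj), max(ri, rj))
        if (is.null(best) ||
            key[1] < best$key[1] - 1e-15 ||
            (abs(key[1] - best$key[1]) <= 1e-15 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    heights[s] <- best$key[1]
    merged <- sort(c(groups[[best$i]], groups[[best$j]]))
    members[[s]] <- merged
    groups[[best$i]] <- merged
    groups[[best$j]] <- NULL
  }
  list(heights = heights, members = members)
}

# exhaustive antichain oracle: maximum total score over all sets of
# internal nodes with pairwise disjoint member sets
best_antichain_total <- function(tree, S) {
  n_nodes <- nrow(tree$merge)
  best <- 0
  for (mask in 0:(2^n_nodes - 1)) {
    nodes <- which(bitwAnd(mask, 2^(seq_len(n_nodes) - 1)) > 0)
    if (!length(nodes)) next
    memb <- unlist(tree$members[nodes])
    if (anyDuplicated(memb)) next
    best <- max(best, sum(S[nodes]))
  }
  best
}

# exact hypergeometric upper tail by combinatorial enumeration
hyper_upper_enum <- function(k, n, K, M) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(M - K, n - j)) / choose(M, n)
}

# independent tf-idf weighting + cosine ranking for index cross-checks
naive_doc_ranking <- function(corpus, target_idx) {
  docs <- corpus$documents
  n <- nrow(docs)
  toks <- lapply(seq_len(n), function(i)
    tokenize(paste(docs$title[i], docs$abstract[i])))
  vocab <- sort(unique(unlist(toks)))
  tf <- sapply(vocab, function(w) vapply(toks, function(t) sum(t == w), 0))
  idf <- log(n / colSums(tf > 0))
  w <- log(1 + tf) %*% diag(idf)
  w <- w / sqrt(rowSums(w^2))
  s <- drop(w %*% w[target_idx, ])
  s[target_idx] <- -Inf
  order(-s, docs$document_id)
}

# labels induced by a set of selected clusters (0 = not covered)
labels_from_clusters <- function(clusters, n_sites) {
  lab <- rep(0L, n_sites)
  for (i in seq_len(nrow(clusters))) lab[clusters$site_idx[[i]]] <- i
  lab
}

# 3 proteins, 2 literature terms; "alpha" spread 2/1/1 over proteins,
# "beta" confined to protein A's documents (4/0/0)
entropy_fixture <- function() {
  docs <- data.frame(
    document_id = sprintf("d%d", 1:8),
    title = c("alpha beta", "alpha beta", "beta gamma", "beta delta",
              "alpha epsilon", "alpha zeta", "omega theta", "omega iota"),
    abstract = "")
  map <- data.frame(
    protein_id = c("A", "A", "A", "A", "B", "C", "Z", "Z"),
    document_id = sprintf("d%d", 1:8))
  knowledge_corpus(docs, map)
}

write_study_inputs <- function(dir, seed = 91) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- gen_study(sizes = c(25, 25, 25), proteins_per_cluster = 6,
                  n_background_proteins = 10, dim = 60, seed = seed)
  # site-specific structure ids so the site->protein map can live in a file
  st$ms$sites$structure_id <- sprintf("S%03X", seq_along(st$site_proteins))
  write_vectors(st$ms, file.path(dir, "vectors.tsv"))
  write_corpus(st$corpus, file.path(dir, "protein_docs.tsv"),
               file.path(dir, "documents.jsonl"))
  utils::write.table(
    data.frame(structure_id = st$ms$sites$structure_id,
               protein_id = st$site_proteins),
    file.path(dir, "site_proteins.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  st
}

pipeline_config <- function(dir, out_dir) {
  list(vectors = file.path(dir, "vectors.tsv"),
       protein_docs = file.path(dir, "protein_docs.tsv"),
       documents = file.path(dir, "documents.jsonl"),
       site_protein_map = file.path(dir, "site_proteins.tsv"),
       out_dir = out_dir, k = 3, n_pc = 20, n_restarts = 3, seed = 5)
}
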