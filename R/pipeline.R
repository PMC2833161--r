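#' Discover functional-site clusters by two-phase clustering
#'
#' The end-to-end discovery procedure: standardize raw microenvironment
#' vectors, reduce them to `n_pc` principal components, partition the
#' reduced vectors into `k` coarse clusters by spherical k-means, build a
#' single-linkage cosine tree within each coarse cluster, score every tree
#' node by node correlation, functional coherence and size, select the
#' optimal disjoint node set per tree, filter by size and coherence, and
#' annotate the surviving clusters with enriched terms.
#'
#' @param vectors a raw or standardized `microenv_set`.
#' @param corpus optional `knowledge_corpus`; without it all functional
#'   coherences are 0 and selection is driven by node correlation and size.
#' @param site_proteins protein id per site (defaults to structure_id).
#' @param k number of coarse clusters (default 40).
#' @param n_pc number of principal components (default 80; clamped to the
#'   feasible maximum).
#' @param m semantic neighbors per document (default 20).
#' @param min_size minimum cluster size (default 5).
#' @param fc_cutoff functional-coherence filter, strict (default 3.0).
#' @param p_cutoff corrected p-value cutoff for annotation (default 0.01).
#' @param entropy_cutoff entropy-score cutoff (default 2.7).
#' @param weights a [score_weights()] configuration.
#' @param n_restarts spherical k-means restarts (default 10).
#' @param seed base seed for all randomized stages.
#' @param annotate annotate the filtered clusters (requires a corpus).
#' @return object of class `site_discovery`: `params`, `pca`, `coarse`,
#'   `trees`, `node_scores` (per coarse cluster), `records` (all selected
#'   clusters), `clusters` (filtered records), `annotations` (named list
#'   per cluster id), `index`, `site_proteins`, `reduced`.
#' @export
discover_sites <- function(vectors, corpus = NULL, site_proteins = NULL,
                           k = 40L, n_pc = 80L, m = 20L, min_size = 5L,
                           fc_cutoff = 3.0, p_cutoff = 0.01,
                           entropy_cutoff = 2.7,
                           weights = score_weights(), n_restarts = 10L,
                           seed = 1L, annotate = TRUE) {
  stopifnot(inherits(vectors, "microenv_set"))
  ms <- if (vectors$space_tag == "raw") standardize(vectors) else vectors
  if (is.null(site_proteins)) site_proteins <- ms$sites$structure_id

  n_pc_eff <- min(n_pc, nrow(ms$features) - 1L, ncol(ms$features))
  pca <- fit_pca(ms, n_pc_eff)
  red <- predict(pca, ms)

  k_eff <- min(k, nrow(red$features))
  coarse <- kmeans_restarts(red, k_eff, n_restarts = n_restarts,
                            base_seed = seed)

  index <- NULL
  if (!is.null(corpus)) index <- build_index(corpus, m = m)

  trees <- list(); scores <- list(); recs <- list()
  for (cc in seq_len(k_eff)) {
    members <- which(coarse$cluster == cc)
    if (length(members) < 2) next
    tree <- hac_cosine(red, members = members)
    sc <- withCallingHandlers(
      score_tree(tree, red, corpus = corpus, index = index,
                 site_proteins = site_proteins, weights = weights),
      warning = function(w) invokeRestart("muffleWarning"))
    sel <- select_clusters(tree, sc)
    trees[[as.character(cc)]] <- tree
    scores[[as.character(cc)]] <- sc
    recs[[as.character(cc)]] <- cluster_records(tree, sel, sc, red,
                                                site_proteins = site_proteins,
                                                coarse_id = cc)
  }
  records <- do.call(rbind, unname(recs))
  if (is.null(records)) {
    records <- data.frame(cluster_id = character(), coarse_id = character(),
                          node = integer(), C = numeric(), F = numeric(),
                          N = integer(), S = numeric(),
                          site_idx = I(list()), sites = I(list()),
                          proteins = I(list()), stringsAsFactors = FALSE)
  }
  rownames(records) <- NULL
  clusters <- filter_clusters(records, min_size = min_size,
                              fc_cutoff = fc_cutoff)

  annotations <- list()
  if (annotate && !is.null(corpus) && nrow(clusters)) {
    for (i in seq_len(nrow(clusters))) {
      ann <- tryCatch(
        annotate_cluster(clusters$proteins[[i]], corpus, index = index,
                         p_cutoff = p_cutoff,
                         entropy_cutoff = entropy_cutoff),
        error = function(e) NULL)
      annotations[[clusters$cluster_id[i]]] <- ann
    }
  }

  structure(list(
    params = list(k = k_eff, n_pc = n_pc_eff, m = m, min_size = min_size,
                  fc_cutoff = fc_cutoff, p_cutoff = p_cutoff,
                  entropy_cutoff = entropy_cutoff, weights = weights,
                  n_restarts = n_restarts, seed = seed),
    pca = pca, coarse = coarse, trees = trees, node_scores = scores,
    records = records, clusters = clusters, annotations = annotations,
    index = index, site_proteins = site_proteins, reduced = red),
    class = "site_discovery")
}

#' @export
print.site_discovery <- function(x, ...) {
  cat("Functional-site discovery\n")
  cat("  k = ", x$params$k, ", n_pc = ", x$params$n_pc,
      ", seed = ", x$params$seed, "\n", sep = "")
  cat("  selected clusters: ", nrow(x$records),
      "; after size >= ", x$params$min_size, " and F > ",
      x$params$fc_cutoff, ": ", nrow(x$clusters), "\n", sep = "")
  invisible(x)
}

#' @export
summary.site_discovery <- function(object, ...) {
  df <- object$clusters
  out <- df[c("cluster_id", "N", "C", "F", "S")]
  out <- out[order(-out$S), ]
  rownames(out) <- NULL
  structure(list(clusters = out, n_selected = nrow(object$records),
                 n_filtered = nrow(df), params = object$params),
            class = "summary.site_discovery")
}

#' @export
print.summary.site_discovery <- function(x, ...) {
  cat(x$n_selected, "clusters selected;", x$n_filtered,
      "pass the size and coherence filters\n\n")
  print(x$clusters, digits = 4)
  invisible(x)
}

#' @export
plot.site_discovery <- function(x, ...) {
  df <- x$records
  graphics::plot(df$C, df$F, cex = sqrt(df$N) / 2,
                 xlab = "node correlation C",
                 ylab = "functional coherence F",
                 main = "Selected clusters", ...)
  graphics::abline(h = x$params$fc_cutoff, lty = 2)
  kept <- df$N >= x$params$min_size & df$F > x$params$fc_cutoff
  graphics::points(df$C[kept], df$F[kept], cex = sqrt(df$N[kept]) / 2,
                   pch = 19)
  invisible(x)
}

#' Run the full pipeline from a configuration file
#'
#' Thin file-and-directory wrapper around [discover_sites()]. The
#' configuration (YAML or JSON file, or an equivalent list) names the
#' input files and parameters; every intermediate artifact is written to
#' the run directory along with a manifest (configuration, seed, input
#' hashes, package version) sufficient to reproduce the run. Reruns with
#' the same configuration and seed produce identical cluster records and
#' byte-identical HTML.
#'
#' Required keys: `vectors` (TSV path), `out_dir`. Optional: `protein_docs`,
#' `documents`, `term_tables` (corpus file paths), `site_protein_map` (TSV
#' with columns structure_id, protein_id), and the parameters of
#' [discover_sites()] (`k`, `n_pc`, `m`, `min_size`, `fc_cutoff`,
#' `p_cutoff`, `entropy_cutoff`, `n_restarts`, `seed`, `w_C`, `w_F`,
#' `F_cap`).
#'
#' @param config path to a YAML/JSON file, or a named list.
#' @param quiet suppress progress messages.
#' @return the `site_discovery` object, invisibly; artifacts in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  req <- setdiff(c("vectors", "out_dir"), names(config))
  if (length(req)) stop("config missing required key(s): ",
                        paste(req, collapse = ", "))
  if (!file.exists(config$vectors)) stop("vectors file not found: ",
                                         config$vectors)
  has_corpus <- all(c("protein_docs", "documents") %in% names(config))
  for (key in intersect(c("protein_docs", "documents", "term_tables",
                          "site_protein_map"), names(config))) {
    if (!file.exists(config[[key]])) stop(key, " file not found: ",
                                          config[[key]])
  }
  say <- function(...) if (!quiet) message("[foresite] ", ...)

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say("reading vectors from ", config$vectors)
  ms <- read_vectors(config$vectors)

  corpus <- NULL
  if (has_corpus) {
    say("reading corpus")
    corpus <- read_corpus(config$protein_docs, config$documents,
                          config$term_tables)
  }
  site_proteins <- NULL
  if (!is.null(config$site_protein_map)) {
    map <- utils::read.delim(config$site_protein_map,
                             stringsAsFactors = FALSE)
    site_proteins <- map$protein_id[match(ms$sites$structure_id,
                                          map$structure_id)]
    site_proteins[is.na(site_proteins)] <- ms$sites$structure_id[is.na(site_proteins)]
  }

  p <- function(key, default) config[[key]] %||% default
  weights <- score_weights(w_C = p("w_C", 0.5), w_F = p("w_F", 0.5),
                           F_cap = p("F_cap", 10))
  say("running discovery (k = ", p("k", 40), ", n_pc = ", p("n_pc", 80), ")")
  fit <- discover_sites(
    ms, corpus = corpus, site_proteins = site_proteins,
    k = p("k", 40L), n_pc = p("n_pc", 80L), m = p("m", 20L),
    min_size = p("min_size", 5L), fc_cutoff = p("fc_cutoff", 3.0),
    p_cutoff = p("p_cutoff", 0.01),
    entropy_cutoff = p("entropy_cutoff", 2.7), weights = weights,
    n_restarts = p("n_restarts", 10L), seed = p("seed", 1L))

  say("writing artifacts to ", out_dir)
  write_pca_json(fit$pca, file.path(out_dir, "pca.json"))
  write_coarse(fit$coarse, fit$reduced,
               file.path(out_dir, "coarse_assignments.tsv"),
               file.path(out_dir, "coarse_centroids.json"))
  all_scores <- do.call(rbind, lapply(names(fit$node_scores), function(cc) {
    cbind(coarse_id = cc, fit$node_scores[[cc]])
  }))
  utils::write.table(all_scores, file.path(out_dir, "node_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_records(fit$records, file.path(out_dir, "selected_clusters.tsv"),
                file.path(out_dir, "selected_clusters.json"))
  write_records(fit$clusters, file.path(out_dir, "filtered_clusters.tsv"),
                file.path(out_dir, "filtered_clusters.json"))

  if (length(fit$annotations)) {
    ann_all <- do.call(rbind, lapply(names(fit$annotations), function(cid) {
      a <- fit$annotations[[cid]]
      if (is.null(a) || !nrow(a)) return(NULL)
      cbind(cluster_id = cid, a)
    }))
    if (!is.null(ann_all)) {
      utils::write.table(ann_all, file.path(out_dir, "annotations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (has_corpus && nrow(fit$clusters)) {
    say("rendering HTML reports")
    html_dir <- file.path(out_dir, "html")
    for (i in seq_len(nrow(fit$clusters))) {
      cid <- fit$clusters$cluster_id[i]
      render_cluster_html(fit$clusters[i, ], fit$annotations[[cid]],
                          corpus, html_dir)
    }
  }
  manifest <- list(
    config = config,
    seed = p("seed", 1L),
    package_version = as.character(utils::packageVersion("foresite")),
    input_md5 = as.list(tools::md5sum(unlist(config[intersect(
      c("vectors", "protein_docs", "documents", "term_tables",
        "site_protein_map"), names(config))]))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: ", nrow(fit$clusters), " cluster(s) pass the filters")
  invisible(fit)
}
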