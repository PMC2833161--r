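# Static HTML cluster reports: one summary page per cluster plus one
# detail page per term category. Rendering is plain sprintf templating so
# output is deterministic (no timestamps, no environment-dependent text).

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

default_url_templates <- function() {
  list(pdb = "https://www.rcsb.org/structure/%s",
       uniprot = "https://www.uniprot.org/uniprotkb/%s",
       pubmed = "https://pubmed.ncbi.nlm.nih.gov/%s")
}

html_page <- function(title, body) {
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">\n<title>",
         html_escape(title), "</title>\n",
         "<style>body{font-family:sans-serif;margin:2em}",
         "table{border-collapse:collapse}",
         "td,th{border:1px solid #999;padding:4px 8px}</style>\n",
         "</head><body>\n", body, "\n</body></html>\n")
}

html_table <- function(df) {
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  rows <- apply(df, 1, function(r) {
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
  })
  paste0("<table>\n", head, "\n", paste(rows, collapse = "\n"), "\n</table>")
}

#' Render HTML report pages for an annotated cluster
#'
#' Writes one summary page (general cluster information, member sites and
#' proteins with external links, and the top-ranked terms per category
#' linking to detail pages) and one detail page per category listing every
#' term with its statistics and contributing proteins/documents (with
#' abstract text for literature terms). Categories without significant
#' terms are reported as such. Re-rendering identical inputs produces
#' byte-identical files.
#'
#' @param record 1-row cluster record (from [cluster_records()]).
#' @param term_scores data.frame from [annotate_cluster()] (may be NULL).
#' @param corpus a `knowledge_corpus` (for document text on detail pages).
#' @param out_dir output directory (created if needed).
#' @param url_templates named list of sprintf templates for `pdb`,
#'   `uniprot`, `pubmed` external links.
#' @param top_n terms shown per category on the summary page.
#' @return character vector of written file paths.
#' @export
render_cluster_html <- function(record, term_scores, corpus, out_dir,
                                url_templates = default_url_templates(),
                                top_n = 10L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cid <- record$cluster_id
  safe <- gsub("[^A-Za-z0-9_-]", "_", cid)
  paths <- character(0)

  categories <- if (!is.null(term_scores) && nrow(term_scores)) {
    sort(unique(term_scores$category))
  } else character(0)

  info <- data.frame(
    field = c("Cluster", "Size (N)", "Node correlation (C)",
              "Functional coherence (F)", "Score (S)"),
    value = c(html_escape(cid), record$N, signif(record$C, 4),
              signif(record$F, 4), signif(record$S, 4)))
  structs <- sort(unique(sub(":.*$", "", record$sites[[1]])))
  site_links <- vapply(structs, function(s) {
    sprintf("<a href=\"%s\">%s</a>", sprintf(url_templates$pdb, s), s)
  }, character(1))
  prot_links <- vapply(record$proteins[[1]], function(p) {
    sprintf("<a href=\"%s\">%s</a>", sprintf(url_templates$uniprot, p),
            html_escape(p))
  }, character(1))

  body <- paste0(
    "<h1>", html_escape(cid), "</h1>\n", html_table(info),
    "\n<h2>Member sites</h2>\n<p>",
    html_escape(paste(sort(record$sites[[1]]), collapse = ", ")),
    "</p>\n<p>Structures: ", paste(site_links, collapse = ", "),
    "</p>\n<h2>Member proteins</h2>\n<p>",
    paste(prot_links, collapse = ", "), "</p>\n")

  all_cats <- unique(c(categories,
                       if (!is.null(corpus$term_tables))
                         sort(unique(corpus$term_tables$category))))
  for (cat in all_cats) {
    body <- paste0(body, "<h2>Top terms: ", html_escape(cat), "</h2>\n")
    sub <- if (length(categories)) {
      term_scores[term_scores$category == cat, , drop = FALSE]
    } else term_scores
    if (is.null(sub) || !nrow(sub)) {
      body <- paste0(body, "<p>no significant terms</p>\n")
      next
    }
    sub <- utils::head(sub[order(sub$p_corrected, sub$term), ], top_n)
    show <- data.frame(term = html_escape(sub$term), k = sub$k,
                       p_corrected = signif(sub$p_corrected, 4),
                       entropy = ifelse(is.na(sub$entropy_score), "",
                                        signif(sub$entropy_score, 4)))
    detail <- sprintf("%s_%s.html", safe, cat)
    body <- paste0(body, html_table(show),
                   "\n<p><a href=\"", detail, "\">all ", cat,
                   " terms</a></p>\n")
  }
  summary_path <- file.path(out_dir, paste0(safe, ".html"))
  writeLines(html_page(paste("Cluster", cid), body), summary_path, sep = "")
  paths <- c(paths, summary_path)

  for (cat in all_cats) {
    sub <- if (!is.null(term_scores) && nrow(term_scores)) {
      term_scores[term_scores$category == cat, , drop = FALSE]
    } else NULL
    body <- paste0("<h1>", html_escape(cid), " &mdash; ", html_escape(cat),
                   " terms</h1>\n<p><a href=\"", safe,
                   ".html\">back to summary</a></p>\n")
    if (is.null(sub) || !nrow(sub)) {
      body <- paste0(body, "<p>no significant terms</p>\n")
    } else {
      sub <- sub[order(sub$p_corrected, sub$term), ]
      for (i in seq_len(nrow(sub))) {
        body <- paste0(
          body, "<h2>", html_escape(sub$term[i]), "</h2>\n",
          "<p>k = ", sub$k[i], " of n = ", sub$n[i],
          "; background K = ", sub$K[i], " of M = ", sub$M[i],
          "; raw p = ", signif(sub$p_raw[i], 4),
          "; corrected p = ", signif(sub$p_corrected[i], 4),
          if (!is.na(sub$entropy_score[i])) {
            paste0("; entropy score = ", signif(sub$entropy_score[i], 4))
          } else "", "</p>\n")
        contrib <- strsplit(sub$contributors[i], ",", fixed = TRUE)[[1]]
        body <- paste0(body, "<p>Contributing proteins: ",
                       paste(html_escape(contrib), collapse = ", "), "</p>\n")
        if (cat %in% c("unigram", "bigram")) {
          docs <- sort(unique(unlist(corpus$protein_docs[contrib])))
          docs <- docs[vapply(docs, function(d) {
            txt <- corpus$documents[corpus$documents$document_id == d, ]
            any(grepl(sub$term[i],
                      paste(txt$title, txt$abstract), fixed = TRUE))
          }, logical(1))]
          for (d in docs) {
            row <- corpus$documents[corpus$documents$document_id == d, ]
            body <- paste0(
              body, "<p><b><a href=\"", sprintf(url_templates$pubmed, d),
              "\">", html_escape(d), "</a></b> ",
              html_escape(row$title), " &mdash; <i>",
              html_escape(row$abstract), "</i></p>\n")
          }
        }
      }
    }
    detail_path <- file.path(out_dir, sprintf("%s_%s.html", safe, cat))
    writeLines(html_page(paste(cid, cat), body), detail_path, sep = "")
    paths <- c(paths, detail_path)
  }
  paths
}
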