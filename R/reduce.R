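#' Fit a principal-component model to standardized microenvironment vectors
#'
#' Vectors are centered (the mean is stored in the model) and projected onto
#' the leading principal axes. The decomposition is delegated to
#' [stats::prcomp()]; on top of it a deterministic sign convention is
#' applied so that for every component the loading with the largest
#' magnitude is positive, making fits reproducible across platforms.
#'
#' @param ms a `microenv_set` with `space_tag = "standardized"`.
#' @param n_components number of components, between 1 and
#'   `min(n_sites - 1, n_features)`.
#' @return An object of class `microenv_pca` with elements `mean`
#'   (feature means), `components` (n_components x D matrix of orthonormal
#'   rows), `explained_variance` (non-increasing, sample variance of the
#'   scores along each axis) and `feature_names`.
#' @export
fit_pca <- function(ms, n_components) {
  stopifnot(inherits(ms, "microenv_set"))
  if (ms$space_tag != "standardized") {
    stop("fit_pca() expects a standardized set; call standardize() first")
  }
  x <- ms$features
  nmax <- min(nrow(x) - 1L, ncol(x))
  if (!(n_components >= 1 && n_components <= nmax)) {
    stop("n_components must be in [1, ", nmax, "], got ", n_components)
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  comp <- t(pr$rotation[, seq_len(n_components), drop = FALSE])
  # sign convention: largest-|loading| entry of each component positive
  for (i in seq_len(nrow(comp))) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  structure(
    list(mean = colMeans(x),
         components = comp,
         explained_variance = pr$sdev[seq_len(n_components)]^2,
         feature_names = colnames(x)),
    class = "microenv_pca")
}

#' @export
print.microenv_pca <- function(x, ...) {
  cat("PCA model: ", nrow(x$components), " components over ",
      ncol(x$components), " features\n", sep = "")
  cat("  explained variance (first 5): ",
      paste(signif(utils::head(x$explained_variance, 5), 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Project microenvironment vectors onto a fitted PCA model
#'
#' @param object a `microenv_pca` model.
#' @param ms a `microenv_set` whose feature dimension matches the model.
#' @param ... unused.
#' @return A `microenv_set` with `space_tag = "reduced"` and feature names
#'   `PC1..PCn`.
#' @export
predict.microenv_pca <- function(object, ms, ...) {
  stopifnot(inherits(ms, "microenv_set"))
  if (ncol(ms$features) != ncol(object$components)) {
    stop("dimension mismatch: model has ", ncol(object$components),
         " features, data has ", ncol(ms$features))
  }
  scores <- sweep(ms$features, 2, object$mean, "-") %*% t(object$components)
  colnames(scores) <- paste0("PC", seq_len(nrow(object$components)))
  out <- ms
  out$features <- scores
  out$space_tag <- "reduced"
  out
}

#' @rdname predict.microenv_pca
#' @param model a `microenv_pca` model.
#' @export
reduce_vectors <- function(model, ms) predict(model, ms)

#' Features contributing most to a principal component
#'
#' @param model a `microenv_pca`.
#' @param component 1-based component index.
#' @param n number of features (clamped to the total feature count).
#' @return data.frame(feature, weight) sorted by decreasing `|weight|`,
#'   ties broken by feature index.
#' @export
top_loadings <- function(model, component, n = 5) {
  stopifnot(inherits(model, "microenv_pca"))
  if (component < 1 || component > nrow(model$components)) {
    stop("component out of range")
  }
  w <- model$components[component, ]
  ord <- order(-abs(w), seq_along(w))
  ord <- ord[seq_len(min(n, length(w)))]
  data.frame(feature = model$feature_names[ord], weight = unname(w[ord]),
             stringsAsFactors = FALSE)
}

#' Serialize / restore a PCA model as JSON
#' @param model a `microenv_pca`.
#' @param path file path.
#' @return `path` invisibly, or the restored model.
#' @export
write_pca_json <- function(model, path) {
  jsonlite::write_json(
    list(mean = model$mean, components = model$components,
         explained_variance = model$explained_variance,
         feature_names = model$feature_names),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_pca_json
#' @export
read_pca_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- j$components
  if (!is.matrix(comp)) comp <- do.call(rbind, lapply(comp, as.numeric))
  structure(list(mean = as.numeric(j$mean),
                 components = unname(comp),
                 explained_variance = as.numeric(j$explained_variance),
                 feature_names = as.character(j$feature_names)),
            class = "microenv_pca")
}
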