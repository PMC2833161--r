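#' Microenvironment vector sets
#'
#' A microenvironment is a spherical region (default radius 7.5 Angstrom)
#' around a site of interest in a protein structure, summarized as a numeric
#' vector of physicochemical property counts collected over concentric
#' radial shells (default 6). A `microenv_set` bundles site identifiers with
#' the sites x features matrix and records which space the matrix lives in:
#' `"raw"` property counts, `"standardized"` (each feature divided by its
#' population standard deviation), or `"reduced"` (principal-component
#' scores).
#'
#' @param sites data.frame with columns `structure_id` (4-character
#'   structure code), `chain`, `residue_number` (integer) and
#'   `residue_name` (3-letter code, stored uppercase). The triple
#'   (structure_id, chain, residue_number) must be unique.
#' @param features numeric matrix, one row per site, all values finite.
#' @param space_tag one of `"raw"`, `"standardized"`, `"reduced"`.
#' @param n_shells number of concentric shells the features are binned over.
#' @param radius_angstrom total microenvironment radius in Angstrom.
#' @return An object of class `microenv_set`.
#' @export
microenv_set <- function(sites, features,
                         space_tag = "raw",
                         n_shells = 6L,
                         radius_angstrom = 7.5) {
  stopifnot(is.data.frame(sites))
  req <- c("structure_id", "chain", "residue_number", "residue_name")
  miss <- setdiff(req, names(sites))
  if (length(miss)) stop("sites is missing column(s): ", paste(miss, collapse = ", "))
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) != nrow(sites)) {
    stop("feature matrix has ", nrow(features), " rows but there are ",
         nrow(sites), " sites")
  }
  if (!all(is.finite(features))) stop("non-finite values in feature matrix")
  space_tag <- match.arg(space_tag, c("raw", "standardized", "reduced"))
  sites$residue_name <- toupper(as.character(sites$residue_name))
  sites$residue_number <- as.integer(sites$residue_number)
  key <- site_key(sites)
  if (anyDuplicated(key)) {
    stop("duplicate site identifier(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  rownames(features) <- NULL
  structure(
    list(sites = sites, features = features, space_tag = space_tag,
         n_shells = as.integer(n_shells), radius_angstrom = radius_angstrom),
    class = "microenv_set")
}

# (structure_id, chain, residue_number) uniquely identifies a site.
site_key <- function(sites) {
  paste(sites$structure_id, sites$chain, sites$residue_number, sep = ":")
}

#' @export
print.microenv_set <- function(x, ...) {
  cat("Microenvironment set: ", nrow(x$features), " sites x ",
      ncol(x$features), " features [", x$space_tag, "]\n", sep = "")
  cat("  shells: ", x$n_shells, ", radius: ", x$radius_angstrom, " A\n", sep = "")
  invisible(x)
}

#' @export
dim.microenv_set <- function(x) dim(x$features)

#' Read microenvironment vectors from a TSV file
#'
#' The expected layout is a header row with the four site-identifier columns
#' `structure_id`, `chain`, `residue_number`, `residue_name` followed by one
#' numeric column per feature; one data row per site.
#'
#' @param path path to a tab-separated file.
#' @return A `microenv_set` with `space_tag = "raw"`; row order preserved.
#' @export
read_vectors <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  id_cols <- c("structure_id", "chain", "residue_number", "residue_name")
  miss <- setdiff(id_cols, names(df))
  if (length(miss)) stop("vector file missing column(s): ", paste(miss, collapse = ", "))
  feat_cols <- setdiff(names(df), id_cols)
  if (!length(feat_cols)) stop("vector file has no feature columns")
  for (cn in feat_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) || anyNA(vn)) {
        row <- if (length(bad)) bad[1] else which(is.na(vn))[1]
        stop("non-numeric or missing value in column '", cn, "' at data row ", row)
      }
      v <- vn
    }
    if (anyNA(v)) {
      stop("non-numeric or missing value in column '", cn,
           "' at data row ", which(is.na(v))[1])
    }
    df[[cn]] <- v
  }
  microenv_set(df[id_cols], as.matrix(df[feat_cols]))
}

#' Write microenvironment vectors to a TSV file
#'
#' Inverse of [read_vectors()]; full precision so that a round trip
#' reproduces the matrix bit-exactly.
#'
#' @param ms a `microenv_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(ms, path) {
  stopifnot(inherits(ms, "microenv_set"))
  feat <- as.data.frame(ms$features)
  # 17 significant digits round-trips IEEE doubles exactly
  feat[] <- lapply(feat, function(v) sprintf("%.17g", v))
  df <- cbind(ms$sites[c("structure_id", "chain", "residue_number", "residue_name")],
              feat)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standardize microenvironment features
#'
#' Divides every feature column by its population (divisor n) standard
#' deviation computed across the whole set, so that each non-constant
#' feature has unit spread. Constant columns (standard deviation zero) are
#' left unchanged, avoiding NaN propagation. No centering is applied at this
#' stage.
#'
#' @param ms a `microenv_set` with `space_tag = "raw"` and at least 2 sites.
#' @return A `microenv_set` with `space_tag = "standardized"`.
#' @export
standardize <- function(ms) {
  stopifnot(inherits(ms, "microenv_set"))
  if (ms$space_tag != "raw") stop("standardize() expects a raw-space set")
  x <- ms$features
  if (nrow(x) < 2) stop("standard deviation undefined for a single site")
  sds <- apply(x, 2, pop_sd)
  sds[sds == 0] <- 1
  out <- ms
  out$features <- sweep(x, 2, sds, "/")
  out$space_tag <- "standardized"
  out
}
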