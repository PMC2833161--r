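# Internal numeric helpers shared across the pipeline.

# Row-wise L2 normalization. Zero rows are rejected: every clustering stage
# works on the unit sphere and a zero vector has no direction.
unit_rows <- function(x, what = "feature matrix") {
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) {
    stop("all-zero row(s) in ", what, " at position(s): ",
         paste(which(nrm == 0), collapse = ", "))
  }
  x / nrm
}

# Cosine similarity between two vectors (no normalization assumed).
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Full pairwise cosine distance matrix (1 - cosine) for unit-normalized rows.
cosine_dist_matrix <- function(x) {
  u <- unit_rows(as.matrix(x))
  d <- 1 - tcrossprod(u)
  d[d < 0] <- 0   # guard FP noise
  diag(d) <- 0
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population standard deviation (divisor n).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
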