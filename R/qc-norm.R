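# Replicate / sample-relationship QC: trimmed-mean-of-M-values (TMM)
# scaling factors, Spearman correlation matrices with midranks, and
# classical MDS on leading log-fold-change distances. All three are
# implemented here directly (not delegated), so the test suite can hold
# them against independent oracles.

#' TMM scaling factors for a count matrix
#'
#' Implements the trimmed mean of M-values: against a reference sample,
#' gene-wise log2 expression ratios (M) and average log2 abundances (A)
#' are computed over genes with nonzero counts in both samples; the
#' `trim_m` most extreme M on each side and the `trim_a` most extreme A
#' on each side are discarded, and the factor is 2 to the
#' precision-weighted mean of the remaining M (weights are inverse
#' binomial variances). Factors are rescaled to geometric mean 1.
#'
#' @param counts Nonnegative count matrix (features x samples).
#' @param trim_m Two-sided trim fraction on M (default 0.30).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @param reference Reference column index/name, or `"auto"`: the sample
#'   whose upper-quartile of library-size-scaled counts is closest to
#'   the mean upper-quartile.
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        reference = "auto") {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  zero_col <- lib == 0
  if (any(zero_col)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[zero_col], collapse = ", "), call. = FALSE)
  }
  if (identical(reference, "auto")) {
    f75 <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(reference)) {
    ref <- match(reference, colnames(counts))
    if (is.na(ref)) stop("unknown reference sample", call. = FALSE)
  } else {
    ref <- as.integer(reference)
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
              trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0L) return(1)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(m[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

#' TMM-normalized expression values
#'
#' @param counts Count matrix (features x samples).
#' @param factors Output of [tmm_factors()] (computed when `NULL`).
#' @return Matrix of `count / (library_size * factor) * 1e6`.
#' @export
normalize_tmm <- function(counts, factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  lib <- colSums(counts)
  sweep(counts, 2, lib * factors, "/") * 1e6
}

# Pearson correlation written out longhand (kept independent from
# stats::cor so tests can use the latter as an oracle)
.pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(dx * dy) / (sx * sy)
}

#' Pairwise Spearman correlation matrix
#'
#' Rank correlation with average ranks for ties (midranks), computed as
#' the Pearson correlation of the rank vectors. Constant columns yield
#' `NA` entries with a warning.
#'
#' @param m Expression matrix (features x samples), >= 2 samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(ncol(m) >= 2L)
  ranks <- apply(m, 2, rank)  # average ranks for ties
  n <- ncol(m)
  out <- diag(1, n)
  dimnames(out) <- list(colnames(m), colnames(m))
  warned <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- .pearson(ranks[, i], ranks[, j])
      if (is.na(r)) warned <- TRUE
      out[i, j] <- out[j, i] <- r
    }
  }
  if (warned) {
    warning("constant column(s): some correlations undefined (NA)",
            call. = FALSE)
  }
  out
}

#' Classical MDS coordinates from leading log-fold-change distances
#'
#' The distance between two samples is the root-mean-square of the
#' `top_n` largest absolute log2 fold-changes between them, computed on
#' `log2(x + prior_count)` of the normalized values. Coordinates come
#' from classical (Torgerson) scaling: double-centred squared-distance
#' matrix, top eigenvectors scaled by the square roots of their
#' eigenvalues. Output is unique only up to sign and rotation.
#'
#' @param norm Normalized expression matrix (features x samples).
#' @param top_n Number of leading fold-changes per pair (default 500,
#'   capped at the feature count).
#' @param dims Number of dimensions (must be < number of samples).
#' @param prior_count Offset added before taking logs (default 0.5).
#' @return List with `coords` (samples x dims matrix) and `dist`
#'   (samples x samples distance matrix).
#' @export
mds_coordinates <- function(norm, top_n = 500, dims = 2,
                            prior_count = 0.5) {
  norm <- as.matrix(norm)
  n <- ncol(norm)
  if (dims >= n) stop("dims must be smaller than the number of samples",
                      call. = FALSE)
  lg <- log2(norm + prior_count)
  top_n <- min(top_n, nrow(norm))
  d <- matrix(0, n, n, dimnames = list(colnames(norm), colnames(norm)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      lfc <- sort(abs(lg[, i] - lg[, j]), decreasing = TRUE)[seq_len(top_n)]
      d[i, j] <- d[j, i] <- sqrt(mean(lfc^2))
    }
  }
  d2 <- d^2
  centering <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * centering %*% d2 %*% centering
  eig <- eigen(b, symmetric = TRUE)
  ev <- pmax(eig$values[seq_len(dims)], 0)
  coords <- eig$vectors[, seq_len(dims), drop = FALSE] %*%
    diag(sqrt(ev), nrow = dims)
  rownames(coords) <- colnames(norm)
  colnames(coords) <- paste0("dim", seq_len(dims))
  list(coords = coords, dist = d)
}
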