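#' Pearson correlation of two response vectors
#'
#' Product-moment correlation over responses at matched dilution levels
#' (typically LOAEC/2, /4, /8). With vectors of unequal length or
#' missing levels, only pairwise-complete positions are used and at
#' least two shared points are required. Zero variance in either vector
#' makes r undefined; it is reported as `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return The correlation coefficient, or `NA_real_`.
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 3, 2)) # 0.5
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("vectors must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2L) stop("need >= 2 shared finite observations")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

#' Contribution of single chemicals to mixture effects
#'
#' Correlates each single chemical's response profile across the shared
#' dilution levels with each mixture's profile. High positive r: the
#' chemical moves with the mixture (a plausible driver); negative r:
#' opposite effect directionality — the green/yellow encoding of the
#' published contribution heatmaps.
#'
#' @param singles Named list of numeric response vectors (one per
#'   chemical), all in the same fixed dilution-level order.
#' @param mixtures Named list of mixture response vectors in the same
#'   level order (a single vector is accepted).
#' @return Matrix of correlations, rows = single chemicals,
#'   columns = mixtures.
#' @export
contribution_heatmap <- function(singles, mixtures) {
  stopifnot(is.list(singles), length(singles) >= 1)
  if (!is.list(mixtures)) mixtures <- list(mixture = mixtures)
  len <- unique(c(lengths(singles), lengths(mixtures)))
  if (length(len) != 1L) {
    stop("all response vectors must share the dilution-level order/length")
  }
  out <- matrix(
    NA_real_, nrow = length(singles), ncol = length(mixtures),
    dimnames = list(names(singles), names(mixtures)))
  for (i in seq_along(singles)) {
    for (j in seq_along(mixtures)) {
      out[i, j] <- pearson_r(singles[[i]], mixtures[[j]])
    }
  }
  out
}

#' Pairwise similarity of mixtures over all endpoints
#'
#' Correlates mixtures pairwise over their concatenated effect profiles
#' (delta values across all endpoints/features), yielding the symmetric
#' unit-diagonal matrix summarised in cross-study correlation plots.
#'
#' @param mixtures Named list of numeric vectors, all sharing one
#'   endpoint/feature ordering.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
mixture_similarity <- function(mixtures) {
  stopifnot(is.list(mixtures), length(mixtures) >= 2)
  if (length(unique(lengths(mixtures))) != 1L) {
    stop("mixtures must share the endpoint/feature ordering (equal length)")
  }
  n <- length(mixtures)
  out <- diag(1, n)
  dimnames(out) <- list(names(mixtures), names(mixtures))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      out[i, j] <- out[j, i] <- pearson_r(mixtures[[i]], mixtures[[j]])
    }
  }
  out
}

#' Render a correlation matrix as a heatmap
#'
#' Thin wrapper around pheatmap with a green (positive, same
#' directionality) to yellow (negative, opposite directionality)
#' palette. Cosmetic only; the matrices themselves are the interface.
#'
#' @param mat Correlation matrix.
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_correlation_heatmap <- function(mat, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("install 'pheatmap' to render heatmaps")
  }
  pal <- grDevices::colorRampPalette(
    c("#b8860b", "#f7f7c6", "#006400"))(101)
  p <- pheatmap::pheatmap(mat, color = pal,
                          breaks = seq(-1, 1, length.out = 102),
                          cluster_rows = FALSE, cluster_cols = FALSE, ...)
  invisible(p)
}
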