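#' Gaussian mutual information between two expression profiles
#'
#' Uses the covariance-determinant form for (assumed) bivariate Gaussian
#' variables,
#' \deqn{I(X,Y) = \tfrac12 \log\frac{|C(X)|\,|C(Y)|}{|C(X,Y)|},}
#' with sample (n-1) covariances and the natural logarithm, so values are in
#' nats. For two scalars this equals \eqn{-\tfrac12\log(1 - r^2)} where r is
#' the sample Pearson correlation; MI is therefore invariant under per-gene
#' affine rescaling such as z-scoring. A singular joint covariance (constant
#' input or perfect collinearity) yields the +Inf sentinel with a warning, so
#' thresholding still works. Tiny negative round-off is clamped to 0.
#'
#' @param x,y Numeric vectors of equal length n >= 3.
#' @return MI in nats (>= 0), or +Inf for singular pairs.
#' @export
mi_pair <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("mi_pair: vectors of unequal length")
  if (n < 3L) stop("mi_pair: need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("mi_pair: non-finite values")
  vx <- stats::var(x)
  vy <- stats::var(y)
  cxy <- stats::cov(x, y)
  det_joint <- vx * vy - cxy * cxy
  if (vx <= 0 || vy <= 0 || det_joint <= 0) {
    warning("singular covariance in mi_pair; returning +Inf sentinel")
    return(Inf)
  }
  max(0, 0.5 * log(vx * vy / det_joint))
}

#' Pairwise Gaussian mutual information matrix
#'
#' Fills every unordered gene pair with [mi_pair()] computed vectorially from
#' the sample covariance matrix of the rows; symmetric by construction. The
#' diagonal carries the +Inf sentinel (a gene is maximally informative about
#' itself). Singular pairs (e.g. rows left constant by preprocessing) get the
#' +Inf sentinel rather than aborting the matrix.
#'
#' @param expr Numeric matrix, genes x observations, >= 3 observations.
#' @return Symmetric numeric matrix with the gene IDs as dimnames, MI in nats.
#' @export
pairwise_mi <- function(expr) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 3L) stop("pairwise_mi: need at least 3 observations")
  if (anyNA(expr)) stop("pairwise_mi: missing values present; interpolate first")
  C <- stats::cov(t(expr))
  v <- diag(C)
  vv <- outer(v, v)
  det_joint <- vv - C * C
  bad <- det_joint <= 0 | outer(v <= 0, v <= 0, "|")
  mi <- 0.5 * log(vv / det_joint)
  mi[mi < 0] <- 0
  mi[bad] <- Inf
  diag(mi) <- Inf
  n_bad <- (sum(bad) - sum(diag(bad))) / 2
  if (n_bad > 0) {
    warning(n_bad, " singular gene pair(s) set to the +Inf MI sentinel")
  }
  dimnames(mi) <- list(rownames(expr), rownames(expr))
  mi
}

#' Dump an MI matrix as TSV for inspection
#'
#' @param mi Symmetric MI matrix from [pairwise_mi()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mi_matrix <- function(mi, path) {
  df <- data.frame(gene = rownames(mi), mi, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
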