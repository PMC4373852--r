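#' Fill missing expression values by linear interpolation
#'
#' Observations are treated as an ordered series within each gene row.
#' Interior gaps are filled by linear interpolation between the flanking
#' observed values; leading/trailing gaps take the nearest observed value.
#' Observed values are never altered.
#'
#' @param expr Numeric matrix, genes x observations, possibly with NAs.
#' @return The matrix with no missing values.
#' @export
interpolate_missing <- function(expr) {
  stopifnot(is.matrix(expr))
  if (!anyNA(expr)) return(expr)
  for (i in seq_len(nrow(expr))) {
    row <- expr[i, ]
    if (all(is.na(row))) {
      stop("gene '", rownames(expr)[i], "' has no observed values")
    }
    if (anyNA(row)) {
      expr[i, ] <- stats::approx(seq_along(row), row, xout = seq_along(row),
                                 method = "linear", rule = 2)$y
    }
  }
  expr
}

#' Z-score each gene row
#'
#' Centers and scales every row to zero mean and unit sample standard
#' deviation (n-1 denominator, matching the sample covariance used by the MI
#' estimator). Constant rows cannot be scaled and are mapped to all-zero with
#' a warning.
#'
#' @param expr Numeric matrix without missing values.
#' @return The normalized matrix.
#' @export
normalize_expression <- function(expr) {
  stopifnot(is.matrix(expr))
  if (anyNA(expr)) stop("normalize_expression: missing values present; interpolate first")
  mu <- rowMeans(expr)
  sd <- apply(expr, 1L, stats::sd)
  const <- sd == 0
  if (any(const)) {
    warning(sum(const), " constant gene row(s) mapped to zero: ",
            paste(utils::head(rownames(expr)[const], 5L), collapse = ", "))
    sd[const] <- 1
  }
  out <- (expr - mu) / sd
  out[const, ] <- 0
  out
}
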