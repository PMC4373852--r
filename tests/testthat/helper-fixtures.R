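# Shared fixture builders. Everything is generated in code at test time.

# Random expression matrix with named genes/observations.
rand_expr <- function(n_genes, n_obs, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_obs), n_genes, n_obs,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("t%02d", seq_len(n_obs))))
  m
}

# Write an expression matrix to a temp TSV and return the path.
write_expr_tsv <- function(m, sep = "\t") {
  path <- tempfile(fileext = if (sep == "\t") ".tsv" else ".csv")
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Planted least-squares system with a generic (iid normal) design:
# response = design %*% coef exactly, so recovery must be exact up to
# numerical precision.
planted_system <- function(n_rows, n_cols, n_nonzero = n_cols, seed = 1) {
  set.seed(seed)
  H <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  colnames(H) <- sprintf("g%02d", seq_len(n_cols))
  p <- numeric(n_cols)
  nz <- sample(n_cols, n_nonzero)
  p[nz] <- sample(c(-1, 1), n_nonzero, TRUE) * runif(n_nonzero, 0.2, 1)
  list(design = H, response = drop(H %*% p), coef = p,
       target_gene = colnames(H)[1L], column_gene_ids = colnames(H))
}

# Aggregate relative coefficient error of an inferred network against a
# planted truth matrix (Frobenius norm ratio over all off-diagonal entries).
coef_rel_error <- function(net, truth) {
  A <- truth$coefficients
  w <- net$weights
  est <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  est[cbind(w$target, w$regulator)] <- w$weight
  offd <- row(A) != col(A)
  sqrt(sum((est[offd] - A[offd])^2) / sum(A[offd]^2))
}
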