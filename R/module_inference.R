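#' Select cross-module candidate regulators for one module
#'
#' For each other module the cross pairs (x in module i, y in module m) are
#' ranked by MI descending (ties broken lexicographically by the (x, y) gene
#' IDs, NA ranks last) and the top `ceiling(fraction * count)` pairs are
#' kept — the sparsity-motivated "top few percent" rule that links otherwise
#' separated modules. The candidate set is the union of the external (y)
#' endpoints of kept pairs, deduplicated in first-appearance rank order.
#'
#' @param i Module index.
#' @param part A `module_partition` with empty `kicked_out`.
#' @param mi Symmetric MI matrix.
#' @param fraction Fraction in (0,1] of cross pairs kept per module pair.
#' @return List with `module_index` and `external_genes` (character, possibly
#'   empty for a single-module partition).
#' @export
select_candidate_set <- function(i, part, mi, fraction = 0.05) {
  stopifnot(inherits(part, "module_partition"),
            fraction > 0, fraction <= 1,
            i >= 1, i <= length(part$modules))
  own <- part$modules[[i]]
  ext <- character()
  for (m in seq_along(part$modules)) {
    if (m == i) next
    other <- part$modules[[m]]
    pairs <- expand.grid(x = own, y = other, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
    val <- mi[cbind(pairs$x, pairs$y)]
    val[is.na(val)] <- -Inf
    ord <- order(-val, pairs$x, pairs$y)
    keep <- ord[seq_len(ceiling(fraction * nrow(pairs)))]
    ext <- c(ext, pairs$y[keep])
  }
  list(module_index = i, external_genes = unique(ext))
}

#' Assemble the per-target linear system for one module
#'
#' The linear ODE model for target gene j in module i reads
#' \deqn{d_j(t_m) = x_j(t_m) - x_j(t_{m-1}) = \sum_k a_{jk} x_k(t_m),}
#' where k ranges over the module's own genes (internal weights) followed by
#' the candidate external regulators. With T ordered observations this gives
#' T-1 rows (m = 2..T): design row m-1 holds the regressor expression at time
#' t_m and the response holds the backward difference of the target. The
#' target's own column is included (self-regulation is estimated but never
#' reported as an edge).
#'
#' @param j Target gene ID (must belong to module i).
#' @param i Module index.
#' @param part A `module_partition`.
#' @param cand Candidate set from [select_candidate_set()] for module i.
#' @param expr Preprocessed expression matrix (genes x T, T >= 3).
#' @return List with `design` ((T-1) x (Ti+Hi) matrix), `response` (length
#'   T-1), `target_gene`, `column_gene_ids`.
#' @export
build_linear_system <- function(j, i, part, cand, expr) {
  own <- part$modules[[i]]
  if (!(j %in% own)) stop("target gene '", j, "' is not in module ", i)
  Tn <- ncol(expr)
  if (Tn < 3L) stop("need at least 3 observations")
  cols <- c(own, cand$external_genes)
  design <- t(expr[cols, 2:Tn, drop = FALSE])
  dimnames(design) <- list(NULL, cols)
  xj <- expr[j, ]
  list(design = design,
       response = xj[2:Tn] - xj[1:(Tn - 1L)],
       target_gene = j,
       column_gene_ids = cols)
}

# Column-equilibrated pivoted-QR least squares; minimum-norm completion on
# rank deficiency. Column scaling is a solution-preserving reparameterization
# that substantially improves the conditioning of designs whose regressor
# trajectories have decayed to very different scales.
qr_least_squares <- function(H, d) {
  sc <- sqrt(colSums(H * H))
  sc[sc == 0] <- 1
  Hs <- sweep(H, 2L, sc, "/")
  qrx <- qr(Hs, LAPACK = TRUE)
  rnk <- sum(abs(diag(qr.R(qrx))) > max(dim(Hs)) * .Machine$double.eps *
               max(abs(diag(qr.R(qrx))), 1e-300))
  if (rnk == ncol(Hs)) {
    p <- qr.coef(qrx, d)
  } else {
    # rank-deficient: fall through to the SVD minimum-norm solution
    sv <- svd(Hs)
    tol <- max(dim(Hs)) * .Machine$double.eps * sv$d[1L]
    pos <- sv$d > tol
    p <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], d)) / sv$d[pos])
    p <- drop(p)
  }
  p <- p / sc
  names(p) <- colnames(H)
  p
}

#' Solve a module linear system for its coefficient vector
#'
#' Minimizes \eqn{\|H P - D\|_2}. The 2-norm condition number of the design
#' picks the branch: above `cond_threshold` (or rank-deficient) the system is
#' solved by Householder QR with column pivoting, completed to the
#' minimum-norm solution when rank-deficient; otherwise the normal equations
#' \eqn{H^T H P = H^T D} are formed and solved by Gaussian elimination with
#' partial pivoting (LAPACK LU). Both branches apply solution-preserving
#' column equilibration first and agree to ~1e-8 relative on well-conditioned
#' systems. A singular normal-equations matrix falls back to the QR branch
#' with a warning.
#'
#' @param sys System from [build_linear_system()].
#' @param cond_threshold Condition-number bound (default 1e6): squaring in the
#'   normal equations doubles the exponent, so 1e6 keeps that branch within
#'   double-precision safety.
#' @param ridge Optional non-negative ridge term added to the normal-equation
#'   diagonal (default 0, i.e. plain least squares).
#' @param force Force `"qr"` or `"normal"` (testing hook); default `"auto"`.
#' @return Named numeric coefficient vector (names = `column_gene_ids`) with
#'   attribute `target_gene`.
#' @export
solve_coefficients <- function(sys, cond_threshold = 1e6, ridge = 0,
                               force = c("auto", "qr", "normal")) {
  force <- match.arg(force)
  H <- sys$design
  d <- sys$response
  if (is.null(dim(H)) || ncol(H) == 0L) stop("empty design matrix")
  branch <- force
  if (branch == "auto") {
    kap <- tryCatch(kappa(H, exact = TRUE), error = function(e) Inf)
    branch <- if (!is.finite(kap) || kap > cond_threshold) "qr" else "normal"
  }
  if (branch == "normal") {
    sc <- sqrt(colSums(H * H)); sc[sc == 0] <- 1
    Hs <- sweep(H, 2L, sc, "/")
    G <- crossprod(Hs)
    if (ridge > 0) G <- G + diag(ridge, ncol(G))
    b <- crossprod(Hs, d)
    p <- tryCatch(drop(solve(G, b)) / sc, error = function(e) NULL)
    if (is.null(p)) {
      warning("normal equations singular; falling back to QR branch")
      p <- qr_least_squares(H, d)
    }
  } else {
    p <- qr_least_squares(H, d)
  }
  names(p) <- sys$column_gene_ids
  attr(p, "target_gene") <- sys$target_gene
  p
}

#' Threshold a coefficient vector into directed edges
#'
#' A regulator column survives iff its coefficient magnitude strictly exceeds
#' `theta`; the target's own column (self-regulation) is never reported.
#' Coefficients are signed regulation weights, so the cut is on |beta|.
#'
#' @param coef Named coefficient vector from [solve_coefficients()].
#' @param theta Magnitude cutoff >= 0.
#' @return data.frame (regulator, target) of retained directed edges.
#' @export
binarize_coefficients <- function(coef, theta) {
  tgt <- attr(coef, "target_gene")
  keep <- abs(coef) > theta & names(coef) != tgt
  data.frame(regulator = names(coef)[keep],
             target = rep(tgt, sum(keep)),
             stringsAsFactors = FALSE)
}

#' Infer the network fragment of one module
#'
#' Runs build/solve for every target gene of module i and returns all
#' estimated non-self coefficients as the module's rows of the global
#' network. A failure on one target is logged and skipped, not fatal.
#'
#' @param i Module index.
#' @param part A `module_partition` (exhaustive).
#' @param cand Candidate set for module i.
#' @param expr Preprocessed expression matrix.
#' @param config A `lsgrn_config`.
#' @return data.frame (regulator, target, weight, module) of weighted pairs;
#'   zero coefficients are dropped (they carry no rank information).
#' @export
infer_module <- function(i, part, cand, expr, config = lsgrn_config()) {
  own <- part$modules[[i]]
  frags <- vector("list", length(own))
  for (k in seq_along(own)) {
    j <- own[k]
    frags[[k]] <- tryCatch({
      sys <- build_linear_system(j, i, part, cand, expr)
      p <- solve_coefficients(sys, cond_threshold = config$cond_threshold,
                              ridge = config$ridge)
      sel <- names(p) != j & p != 0
      data.frame(regulator = names(p)[sel], target = rep(j, sum(sel)),
                 weight = as.numeric(p[sel]), stringsAsFactors = FALSE)
    }, error = function(e) {
      message("module ", i, ", target '", j, "' skipped: ", conditionMessage(e))
      NULL
    })
  }
  out <- do.call(rbind, frags)
  if (is.null(out)) {
    out <- data.frame(regulator = character(), target = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  }
  out$module <- rep(i, nrow(out))
  out
}
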