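#' Generate a planted modular sparse regulatory network
#'
#' Genes are split evenly into modules. Exactly
#' `round(density * n * (n-1))` off-diagonal coefficients are planted,
#' sampled without replacement with within-module ordered pairs weighted
#' `modularity_bias` : 1 against cross-module pairs, so the realized density
#' matches the request to within one entry while intra-module edges dominate
#' whenever the bias exceeds 1. Planted weights are signed and uniform in
#' magnitude on `[min_weight, weight_range]`; the dead zone below
#' `min_weight` guarantees a separating theta exists for structure recovery.
#' Every gene additionally receives a negative self-decay coefficient drawn
#' from `-decay_range`; self-regulation stabilizes the linear dynamics and
#' makes the simulated trajectories informative (pairwise-distinct decay
#' rates give the propagation matrix a full set of distinct modes), and
#' self-edges are never part of the scored network.
#'
#' @param n_genes Number of genes N >= n_modules.
#' @param n_modules Number of planted modules >= 1.
#' @param density Target fraction of nonzero off-diagonal entries, in (0,1).
#' @param modularity_bias Intra- vs cross-module placement odds (default 3).
#' @param weight_range Maximum |weight| (default 0.5).
#' @param min_weight Dead zone: minimum |weight| (default 0.2).
#' @param decay_range Range of self-decay magnitudes (default c(0.05, 0.5)).
#' @param seed Integer seed; the same seed reproduces the same truth.
#' @return A `synthetic_truth`: list with `coefficients` (N x N matrix A,
#'   A[j,k] = effect of gene k on gene j), `module_labels` (integer vector),
#'   `gene_ids`, `seed`.
#' @export
generate_truth <- function(n_genes, n_modules, density,
                           modularity_bias = 3, weight_range = 0.5,
                           min_weight = 0.2, decay_range = c(0.05, 0.5),
                           seed = 1L) {
  stopifnot(n_genes >= n_modules, n_modules >= 1,
            density > 0, density < 1,
            weight_range >= min_weight, min_weight > 0,
            modularity_bias > 0)
  K <- round(density * n_genes * (n_genes - 1))
  if (K < 1) stop("density too low: no edge to plant")
  if (K > n_genes * (n_genes - 1)) stop("infeasible density")
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  gene_ids <- sprintf("G%0*d", nchar(n_genes), seq_len(n_genes))
  labels <- sort(rep_len(seq_len(n_modules), n_genes))
  intra <- outer(labels, labels, "==")
  w <- ifelse(intra, modularity_bias, 1)
  diag(w) <- 0
  idx <- sample.int(n_genes * n_genes, K, prob = as.vector(w))
  A <- matrix(0, n_genes, n_genes, dimnames = list(gene_ids, gene_ids))
  A[idx] <- sample(c(-1, 1), K, replace = TRUE) *
    stats::runif(K, min_weight, weight_range)
  diag(A) <- -stats::runif(n_genes, decay_range[1L], decay_range[2L])
  structure(list(coefficients = A, module_labels = labels,
                 gene_ids = gene_ids, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  A <- x$coefficients
  nz <- sum(A != 0) - nrow(A)
  cat("Synthetic truth:", nrow(A), "genes,",
      length(unique(x$module_labels)), "modules,", nz, "planted edges\n")
  invisible(x)
}

#' Planted edges of a synthetic truth as a gold standard
#'
#' Self-loops (the stabilizing decay diagonal) are excluded, matching the
#' convention that self-edges are never scored.
#'
#' @param truth A `synthetic_truth`.
#' @return A `gold_standard` over the truth's gene set.
#' @export
truth_gold_standard <- function(truth) {
  A <- truth$coefficients
  nz <- which(A != 0 & !diag(nrow(A)) > 0, arr.ind = TRUE)
  gold_standard(regulator = truth$gene_ids[nz[, 2L]],
                target = truth$gene_ids[nz[, 1L]],
                universe = truth$gene_ids)
}

#' Simulate expression time series from a planted network
#'
#' Integrates dx/dt = A x by the explicit Euler difference scheme with unit
#' step, using the implicit-in-regressor recurrence
#' \deqn{x(t) - x(t-1) = A\,x(t) \iff x(t) = (I - A)^{-1} x(t-1),}
#' which makes the inference model exactly well-specified: at zero noise the
#' backward differences of the series equal A times the current state, so
#' planted coefficients solve every per-target regression with zero
#' residual. Gaussian observation noise of sd `noise_sd` is added on top of
#' the latent trajectory. If the latent trajectory exceeds `divergence_bound`
#' the whole trajectory is rescaled by a scalar (a homogeneous linear system
#' is scale-invariant, so the recurrence is preserved exactly) with a
#' warning; overflow beyond rescue raises an error suggesting smaller
#' weights.
#'
#' @param truth A `synthetic_truth`.
#' @param T_points Number of time points T >= 3 (default 60).
#' @param noise_sd Observation noise sd (default 0).
#' @param x0_range Range of the uniform random initial state (default c(-1,1)).
#' @param divergence_bound Rescale trigger on max |x| (default 1e6).
#' @param seed Integer seed.
#' @return Numeric matrix genes x T with gene IDs as rownames and labels
#'   t001.. as colnames.
#' @export
simulate_expression <- function(truth, T_points = 60L, noise_sd = 0,
                                x0_range = c(-1, 1), divergence_bound = 1e6,
                                seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), T_points >= 3, noise_sd >= 0)
  A <- truth$coefficients
  n <- nrow(A)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  B <- tryCatch(solve(diag(n) - A), error = function(e)
    stop("I - A is singular; the planted system has a unit eigenvalue"))
  X <- matrix(0, n, T_points)
  X[, 1L] <- stats::runif(n, x0_range[1L], x0_range[2L])
  for (t in 2:T_points) {
    X[, t] <- B %*% X[, t - 1L]
    if (!all(is.finite(X[, t]))) {
      stop("trajectory overflow: planted weights too large for a stable simulation")
    }
  }
  m <- max(abs(X))
  if (m > divergence_bound) {
    warning("trajectory rescaled by ", format(divergence_bound / m),
            " to stay within the divergence bound")
    X <- X * (divergence_bound / m)
  }
  if (noise_sd > 0) {
    X <- X + matrix(stats::rnorm(n * T_points, sd = noise_sd), n, T_points)
  }
  dimnames(X) <- list(truth$gene_ids,
                      sprintf("t%03d", seq_len(T_points)))
  X
}
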