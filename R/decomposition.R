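#' Threshold an MI matrix into a binary association graph
#'
#' An undirected edge (i,j) is present iff MI(i,j) is strictly greater than
#' `lambda_mi`; the +Inf sentinel therefore always passes, NA never does. The
#' diagonal is zero.
#'
#' @param mi Symmetric MI matrix.
#' @param lambda_mi Cutoff in nats.
#' @return Symmetric 0/1 integer matrix with zero diagonal, same dimnames.
#' @export
threshold_adjacency <- function(mi, lambda_mi) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi), lambda_mi >= 0)
  a <- (!is.na(mi)) & (mi > lambda_mi)
  storage.mode(a) <- "integer"
  diag(a) <- 0L
  a
}

#' Construct a module partition object
#'
#' @param modules List of character vectors (disjoint gene ID sets).
#' @param kicked_out Character vector of genes not yet assigned to a module.
#' @return A `module_partition`.
#' @export
module_partition <- function(modules, kicked_out = character()) {
  modules <- lapply(modules, as.character)
  all_g <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(all_g)) stop("modules are not disjoint")
  if (any(lengths(modules) == 0L)) stop("empty module")
  structure(list(modules = modules, kicked_out = as.character(kicked_out)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition:", length(x$modules), "modules, sizes",
      paste(lengths(x$modules), collapse = "/"),
      if (length(x$kicked_out)) paste0("; ", length(x$kicked_out), " unassigned")
      else "", "\n")
  invisible(x)
}

#' Cluster a thresholded graph into modules
#'
#' Genes with at least one edge are partitioned by greedy modularity
#' maximization (Newman fast-greedy community detection, the algorithm family
#' behind module detection in large sparse biological networks); isolated
#' genes go to `kicked_out` for later reinsertion. The procedure is
#' deterministic: fast-greedy uses no randomness, and modules are reported
#' ordered by their smallest member's row index. Label propagation is offered
#' as a (seeded) alternative.
#'
#' @param adjacency Symmetric 0/1 matrix from [threshold_adjacency()].
#' @param method `"fast_greedy"` (default) or `"label_prop"`.
#' @param seed Seed used only by `"label_prop"`.
#' @return A `module_partition` with non-empty `kicked_out` when the cutoff
#'   isolated genes.
#' @export
cluster_modules <- function(adjacency, method = c("fast_greedy", "label_prop"),
                            seed = 1L) {
  method <- match.arg(method)
  genes <- rownames(adjacency)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(adjacency)))
  deg <- rowSums(adjacency)
  iso <- genes[deg == 0]
  keep <- genes[deg > 0]
  if (length(keep) == 0L) {
    stop("thresholded graph has no edges: every gene is isolated; lower lambda_mi")
  }
  g <- igraph::graph_from_adjacency_matrix(
    adjacency[keep, keep, drop = FALSE], mode = "undirected", diag = FALSE)
  memb <- if (method == "fast_greedy") {
    cm <- igraph::cluster_fast_greedy(g)
    # cut the merge tree at maximum modularity; on ties (e.g. a complete
    # graph, where every cut scores 0) prefer the fewest communities
    mod_seq <- cm$modularity
    best <- max(which(mod_seq >= max(mod_seq) - 1e-12))
    n_comm <- igraph::vcount(g) - (best - 1L)
    igraph::cut_at(cm, no = n_comm)
  } else {
    withr_seed <- function(expr) { # local seed, do not disturb caller RNG
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed); expr
    }
    withr_seed(igraph::membership(igraph::cluster_label_prop(g)))
  }
  mods <- split(keep, memb)
  # deterministic module order: by smallest member row index
  first_idx <- vapply(mods, function(m) min(match(m, genes)), numeric(1))
  mods <- mods[order(first_idx)]
  # within-module gene order follows the input row order
  mods <- lapply(mods, function(m) m[order(match(m, genes))])
  names(mods) <- NULL
  big <- lengths(mods) > 0.5 * length(genes)
  if (any(big)) {
    warning("module covering more than half the genes defeats the divide-and-conquer split")
  }
  module_partition(mods, kicked_out = iso)
}

#' Reassign isolated genes to modules by the maximum-MI rule
#'
#' Every kicked-out gene x joins the module holding its single strongest MI
#' partner: the chosen index maximizes, over modules, the maximum MI between
#' x and any member. Modules are frozen as clustered (the result does not
#' depend on reinsertion order) and ties go to the lowest module index. A
#' gene whose MI to every member is NA falls back to the largest module with
#' a warning. After reinsertion the partition is disjoint and exhaustive over
#' the MI matrix's gene set; this is asserted.
#'
#' @param part A `module_partition` with possibly non-empty `kicked_out`.
#' @param mi Symmetric MI matrix covering all genes.
#' @return A `module_partition` with empty `kicked_out`.
#' @export
reinsert_isolated <- function(part, mi) {
  stopifnot(inherits(part, "module_partition"))
  genes <- rownames(mi)
  frozen <- part$modules
  target <- integer(length(part$kicked_out))
  for (k in seq_along(part$kicked_out)) {
    x <- part$kicked_out[k]
    best <- vapply(frozen, function(mod) {
      v <- mi[x, setdiff(mod, x)]
      v <- v[!is.na(v)]
      if (length(v)) max(v) else -Inf
    }, numeric(1))
    if (all(best == -Inf)) {
      warning("gene '", x, "' has no valid MI to any module; assigning to the largest")
      target[k] <- which.max(lengths(frozen))
    } else {
      target[k] <- which.max(best) # which.max takes the lowest index on ties
    }
  }
  mods <- part$modules
  for (k in seq_along(part$kicked_out)) {
    mods[[target[k]]] <- c(mods[[target[k]]], part$kicked_out[k])
  }
  out <- module_partition(mods, kicked_out = character())
  assigned <- sort(unlist(out$modules, use.names = FALSE))
  if (!identical(assigned, sort(genes))) {
    stop("internal error: partition does not cover the gene universe")
  }
  out
}
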