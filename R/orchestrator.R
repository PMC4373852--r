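#' Balance modules across workers
#'
#' Longest-processing-time greedy: modules are taken in decreasing size order
#' (ties by lower module index) and each is assigned to the currently
#' least-loaded worker (ties by lower worker index). Every module is assigned
#' exactly once; with more workers than modules each module sits alone.
#'
#' @param sizes Integer vector of module sizes (length M >= 1).
#' @param workers Worker count W >= 1.
#' @return Integer vector: worker index for each module.
#' @export
assign_modules <- function(sizes, workers) {
  stopifnot(length(sizes) >= 1, workers >= 1)
  ord <- order(-sizes, seq_along(sizes))
  load <- numeric(workers)
  assignment <- integer(length(sizes))
  for (m in ord) {
    w <- which.min(load)
    assignment[m] <- w
    load[w] <- load[w] + sizes[m]
  }
  assignment
}

#' Merge per-module network fragments into one network
#'
#' Fragments are keyed by module index, so the merge is independent of the
#' order in which workers delivered them. A directed pair reported by two
#' fragments (possible through overlapping candidate sets) keeps the
#' coefficient of larger magnitude; on an exact tie the lower module index
#' wins. The merge is associative under these rules.
#'
#' @param fragments List of data.frames from [infer_module()] (columns
#'   regulator, target, weight, module), in any order.
#' @param theta Magnitude cutoff stored on the resulting network.
#' @param n_modules If given, checks that modules `1..n_modules` all
#'   delivered a fragment and errors naming any missing one.
#' @return A `grn_network`.
#' @export
assemble <- function(fragments, theta = 0, n_modules = NULL) {
  if (!is.null(n_modules)) {
    present <- !vapply(fragments, is.null, logical(1))
    if (length(fragments) < n_modules || !all(present[seq_len(n_modules)])) {
      miss <- if (length(fragments) < n_modules) {
        (length(fragments) + 1L):n_modules
      } else which(!present[seq_len(n_modules)])
      stop("missing fragment(s) for module(s): ", paste(miss, collapse = ", "))
    }
  }
  fragments <- Filter(Negate(is.null), fragments)
  all_f <- do.call(rbind, fragments)
  if (is.null(all_f) || nrow(all_f) == 0L) return(grn_network(theta = theta))
  # duplicate rule: larger |weight| wins, ties -> lower module index
  ord <- order(all_f$regulator, all_f$target, -abs(all_f$weight), all_f$module)
  all_f <- all_f[ord, , drop = FALSE]
  key <- paste(all_f$regulator, all_f$target, sep = "\r")
  all_f <- all_f[!duplicated(key), , drop = FALSE]
  grn_network(all_f$regulator, all_f$target, all_f$weight, theta = theta)
}

#' Run the full divide-and-conquer inference pipeline
#'
#' Stages: interpolate -> (optionally) normalize -> pairwise MI -> lambda
#' threshold -> fast-greedy module detection -> maximum-MI reinsertion of
#' isolated genes -> per-module candidate selection -> per-module linear-ODE
#' least squares on a worker pool -> keyed assembly. The result is identical
#' for any worker count and any fragment arrival order, because fragments are
#' merged by module index. When a gold standard is given the binarized
#' network is scored as well.
#'
#' @param expr Expression matrix (genes x observations) or a file path
#'   readable by [read_expression()].
#' @param config A [lsgrn_config()].
#' @param gold Optional `gold_standard` (or file path; the expression gene
#'   set is then used as universe).
#' @param verbose Log stage timings via `message()`.
#' @return List with `network` (`grn_network`), `partition`
#'   (`module_partition`), `candidates`, `mi` (MI matrix), `lambda_mi`
#'   (cutoff actually used) and, when `gold` is given, `evaluation`
#'   (confusion counts + metrics).
#' @export
run_lsgrn <- function(expr, config = lsgrn_config(), gold = NULL,
                      verbose = FALSE) {
  log_stage <- function(name, t0) {
    if (verbose) message(sprintf("[%s] %.2fs", name,
                                 as.numeric(Sys.time()) - t0))
  }
  stage <- function(name, fn) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_stage(name, t0)
    out
  }
  if (is.character(expr)) expr <- stage("read_expression", function() read_expression(expr))
  if (is.character(gold)) {
    gold_path <- gold
    gold <- stage("read_gold_standard",
                  function() read_gold_standard(gold_path, rownames(expr)))
  }
  expr <- stage("interpolate", function() interpolate_missing(expr))
  if (config$normalize) expr <- stage("normalize", function() normalize_expression(expr))
  mi <- stage("pairwise_mi", function() pairwise_mi(expr))
  lambda <- config$lambda_mi
  if (!is.null(config$lambda_quantile)) {
    off <- mi[upper.tri(mi)]
    lambda <- as.numeric(stats::quantile(off[is.finite(off)],
                                         config$lambda_quantile))
  }
  adj <- stage("threshold_adjacency", function() threshold_adjacency(mi, lambda))
  part <- stage("cluster_modules", function() cluster_modules(adj, seed = config$seed))
  part <- stage("reinsert_isolated", function() reinsert_isolated(part, mi))
  cands <- stage("select_candidates", function() {
    lapply(seq_along(part$modules), function(i)
      select_candidate_set(i, part, mi, config$candidate_fraction))
  })
  fragments <- stage("infer_modules", function() {
    run_worker_pool(part, cands, expr, config)
  })
  net <- stage("assemble", function() {
    assemble(fragments, theta = config$theta, n_modules = length(part$modules))
  })
  out <- list(network = net, partition = part, candidates = cands,
              mi = mi, lambda_mi = lambda)
  if (!is.null(gold)) {
    out$evaluation <- stage("evaluate", function() {
      cc <- confusion_counts(network_edges(net), gold)
      c(cc, metrics(cc))
    })
  }
  out
}

# Transport-agnostic worker pool. Modules are balanced across `workers`
# logical workers (LPT greedy); each worker processes its modules and the
# fragments are collected keyed by module index, so any completion order --
# here optionally shuffled to exercise the asynchrony contract -- yields the
# same assembly input. A module whose inference fails is retried once before
# aborting.
run_worker_pool <- function(part, cands, expr, config,
                            shuffle_completion = FALSE) {
  M <- length(part$modules)
  assignment <- assign_modules(lengths(part$modules), config$workers)
  fragments <- vector("list", M)
  worker_order <- seq_len(config$workers)
  if (shuffle_completion) worker_order <- sample(worker_order)
  for (w in worker_order) {
    for (i in which(assignment == w)) {
      frag <- tryCatch(infer_module(i, part, cands[[i]], expr, config),
                       error = function(e) NULL)
      if (is.null(frag)) { # single retry on the master
        frag <- infer_module(i, part, cands[[i]], expr, config)
      }
      fragments[[i]] <- frag
    }
  }
  fragments
}
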