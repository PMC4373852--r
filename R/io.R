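#' Read a gene expression matrix from a delimited text file
#'
#' Expects genes in rows: the first column holds gene identifiers and the
#' header row holds observation labels (time points or chip IDs, kept in file
#' order). The field separator is sniffed from the header line: tab wins over
#' comma when both occur. Empty cells and the literal `NA` are read as missing
#' values; [interpolate_missing()] fills them before analysis.
#'
#' @param path Path to a TSV or CSV file.
#' @return A numeric matrix (genes x observations) with gene IDs as rownames
#'   and observation labels as colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), fill = FALSE,
                          colClasses = NA, comment.char = "")
  if (ncol(df) < 2L) stop("expression file needs a gene ID column plus data columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene IDs in expression file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  m <- as.matrix(vals)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(vals, 2L, as.numeric))) & !is.na(as.matrix(vals)),
                 arr.ind = TRUE)
    if (nrow(bad)) stop("non-numeric expression value at row ", bad[1L, 1L],
                        ", column ", bad[1L, 2L])
    m <- apply(vals, 2L, as.numeric)
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression matrix to a tab-separated file
#'
#' @param expr Numeric matrix with gene rownames and observation colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gold-standard edge list
#'
#' Accepts the DREAM-style format: two columns (regulator, target) listing
#' positive edges, or three columns with a 0/1 label in the third. Only
#' label-1 pairs with both endpoints inside `universe` are kept; pairs with a
#' foreign endpoint or equal endpoints are dropped with a warning.
#'
#' @param path Path to a whitespace/tab-separated edge list (no header).
#' @param universe Character vector of gene IDs defining the evaluated space.
#' @return A `gold_standard` object: list with `edges` (data.frame with
#'   columns regulator, target) and `universe`.
#' @export
read_gold_standard <- function(path, universe) {
  if (!file.exists(path)) stop("gold-standard file not found: ", path)
  universe <- as.character(universe)
  raw <- tryCatch(utils::read.table(path, header = FALSE,
                                    stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) {
    return(gold_standard(character(), character(), universe))
  }
  if (ncol(raw) >= 3L) {
    lab <- raw[[3L]]
    if (!all(lab %in% c(0L, 1L))) {
      stop("gold-standard labels must be 0 or 1; saw: ",
           paste(utils::head(setdiff(unique(lab), c(0, 1))), collapse = ", "))
    }
    raw <- raw[lab == 1L, , drop = FALSE]
  }
  reg <- as.character(raw[[1L]])
  tgt <- as.character(raw[[2L]])
  inside <- reg %in% universe & tgt %in% universe
  if (any(!inside)) {
    warning(sum(!inside), " gold-standard edge(s) dropped: endpoint outside universe")
  }
  reg <- reg[inside]; tgt <- tgt[inside]
  self <- reg == tgt
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped from gold standard")
    reg <- reg[!self]; tgt <- tgt[!self]
  }
  gold_standard(reg, tgt, universe)
}

#' Construct a gold-standard object
#'
#' @param regulator,target Character vectors of equal length (positive edges).
#' @param universe Gene IDs over which negatives are defined.
#' @return A `gold_standard` object.
#' @export
gold_standard <- function(regulator, target, universe) {
  edges <- data.frame(regulator = as.character(regulator),
                      target = as.character(target),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  structure(list(edges = edges, universe = as.character(universe)),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("Gold standard:", nrow(x$edges), "positive edges over",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Write an inferred network as a ranked edge list
#'
#' Writes three tab-separated columns (regulator, target, weight), sorted by
#' decreasing |weight| with ties broken lexicographically by (regulator,
#' target) so the output is a deterministic total order. With
#' `binarized = TRUE` a fourth 0/1 column marks edges passing the network's
#' theta cut. Weights are printed with 12 significant digits so a write/read
#' round trip preserves them.
#'
#' @param net A `grn_network` object (see [grn_network()]).
#' @param path Output path.
#' @param binarized Add a 0/1 label column for the theta-binarized edge set.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, binarized = FALSE) {
  stopifnot(inherits(net, "grn_network"))
  w <- net$weights
  header <- c("regulator", "target", "weight")
  if (binarized) header <- c(header, "label")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(w)) {
    lines <- paste(w$regulator, w$target, sprintf("%.12g", w$weight), sep = "\t")
    if (binarized) {
      lab <- as.integer(abs(w$weight) > net$theta)
      lines <- paste(lines, lab, sep = "\t")
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a network edge list written by [write_network()]
#'
#' @param path Path to the edge-list file.
#' @param theta Magnitude cutoff used to rebuild the binarized edge set.
#' @return A `grn_network` object.
#' @export
read_network <- function(path, theta = 0) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  grn_network(df$regulator, df$target, df$weight, theta = theta)
}

#' Construct an inferred-network object
#'
#' Holds the full weighted directed edge map (every estimated non-self
#' coefficient, kept for ROC sweeps) plus the magnitude cutoff `theta` that
#' defines the reported binary edge set. Edges are stored in the canonical
#' deterministic order: decreasing |weight|, ties by (regulator, target).
#'
#' @param regulator,target Character vectors (directed edges regulator->target).
#' @param weight Numeric coefficients.
#' @param theta Magnitude cutoff; an edge is reported iff |weight| > theta.
#' @return A `grn_network` object with elements `weights` (data.frame) and
#'   `theta`.
#' @export
grn_network <- function(regulator = character(), target = character(),
                        weight = numeric(), theta = 0) {
  w <- data.frame(regulator = as.character(regulator),
                  target = as.character(target),
                  weight = as.numeric(weight),
                  stringsAsFactors = FALSE)
  if (nrow(w)) {
    ord <- order(-abs(w$weight), w$regulator, w$target)
    w <- w[ord, , drop = FALSE]
    rownames(w) <- NULL
  }
  structure(list(weights = w, theta = as.numeric(theta)), class = "grn_network")
}

#' Binary edge set of a network at its theta cut
#'
#' @param net A `grn_network`.
#' @param theta Optional override of the stored cutoff.
#' @return data.frame (regulator, target) of edges with |weight| > theta.
#' @export
network_edges <- function(net, theta = net$theta) {
  w <- net$weights
  w[abs(w$weight) > theta & w$regulator != w$target,
    c("regulator", "target"), drop = FALSE]
}

#' @export
print.grn_network <- function(x, ...) {
  cat("Inferred network:", nrow(x$weights), "weighted pairs;",
      nrow(network_edges(x)), "edges at theta =", x$theta, "\n")
  invisible(x)
}

#' Run configuration
#'
#' Bundles the tuning parameters of the pipeline. `lambda_mi` is the mutual
#' information cutoff (in nats) that builds the initial binary graph; when
#' `lambda_quantile` is non-NULL, `lambda_mi` is instead taken at run time as
#' that quantile of the off-diagonal MI values, which adapts the cutoff to the
#' MI scale of the data set. `theta` is the coefficient magnitude cutoff
#' turning regression weights into edges, and `candidate_fraction` the
#' fraction of top-ranked cross-module MI pairs admitted as external
#' regressors.
#'
#' @param lambda_mi MI cutoff, nats (default 1.2).
#' @param theta Coefficient cutoff (default 0.18).
#' @param candidate_fraction Fraction in (0,1] of cross-module pairs kept
#'   (default 0.05).
#' @param workers Positive integer worker count for module inference.
#' @param seed Integer seed controlling any randomized stage.
#' @param cond_threshold Condition-number bound selecting the QR solver branch.
#' @param ridge Optional ridge term added to the normal equations (default 0).
#' @param normalize Z-score each gene row before analysis (default TRUE).
#'   Centering makes coefficients incomparable to a generating linear model,
#'   so simulation studies that check coefficient recovery disable it.
#' @param lambda_quantile If non-NULL, overrides `lambda_mi` with this
#'   quantile of the finite off-diagonal MI values.
#' @return A `lsgrn_config` list.
#' @export
lsgrn_config <- function(lambda_mi = 1.2, theta = 0.18, candidate_fraction = 0.05,
                         workers = 1L, seed = 1L, cond_threshold = 1e6,
                         ridge = 0, normalize = TRUE, lambda_quantile = NULL) {
  stopifnot(lambda_mi >= 0, theta >= 0,
            candidate_fraction > 0, candidate_fraction <= 1,
            workers >= 1, cond_threshold > 1)
  structure(list(lambda_mi = lambda_mi, theta = theta,
                 candidate_fraction = candidate_fraction,
                 workers = as.integer(workers), seed = as.integer(seed),
                 cond_threshold = cond_threshold, ridge = ridge,
                 normalize = isTRUE(normalize),
                 lambda_quantile = lambda_quantile),
            class = "lsgrn_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [lsgrn_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A `lsgrn_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(lsgrn_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(lsgrn_config, vals)
}

#' Export a module partition as a two-column table
#'
#' @param part A `module_partition`.
#' @param path Output TSV path (gene, module_index).
#' @return Invisibly, `path`.
#' @export
write_partition <- function(part, path) {
  stopifnot(inherits(part, "module_partition"))
  df <- data.frame(
    gene = unlist(part$modules, use.names = FALSE),
    module_index = rep(seq_along(part$modules), lengths(part$modules)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
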