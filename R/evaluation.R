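#' Confusion counts of a predicted edge set against a gold standard
#'
#' The evaluated space is all ordered non-self gene pairs over the gold
#' universe (direction is scored: regulations are directed). Predicted edges
#' with an endpoint outside the universe are dropped with a warning;
#' self-pairs are excluded from the space.
#'
#' @param pred data.frame with columns regulator, target (e.g. from
#'   [network_edges()]).
#' @param gold A `gold_standard`.
#' @return Named list TP, FP, TN, FN summing to n*(n-1).
#' @export
confusion_counts <- function(pred, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  uni <- gold$universe
  n <- length(uni)
  inside <- pred$regulator %in% uni & pred$target %in% uni
  if (any(!inside)) {
    warning(sum(!inside), " predicted edge(s) outside the gold universe dropped")
    pred <- pred[inside, , drop = FALSE]
  }
  pred <- pred[pred$regulator != pred$target, , drop = FALSE]
  pkey <- unique(paste(pred$regulator, pred$target, sep = "\r"))
  gkey <- paste(gold$edges$regulator, gold$edges$target, sep = "\r")
  total <- n * (n - 1L)
  TP <- sum(pkey %in% gkey)
  FP <- length(pkey) - TP
  FN <- length(gkey) - TP
  TN <- total - TP - FP - FN
  list(TP = TP, FP = FP, TN = TN, FN = FN)
}

#' Classification metrics from confusion counts
#'
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN), PPV = TP/(TP+FP),
#' ACC = (TP+TN)/(TP+FP+TN+FN). Any 0/0 ratio is reported as 0 (flagged with
#' a warning when all counts are zero) so result tables never carry missing
#' cells.
#'
#' @param counts Named list or vector with TP, FP, TN, FN.
#' @return Named list TPR, FPR, PPV, ACC in [0,1].
#' @export
metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  total <- TP + FP + TN + FN
  if (total == 0) warning("all-zero confusion counts; metrics reported as 0")
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  list(TPR = safe_div(TP, TP + FN),
       FPR = safe_div(FP, FP + TN),
       PPV = safe_div(TP, TP + FP),
       ACC = safe_div(TP + TN, total))
}

#' ROC points over a theta sweep
#'
#' Binarizes the weighted network at every theta in the grid, scores each
#' edge set against the gold standard and returns one (FPR, TPR) point per
#' theta, sorted by FPR, with the (0,0) and (1,1) endpoints appended. Since
#' the binarized sets are nested along theta, TPR and FPR are monotone
#' non-increasing in theta.
#'
#' @param net A `grn_network` holding all weighted pairs.
#' @param gold A `gold_standard`.
#' @param theta_grid Numeric vector of cutoffs (default 0 to 0.4 by 0.01).
#' @return data.frame with columns theta, FPR, TPR (endpoints have NA theta),
#'   sorted by FPR.
#' @export
roc_points <- function(net, gold, theta_grid = seq(0, 0.4, by = 0.01)) {
  stopifnot(inherits(net, "grn_network"))
  pts <- lapply(theta_grid, function(th) {
    m <- metrics(confusion_counts(network_edges(net, theta = th), gold))
    data.frame(theta = th, FPR = m$FPR, TPR = m$TPR)
  })
  out <- do.call(rbind, pts)
  out <- rbind(data.frame(theta = NA_real_, FPR = 0, TPR = 0),
               out,
               data.frame(theta = NA_real_, FPR = 1, TPR = 1))
  out <- out[order(out$FPR, out$TPR), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Theta-sweep metric table
#'
#' Computes all four indexes over a theta grid; the companion of the
#' stability analysis reported for the method.
#'
#' @inheritParams roc_points
#' @return data.frame with columns theta, TP, FP, TN, FN, TPR, FPR, PPV, ACC.
#' @export
theta_sweep <- function(net, gold, theta_grid = seq(0, 0.4, by = 0.01)) {
  rows <- lapply(theta_grid, function(th) {
    cc <- confusion_counts(network_edges(net, theta = th), gold)
    data.frame(theta = th, as.data.frame(cc), as.data.frame(metrics(cc)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a metrics report
#'
#' @param eval_row Named list/vector with TP, FP, TN, FN, TPR, FPR, PPV, ACC.
#' @param path Output path; `.tsv` gets a machine-readable table, anything
#'   else a short human-readable report.
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(eval_row, path) {
  if (grepl("\\.tsv$", path)) {
    utils::write.table(as.data.frame(eval_row), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    lines <- c("Network evaluation",
               sprintf("  TP=%d FP=%d TN=%d FN=%d",
                       eval_row$TP, eval_row$FP, eval_row$TN, eval_row$FN),
               sprintf("  TPR=%.4f FPR=%.4g PPV=%.4f ACC=%.4f",
                       eval_row$TPR, eval_row$FPR, eval_row$PPV, eval_row$ACC))
    writeLines(lines, path)
  }
  invisible(path)
}
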