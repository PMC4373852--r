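test_that("candidate selection keeps top-ranked cross pairs per module pair", {
  ids <- c(paste0("a", 1:4), paste0("b", 1:5))
  part <- module_partition(list(ids[1:4], ids[5:9]))
  set.seed(60)
  mi <- matrix(runif(81), 9, 9, dimnames = list(ids, ids))
  mi <- (mi + t(mi)) / 2; diag(mi) <- Inf

  # fraction 1.0: every external gene that pairs with the module
  cs <- select_candidate_set(1, part, mi, fraction = 1.0)
  expect_setequal(cs$external_genes, ids[5:9])
  expect_length(intersect(cs$external_genes, ids[1:4]), 0)

  # 4x5 = 20 cross pairs, fraction 0.05 -> ceil(1) = 1 pair kept
  cs2 <- select_candidate_set(1, part, mi, fraction = 0.05)
  expect_length(cs2$external_genes, 1)
  pairs <- expand.grid(x = ids[1:4], y = ids[5:9], stringsAsFactors = FALSE)
  pairs$mi <- mi[cbind(pairs$x, pairs$y)]
  expect_equal(cs2$external_genes, pairs$y[which.max(pairs$mi)])

  # tied MI at the cut: lexicographic (x, y) tie-break
  mi[] <- 1; diag(mi) <- Inf
  cs3 <- select_candidate_set(2, part, mi, fraction = 0.05)
  expect_equal(cs3$external_genes, "a1")  # (a?,?) ranked by x then y... x in module 2 is b*, y is a*
  # single-module partition -> empty candidate set
  p1 <- module_partition(list(ids))
  expect_length(select_candidate_set(1, p1, mi, 0.5)$external_genes, 0)
})

test_that("linear systems have the difference response and time-t regressors", {
  # 1-gene module, no candidates, x = (1,2,4)
  expr <- rbind(g1 = c(1, 2, 4))
  part <- module_partition(list("g1"))
  cand <- list(module_index = 1, external_genes = character())
  sys <- build_linear_system("g1", 1, part, cand, expr)
  expect_equal(unname(sys$design), cbind(c(2, 4)))
  expect_equal(unname(sys$response), c(1, 2))
  expect_equal(sys$column_gene_ids, "g1")

  # constant target -> zero response
  expr2 <- rbind(g1 = rep(3, 5), g2 = rnorm(5))
  part2 <- module_partition(list(c("g1", "g2")))
  sys2 <- build_linear_system("g1", 1, part2, cand, expr2)
  expect_equal(unname(sys2$response), rep(0, 4))

  # column order: module genes in partition order then candidates
  expr3 <- rand_expr(5, 6, seed = 61)
  part3 <- module_partition(list(c("g02", "g01"), c("g03", "g04", "g05")))
  cand3 <- list(module_index = 1, external_genes = c("g05", "g03"))
  sys3 <- build_linear_system("g01", 1, part3, cand3, expr3)
  expect_equal(sys3$column_gene_ids, c("g02", "g01", "g05", "g03"))
  expect_equal(sys3$design[, "g05"], unname(expr3["g05", 2:6]))
  expect_error(build_linear_system("g03", 1, part3, cand3, expr3),
               "not in module")
})

test_that("simulated series satisfy design %*% planted = response", {
  truth <- generate_truth(12, 3, 0.04, seed = 62)
  expr <- simulate_expression(truth, T_points = 20, seed = 62)
  A <- truth$coefficients
  part <- module_partition(list(truth$gene_ids))
  cand <- list(module_index = 1, external_genes = character())
  for (j in truth$gene_ids[1:4]) {
    sys <- build_linear_system(j, 1, part, cand, expr)
    resid <- sys$response - drop(sys$design %*% A[j, sys$column_gene_ids])
    expect_lt(max(abs(resid)), 1e-12)
  }
})

test_that("solver handles the identity design and recovers planted systems", {
  sys <- list(design = diag(5), response = c(0, 0, 0, 0, 1),
              target_gene = "g01", column_gene_ids = sprintf("g%02d", 1:5))
  expect_equal(as.numeric(solve_coefficients(sys)), c(0, 0, 0, 0, 1))

  for (s in 1:10) {
    ps <- planted_system(30, 8, seed = s)
    p <- solve_coefficients(ps)
    expect_lt(sqrt(sum((p - ps$coef)^2)) / sqrt(sum(ps$coef^2)), 1e-8)
  }
  expect_error(solve_coefficients(list(design = matrix(0, 3, 0),
                                       response = 1:3)), "empty design")
})

test_that("QR and normal-equation branches agree on well-conditioned systems", {
  for (s in 1:20) {
    ps <- planted_system(10, 5, seed = 100 + s)
    ps$response <- ps$response + rnorm(10, sd = 0.1)  # non-trivial residual
    p_qr <- solve_coefficients(ps, force = "qr")
    p_ne <- solve_coefficients(ps, force = "normal")
    expect_lt(max(abs(p_qr - p_ne)) / max(abs(p_qr)), 1e-8)
  }
})

test_that("returned solutions satisfy the least-squares optimality certificate", {
  set.seed(63)
  for (s in 1:5) {
    ps <- planted_system(12, 6, seed = 200 + s)
    ps$response <- ps$response + rnorm(12, sd = 0.3)
    p <- solve_coefficients(ps)
    base <- sum((ps$response - ps$design %*% p)^2)
    for (k in 1:20) {
      delta <- rnorm(6, sd = 0.01)
      expect_gte(sum((ps$response - ps$design %*% (p + delta))^2), base - 1e-10)
    }
  }
})

test_that("rank-deficient designs fall back to a minimum-norm QR solution", {
  set.seed(64)
  H <- matrix(rnorm(20), 10, 2)
  H <- cbind(H, H[, 1] + H[, 2])  # exactly collinear third column
  colnames(H) <- c("a", "b", "c")
  d <- rnorm(10)
  sys <- list(design = H, response = d, target_gene = "a",
              column_gene_ids = colnames(H))
  expect_warning(p_auto <- solve_coefficients(sys, cond_threshold = 1e30,
                                              force = "normal"), "singular")
  p <- solve_coefficients(sys)  # auto-routes to QR (cond = Inf)
  # optimal residual equals that of the full-rank two-column subproblem
  opt <- sum(qr.resid(qr(H[, 1:2]), d)^2)
  expect_equal(sum((d - H %*% p)^2), opt, tolerance = 1e-8)
  # among exact solutions of the consistent case, min-norm is returned
  d2 <- drop(H %*% c(1, 1, 0))
  sys2 <- list(design = H, response = d2, target_gene = "a",
               column_gene_ids = colnames(H))
  p2 <- solve_coefficients(sys2)
  expect_lt(max(abs(H %*% p2 - d2)), 1e-10)
  expect_lte(sum(p2^2), sum(c(1, 1, 0)^2) + 1e-10)
})

test_that("binarization applies |beta| > theta, excludes self, is monotone", {
  p <- c(g1 = 0.3, g2 = -0.5, g3 = 0.05)
  attr(p, "target_gene") <- "g3"
  e0 <- binarize_coefficients(p, 0)
  expect_setequal(e0$regulator, c("g1", "g2"))  # self g3 excluded even at 0
  e1 <- binarize_coefficients(p, 0.4)
  expect_equal(e1$regulator, "g2")
  # nested edge sets along the standard theta grid
  set.seed(65)
  pp <- rnorm(50, sd = 0.2)
  names(pp) <- sprintf("g%02d", 1:50)
  attr(pp, "target_gene") <- "g01"
  prev <- binarize_coefficients(pp, 0)
  for (th in seq(0.01, 0.4, by = 0.01)) {
    cur <- binarize_coefficients(pp, th)
    expect_true(all(cur$regulator %in% prev$regulator))
    prev <- cur
  }
})

test_that("infer_module recovers a planted module and honors the loop contract", {
  set.seed(66)
  # planted 5-gene module, generic design: simulate via synthetic truth on
  # 5 genes only (module = all genes, no candidates)
  truth <- generate_truth(5, 1, 0.2, seed = 66)
  expr <- simulate_expression(truth, T_points = 30, seed = 66)
  part <- module_partition(list(truth$gene_ids))
  cand <- list(module_index = 1, external_genes = character())
  frag <- infer_module(1, part, cand, expr, lsgrn_config(normalize = FALSE))
  expect_equal(length(unique(frag$target)), 5L)  # one vector per gene
  A <- truth$coefficients
  theta <- 0.1  # half the dead zone
  got <- frag[abs(frag$weight) > theta, c("regulator", "target")]
  planted <- which(A != 0 & row(A) != col(A), arr.ind = TRUE)
  expect_setequal(paste(got$regulator, got$target),
                  paste(truth$gene_ids[planted[, 2]], truth$gene_ids[planted[, 1]]))
  # coefficients match to high precision
  err <- max(abs(frag$weight - A[cbind(frag$target, frag$regulator)]))
  expect_lt(err, 1e-6)

  # single constant gene -> empty fragment
  cexpr <- rbind(g1 = rep(2, 10))
  p1 <- module_partition(list("g1"))
  f1 <- infer_module(1, p1, cand, cexpr, lsgrn_config(normalize = FALSE))
  expect_equal(nrow(f1), 0L)
})
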