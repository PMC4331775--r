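make_two_group <- function(vals1, vals0, gene = "g1") {
  expr <- matrix(c(vals1, vals0), 1,
                 dimnames = list(gene, c(paste0("t", seq_along(vals1)),
                                         paste0("c", seq_along(vals0)))))
  samples <- data.frame(
    sample_id = colnames(expr), tissue = "m",
    condition = rep(c("cx", "sham"), c(length(vals1), length(vals0))),
    replicate = 1, stringsAsFactors = FALSE)
  fit_per_gene(expr, samples, "m", "cx_vs_sham")
}

test_that("two-group fits give exact textbook estimates", {
  f <- make_two_group(c(1, 1), c(0, 0))
  expect_equal(f$log2fc, 1)
  expect_equal(f$s2, 0)
  expect_equal(f$df, 2L)

  f2 <- make_two_group(c(2, 4), c(1, 3))
  expect_equal(f2$log2fc, 1)
  expect_equal(f2$s2, 2)   # pooled variance of {2,4} and {1,3}
  expect_equal(f2$u, 1)    # sqrt(1/2 + 1/2)
})

test_that("fits are invariant to sample order and stratified by tissue", {
  set.seed(31)
  sim <- generate_expression(study_design(),
                             synth_config(n_genes = 40, seed = 31))
  perm <- sample(ncol(sim$expr))
  f1 <- fit_per_gene(sim$expr, sim$samples, "prostate", "T_vs_cx")
  f2 <- fit_per_gene(sim$expr[, perm], sim$samples[perm, ], "prostate",
                     "T_vs_cx")
  expect_equal(f1, f2)
  f3 <- fit_per_gene(sim$expr, sim$samples, "levator_ani", "T_vs_cx")
  expect_false(isTRUE(all.equal(f1$log2fc, f3$log2fc)))
  expect_error(fit_per_gene(sim$expr, sim$samples, "kidney", "T_vs_cx"),
               "replicates")
})

test_that("moderation prior estimation handles the degenerate equal-variance case", {
  fits <- data.frame(s2 = rep(2.5, 10), df = 6L)
  est <- estimate_moderation(fits)
  expect_identical(est$d0, Inf)
  expect_equal(est$s02, 2.5)
  # ordering invariance
  set.seed(5)
  fits2 <- data.frame(s2 = rchisq(500, 4), df = 6L)
  e1 <- estimate_moderation(fits2)
  e2 <- estimate_moderation(fits2[sample(500), , drop = FALSE])
  expect_equal(e1, e2)
})

test_that("moderation prior recovery matches limma's empirical-Bayes fit", {
  set.seed(8)
  n <- 5000; d0 <- 4; s02 <- 1; d <- 6
  sigma2 <- d0 * s02 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, d) / d
  est <- estimate_moderation(data.frame(s2 = s2, df = d))
  sq <- limma::squeezeVar(s2, df = d)
  expect_equal(est$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(est$s02, sq$var.prior, tolerance = 1e-6)
})

test_that("moderated t matches the hand-worked shrinkage example", {
  fits <- data.frame(gene_id = "g", log2fc = 1, s2 = 2, u = 1, df = 2)
  res <- moderated_t(fits, list(d0 = 4, s02 = 1))
  s2_post <- (4 * 1 + 2 * 2) / 6
  expect_equal(s2_post, 4 / 3)
  expect_equal(res$t_mod, 1 / sqrt(4 / 3), tolerance = 1e-12)
  # independent p via the F-distribution identity t^2 ~ F(1, df)
  expect_equal(res$p, 1 - pf(res$t_mod^2, 1, 6), tolerance = 1e-12)
})

test_that("no-moderation limit equals the ordinary pooled t-test", {
  set.seed(12)
  x1 <- rnorm(5, 1); x0 <- rnorm(6)
  f <- data.frame(gene_id = "g", log2fc = mean(x1) - mean(x0),
                  s2 = ((4 * var(x1)) + (5 * var(x0))) / 9,
                  u = sqrt(1 / 5 + 1 / 6), df = 9)
  res <- moderated_t(f, list(d0 = 0, s02 = 1))
  tt <- t.test(x1, x0, var.equal = TRUE)
  expect_equal(res$t_mod, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
})

test_that("full-shrinkage limit uses the normal reference distribution", {
  f <- data.frame(gene_id = "g", log2fc = 2, s2 = 5, u = 1, df = 3)
  res <- moderated_t(f, list(d0 = Inf, s02 = 4))
  expect_equal(res$t_mod, 2 / sqrt(4))
  expect_equal(res$p, 2 * pnorm(-1))
  expect_error(moderated_t(data.frame(log2fc = 1, s2 = 1, u = 0, df = 2),
                           list(d0 = 1, s02 = 1)), "u must be positive")
})

test_that("moderated p-values converge to ordinary t-test p-values as d0 shrinks", {
  fits <- data.frame(gene_id = "g", log2fc = 0.8, s2 = 1.3, u = 0.7, df = 6)
  p_plain <- moderated_t(fits, list(d0 = 0, s02 = 1))$p
  p_seq <- vapply(c(1, 0.1, 0.001, 1e-6), function(d0)
    moderated_t(fits, list(d0 = d0, s02 = 1))$p, numeric(1))
  expect_true(all(diff(abs(p_seq - p_plain)) < 0))
  expect_equal(p_seq[4], p_plain, tolerance = 1e-5)
})

test_that("moderated analysis agrees with limma end to end", {
  set.seed(77)
  n <- 300
  expr <- matrix(rnorm(n * 8), n,
                 dimnames = list(sprintf("g%03d", 1:n), paste0("s", 1:8)))
  expr[1:20, 1:4] <- expr[1:20, 1:4] + 1.5
  samples <- data.frame(sample_id = colnames(expr), tissue = "m",
                        condition = rep(c("cx", "sham"), each = 4),
                        replicate = 1:4)
  fits <- fit_per_gene(expr, samples, "m", "cx_vs_sham")
  res <- moderated_t(fits, estimate_moderation(fits))
  design <- cbind(1, rep(c(1, 0), each = 4))
  lf <- limma::eBayes(limma::lmFit(expr, design))
  expect_equal(res$log2fc, unname(lf$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(res$t_mod, unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p, unname(lf$p.value[, 2]), tolerance = 1e-6)
})

test_that("BH adjustment reproduces the step-up examples and validates input", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "finite")
  # q >= p and monotone in p-rank
  set.seed(2)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("BH adjustment matches the brute-force suffix-minimum oracle", {
  set.seed(14)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1)) ^ sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 0)
  }
})
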