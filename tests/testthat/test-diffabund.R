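test_that("moderated t matches a brute-force evaluation of the shrinkage formulas", {
  x <- make_two_group_matrix(n_proteins = 5, n_a = 6, n_b = 6,
                             shift = list(P01 = 1.2, P03 = -0.8), seed = 4)
  # knock out a couple of cells so unequal per-protein n is exercised
  x$values[2, 1] <- NA
  x$values[4, c(7, 8)] <- NA
  ct <- two_group_contrast()
  for (prior in list(list(d0 = 3, s0_sq = 0.4),
                     list(d0 = 0, s0_sq = 1),
                     list(d0 = Inf, s0_sq = 0.25))) {
    res <- fit_moderated_t(x, ct, prior = prior)
    oracle <- brute_force_moderated_t(x$values, ct$group_a, ct$group_b,
                                      prior$d0, prior$s0_sq)
    expect_equal(res$log2fc, oracle$log2fc, tolerance = 1e-10)
    expect_equal(res$t_mod, oracle$t_mod, tolerance = 1e-10)
    expect_equal(res$df_total, oracle$df_total, tolerance = 1e-10)
    expect_equal(res$p, oracle$p, tolerance = 1e-10)
  }
})

test_that("d0 = 0 reduces to the ordinary pooled-variance t-test", {
  x <- make_two_group_matrix(n_proteins = 4, seed = 9)
  ct <- two_group_contrast()
  res <- fit_moderated_t(x, ct, prior = list(d0 = 0, s0_sq = 1))
  for (i in 1:4) {
    tt <- t.test(x$values[i, ct$group_a], x$values[i, ct$group_b],
                 var.equal = TRUE)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("identical group means give t = 0 and p = 1", {
  vals <- matrix(rep(c(1, 2, 3, 4), 2), 1, 8,
                 dimnames = list("P1", sprintf("S%02d", 1:8)))
  x <- abundance_matrix(vals, scale = "log2")
  ct <- contrast("eq", sprintf("S%02d", 1:4), sprintf("S%02d", 5:8))
  res <- fit_moderated_t(x, ct, prior = list(d0 = 2, s0_sq = 1))
  expect_equal(res$t_mod, 0)
  expect_equal(res$p, 1)
})

test_that("moderated t agrees with limma on a complete two-group design", {
  library(limma)
  set.seed(12)
  # heterogeneous per-protein variances so the prior df is finite
  sds <- sqrt(4 * 0.5 / rchisq(40, df = 4))
  vals <- sweep(matrix(rnorm(40 * 16), 40, 16), 1, sds, "*") + 20
  dimnames(vals) <- list(sprintf("P%02d", 1:40), sprintf("S%02d", 1:16))
  vals[1, 1:8] <- vals[1, 1:8] + 1.5
  x <- abundance_matrix(vals, scale = "log2")
  ct <- two_group_contrast(8, 8)
  res <- fit_moderated_t(x, ct)
  design <- cbind(rest = 1, a = rep(c(1, 0), each = 8))
  ebf <- limma::eBayes(limma::lmFit(x$values, design))
  prior <- attr(res, "prior")
  expect_equal(prior$d0, ebf$df.prior, tolerance = 1e-8)
  expect_equal(prior$s0_sq, ebf$s2.prior, tolerance = 1e-8)
  expect_equal(res$t_mod, unname(ebf$t[, "a"]), tolerance = 1e-8)
  expect_equal(res$p, unname(ebf$p.value[, "a"]), tolerance = 1e-8)
})

test_that("limiting behavior: d0 -> 0 ordinary t, huge d0 common-variance z", {
  x <- make_two_group_matrix(n_proteins = 6, seed = 3)
  ct <- two_group_contrast()
  res_big <- fit_moderated_t(x, ct, prior = list(d0 = 1e12, s0_sq = 0.5))
  lfc <- res_big$log2fc
  z <- lfc / sqrt(0.5 * (1 / 6 + 1 / 6))
  expect_equal(res_big$t_mod, z, tolerance = 1e-6)
})

test_that("swapping contrast sides negates log2fc and t exactly", {
  x <- make_two_group_matrix(n_proteins = 7, seed = 15,
                             shift = list(P02 = 2))
  ct <- two_group_contrast()
  rev_ct <- contrast("B_vs_A", ct$group_b, ct$group_a)
  a <- fit_moderated_t(x, ct, prior = list(d0 = 4, s0_sq = 0.3))
  b <- fit_moderated_t(x, rev_ct, prior = list(d0 = 4, s0_sq = 0.3))
  expect_equal(a$log2fc, -b$log2fc, tolerance = 0)
  expect_equal(a$t_mod, -b$t_mod, tolerance = 0)
  expect_equal(a$p, b$p, tolerance = 0)
})

test_that("EB prior estimation: degenerate and simulated recovery", {
  # all variances equal: no excess dispersion, infinite prior df
  pr <- estimate_eb_prior(rep(0.7, 30), 10)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 0.7, tolerance = 0.15)
  expect_error(estimate_eb_prior(rep(1, 5), 4), "at least 10")
  # scaled inverse-chi-square truth d0 = 4, s0² = 1
  hits <- vapply(1:30, function(s) {
    set.seed(500 + s)
    sigma2 <- 4 * 1 / rchisq(5000, df = 4)
    s2 <- sigma2 * rchisq(5000, df = 10) / 10
    pr <- estimate_eb_prior(s2, 10)
    (pr$d0 >= 3 && pr$d0 <= 5.3) && (pr$s0_sq >= 0.9 && pr$s0_sq <= 1.1)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("trigamma inversion matches a bisection oracle", {
  bisect <- function(x, lo = 1e-8, hi = 1e8) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (trigamma(mid) > x) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (x in c(0.01, 0.5, 1, 5, 50)) {
    expect_equal(histoprot:::invert_trigamma(x), bisect(x),
                 tolerance = 1e-8)
  }
})

test_that("BH adjustment matches the step-up definition and its properties", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
  set.seed(77)
  for (i in 1:5) {
    p <- runif(50)^2
    adj <- benjamini_hochberg(p)
    expect_equal(adj, brute_force_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= 0))  # monotone in p rank
    perm <- sample(50)
    expect_equal(benjamini_hochberg(p[perm]), adj[perm])
  }
})

test_that("DAP calling applies strict FDR and inclusive linear FC thresholds", {
  res <- data.frame(protein = paste0("P", 1:4), symbol = paste0("G", 1:4),
                    description = NA, log2fc = c(1.0, 0.3, 2.0, -0.7),
                    t_mod = 0, df_total = 10,
                    p = c(0.001, 0.001, 0.1, 0.01),
                    fdr = c(0.01, 0.01, 0.2, 0.04),
                    n_a = 5, n_b = 5, dap_flag = "none")
  class(res) <- c("DAResult", "data.frame")
  out <- call_daps(res)
  expect_identical(out$dap_flag, c("up", "none", "none", "down"))
  # boundary: |log2fc| exactly log2(1.5) is included, fdr exactly 0.05 not
  res$log2fc <- c(log2(1.5), -log2(1.5), 1, 1)
  res$fdr <- c(0.04, 0.04, 0.05, 0.049)
  out <- call_daps(res)
  expect_identical(out$dap_flag, c("up", "down", "none", "up"))
  expect_identical(call_daps(res[0, ])$dap_flag, character(0))
})

test_that("one-vs-rest equals the pairwise contrast with two groups", {
  x <- make_two_group_matrix(n_proteins = 14, seed = 6,
                             shift = list(P05 = 1))
  ann <- two_group_annotation()
  ovr <- one_vs_rest_contrasts(x, ann)
  direct <- call_daps(fit_moderated_t(x, two_group_contrast()))
  expect_equal(ovr$A$t_mod, direct$t_mod, tolerance = 1e-12)
  expect_equal(ovr$A$t_mod, -ovr$B$t_mod, tolerance = 1e-12)
  # result independent of target list order
  ovr2 <- one_vs_rest_contrasts(x, ann, c("B", "A"))
  expect_equal(ovr2$A, ovr$A)
  expect_error(one_vs_rest_contrasts(x, ann, "Z"), "absent")
})

test_that("a planted histotype effect is flagged only in its own contrast", {
  sizes <- c(W = 25L, X = 25L, Y = 25L, Z = 25L)
  cfg <- cohort_config(group_sizes = sizes, n_proteins = 120,
                       effect_table = data.frame(protein = "P0010",
                                                 group = "X", log2fc = 2.5),
                       missingness = NULL, survival = NULL, seed = 41)
  co <- generate_cohort(cfg)
  m <- log2_transform(co$abundance)
  ovr <- one_vs_rest_contrasts(m, co$annotation)
  flags <- vapply(ovr, function(d) d$dap_flag[d$protein == "P0010"], "")
  expect_identical(unname(flags["X"]), "up")
  expect_true(all(flags[c("W", "Y", "Z")] != "up"))
})

test_that("planted DAP recall exceeds 0.9 at |log2FC| = 2, n = 40 per group", {
  recalls <- vapply(1:10, function(s) {
    eff <- data.frame(protein = sprintf("P%04d", 1:10), group = "A",
                      log2fc = rep(c(2, -2), 5))
    cfg <- cohort_config(group_sizes = c(A = 40L, B = 40L),
                         n_proteins = 150, effect_table = eff,
                         missingness = NULL, survival = NULL,
                         seed = 600 + s)
    co <- generate_cohort(cfg)
    da <- one_vs_rest_contrasts(log2_transform(co$abundance),
                                co$annotation, "A")$A
    called <- da$protein[da$dap_flag != "none"]
    mean(eff$protein %in% called)
  }, 0)
  expect_gt(mean(recalls), 0.9)
})

test_that("Wilcoxon pairwise tests: exact p, rank invariance, identical groups", {
  vals <- rbind(c(1, 2, 3, 10, 11, 12),
                c(5, 6, 7, 5, 6, 7))
  dimnames(vals) <- list(c("P1", "P2"), sprintf("S%02d", 1:6))
  x <- abundance_matrix(vals, scale = "log2")
  ann <- two_group_annotation(3, 3)
  pw <- pairwise_wilcoxon(x, ann, "P1")
  expect_equal(pw$p, 0.1)  # exact two-sided rank-sum over C(6,3) orderings
  # strictly monotone transform leaves the p unchanged
  x2 <- abundance_matrix(exp(vals / 3), scale = "log2")
  expect_equal(pairwise_wilcoxon(x2, ann, "P1")$p, 0.1)
  pw2 <- pairwise_wilcoxon(x, ann, "P2")
  expect_gt(pw2$p, 0.99)
})
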