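test_that("Cox fit matches grid-search partial-likelihood maximization", {
  fx <- cox_fixture_8()
  fit <- fit_cox(fx$times, fx$events, data.frame(x = fx$x))
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, partial_loglik_1d, 0, times = fx$times,
               events = fx$events, x = fx$x)
  beta_grid <- grid[which.max(ll)]
  expect_equal(unname(fit$beta), beta_grid, tolerance = 1e-3)
  # refine with optimize to reach 1e-6
  opt <- optimize(partial_loglik_1d, c(beta_grid - 0.01, beta_grid + 0.01),
                  times = fx$times, events = fx$events, x = fx$x,
                  maximum = TRUE, tol = 1e-9)
  expect_equal(unname(fit$beta), opt$maximum, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$n_events, 6)
  expect_lte(fit$ci_low, fit$hr); expect_gte(fit$ci_high, fit$hr)
})

test_that("two-parameter Cox fit matches brute-force maximization", {
  set.seed(61)
  n <- 9
  times <- sort(rexp(n, 1 / 10))
  events <- c(1, 1, 1, 0, 1, 1, 0, 1, 1)
  X <- cbind(a = rnorm(n), b = rnorm(n))
  fit <- fit_cox(times, events, as.data.frame(X))
  opt <- optim(c(0, 0), function(b)
    -partial_loglik_2d(b, times, events, X), method = "BFGS",
    control = list(reltol = 1e-14))
  expect_equal(unname(fit$beta), opt$par, tolerance = 1e-5)
})

test_that("identical event experience in both arms gives beta = 0", {
  times <- c(1, 2, 3, 4, 1, 2, 3, 4)
  events <- rep(1, 8)
  x <- rep(c(0, 1), each = 4)
  fit <- fit_cox(times, events, data.frame(x = x))
  expect_lt(abs(unname(fit$beta)), 1e-6)
  expect_gt(unname(fit$p_wald), 0.99)
})

test_that("separation is reported as non-convergence, constants rejected", {
  times <- c(1, 2, 3, 10, 11, 12)
  events <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- suppressWarnings(fit_cox(times, events, data.frame(x = x)))
  expect_false(fit$converged)
  expect_error(fit_cox(times, events, data.frame(x = rep(2, 6))),
               "constant")
  expect_error(fit_cox(times, rep(0, 6), data.frame(x = x)), "event")
})

test_that("log-rank equals the Cox score test without ties", {
  set.seed(71)
  n <- 30
  times <- rexp(n); events <- rbinom(n, 1, 0.8)
  ab <- rnorm(n)
  med <- median(ab)
  lr <- logrank_median_split(ab, times, events)
  grp <- as.integer(ab > med)
  sc <- survival::coxph(survival::Surv(times, events) ~ grp)
  score_chisq <- unname(summary(sc)$sctest["test"])
  expect_equal(lr$chi_sq, score_chisq, tolerance = 1e-8)
  expect_equal(lr$group_sizes, c(low = 15L, high = 15L),
               ignore_attr = TRUE)
  # relabeling high/low leaves the statistic unchanged
  lr2 <- logrank_median_split(-ab, times, events)
  expect_equal(lr2$chi_sq, lr$chi_sq, tolerance = 1e-8)
})

test_that("log-rank hand fixture and degenerate strata", {
  # 6 subjects, all events, split 3/3 by abundance
  ab <- c(1, 2, 3, 10, 11, 12)
  times <- c(1, 2, 3, 4, 5, 6)
  events <- rep(1, 6)
  lr <- logrank_median_split(ab, times, events)
  # hand computation: O_low = 3; E_low = 1/2+2/5+1/4+0+0+0 = 1.15;
  # hypergeometric variances 1/4+6/25+3/16+2/9+1/4 (last two terms with
  # one group empty contribute 0): sum over event times with both groups
  # at risk: v = sum n1 n2 (n-d) d / (n^2 (n-1)) with d = 1 each
  o_minus_e <- 3 - (1 / 2 + 2 / 5 + 1 / 4)
  v <- (3 * 3 * 5) / (36 * 5) + (2 * 3 * 4) / (25 * 4) + (1 * 3 * 3) / (16 * 3)
  expect_equal(lr$chi_sq, o_minus_e^2 / v, tolerance = 1e-8)
  expect_equal(lr$p, pchisq(o_minus_e^2 / v, 1, lower.tail = FALSE))
  # identical survival in both strata: statistic 0
  lr0 <- logrank_median_split(c(1, 2, 3, 10, 11, 12),
                              c(5, 6, 7, 5, 6, 7), rep(1, 6))
  expect_lt(lr0$chi_sq, 1e-10)
  expect_error(logrank_median_split(c(1, 1, 1, 2), 1:4, rep(1, 4)),
               "degenerate")
})

test_that("Kaplan-Meier product-limit estimator on worked fixtures", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  km2 <- kaplan_meier(c(1, 2, 3), c(0, 1, 1))
  expect_equal(km2$surv[km2$time == 2], 0.5)
  expect_equal(km2$surv[km2$time == 3], 0)
  km3 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  expect_true(all(diff(kaplan_meier(rexp(20), rbinom(20, 1, 0.5))$surv) <= 0))
})

test_that("concordance index matches exhaustive pair enumeration", {
  enum_c <- function(r, t, e) {
    num <- den <- 0
    for (i in seq_along(t)) for (j in seq_along(t)) {
      if (i == j) next
      if (e[i] == 1 && t[i] < t[j]) {  # i fails first, j still at risk
        den <- den + 1
        num <- num + (r[i] > r[j]) + 0.5 * (r[i] == r[j])
      }
    }
    num / den
  }
  t4 <- c(2, 4, 6, 8); e4 <- c(1, 1, 0, 1); r4 <- c(4, 3, 2, 1)
  expect_equal(concordance_index(r4, t4, e4), enum_c(r4, t4, e4))
  expect_equal(concordance_index(r4, t4, e4), 1)           # anti-ordered
  expect_equal(concordance_index(-r4, t4, e4), 0)          # reversed
  set.seed(81)
  for (i in 1:5) {
    t <- rexp(12); e <- rbinom(12, 1, 0.7); r <- sample(1:5, 12, TRUE)
    expect_equal(concordance_index(r, t, e), enum_c(r, t, e),
                 tolerance = 1e-12)
  }
})

test_that("univariate screen flags planted effects and stays calibrated", {
  cfg <- cohort_config(
    group_sizes = c(A = 120L), n_proteins = 60,
    effect_table = NULL, missingness = NULL,
    survival = survival_sim_params(betas = c(P0005 = log(2)),
                                   censoring_rate = 1 / 6000),
    seed = 19)
  hits <- vapply(1:20, function(s) {
    cfg$seed <- 900L + s
    co <- generate_cohort(cfg)
    scr <- univariate_protein_screen(log2_transform(co$abundance),
                                     co$annotation, "os")
    scr$pass[scr$protein == "P0005"]
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # null proteins pass at roughly the nominal rate
  co <- generate_cohort(cfg)
  scr <- univariate_protein_screen(log2_transform(co$abundance),
                                   co$annotation, "os")
  null_rate <- mean(scr$pass[scr$protein != "P0005"])
  expect_lt(null_rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 59) + 0.03)
})

test_that("screen skips unusable proteins with a reason", {
  cfg <- cohort_config(group_sizes = c(A = 30L), n_proteins = 15,
                       effect_table = NULL, missingness = NULL,
                       survival = survival_sim_params(betas = c()),
                       seed = 5)
  co <- generate_cohort(cfg)
  m <- log2_transform(co$abundance)
  m$values["P0003", ] <- NA
  scr <- univariate_protein_screen(m, co$annotation, "os")
  expect_false("P0003" %in% scr$protein)
  expect_true("P0003" %in% attr(scr, "skipped")$protein)
})

test_that("LASSO covariate selection finds a strong planted covariate", {
  found <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    n <- 200
    ann <- data.frame(sample_id = sprintf("S%03d", 1:n), group = "A",
                      stage = sample(1:4, n, TRUE),
                      age = rnorm(n, 60, 10),
                      ca125 = exp(rnorm(n, 4, 1)),
                      residual_tumor = sample(0:3, n, TRUE))
    ann <- simulate_survival(ann, NULL,
                             survival_sim_params(betas = c(stage = 0.8),
                                                 censoring_rate = 1 / 6000),
                             seed = 2000 + s)
    sel <- select_covariates_lasso_cox(ann, "os", seed = s)
    "stage" %in% sel
  }, TRUE)
  expect_gte(mean(found), 0.9)
  # determinism under a fixed seed
  set.seed(77)
  n <- 100
  ann <- data.frame(sample_id = sprintf("S%03d", 1:n), group = "A",
                    stage = sample(1:4, n, TRUE), age = rnorm(n, 60, 10),
                    ca125 = exp(rnorm(n, 4, 1)),
                    residual_tumor = sample(0:3, n, TRUE))
  ann <- simulate_survival(ann, NULL,
                           survival_sim_params(betas = c(stage = 0.5)),
                           seed = 4)
  expect_identical(select_covariates_lasso_cox(ann, "os", seed = 9),
                   select_covariates_lasso_cox(ann, "os", seed = 9))
})

test_that("adjusted model nests the univariate fit and removes confounding", {
  cfg <- cohort_config(group_sizes = c(A = 100L), n_proteins = 20,
                       effect_table = NULL, missingness = NULL,
                       survival = survival_sim_params(betas = c()),
                       seed = 15)
  co <- generate_cohort(cfg)
  m <- log2_transform(co$abundance)
  # no covariates: exactly the univariate fit
  adj <- multivariate_adjusted_cox("P0002", m, co$annotation,
                                   character(0), "os")
  uni <- univariate_protein_screen(
    subset_abundance(m, proteins = "P0002"), co$annotation, "os")
  expect_equal(unname(adj$hr["abundance"]), uni$hr, tolerance = 1e-10)
  expect_equal(unname(adj$p_wald["abundance"]), uni$p_wald,
               tolerance = 1e-10)
  # confounded design: protein tracks stage, true protein effect 0
  cover <- vapply(1:12, function(s) {
    set.seed(3000 + s)
    n <- 150
    stage <- sample(1:4, n, TRUE)
    ab <- matrix(20 + stage + rnorm(n, 0, 0.7), 1, n,
                 dimnames = list("PC", sprintf("S%03d", 1:n)))
    ann <- data.frame(sample_id = sprintf("S%03d", 1:n), group = "A",
                      stage = stage, age = rnorm(n, 60, 5),
                      ca125 = exp(rnorm(n, 4, 1)), residual_tumor = 0)
    ann <- simulate_survival(ann, NULL,
                             survival_sim_params(betas = c(stage = 0.7),
                                                 censoring_rate = 1 / 8000),
                             seed = 4000 + s)
    mm <- abundance_matrix(ab, scale = "log2")
    a <- multivariate_adjusted_cox("PC", mm, ann, "stage", "os")
    u <- multivariate_adjusted_cox("PC", mm, ann, character(0), "os")
    c(adj_covers = a$ci_low["abundance"] <= 1 & a$ci_high["abundance"] >= 1,
      una_covers = u$ci_low["abundance"] <= 1 & u$ci_high["abundance"] >= 1)
  }, c(adj_covers = TRUE, una_covers = TRUE))
  expect_gte(mean(cover["adj_covers", ]), 0.8)
  expect_lt(mean(cover["una_covers", ]), mean(cover["adj_covers", ]))
})

test_that("bootstrap validation separates planted from null effects", {
  cfg <- cohort_config(
    group_sizes = c(A = 150L), n_proteins = 12,
    effect_table = NULL, missingness = NULL,
    survival = survival_sim_params(betas = c(P0001 = log(3)),
                                   censoring_rate = 1 / 6000),
    seed = 27)
  co <- generate_cohort(cfg)
  m <- log2_transform(co$abundance)
  strong <- bootstrap_validate("P0001", m, co$annotation,
                               n_boot = 200, seed = 3)
  expect_true(strong$pass)
  expect_true(strong$reliable)
  null_ps <- vapply(sprintf("P%04d", 5:10), function(p) {
    bootstrap_validate(p, m, co$annotation, n_boot = 120,
                       seed = 11)$boot_mean_p
  }, 0)
  # under the null the Wald p is roughly uniform: mean near 0.5
  expect_gt(mean(null_ps), 0.25)
  expect_false(all(null_ps < 0.2))
  # determinism
  b1 <- bootstrap_validate("P0002", m, co$annotation, n_boot = 60, seed = 8)
  b2 <- bootstrap_validate("P0002", m, co$annotation, n_boot = 60, seed = 8)
  expect_identical(b1$boot_mean_p, b2$boot_mean_p)
})

test_that("risk classification follows the HR/CI/FDR/bootstrap definition", {
  mk <- function(hr, lo, hi) {
    structure(list(hr = c(abundance = hr), ci_low = c(abundance = lo),
                   ci_high = c(abundance = hi), converged = TRUE),
              class = "CoxResult")
  }
  expect_identical(classify_risk(mk(0.5, 0.3, 0.8), 0.01, TRUE),
                   "favorable")
  expect_identical(classify_risk(mk(2, 0.9, 4.4), 0.01, TRUE),
                   "inconclusive")
  expect_identical(classify_risk(mk(1.8, 1.2, 2.7), 0.03, TRUE),
                   "unfavorable")
  expect_identical(classify_risk(mk(1.8, 1.2, 2.7), 0.03, FALSE),
                   "inconclusive")
  expect_identical(classify_risk(mk(0.5, 0.3, 0.8), 0.2, TRUE),
                   "inconclusive")
})

test_that("HR recovery at n = 400 is within 10% in the median across seeds", {
  hrs <- vapply(1:15, function(s) {
    ann <- data.frame(sample_id = sprintf("S%03d", 1:400), group = "A",
                      arm = rep(0:1, 200))
    si <- simulate_survival(ann, NULL,
                            survival_sim_params(betas = c(arm = log(2)),
                                                censoring_rate = 1 / 8000),
                            seed = 5000 + s)
    unname(fit_cox(si$os_time, si$os_event,
                   data.frame(arm = si$arm))$hr)
  }, 0)
  expect_lt(abs(median(hrs) - 2) / 2, 0.1)
})

test_that("survival cascade candidates passed every upstream filter", {
  cfg <- cohort_config(
    group_sizes = c(A = 120L), n_proteins = 40,
    effect_table = NULL, missingness = NULL,
    survival = survival_sim_params(
      betas = c(P0004 = 0.6, P0009 = -0.6, stage = 0.3),
      censoring_rate = 1 / 6000),
    seed = 53)
  co <- generate_cohort(cfg)
  m <- log2_transform(co$abundance)
  res <- survival_screen(m, co$annotation, "os", n_boot = 80, seed = 5)
  expect_gt(nrow(res), 0)
  uni <- univariate_protein_screen(m, co$annotation, "os")
  for (i in seq_len(nrow(res))) {
    expect_true(uni$p_wald[uni$protein == res$protein[i]] < 0.05)
    expect_lt(res$logrank_p[i], 0.05)
  }
  classified <- res[res$risk_class != "inconclusive", ]
  for (i in seq_len(nrow(classified))) {
    expect_lt(classified$fdr[i], 0.05)
    expect_lt(classified$boot_mean_p[i], 0.2)
    if (classified$risk_class[i] == "favorable") {
      expect_lt(classified$hr_adj[i], 1)
      expect_lt(classified$ci_high[i], 1)
    } else {
      expect_gt(classified$hr_adj[i], 1)
      expect_gt(classified$ci_low[i], 1)
    }
  }
  # planted effects recovered with correct directions
  expect_true("P0004" %in% res$protein)
  expect_true("P0009" %in% res$protein)
  expect_gt(res$hr_adj[res$protein == "P0004"], 1)
  expect_lt(res$hr_adj[res$protein == "P0009"], 1)
})
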