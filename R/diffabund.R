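#' Empirical-Bayes prior for protein-wise variances
#'
#' Method-of-moments estimation of the scaled inverse-chi-square prior
#' (`d0` degrees of freedom, `s0²` scale) underlying the moderated
#' t-statistic, from the observed per-protein sample variances and their
#' residual degrees of freedom. On the log scale,
#' `e = log(s²) - digamma(df/2) + log(df/2)` is an unbiased estimate of
#' `log(s0²) + digamma(d0/2) - log(d0/2)` with variance
#' `trigamma(df/2) + trigamma(d0/2)`; matching the first two moments gives
#' `trigamma(d0/2) = var(e) - mean(trigamma(df/2))`, solved by monotone
#' root-finding (trigamma is strictly decreasing). Zero or negative excess
#' dispersion yields an infinite prior (complete shrinkage to `s0²`).
#'
#' @param sample_variances Per-protein pooled residual variances.
#' @param dfs Residual degrees of freedom, recycled if scalar.
#' @return List of class `EBPrior` with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_eb_prior <- function(sample_variances, dfs) {
  dfs <- rep_len(dfs, length(sample_variances))
  ok <- is.finite(sample_variances) & sample_variances > 0 & dfs > 0
  s2 <- sample_variances[ok]
  df <- dfs[ok]
  if (length(s2) < 10) stop("need at least 10 positive-df variances")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  excess <- stats::var(e) - mean(trigamma(df / 2))
  if (!is.finite(excess) || excess <= 0) {
    prior <- list(d0 = Inf, s0_sq = exp(mean(e)))
  } else {
    d0 <- 2 * invert_trigamma(excess)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    prior <- list(d0 = d0, s0_sq = s0_sq)
  }
  class(prior) <- "EBPrior"
  prior
}

# Solve trigamma(y) = x for y > 0. trigamma is strictly decreasing with
# range (0, Inf), so bracket geometrically then bisect via uniroot.
invert_trigamma <- function(x, tol = 1e-10) {
  stopifnot(x > 0)
  lo <- 1; hi <- 1
  while (trigamma(lo) < x) lo <- lo / 2
  while (trigamma(hi) > x) hi <- hi * 2
  stats::uniroot(function(y) trigamma(y) - x, lower = lo, upper = hi,
                 tol = tol)$root
}

#' Define a two-sided contrast
#'
#' @param name Contrast label.
#' @param group_a,group_b Disjoint, non-empty character vectors of sample
#'   ids; for a one-vs-rest contrast `group_b` is every other sample.
#' @export
contrast <- function(name, group_a, group_b) {
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("contrast sides must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("contrast sides must be disjoint")
  }
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "Contrast")
}

#' Moderated-t differential abundance for one contrast
#'
#' For each protein the two group means are compared with a pooled-variance
#' two-sample t-statistic whose variance is shrunk toward the
#' empirical-Bayes prior: with pooled residual variance `s²` on
#' `df = n_a + n_b - 2` degrees of freedom, the posterior variance is
#' `s²_post = (d0·s0² + df·s²) / (d0 + df)` and
#' `t = log2FC / (s_post · sqrt(1/n_a + 1/n_b))`, referred to a
#' t-distribution on `df + d0` degrees of freedom. `d0 = 0` recovers the
#' ordinary pooled t-test; `d0 = Inf` fixes every variance at `s0²`.
#' Each protein is tested on its complete observations (no imputation);
#' proteins with fewer than two complete observations on either side are
#' skipped with a reason. Benjamini-Hochberg adjustment is applied across
#' the tested proteins of the contrast.
#'
#' @param x Log2-scale `AbundanceMatrix`.
#' @param ct A [contrast()].
#' @param prior `"auto"` (estimate from this contrast's variances via
#'   [estimate_eb_prior()]) or an `EBPrior` / list with `d0`, `s0_sq`.
#' @return A `DAResult` data frame: `protein`, `symbol`, `description`,
#'   `log2fc` (mean A - mean B), `t_mod`, `df_total`, `p`, `fdr`, `n_a`,
#'   `n_b`, `dap_flag` (filled by [call_daps()]); skipped proteins in the
#'   `"skipped"` attribute, the prior in `"prior"`, the contrast name in
#'   `"contrast"`.
#' @export
fit_moderated_t <- function(x, ct, prior = "auto") {
  stopifnot(inherits(x, "AbundanceMatrix"), inherits(ct, "Contrast"))
  if (x$scale != "log2") stop("matrix must be log2-transformed")
  a <- x$values[, ct$group_a, drop = FALSE]
  b <- x$values[, ct$group_b, drop = FALSE]
  n_a <- rowSums(!is.na(a))
  n_b <- rowSums(!is.na(b))
  testable <- n_a >= 2 & n_b >= 2
  if (!any(testable)) stop("all proteins skipped (insufficient data)")

  mean_a <- rowMeans(a, na.rm = TRUE)
  mean_b <- rowMeans(b, na.rm = TRUE)
  ss_a <- rowSums((a - mean_a)^2, na.rm = TRUE)
  ss_b <- rowSums((b - mean_b)^2, na.rm = TRUE)
  df <- n_a + n_b - 2
  s2 <- ifelse(df > 0, (ss_a + ss_b) / df, NA_real_)

  if (identical(prior, "auto")) {
    prior <- estimate_eb_prior(s2[testable], df[testable])
  }
  stopifnot(is.list(prior), prior$d0 >= 0, prior$s0_sq > 0)

  idx <- which(testable)
  log2fc <- (mean_a - mean_b)[idx]
  d0 <- prior$d0; s0 <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0, length(idx)) else {
    (d0 * s0 + df[idx] * s2[idx]) / (d0 + df[idx])
  }
  se <- sqrt(s2_post * (1 / n_a[idx] + 1 / n_b[idx]))
  t_mod <- log2fc / se
  df_total <- df[idx] + d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  fdr <- benjamini_hochberg(p)

  ids <- protein_ids(x)[idx]
  res <- data.frame(
    protein = ids, symbol = unname(x$symbols[ids]),
    description = unname(x$descriptions[ids]),
    log2fc = unname(log2fc), t_mod = unname(t_mod),
    df_total = unname(df_total), p = unname(p), fdr = unname(fdr),
    n_a = unname(n_a[idx]), n_b = unname(n_b[idx]),
    dap_flag = "none", stringsAsFactors = FALSE)
  skipped <- protein_ids(x)[!testable]
  attr(res, "skipped") <- data.frame(
    protein = skipped,
    reason = rep("fewer than 2 complete observations on one side",
                 length(skipped)),
    stringsAsFactors = FALSE)
  attr(res, "prior") <- prior
  attr(res, "contrast") <- ct$name
  class(res) <- c("DAResult", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially abundant proteins
#'
#' A protein is an upregulated DAP when `fdr < fdr_cut` and its linear fold
#' change is at least `fc_cut` (i.e. `log2fc >= log2(fc_cut)`);
#' downregulated mirror-image. The fold-change threshold is interpreted on
#' the linear scale with an inclusive boundary; the FDR threshold is
#' strict.
#'
#' @param daresult A `DAResult` from [fit_moderated_t()].
#' @param fdr_cut FDR threshold (default 0.05, strict `<`).
#' @param fc_cut Linear fold-change threshold (default 1.5, inclusive on
#'   `|log2fc| >= log2(fc_cut)`).
#' @return The `DAResult` with `dap_flag` set to `up`/`down`/`none`.
#' @export
call_daps <- function(daresult, fdr_cut = 0.05, fc_cut = 1.5) {
  stopifnot(inherits(daresult, "DAResult") || is.data.frame(daresult))
  lfc_cut <- log2(fc_cut)
  flag <- rep("none", nrow(daresult))
  sig <- daresult$fdr < fdr_cut
  flag[sig & daresult$log2fc >= lfc_cut] <- "up"
  flag[sig & daresult$log2fc <= -lfc_cut] <- "down"
  daresult$dap_flag <- flag
  daresult
}

#' One-vs-rest moderated-t contrasts for every target group
#'
#' Each target histotype is compared against all other samples pooled as a
#' single combined group; BH adjustment is applied within each contrast
#' separately.
#'
#' @param x Log2-scale `AbundanceMatrix`.
#' @param annotation Sample annotation with `sample_id`, `group`.
#' @param target_groups Groups to test; default every group in the
#'   annotation.
#' @param prior Passed to [fit_moderated_t()].
#' @inheritParams call_daps
#' @return Named list of `DAResult`, one per target group, with DAP flags
#'   set.
#' @export
one_vs_rest_contrasts <- function(x, annotation,
                                  target_groups = NULL, prior = "auto",
                                  fdr_cut = 0.05, fc_cut = 1.5) {
  groups <- group_lookup(annotation, sample_ids(x))
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  if (is.null(target_groups)) target_groups <- unique(groups)
  if (!all(target_groups %in% groups)) {
    stop("target group absent from annotation")
  }
  res <- lapply(target_groups, function(g) {
    ct <- contrast(paste0(g, "_vs_rest"),
                   sample_ids(x)[groups == g],
                   sample_ids(x)[groups != g])
    call_daps(fit_moderated_t(x, ct, prior = prior),
              fdr_cut = fdr_cut, fc_cut = fc_cut)
  })
  stats::setNames(res, target_groups)
}

#' Pairwise Wilcoxon rank-sum tests for one protein
#'
#' Two-sided rank-sum p-value for every pair of groups using the available
#' (non-missing) values, BH-adjusted across the pairs; used for boxplot
#' annotation statistics.
#'
#' @param x Log2-scale `AbundanceMatrix`.
#' @param annotation Sample annotation.
#' @param protein Protein id.
#' @param groups Optional subset of groups to compare.
#' @return Data frame `group_a`, `group_b`, `p`, `fdr`; pairs with fewer
#'   than 2 observations on a side are skipped.
#' @export
pairwise_wilcoxon <- function(x, annotation, protein, groups = NULL) {
  stopifnot(protein %in% protein_ids(x))
  glab <- group_lookup(annotation, sample_ids(x))
  if (is.null(groups)) groups <- unique(glab)
  vals <- x$values[protein, ]
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    va <- vals[glab == pr[1]]; va <- va[!is.na(va)]
    vb <- vals[glab == pr[2]]; vb <- vb[!is.na(vb)]
    if (length(va) < 2 || length(vb) < 2) return(NULL)
    p <- suppressWarnings(
      stats::wilcox.test(va, vb, alternative = "two.sided")$p.value)
    data.frame(group_a = pr[1], group_b = pr[2], p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable group pair for ", protein)
  out$fdr <- benjamini_hochberg(out$p)
  out
}
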