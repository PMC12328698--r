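#' Fit a Cox proportional-hazards model
#'
#' Thin, validated wrapper around partial-likelihood maximization with the
#' Efron tie correction. Returns per-covariate hazard ratios with 95% Wald
#' confidence intervals, Wald p-values and Harrell's concordance from the
#' model risk scores. Monotone-likelihood/separation fits are flagged as
#' non-converged rather than errored.
#'
#' @param times Follow-up times (>= 0).
#' @param events Event indicators (0/1).
#' @param covariates Data frame or matrix of finite numeric covariates; a
#'   constant covariate is rejected.
#' @param ties Tie-handling method, `"efron"` by default.
#' @return List of class `CoxResult`: `beta`, `hr`, `ci_low`, `ci_high`,
#'   `p_wald` (named per covariate), `c_index`, `converged`, `n`,
#'   `n_events`, `loglik`.
#' @export
fit_cox <- function(times, events, covariates, ties = "efron") {
  covariates <- as.data.frame(covariates)
  stopifnot(length(times) == nrow(covariates),
            length(events) == length(times),
            all(events %in% c(0, 1)), all(times >= 0))
  if (sum(events) < 1) stop("need at least one event")
  if (!all(vapply(covariates, function(v) all(is.finite(v)), TRUE))) {
    stop("covariates must be finite")
  }
  consts <- vapply(covariates, function(v) stats::sd(v) == 0, TRUE)
  if (any(consts)) stop("constant covariate: ",
                        paste(names(covariates)[consts], collapse = ", "))
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  if (any(abs(stats::coef(fit)) > 15)) converged <- FALSE
  sm <- summary(fit)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  structure(list(
    beta = beta,
    hr = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p_wald = stats::setNames(sm$coefficients[, "Pr(>|z|)"], names(beta)),
    c_index = unname(sm$concordance["C"]),
    converged = converged,
    n = length(times),
    n_events = sum(events),
    loglik = fit$loglik[2]), class = "CoxResult")
}

#' Proteome-wide univariate Cox screen
#'
#' One continuous-covariate Cox fit per protein on its log2 abundance
#' (complete cases). Proteins with fewer than `min_n` complete cases or
#' `min_events` events are skipped with a reason; proteins with Wald
#' p < 0.05 are flagged as passing.
#'
#' @param x Log2-scale `AbundanceMatrix`.
#' @param annotation Annotation containing `<endpoint>_time` and
#'   `<endpoint>_event` columns.
#' @param endpoint `"os"` or `"dss"`.
#' @param p_cut Wald significance threshold.
#' @param min_n,min_events Usability thresholds per protein.
#' @return Data frame `protein`, `hr`, `ci_low`, `ci_high`, `p_wald`,
#'   `c_index`, `n`, `n_events`, `converged`, `pass`; skipped proteins in
#'   the `"skipped"` attribute.
#' @export
univariate_protein_screen <- function(x, annotation, endpoint = c("os", "dss"),
                                      p_cut = 0.05, min_n = 10,
                                      min_events = 3) {
  endpoint <- match.arg(endpoint)
  ep <- endpoint_columns(annotation, endpoint, sample_ids(x))
  rows <- list(); skipped <- list()
  for (p in protein_ids(x)) {
    ab <- x$values[p, ]
    ok <- !is.na(ab) & !is.na(ep$time) & !is.na(ep$event)
    if (sum(ok) < min_n || sum(ep$event[ok]) < min_events) {
      skipped[[p]] <- "insufficient complete cases or events"
      next
    }
    fit <- try(fit_cox(ep$time[ok], ep$event[ok],
                       data.frame(abundance = ab[ok])), silent = TRUE)
    if (inherits(fit, "try-error")) {
      skipped[[p]] <- conditionMessage(attr(fit, "condition"))
      next
    }
    rows[[p]] <- data.frame(
      protein = p, hr = unname(fit$hr), ci_low = unname(fit$ci_low),
      ci_high = unname(fit$ci_high), p_wald = unname(fit$p_wald),
      c_index = fit$c_index, n = fit$n, n_events = fit$n_events,
      converged = fit$converged, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no usable protein for the survival screen")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$pass <- res$converged & res$p_wald < p_cut
  attr(res, "skipped") <- if (length(skipped)) {
    data.frame(protein = names(skipped), reason = unlist(skipped),
               stringsAsFactors = FALSE)
  } else data.frame(protein = character(0), reason = character(0))
  res
}

endpoint_columns <- function(annotation, endpoint, samples) {
  tc <- paste0(endpoint, "_time"); ec <- paste0(endpoint, "_event")
  if (!all(c(tc, ec) %in% names(annotation))) {
    stop("annotation lacks ", tc, "/", ec)
  }
  idx <- match(samples, annotation$sample_id)
  list(time = annotation[[tc]][idx], event = annotation[[ec]][idx])
}

#' Median-split log-rank test
#'
#' Dichotomizes subjects at the median abundance (values equal to the
#' median go to "low") and compares the two strata with the standard
#' two-group log-rank statistic (chi-square, 1 df).
#'
#' @param abundance Numeric vector (one protein).
#' @param times,events Survival data parallel to `abundance`.
#' @return List `chi_sq`, `p`, `group_sizes` (low/high).
#' @export
logrank_median_split <- function(abundance, times, events) {
  ok <- !is.na(abundance) & !is.na(times) & !is.na(events)
  abundance <- abundance[ok]; times <- times[ok]; events <- events[ok]
  med <- stats::median(abundance)
  high <- abundance > med
  if (sum(high) < 2 || sum(!high) < 2) {
    stop("degenerate stratum after median split")
  }
  sd_ <- survival::survdiff(
    survival::Surv(times, events) ~ high)
  list(chi_sq = unname(sd_$chisq),
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       group_sizes = c(low = sum(!high), high = sum(high)))
}

#' LASSO selection of clinical covariates for adjusted Cox models
#'
#' L1-penalized Cox regression over the candidate clinical covariates only
#' (not proteins), lambda chosen by 5-fold cross-validated partial
#' likelihood; covariates with non-zero coefficients at `lambda.min` are
#' returned (possibly none, in which case downstream models are
#' unadjusted). CA-125 enters on the log scale; stage and residual tumor
#' size as ordinal numerics. Covariates missing in more than
#' `max_missing` of the subjects are dropped from candidacy with a
#' warning, and remaining missingness is handled by complete-case
#' analysis.
#'
#' @param annotation Annotation data frame (one histotype's rows).
#' @param endpoint `"os"` or `"dss"`.
#' @param candidates Candidate covariate column names.
#' @param seed Integer seed fixing the CV folds.
#' @param max_missing Maximum tolerated missing fraction per covariate.
#' @return Character vector of selected covariate names (possibly empty).
#' @export
select_covariates_lasso_cox <- function(annotation, endpoint = c("os", "dss"),
                                        candidates = c("stage", "age",
                                                       "ca125",
                                                       "residual_tumor"),
                                        seed = 1L, max_missing = 0.3) {
  endpoint <- match.arg(endpoint)
  tc <- paste0(endpoint, "_time"); ec <- paste0(endpoint, "_event")
  usable <- character(0)
  for (cv in candidates) {
    if (!cv %in% names(annotation)) {
      warning("covariate absent: ", cv); next
    }
    if (mean(is.na(annotation[[cv]])) > max_missing) {
      warning("covariate dropped (missing > ", max_missing * 100, "%): ", cv)
      next
    }
    usable <- c(usable, cv)
  }
  if (length(usable) == 0) return(character(0))
  xmat <- covariate_design(annotation, usable)
  ok <- stats::complete.cases(xmat) & !is.na(annotation[[tc]]) &
    !is.na(annotation[[ec]]) & annotation[[tc]] > 0
  xmat <- xmat[ok, , drop = FALSE]
  y <- survival::Surv(annotation[[tc]][ok], annotation[[ec]][ok])
  if (sum(annotation[[ec]][ok]) < 5 || nrow(xmat) < 15) {
    return(character(0))  # too little signal to adjust for anything
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  foldid <- stratified_folds(annotation[[ec]][ok], 5)
  cv_fit <- glmnet::cv.glmnet(xmat, y, family = "cox", alpha = 1,
                              foldid = foldid)
  beta <- as.matrix(stats::coef(cv_fit, s = "lambda.min"))[, 1]
  names(beta)[beta != 0]
}

# Clinical covariates on modeling scale: log CA-125, ordinal stage and
# residual tumor, age in years.
covariate_design <- function(annotation, covariates) {
  cols <- lapply(covariates, function(cv) {
    v <- as.numeric(annotation[[cv]])
    if (cv == "ca125") v <- log(v)
    v
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Covariate-adjusted Cox model for one protein
#'
#' Fits abundance plus the selected clinical covariates; with no
#' covariates selected this reduces exactly to the univariate fit.
#'
#' @param protein Protein id.
#' @param x Log2-scale `AbundanceMatrix`.
#' @param annotation Annotation for the same samples.
#' @param selected_covariates Covariate names from
#'   [select_covariates_lasso_cox()] (may be empty).
#' @param endpoint `"os"` or `"dss"`.
#' @return A `CoxResult`; the protein coefficient is named `abundance`.
#' @export
multivariate_adjusted_cox <- function(protein, x, annotation,
                                      selected_covariates = character(0),
                                      endpoint = c("os", "dss")) {
  endpoint <- match.arg(endpoint)
  ep <- endpoint_columns(annotation, endpoint, sample_ids(x))
  ab <- x$values[protein, ]
  design <- data.frame(abundance = ab)
  if (length(selected_covariates) > 0) {
    idx <- match(sample_ids(x), annotation$sample_id)
    design <- cbind(design,
                    covariate_design(annotation[idx, , drop = FALSE],
                                     selected_covariates))
  }
  ok <- stats::complete.cases(design) & !is.na(ep$time) & !is.na(ep$event)
  fit_cox(ep$time[ok], ep$event[ok], design[ok, , drop = FALSE])
}

#' Bootstrap validation of a protein survival model
#'
#' Resamples patients with replacement `n_boot` times, refits the
#' covariate-adjusted model, and averages the protein's Wald p-value over
#' resamples that fit successfully (resamples with no events, a constant
#' covariate, or a failed fit are skipped and counted). The model passes
#' when the mean bootstrap p-value is below `p_cut`; validation is marked
#' unreliable when more than half the resamples were skipped.
#'
#' @param protein Protein id.
#' @param x Log2-scale `AbundanceMatrix`.
#' @param annotation Matching annotation.
#' @param selected_covariates Covariates fixed from the full-data
#'   selection (not re-selected per resample).
#' @param endpoint `"os"` or `"dss"`.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param p_cut Pass threshold on the mean bootstrap p-value.
#' @param seed Integer seed.
#' @return List `boot_mean_p`, `pass`, `n_used`, `n_skipped`, `reliable`.
#' @export
bootstrap_validate <- function(protein, x, annotation,
                               selected_covariates = character(0),
                               endpoint = c("os", "dss"),
                               n_boot = 1000, p_cut = 0.2, seed = 1L) {
  endpoint <- match.arg(endpoint)
  ep <- endpoint_columns(annotation, endpoint, sample_ids(x))
  ab <- x$values[protein, ]
  design <- data.frame(abundance = ab)
  if (length(selected_covariates) > 0) {
    idx <- match(sample_ids(x), annotation$sample_id)
    design <- cbind(design,
                    covariate_design(annotation[idx, , drop = FALSE],
                                     selected_covariates))
  }
  ok <- stats::complete.cases(design) & !is.na(ep$time) & !is.na(ep$event)
  design <- design[ok, , drop = FALSE]
  times <- ep$time[ok]; events <- ep$event[ok]
  n <- length(times)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (sum(events[idx]) < 2) next
    fit <- try(suppressWarnings(
      fit_cox(times[idx], events[idx], design[idx, , drop = FALSE])),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    ps[b] <- unname(fit$p_wald["abundance"])
  }
  used <- !is.na(ps)
  boot_mean_p <- mean(ps[used])
  list(boot_mean_p = boot_mean_p,
       pass = isTRUE(boot_mean_p < p_cut),
       n_used = sum(used), n_skipped = sum(!used),
       reliable = mean(!used) <= 0.5)
}

#' Classify a protein's prognostic direction
#'
#' Favorable: adjusted HR < 1 with the 95% CI excluding 1, FDR below the
#' cutoff and a passing bootstrap; unfavorable is the mirror image;
#' anything else is inconclusive.
#'
#' @param result `CoxResult` of the adjusted model (protein coefficient
#'   `abundance`).
#' @param fdr BH-adjusted protein Wald p across the histotype/endpoint
#'   stream.
#' @param boot_pass Logical bootstrap pass flag.
#' @param fdr_cut FDR threshold.
#' @return `"favorable"`, `"unfavorable"` or `"inconclusive"`.
#' @export
classify_risk <- function(result, fdr, boot_pass, fdr_cut = 0.05) {
  hr <- unname(result$hr["abundance"])
  lo <- unname(result$ci_low["abundance"])
  hi <- unname(result$ci_high["abundance"])
  if (!isTRUE(result$converged) || is.na(hr)) return("inconclusive")
  excl1 <- (lo > 1) || (hi < 1)
  if (hr < 1 && excl1 && fdr < fdr_cut && isTRUE(boot_pass)) "favorable"
  else if (hr > 1 && excl1 && fdr < fdr_cut && isTRUE(boot_pass)) "unfavorable"
  else "inconclusive"
}

#' Kaplan-Meier product-limit estimator
#'
#' @param times,events Survival data.
#' @return Data frame `time`, `n_risk`, `n_event`, `surv` at the distinct
#'   observed times; `surv` is non-increasing with S(0) = 1.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs (the one with the earlier event
#' versus a longer survivor) correctly ordered by risk score, ties in
#' score credited one half.
#'
#' @param risk_scores Higher = higher predicted hazard.
#' @param times,events Survival data.
#' @return Concordance in \[0, 1\].
#' @export
concordance_index <- function(risk_scores, times, events) {
  df <- data.frame(t = times, e = events, r = risk_scores)
  cc <- survival::concordance(survival::Surv(t, e) ~ r, data = df,
                              reverse = TRUE)
  unname(cc$concordance)
}

#' Full prognostic screen for one histotype and endpoint
#'
#' Chains the cascade: univariate Wald screen (p < 0.05), median-split
#' log-rank filter (p < 0.05), LASSO covariate selection, adjusted
#' multivariate Cox with BH-FDR across the surviving proteins, bootstrap
#' robustness validation, and risk classification.
#'
#' @param x Log2-scale `AbundanceMatrix` restricted to one histotype's
#'   samples.
#' @param annotation Matching annotation rows.
#' @param endpoint `"os"` or `"dss"`.
#' @param n_boot Bootstrap resamples per protein.
#' @param fdr_cut FDR threshold for risk classification.
#' @param boot_p_cut Mean bootstrap p threshold.
#' @param seed Integer seed.
#' @param max_proteins Optional cap on the number of proteins carried into
#'   the bootstrap stage (most significant first), for bounded runtimes on
#'   large screens; `Inf` disables.
#' @return Data frame of `SurvivalCandidate` rows: `protein`, `endpoint`,
#'   `hr_adj`, `ci_low`, `ci_high`, `p_adj_model`, `fdr`, `logrank_p`,
#'   `boot_mean_p`, `boot_pass`, `risk_class`, `covariates_used`.
#' @export
survival_screen <- function(x, annotation, endpoint = c("os", "dss"),
                            n_boot = 1000, fdr_cut = 0.05,
                            boot_p_cut = 0.2, seed = 1L,
                            max_proteins = Inf) {
  endpoint <- match.arg(endpoint)
  uni <- univariate_protein_screen(x, annotation, endpoint)
  cand <- uni$protein[uni$pass]
  if (length(cand) == 0) {
    return(empty_candidates(endpoint))
  }
  ep <- endpoint_columns(annotation, endpoint, sample_ids(x))
  lr_keep <- vapply(cand, function(p) {
    ab <- x$values[p, ]
    ok <- !is.na(ab) & !is.na(ep$time) & !is.na(ep$event)
    lr <- try(logrank_median_split(ab[ok], ep$time[ok], ep$event[ok]),
              silent = TRUE)
    if (inherits(lr, "try-error")) return(NA_real_)
    lr$p
  }, 0)
  cand <- cand[!is.na(lr_keep) & lr_keep < 0.05]
  logrank_p <- lr_keep[!is.na(lr_keep) & lr_keep < 0.05]
  if (length(cand) == 0) return(empty_candidates(endpoint))

  covs <- select_covariates_lasso_cox(annotation, endpoint, seed = seed)
  fits <- lapply(cand, function(p) {
    try(suppressWarnings(
      multivariate_adjusted_cox(p, x, annotation, covs, endpoint)),
      silent = TRUE)
  })
  ok_fit <- !vapply(fits, inherits, TRUE, "try-error")
  cand <- cand[ok_fit]; fits <- fits[ok_fit]; logrank_p <- logrank_p[ok_fit]
  if (length(cand) == 0) return(empty_candidates(endpoint))
  p_model <- vapply(fits, function(f) unname(f$p_wald["abundance"]), 0)
  fdr <- benjamini_hochberg(p_model)

  if (is.finite(max_proteins) && length(cand) > max_proteins) {
    keep <- order(p_model)[seq_len(max_proteins)]
    cand <- cand[keep]; fits <- fits[keep]
    logrank_p <- logrank_p[keep]; p_model <- p_model[keep]
    fdr <- fdr[keep]
  }

  rows <- lapply(seq_along(cand), function(i) {
    bv <- bootstrap_validate(cand[i], x, annotation, covs, endpoint,
                             n_boot = n_boot, p_cut = boot_p_cut,
                             seed = seed + i)
    data.frame(
      protein = cand[i], endpoint = endpoint,
      hr_adj = unname(fits[[i]]$hr["abundance"]),
      ci_low = unname(fits[[i]]$ci_low["abundance"]),
      ci_high = unname(fits[[i]]$ci_high["abundance"]),
      p_adj_model = p_model[i], fdr = fdr[i],
      logrank_p = unname(logrank_p[i]),
      boot_mean_p = bv$boot_mean_p, boot_pass = bv$pass,
      risk_class = classify_risk(fits[[i]], fdr[i], bv$pass,
                                 fdr_cut = fdr_cut),
      covariates_used = paste(covs, collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_candidates <- function(endpoint) {
  data.frame(protein = character(0), endpoint = character(0),
             hr_adj = numeric(0), ci_low = numeric(0),
             ci_high = numeric(0), p_adj_model = numeric(0),
             fdr = numeric(0), logrank_p = numeric(0),
             boot_mean_p = numeric(0), boot_pass = logical(0),
             risk_class = character(0), covariates_used = character(0),
             stringsAsFactors = FALSE)
}
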