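#' Default histotype group sizes
#'
#' The composition of a 300-patient epithelial ovarian tumor cohort:
#' carcinoma histotypes (HGSC, LGSC, EC, MC, CCC), borderline tumors
#' (SBL serous, MBL mucinous, SMBL seromucinous, EBL endometrioid) and
#' benign tissues (SB serous, MB mucinous).
#'
#' @return Named integer vector summing to 300.
#' @export
default_group_sizes <- function() {
  c(HGSC = 122L, LGSC = 8L, EC = 42L, MC = 35L, CCC = 45L,
    SBL = 16L, MBL = 10L, SMBL = 4L, EBL = 1L, SB = 11L, MB = 6L)
}

#' Default planted differential-abundance effects
#'
#' A deterministic effect table emulating histotype-specific markers: each
#' of the four main carcinoma histotypes receives 12 upregulated and 8
#' downregulated proteins with log2 fold changes spanning roughly 1-3 in
#' magnitude, mimicking the strong, largely histotype-private markers seen
#' in real ovarian-tumor proteomes.
#'
#' @param n_proteins Number of proteins in the cohort (effects are assigned
#'   to the first proteins in blocks).
#' @return Data frame with columns `protein`, `group`, `log2fc`.
#' @export
default_effect_table <- function(n_proteins = 1000) {
  groups <- c("HGSC", "EC", "MC", "CCC")
  up <- seq(1.0, 3.0, length.out = 12)
  down <- seq(-3.0, -1.0, length.out = 8)
  per_group <- length(up) + length(down)
  stopifnot(n_proteins >= per_group * length(groups))
  rows <- lapply(seq_along(groups), function(gi) {
    idx <- (gi - 1) * per_group + seq_len(per_group)
    data.frame(protein = sprintf("P%04d", idx),
               group = groups[gi],
               log2fc = c(up, down),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort simulation configuration
#'
#' Bundles every parameter of the synthetic cohort: group sizes, number of
#' proteins, the log2-intensity baseline distribution, the scaled
#' inverse-chi-square prior for per-protein variances, planted
#' log2-fold-change effects, intensity-dependent (MNAR) missingness and a
#' Weibull proportional-hazards survival model.
#'
#' @param group_sizes Named counts per group; defaults to
#'   [default_group_sizes()].
#' @param n_proteins Number of simulated proteins.
#' @param baseline_mean,baseline_sd Normal distribution of per-protein
#'   baseline log2 intensities.
#' @param variance_prior_df,variance_prior_scale Degrees of freedom and
#'   scale of the scaled inverse-chi-square distribution the per-protein
#'   residual variances are drawn from; this is exactly the prior the
#'   empirical-Bayes moderated t assumes, making prior recovery testable.
#' @param effect_table Data frame `protein`, `group`, `log2fc` of planted
#'   mean shifts; `NULL` for a null cohort.
#' @param missingness `NULL` (complete data) or a list from [mnar_params()].
#' @param survival `NULL` or a list from [survival_sim_params()].
#' @param seed Integer seed; the full cohort is a deterministic function of
#'   the configuration including this seed.
#'
#' @return A list of class `CohortConfig`.
#' @export
cohort_config <- function(group_sizes = default_group_sizes(),
                          n_proteins = 1000,
                          baseline_mean = 20, baseline_sd = 1.5,
                          variance_prior_df = 4,
                          variance_prior_scale = 0.5,
                          effect_table = default_effect_table(n_proteins),
                          missingness = mnar_params(),
                          survival = survival_sim_params(),
                          seed = 1L) {
  group_sizes <- unlist(group_sizes)  # accept YAML-style named lists
  if (any(group_sizes <= 0)) stop("group sizes must be positive")
  if (is.null(names(group_sizes)) || anyDuplicated(names(group_sizes))) {
    stop("group sizes must be uniquely named")
  }
  stopifnot(n_proteins >= 1, baseline_sd >= 0,
            variance_prior_df > 0, variance_prior_scale > 0)
  if (!is.null(effect_table)) {
    stopifnot(all(c("protein", "group", "log2fc") %in% names(effect_table)))
    if (!all(is.finite(effect_table$log2fc))) stop("non-finite log2fc")
    if (!all(effect_table$group %in% names(group_sizes))) {
      stop("effect references unknown group")
    }
    if (!all(effect_table$protein %in% sprintf("P%04d", 1:n_proteins))) {
      stop("effect references unknown protein")
    }
  }
  structure(list(group_sizes = group_sizes, n_proteins = n_proteins,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 variance_prior_df = variance_prior_df,
                 variance_prior_scale = variance_prior_scale,
                 effect_table = effect_table, missingness = missingness,
                 survival = survival, seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Intensity-dependent missingness parameters
#'
#' A logistic model of DIA detection dropout: the probability that a cell
#' is missing is `max(floor_rate, plogis(intercept + slope * value))` with
#' `value` the latent log2 intensity. A non-positive slope makes low
#' intensities drop out more often (missing-not-at-random), the dominant
#' missingness mechanism of DIA proteomics; `floor_rate` adds a small
#' intensity-independent dropout floor.
#'
#' @param intercept,slope Logistic coefficients (`slope <= 0`).
#' @param floor_rate Minimum dropout probability in \[0, 1\].
#' @export
mnar_params <- function(intercept = 14.5, slope = -0.8, floor_rate = 0.01) {
  if (slope > 0) stop("slope must be <= 0 (low intensity drops out)")
  stopifnot(floor_rate >= 0, floor_rate <= 1)
  list(intercept = intercept, slope = slope, floor_rate = floor_rate)
}

#' Survival simulation parameters
#'
#' Weibull baseline hazard under a proportional-hazards linear predictor,
#' exponential censoring, and a cause-mixture weight that thins overall
#' deaths into disease-specific deaths so that OS and DSS endpoints share
#' one risk structure.
#'
#' @param baseline_shape,baseline_scale Weibull shape/scale (days).
#' @param betas Named numeric log-hazard coefficients; names refer to
#'   annotation columns (e.g. `stage`, `age`) or protein ids (effect per
#'   log2-intensity unit).
#' @param censoring_rate Rate of the exponential censoring distribution
#'   (per day); 0 disables censoring.
#' @param dss_weight Probability that a death is disease-specific.
#' @export
survival_sim_params <- function(baseline_shape = 1.2,
                                baseline_scale = 2500,
                                betas = c(stage = 0.35,
                                          P0001 = 0.35, P0013 = -0.35),
                                censoring_rate = 1 / 4000,
                                dss_weight = 0.8) {
  stopifnot(baseline_shape > 0, baseline_scale > 0, censoring_rate >= 0,
            dss_weight >= 0, dss_weight <= 1)
  list(baseline_shape = baseline_shape, baseline_scale = baseline_scale,
       betas = betas, censoring_rate = censoring_rate,
       dss_weight = dss_weight)
}

#' Generate a synthetic proteomic cohort
#'
#' Draws per-protein baselines and residual variances (scaled
#' inverse-chi-square), adds the planted group effects, samples latent log2
#' intensities, applies MNAR missingness and simulates survival endpoints.
#' Identical configurations (including seed) give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return List with `abundance` (raw-scale [abundance_matrix()]),
#'   `annotation` (data frame with group, clinical covariates and OS/DSS
#'   endpoints) and `truth` (planted DAPs, per-protein prognostic log-HRs,
#'   the missingness mask and per-protein true variances).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  sizes <- config$group_sizes
  n_s <- sum(sizes)
  n_p <- config$n_proteins
  proteins <- sprintf("P%04d", seq_len(n_p))
  samples <- sprintf("S%03d", seq_len(n_s))
  groups <- rep(names(sizes), times = sizes)

  baseline <- stats::rnorm(n_p, config$baseline_mean, config$baseline_sd)
  # scaled inverse-chi-square: sigma2 = df * scale / chisq_df
  sigma2 <- config$variance_prior_df * config$variance_prior_scale /
    stats::rchisq(n_p, df = config$variance_prior_df)

  latent <- matrix(baseline, nrow = n_p, ncol = n_s) +
    matrix(stats::rnorm(n_p * n_s), n_p, n_s) * sqrt(sigma2)
  dimnames(latent) <- list(proteins, samples)

  eff <- config$effect_table
  if (!is.null(eff) && nrow(eff) > 0) {
    for (i in seq_len(nrow(eff))) {
      cols <- groups == eff$group[i]
      latent[eff$protein[i], cols] <- latent[eff$protein[i], cols] +
        eff$log2fc[i]
    }
  }

  annotation <- simulate_clinical(samples, groups)

  mask <- matrix(FALSE, n_p, n_s, dimnames = dimnames(latent))
  observed <- latent
  if (!is.null(config$missingness)) {
    miss_seed <- config$seed + 1000003L
    masked <- apply_missingness(
      abundance_matrix(2^latent, scale = "raw"),
      config$missingness, seed = miss_seed)
    mask <- is.na(masked$values)
    observed[mask] <- NA
  }

  if (!is.null(config$survival)) {
    annotation <- simulate_survival(annotation, latent,
                                    config$survival,
                                    seed = config$seed + 2000003L)
  }

  truth <- list(
    true_daps = if (is.null(eff)) eff_empty() else eff,
    true_prognostic = if (is.null(config$survival)) numeric(0) else {
      b <- config$survival$betas
      b[names(b) %in% proteins]
    },
    missing_mask = mask,
    sigma2 = stats::setNames(sigma2, proteins)
  )

  list(abundance = abundance_matrix(2^observed, scale = "raw"),
       annotation = annotation,
       truth = truth)
}

eff_empty <- function() {
  data.frame(protein = character(0), group = character(0),
             log2fc = numeric(0), stringsAsFactors = FALSE)
}

# Clinical covariates: FIGO-like stage skewed late for invasive carcinomas,
# early for borderline/benign; age ~ N(62, 11); CA-125 log-normal, elevated
# in serous carcinoma; residual tumor size ordinal 0-3.
simulate_clinical <- function(samples, groups) {
  n <- length(samples)
  invasive <- groups %in% c("HGSC", "LGSC", "EC", "MC", "CCC")
  stage_probs <- ifelse(invasive, 1, 0)
  stage <- integer(n)
  for (i in seq_len(n)) {
    p <- if (invasive[i]) c(0.25, 0.15, 0.45, 0.15) else c(0.9, 0.08, 0.02, 0)
    stage[i] <- sample.int(4, 1, prob = p)
  }
  age <- round(stats::rnorm(n, 62, 11))
  age <- pmax(pmin(age, 95), 20)
  ca125 <- exp(stats::rnorm(n, ifelse(groups %in% c("HGSC", "LGSC"),
                                      5.5, 3.8), 1.1))
  residual <- ifelse(invasive,
                     sample.int(4, n, replace = TRUE,
                                prob = c(0.5, 0.25, 0.15, 0.1)) - 1L,
                     0L)
  data.frame(sample_id = samples, group = groups, stage = stage,
             age = age, ca125 = ca125, residual_tumor = residual,
             stringsAsFactors = FALSE)
}

#' Apply intensity-dependent missingness to a complete matrix
#'
#' Each cell is independently set missing with probability
#' `max(floor_rate, plogis(intercept + slope * log2(value)))`; the logistic
#' acts on the latent log2 intensity regardless of the storage scale.
#'
#' @param x Complete (no `NA`) `AbundanceMatrix`.
#' @param params [mnar_params()].
#' @param seed Integer seed.
#' @return The matrix with cells masked to `NA`.
#' @export
apply_missingness <- function(x, params, seed = 1L) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  if (anyNA(x$values)) stop("matrix must be complete")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lat <- if (x$scale == "raw") log2(x$values) else x$values
  p <- pmax(stats::plogis(params$intercept + params$slope * lat),
            params$floor_rate)
  drop <- matrix(stats::runif(length(p)) < p, nrow = nrow(lat))
  v <- x$values
  v[drop] <- NA
  abundance_matrix(v, symbols = x$symbols, descriptions = x$descriptions,
                   scale = x$scale)
}

#' Simulate proportional-hazards survival endpoints
#'
#' Event times follow a Weibull baseline accelerated by the linear
#' predictor: `T = scale * (-log(U) / exp(x'beta))^(1/shape)`, the standard
#' inverse-transform sampler for a Weibull proportional-hazards model.
#' Censoring times are exponential; the observed time is the minimum.
#' Disease-specific deaths are overall deaths thinned by a Bernoulli cause
#' indicator with probability `dss_weight`, so both endpoints share one
#' risk structure.
#'
#' @param annotation Sample annotation data frame.
#' @param latent Proteins-by-samples latent log2 matrix (for protein
#'   covariates in `betas`); may be `NULL` when no protein has an effect.
#' @param params [survival_sim_params()].
#' @param seed Integer seed.
#' @return The annotation with `os_time`, `os_event`, `dss_time`,
#'   `dss_event` columns added (times in days, events 0/1).
#' @export
simulate_survival <- function(annotation, latent = NULL, params, seed = 1L) {
  stopifnot(params$baseline_shape > 0, params$baseline_scale > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(annotation)
  lp <- numeric(n)
  for (nm in names(params$betas)) {
    if (nm %in% names(annotation)) {
      xv <- as.numeric(annotation[[nm]])
      lp <- lp + params$betas[[nm]] * (xv - mean(xv, na.rm = TRUE))
    } else if (!is.null(latent) && nm %in% rownames(latent)) {
      xv <- latent[nm, annotation$sample_id]
      lp <- lp + params$betas[[nm]] * (xv - mean(xv))
    } else {
      stop("covariate not found for survival simulation: ", nm)
    }
  }
  u <- stats::runif(n)
  t_event <- params$baseline_scale *
    (-log(u) / exp(lp))^(1 / params$baseline_shape)
  t_cens <- if (params$censoring_rate > 0) {
    stats::rexp(n, rate = params$censoring_rate)
  } else rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  cause <- stats::rbinom(n, 1, params$dss_weight)
  annotation$os_time <- round(time, 2)
  annotation$os_event <- event
  annotation$dss_time <- annotation$os_time
  annotation$dss_event <- as.integer(event == 1L & cause == 1L)
  annotation
}

# Save/restore the global RNG state so generators are pure functions of
# their seed argument and never perturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
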