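# Small in-code fixtures shared across test files.

# complete log2-scale matrix with two groups and optional planted shift
make_two_group_matrix <- function(n_proteins = 5, n_a = 6, n_b = 6,
                                  shift = NULL, sd = 0.5, seed = 1) {
  set.seed(seed)
  n <- n_a + n_b
  vals <- matrix(rnorm(n_proteins * n, mean = 20, sd = sd), n_proteins, n)
  rownames(vals) <- sprintf("P%02d", seq_len(n_proteins))
  colnames(vals) <- sprintf("S%02d", seq_len(n))
  if (!is.null(shift)) {
    for (p in names(shift)) {
      vals[p, seq_len(n_a)] <- vals[p, seq_len(n_a)] + shift[[p]]
    }
  }
  abundance_matrix(vals, scale = "log2")
}

two_group_annotation <- function(n_a = 6, n_b = 6,
                                 groups = c("A", "B")) {
  data.frame(sample_id = sprintf("S%02d", seq_len(n_a + n_b)),
             group = rep(groups, c(n_a, n_b)),
             stringsAsFactors = FALSE)
}

two_group_contrast <- function(n_a = 6, n_b = 6) {
  contrast("A_vs_B", sprintf("S%02d", seq_len(n_a)),
           sprintf("S%02d", n_a + seq_len(n_b)))
}

# independent brute-force moderated t (shrinkage formulas written from
# scratch, scalar loops only) used as the oracle for fit_moderated_t
brute_force_moderated_t <- function(values, idx_a, idx_b, d0, s0_sq) {
  out <- data.frame(log2fc = numeric(0), t_mod = numeric(0),
                    df_total = numeric(0), p = numeric(0))
  for (i in seq_len(nrow(values))) {
    a <- values[i, idx_a]; a <- a[!is.na(a)]
    b <- values[i, idx_b]; b <- b[!is.na(b)]
    na <- length(a); nb <- length(b)
    lfc <- mean(a) - mean(b)
    df <- na + nb - 2
    s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
    s2_post <- if (is.infinite(d0)) s0_sq else
      (d0 * s0_sq + df * s2) / (d0 + df)
    tm <- lfc / sqrt(s2_post * (1 / na + 1 / nb))
    dft <- df + d0
    out[i, ] <- c(lfc, tm, dft, 2 * pt(-abs(tm), df = dft))
  }
  out
}

# hand step-up BH for the oracle comparison
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

# exact 1-covariate Cox partial log-likelihood (Efron ties) for grid oracles
partial_loglik_1d <- function(beta, times, events, x) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    d_idx <- which(times == t & events == 1)
    r_idx <- which(times >= t)
    d <- length(d_idx)
    eta_d <- exp(beta * x[d_idx])
    eta_r <- exp(beta * x[r_idx])
    ll <- ll + sum(beta * x[d_idx])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum(eta_r) - (l / d) * sum(eta_d))
    }
  }
  ll
}

partial_loglik_2d <- function(beta, times, events, X) {
  eta_all <- as.vector(X %*% beta)
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    d_idx <- which(times == t & events == 1)
    r_idx <- which(times >= t)
    d <- length(d_idx)
    ll <- ll + sum(eta_all[d_idx])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum(exp(eta_all[r_idx])) -
                       (l / d) * sum(exp(eta_all[d_idx])))
    }
  }
  ll
}

# small survival fixture without ties
cox_fixture_8 <- function() {
  list(times = c(2, 4, 5, 7, 9, 12, 15, 20),
       events = c(1, 1, 0, 1, 1, 0, 1, 1),
       x = c(1, 1, 0, 1, 0, 1, 0, 0))
}

skip_if_no_limma <- function() {
  testthat::skip_if_not_installed("limma")
}
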