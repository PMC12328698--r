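#' Build a ranked gene list from a differential-abundance result
#'
#' Symbols ordered by one-vs-rest log2 fold change, from highest to lowest.
#' Ties are broken by smaller p-value, then lexicographically by symbol;
#' duplicate symbols (multiple protein groups mapping to one gene) collapse
#' to the entry with the largest absolute log2 fold change.
#'
#' @param daresult A `DAResult`.
#' @return Data frame `symbol`, `score` in descending score order (class
#'   `RankedList`).
#' @export
rank_by_logfc <- function(daresult) {
  if (nrow(daresult) == 0) stop("empty differential-abundance result")
  df <- data.frame(symbol = daresult$symbol, score = daresult$log2fc,
                   p = daresult$p, stringsAsFactors = FALSE)
  # dedup: keep largest |score| per symbol (deterministic tie-break by p)
  df <- df[order(-abs(df$score), df$p, df$symbol), ]
  df <- df[!duplicated(df$symbol), ]
  df <- df[order(-df$score, df$p, df$symbol), ]
  out <- df[, c("symbol", "score")]
  rownames(out) <- NULL
  class(out) <- c("RankedList", "data.frame")
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: positions in the set increment the running sum by
#' `|score|^weight / sum_hits |score|^weight`, positions outside decrement
#' it by `1/(N - N_hits)`. The enrichment score is the running-sum value of
#' maximal absolute deviation from zero (signed); ties between equal
#' positive and negative deviations resolve to the positive one.
#'
#' @param ranked A `RankedList` (or data frame `symbol`, `score`).
#' @param members Character vector of set member symbols.
#' @param weight Score-weight exponent (1 = classic weighted statistic,
#'   0 = unweighted KS).
#' @return List `es`, `running_sum` (length N), `peak_index`,
#'   `leading_edge` (member symbols up to/from the peak).
#' @export
enrichment_score <- function(ranked, members, weight = 1) {
  sym <- ranked$symbol
  hit <- sym %in% members
  if (!any(hit)) stop("no set member present in the ranked list")
  n <- length(sym)
  n_hit <- sum(hit)
  if (n_hit == n) {
    # no misses: the running sum climbs to exactly 1
    rs <- cumsum(abs(ranked$score)^weight) / sum(abs(ranked$score)^weight)
    return(list(es = 1, running_sum = rs, peak_index = n,
                leading_edge = sym))
  }
  w <- abs(ranked$score)^weight
  incr <- numeric(n)
  incr[hit] <- w[hit] / sum(w[hit])
  incr[!hit] <- -1 / (n - n_hit)
  rs <- cumsum(incr)
  i_max <- which.max(rs); i_min <- which.min(rs)
  es <- if (rs[i_max] >= -rs[i_min]) rs[i_max] else rs[i_min]
  peak <- if (rs[i_max] >= -rs[i_min]) i_max else i_min
  le <- if (es >= 0) sym[seq_len(peak)][hit[seq_len(peak)]]
        else sym[peak:n][hit[peak:n]]
  list(es = es, running_sum = rs, peak_index = peak, leading_edge = le)
}

# ES from sorted hit positions only — O(k) per evaluation, used for the
# permutation null. Extremes of the running sum occur at hit positions
# (just after the increment) or immediately before a hit (after a run of
# decrements), so only 2k candidate values need checking.
es_from_positions <- function(pos, w_all, n, weight_sum = NULL) {
  k <- length(pos)
  if (k >= n) return(1)
  pos <- sort(pos)
  wh <- w_all[pos]
  if (is.null(weight_sum)) weight_sum <- sum(wh)
  if (weight_sum <= 0) return(0)
  dec <- 1 / (n - k)
  cw <- cumsum(wh) / weight_sum
  at_hit <- cw - (pos - seq_len(k)) * dec          # value at each hit
  before_hit <- c(0, cw[-k]) - (pos - seq_len(k)) * dec  # just before
  hi <- max(at_hit)
  lo <- min(before_hit)
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted KS enrichment score for every set, builds a
#' gene-permutation null (random member labels of matching size drawn from
#' the ranked universe), normalizes by the mean absolute null ES of
#' matching sign (NES), derives one-sided permutation p-values with the
#' +1 correction, and BH-adjusts across sets.
#'
#' @param ranked A `RankedList`.
#' @param collection Named list of member-symbol vectors (e.g. from
#'   [read_gmt()]).
#' @param n_perm Number of permutations per set.
#' @param seed Integer seed.
#' @param min_size,max_size Set-size bounds after intersection with the
#'   ranked universe.
#' @param weight Score-weight exponent.
#' @param fdr_cut Cutoff used only to flag significance in the output.
#' @return Data frame (class `GseaResult`), one row per retained set:
#'   `set`, `size`, `es`, `nes`, `p_perm`, `fdr`, `significant`,
#'   `leading_edge` (comma-separated), sorted by decreasing NES.
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000, seed = 1L,
                           min_size = 10, max_size = 500, weight = 1,
                           fdr_cut = 0.05) {
  sym <- ranked$symbol
  n <- length(sym)
  sizes <- vapply(collection, function(m) sum(sym %in% m), 0L)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) stop("no gene set survives the size filter")
  collection <- collection[keep]
  sizes <- sizes[keep]

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  w_all <- abs(ranked$score)^weight

  # shared null permutations per distinct set size
  null_by_size <- new.env(parent = emptyenv())
  null_es <- function(k) {
    key <- as.character(k)
    if (!is.null(null_by_size[[key]])) return(null_by_size[[key]])
    es <- vapply(seq_len(n_perm), function(i) {
      es_from_positions(sample.int(n, k), w_all, n)
    }, 0)
    null_by_size[[key]] <- es
    es
  }

  rows <- lapply(names(collection), function(nm) {
    obs <- enrichment_score(ranked, collection[[nm]], weight = weight)
    nulls <- null_es(sizes[[nm]])
    same <- if (obs$es >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    nes <- if (length(same) > 0 && mean(abs(same)) > 0) {
      obs$es / mean(abs(same))
    } else NA_real_
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    data.frame(set = nm, size = sizes[[nm]], es = obs$es, nes = nes,
               p_perm = p,
               leading_edge = paste(obs$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- benjamini_hochberg(res$p_perm)
  res$significant <- res$fdr < fdr_cut
  res <- res[order(-res$nes), ]
  rownames(res) <- NULL
  res <- res[, c("set", "size", "es", "nes", "p_perm", "fdr",
                 "significant", "leading_edge")]
  class(res) <- c("GseaResult", "data.frame")
  res
}

#' Top enriched sets by normalized enrichment score
#'
#' @param gsea A `GseaResult`.
#' @param n Number of sets per direction.
#' @param significant_only Restrict to sets passing the FDR cutoff.
#' @return Data frame of up to `n` top positive-NES and `n` top
#'   negative-NES sets with a `direction` column.
#' @export
top_enriched <- function(gsea, n = 5, significant_only = TRUE) {
  df <- if (significant_only) gsea[gsea$significant, ] else gsea
  up <- df[!is.na(df$nes) & df$nes > 0, ]
  up <- utils::head(up[order(-up$nes), ], n)
  dn <- df[!is.na(df$nes) & df$nes < 0, ]
  dn <- utils::head(dn[order(dn$nes), ], n)
  if (nrow(up)) up$direction <- "up"
  if (nrow(dn)) dn$direction <- "down"
  out <- rbind(up, dn)
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation analysis
#'
#' For every term the upper-tail hypergeometric probability of observing at
#' least `k` hit-list members among the term's `K` universe members, given
#' `n` hits in a universe of `N`; BH adjustment across terms. Terms
#' disjoint from the universe are excluded.
#'
#' @param dap_symbols Hit list (e.g. DAP gene symbols); must be a subset of
#'   the universe.
#' @param universe_symbols Background universe (all quantified symbols).
#' @param collection Named list of term-member vectors.
#' @param fdr_cut Cutoff used to flag significance.
#' @return Data frame (class `OraResult`): `term`, `k`, `K`, `n`, `N`,
#'   `p`, `fdr`, `significant`, `members`, ordered by p.
#' @export
ora_hypergeometric <- function(dap_symbols, universe_symbols, collection,
                               fdr_cut = 0.05) {
  universe <- unique(universe_symbols)
  if (length(universe) == 0) stop("empty universe")
  daps <- unique(dap_symbols)
  if (!all(daps %in% universe)) stop("hit list must be within the universe")
  n <- length(daps); N <- length(universe)
  rows <- lapply(names(collection), function(nm) {
    in_term <- intersect(collection[[nm]], universe)
    K <- length(in_term)
    if (K == 0) return(NULL)
    hits <- intersect(daps, in_term)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, K = K, n = n, N = N, p = p,
               members = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no term overlaps the universe")
  res$fdr <- benjamini_hochberg(res$p)
  res$significant <- res$fdr < fdr_cut
  res <- res[order(res$p, res$term), ]
  rownames(res) <- NULL
  res <- res[, c("term", "k", "K", "n", "N", "p", "fdr", "significant",
                 "members")]
  class(res) <- c("OraResult", "data.frame")
  res
}

#' Member occurrence counts across significant ORA terms
#'
#' How often each hit symbol drives the significant terms — the basis of a
#' gene-prevalence dot plot.
#'
#' @param ora An `OraResult`.
#' @return Data frame `symbol`, `n_terms`, decreasing.
#' @export
ora_member_counts <- function(ora) {
  sig <- ora[ora$significant & ora$k > 0, ]
  if (nrow(sig) == 0) {
    return(data.frame(symbol = character(0), n_terms = integer(0)))
  }
  members <- unlist(strsplit(sig$members, ",", fixed = TRUE))
  tab <- sort(table(members), decreasing = TRUE)
  data.frame(symbol = names(tab), n_terms = as.integer(tab),
             stringsAsFactors = FALSE)
}
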