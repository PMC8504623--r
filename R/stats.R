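# Combination statistics: per-spacer best-hit P-values, per-pair combined
# scores, and empirical FDR against a null database.

#' Best-hit P-value for one spacer against one target set
#'
#' Given the per-hit P-values of all fragments of one spacer against the
#' fragments of one phage, the best-hit P-value is the first-order
#' statistic of the minimum under independence:
#' `p_bh = 1 - (1 - p_min)^n_T`, where `n_T` is the number of fragments in
#' the target set. Computed in log space so tiny `p_min` survive.
#'
#' @param p_hits numeric vector of per-hit P-values (non-empty).
#' @param n_T number of fragments in the target set (`>= 1`).
#' @return `p_bh` in `[0, 1]`.
#' @examples
#' best_hit_pvalue(0.01, 100)   # 1 - 0.99^100
#' @export
best_hit_pvalue <- function(p_hits, n_T) {
  if (!length(p_hits)) stop("no hits")
  if (!is.numeric(n_T) || n_T < 1) stop("n_T must be >= 1")
  p_min <- min(p_hits)
  if (p_min <= 0) return(0)
  min(1, max(0, -expm1(n_T * log1p(-p_min))))
}

#' Combine best-hit P-values with a truncated-product score
#'
#' Multiplies the P-values at or below the truncation threshold `tau`,
#' each scaled by `tau`, keeping one factor of `tau`:
#' `s_comb = tau * prod(p/tau)` over `p <= tau`. A single `p = tau` gives
#' `s_comb = tau`; each additional significant spacer multiplies by
#' `p/tau <= 1`, so independent evidence from multiple spacers compounds.
#' If no P-value passes the threshold the minimum is returned, so a single
#' weak hit still yields a (weak) score. Smaller is stronger.
#'
#' @param p_values numeric vector of best-hit P-values (non-empty).
#' @param tau truncation threshold in `(0, 1]`, default 0.1.
#' @return combined score `s_comb` in `(0, 1]` (0 possible if a P-value
#'   is exactly 0).
#' @examples
#' combine_truncated_product(c(0.01, 0.02))  # 0.002
#' @export
combine_truncated_product <- function(p_values, tau = 0.1) {
  if (!length(p_values)) stop("no P-values to combine")
  stopifnot(all(p_values >= 0 & p_values <= 1), tau > 0, tau <= 1)
  sel <- p_values[p_values <= tau]
  if (!length(sel)) return(min(p_values))
  exp(sum(log(sel)) - (length(sel) - 1L) * log(tau))
}

#' Empirical P-value of a combined score against null scores
#'
#' Fraction of null host-phage pairs whose combined score is at most `s`,
#' with add-one smoothing: `(1 + #{null <= s}) / (1 + n_null_pairs)`.
#' Null pairs that produced no hit contribute no score but count in the
#' denominator.
#'
#' @param s combined score(s).
#' @param null_scores numeric vector of null-pair combined scores.
#' @param n_null_pairs total number of evaluated null pairs
#'   (`>= length(null_scores)`).
#' @return empirical P-value(s) in `(0, 1]`.
#' @export
empirical_pvalue <- function(s, null_scores, n_null_pairs) {
  if (n_null_pairs < 1) stop("null database produced no comparisons")
  ns <- sort(null_scores)
  (1 + findInterval(s, ns)) / (1 + n_null_pairs)
}

#' Estimate the false discovery rate and filter matches
#'
#' Sorts real matches by combined score (ascending, best first). At the
#' cutoff given by the k-th match, the estimated FDR is
#' `min(1, size_ratio * #{null <= cutoff} / k)`; estimates are then
#' monotonized by a cumulative minimum from the weakest cutoff down
#' (q-value convention), and matches with monotonized FDR below
#' `threshold` are flagged as retained.
#'
#' @param matches data.frame with (at least) an `s_comb` column.
#' @param null_scores combined scores of null-database pairs.
#' @param size_ratio number of real target sets divided by number of null
#'   target sets (scales null counts when the null DB size differs).
#' @param threshold retention threshold, default `0.05` (matches with
#'   `fdr < threshold` are retained).
#' @return `matches` sorted by `s_comb` with columns `fdr` and `retained`
#'   added.
#' @export
estimate_fdr <- function(matches, null_scores, size_ratio = 1,
                         threshold = 0.05) {
  if (!nrow(matches)) {
    matches$fdr <- numeric(0); matches$retained <- logical(0)
    return(matches)
  }
  matches <- matches[order(matches$s_comb), , drop = FALSE]
  k <- seq_len(nrow(matches))
  n_null_le <- findInterval(matches$s_comb, sort(null_scores))
  raw <- pmin(1, size_ratio * n_null_le / k)
  matches$fdr <- rev(cummin(rev(raw)))
  matches$retained <- matches$fdr < threshold
  rownames(matches) <- NULL
  matches
}

# Per (Q, T) pair: group hits by spacer, take best-hit P-values, combine.
# Returns list(s_comb, best_hits = data.frame one row per spacer).
pair_statistics <- function(hits, n_T, tau = 0.1) {
  stopifnot(nrow(hits) > 0L, n_T >= 1L)
  by_spacer <- split(hits, hits$spacer_accession)
  bh <- do.call(rbind, lapply(by_spacer, function(h) {
    i <- which.min(h$p_hit)
    out <- h[i, , drop = FALSE]
    out$p_bh <- best_hit_pvalue(h$p_hit, n_T)
    out
  }))
  rownames(bh) <- NULL
  bh <- bh[order(bh$p_bh, bh$spacer_accession), , drop = FALSE]
  list(s_comb = combine_truncated_product(bh$p_bh, tau), best_hits = bh)
}
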