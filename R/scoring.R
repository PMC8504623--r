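# Scoring scheme: substitution matrix, affine gap costs, spaced k-mer
# pattern, and Gumbel parameters for per-hit P-values.

# Gumbel tail parameters calibrated by calibrate_gumbel(n = 1e5,
# seed = 20210401) under the default scheme (PAM40, gaps 16/2), query
# lengths 9-14 aa vs target lengths 50-300 aa, Robinson-Robinson residue
# frequencies. Frozen here so the package is deterministic at run time.
GUMBEL_DEFAULTS <- c(lambda = 0.3652102, K = 0.3359693)

# Robinson & Robinson (1991) amino-acid background frequencies.
AA_BACKGROUND <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

default_score_matrix <- function() {
  e <- new.env()
  utils::data("PAM40", package = "Biostrings", envir = e)
  m <- e$PAM40
  storage.mode(m) <- "integer"
  m
}

#' Construct a scoring scheme
#'
#' Bundles the substitution matrix, affine gap costs, the spaced k-mer
#' prefilter pattern and the Gumbel parameters of the per-hit P-value
#' model. Defaults follow the short-highly-similar-peptide regime of
#' spacer-protospacer matching: a short-evolutionary-distance matrix
#' (PAM40), gap open 16 / extend 2 (a length-g gap costs
#' `16 + (g-1)*2`), and the pattern `"10111011"` with six informative
#' positions.
#'
#' @param matrix symmetric integer substitution matrix over an amino-acid
#'   alphabet including `X` and `*`; default PAM40. See
#'   [read_score_matrix()] to load an NCBI-format matrix file.
#' @param gap_open,gap_extend positive integers, `gap_open >= gap_extend`.
#' @param kmer_pattern binary string; `'1'` marks compared positions. Must
#'   start and end with `'1'` and contain exactly six `'1'`s.
#' @param lambda,K positive Gumbel parameters; defaults are calibrated by
#'   [calibrate_gumbel()] for the default matrix and gap costs.
#' @return object of class `scoring_scheme`.
#' @examples
#' scheme <- scoring_scheme()
#' scheme$gap_open
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 16L, gap_extend = 2L,
                           kmer_pattern = "10111011",
                           lambda = GUMBEL_DEFAULTS[["lambda"]],
                           K = GUMBEL_DEFAULTS[["K"]]) {
  if (is.null(matrix)) matrix <- default_score_matrix()
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            identical(rownames(matrix), colnames(matrix)),
            isSymmetric(unname(matrix)),
            all(c("X", "*") %in% rownames(matrix)))
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (!(gap_open >= gap_extend && gap_extend >= 1L))
    stop("require gap_open >= gap_extend >= 1")
  if (!grepl("^1[01]*1$", kmer_pattern) ||
      nchar(gsub("0", "", kmer_pattern)) != 6L)
    stop("kmer_pattern must start and end with '1' and have six '1' positions")
  if (!is.finite(lambda) || lambda <= 0 || !is.finite(K) || K <= 0)
    stop("configuration error: Gumbel lambda and K must be positive")
  storage.mode(matrix) <- "integer"
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, kmer_pattern = kmer_pattern,
                 lambda = lambda, K = K,
                 pattern_offsets = which(str_chars(kmer_pattern) == "1") - 1L),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("Scoring scheme:", nrow(x$matrix), "x", ncol(x$matrix),
      "substitution matrix;",
      "gap open", x$gap_open, "/ extend", x$gap_extend, "\n")
  cat("  prefilter pattern", x$kmer_pattern,
      sprintf("(%d informative positions); Gumbel lambda = %.4g, K = %.4g\n",
              length(x$pattern_offsets), x$lambda, x$K))
  invisible(x)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format used by BLAST (`#` comments, a
#' header row of residues, one labelled row per residue).
#'
#' @param path file path.
#' @return symmetric integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  m <- t(vapply(rows, function(r) as.integer(r[-1L]), integer(length(cols))))
  dimnames(m) <- list(vapply(rows, `[`, "", 1L), cols)
  if (!isSymmetric(unname(m))) stop("substitution matrix is not symmetric")
  m
}

# encode an aa string as 0-based indices into the scheme matrix;
# unknown letters map to the X column
encode_aa <- function(aa, scheme) {
  alpha <- rownames(scheme$matrix)
  i <- match(str_chars(aa), alpha)
  i[is.na(i)] <- match("X", alpha)
  i - 1L
}

#' Optimal local protein alignment of two fragments
#'
#' Exact Smith-Waterman under affine gaps: a length-g gap costs
#' `gap_open + (g-1) * gap_extend`. Returns the optimal score and the
#' fragment-local alignment coordinates (0-based half-open). Among
#' equal-scoring alignments the one ending earliest in the query, then in
#' the target, is reported, with gaps placed deterministically.
#'
#' @param q_aa,t_aa amino-acid strings.
#' @param scheme a [scoring_scheme()].
#' @return list with `score`, `q_start`, `q_end`, `t_start`, `t_end`.
#' @examples
#' align_protein("MKVLA", "GGMKVLAGG", scoring_scheme())
#' @export
align_protein <- function(q_aa, t_aa, scheme = scoring_scheme()) {
  .sw_align_cpp(encode_aa(q_aa, scheme), encode_aa(t_aa, scheme),
                scheme$matrix, scheme$gap_open, scheme$gap_extend)
}

#' Per-hit P-value from the Gumbel tail of local alignment scores
#'
#' `p = 1 - exp(-K * m * n * exp(-lambda * score))`, the Karlin-Altschul
#' extreme-value tail, clamped to `[0, 1]`. Strictly decreasing in the
#' score and increasing in `m * n`.
#'
#' @param score raw alignment score(s), non-negative.
#' @param m,n amino-acid lengths of the two aligned fragments.
#' @param scheme a [scoring_scheme()] supplying `lambda` and `K`.
#' @return numeric vector of P-values in `[0, 1]`.
#' @export
hit_pvalue <- function(score, m, n, scheme = scoring_scheme()) {
  p <- -expm1(-scheme$K * m * n * exp(-scheme$lambda * score))
  pmin(1, pmax(0, p))
}

#' Calibrate Gumbel parameters by simulation
#'
#' Aligns `n` random fragment pairs (query lengths drawn uniformly from
#' `q_len`, targets from `t_len`, residues from the Robinson-Robinson
#' background) and fits the tail of the extreme-value model
#' `P(S >= s) = 1 - exp(-K m n e^(-lambda s))` by maximum likelihood,
#' with the pair-specific `m`, `n` entering through the location. Scores
#' above the `tail_q` quantile contribute an interval likelihood
#' (accounting for score discreteness); scores below contribute a
#' censoring term, so the tail drives the fit. The returned `K` absorbs
#' the half-integer continuity shift, so [hit_pvalue()] evaluated at an
#' integer score estimates `P(S >= score)`.
#'
#' @param scheme a [scoring_scheme()] (its `lambda`/`K` are ignored).
#' @param n number of simulated pairs.
#' @param q_len,t_len integer ranges of fragment lengths (aa).
#' @param tail_q censoring quantile (default 0.9).
#' @param seed RNG seed.
#' @return named vector `c(lambda=, K=)`.
#' @export
calibrate_gumbel <- function(scheme = scoring_scheme(), n = 1e5,
                             q_len = 9:14, t_len = 50:300, tail_q = 0.9,
                             seed = 20210401) {
  set.seed(seed)
  sim <- simulate_null_scores(scheme, n, q_len, t_len)
  fit_gumbel_ml(sim$score, sim$m, sim$n, tail_q)
}

# draw random fragment pairs and score them; returns data.frame(score, m, n)
simulate_null_scores <- function(scheme, n, q_len, t_len) {
  alpha <- rownames(scheme$matrix)
  bg_idx <- match(names(AA_BACKGROUND), alpha) - 1L
  m <- sample(q_len, n, replace = TRUE)
  nn <- sample(t_len, n, replace = TRUE)
  draw <- function(len) sample(bg_idx, len, replace = TRUE,
                               prob = AA_BACKGROUND)
  qs <- lapply(m, draw)
  ts <- lapply(nn, draw)
  s <- .sw_scores_cpp(qs, ts, scheme$matrix, scheme$gap_open,
                      scheme$gap_extend)
  data.frame(score = s, m = m, n = nn)
}

# Censored interval ML fit of the EVD with location ln(K m n)/lambda per
# observation. CDF F(s) = exp(-K m n e^(-lambda s)); scores above the
# censoring threshold contribute F(s+1/2) - F(s-1/2), the rest F(c+1/2).
fit_gumbel_ml <- function(score, m, n, tail_q = 0.9) {
  lmn <- log(as.numeric(m) * as.numeric(n))
  cthr <- as.numeric(stats::quantile(score, tail_q))
  up <- score > cthr
  Fv <- function(x, l, lambda, logK) exp(-exp(logK + l - lambda * x))
  nll <- function(par) {
    lambda <- exp(par[1L]); logK <- par[2L]
    dens <- pmax(Fv(score[up] + 0.5, lmn[up], lambda, logK) -
                   Fv(score[up] - 0.5, lmn[up], lambda, logK), 1e-300)
    cens <- pmax(Fv(cthr + 0.5, lmn[!up], lambda, logK), 1e-300)
    -(sum(log(dens)) + sum(log(cens)))
  }
  fit <- stats::optim(c(log(0.3), log(0.2)), nll, method = "BFGS")
  lambda <- exp(fit$par[1L])
  # fold the continuity shift into K: formula at integer s ~ P(S >= s)
  c(lambda = lambda, K = exp(fit$par[2L]) * exp(lambda / 2))
}
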