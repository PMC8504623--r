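# Stage 1: spaced k-mer prefilter + gapped local protein alignment of
# query fragments (translated spacers) against target fragments
# (translated phage regions), followed by ungapped nucleotide
# re-alignment of every protein hit.

# all spaced k-mers of an aa string under the scheme's pattern
spaced_kmers <- function(aa, scheme) {
  L <- nchar(aa)
  w <- nchar(scheme$kmer_pattern)
  if (L < w) return(character())
  starts <- seq_len(L - w + 1L)
  parts <- lapply(scheme$pattern_offsets, function(o)
    substring(aa, starts + o, starts + o))
  unique(do.call(paste0, parts))
}

#' Spaced k-mer prefilter of a query set against a target set
#'
#' A query-target fragment pair is a candidate iff the two fragments share
#' at least one identical spaced k-mer: every length-8 window is reduced
#' to the six residues at the `'1'` positions of the pattern. Any pair
#' with an exact 8-residue ungapped match is therefore always a candidate.
#'
#' @param Q,T fragment sets from [build_sets()] (lists with a `fragments`
#'   data.frame).
#' @param scheme a [scoring_scheme()].
#' @return data.frame with columns `q_idx`, `t_idx` (row indices into the
#'   respective `fragments` tables).
#' @export
prefilter <- function(Q, T, scheme = scoring_scheme()) {
  empty <- data.frame(q_idx = integer(), t_idx = integer())
  if (!Q$n_fragments || !T$n_fragments) return(empty)
  tk <- lapply(T$fragments$aa, spaced_kmers, scheme = scheme)
  qk <- lapply(Q$fragments$aa, spaced_kmers, scheme = scheme)
  tidx <- rep.int(seq_along(tk), lengths(tk))
  qidx <- rep.int(seq_along(qk), lengths(qk))
  tkm <- unlist(tk, use.names = FALSE)
  qkm <- unlist(qk, use.names = FALSE)
  if (!length(tkm) || !length(qkm)) return(empty)
  # expand all (q, t) pairs sharing a k-mer via the k-mer string as key
  key_t <- split(tidx, tkm)
  hitq <- which(qkm %in% names(key_t))
  if (!length(hitq)) return(empty)
  pairs <- do.call(rbind, lapply(hitq, function(i)
    cbind(q_idx = qidx[i], t_idx = key_t[[qkm[i]]])))
  pairs <- unique(as.data.frame(pairs))
  rownames(pairs) <- NULL
  pairs[order(pairs$q_idx, pairs$t_idx), , drop = FALSE]
}

# map a fragment-local aa coordinate to a nt position on the fragment's
# own strand (oriented coordinates, 0-based)
oriented_start <- function(frag) {
  ifelse(frag$strand == "+", frag$nt_start,
         frag$parent_length - frag$nt_end)
}

#' Ungapped nucleotide re-alignment of a protein hit
#'
#' Compares the full spacer against the phage region implied by the
#' protein alignment (anchored at the alignment start, extended to spacer
#' length, strand-aware, clipped at genome ends). Near-perfect hits --
#' at most 2 mismatches and at least 95% spacer coverage -- are
#' prioritized by flooring the protein-level P-value at `p_floor`.
#'
#' @param hit one-row data.frame as produced by [search_sets()] (protein
#'   alignment fields plus fragment metadata).
#' @param spacer_seq full spacer nucleotide sequence.
#' @param genome_seq full phage genome sequence.
#' @param p_floor P-value assigned to near-perfect hits (default 1e-10).
#' @return the hit enriched with `nt_identity`, `nt_mismatches`,
#'   `nt_coverage`, `near_perfect`, updated `p_hit`, protospacer
#'   coordinates `proto_start`/`proto_end` (0-based half-open, forward
#'   strand of the genome), `proto_strand` (genome strand carrying the
#'   spacer sequence as given), and spacer coordinates
#'   `spacer_aln_start`/`spacer_aln_end`.
#' @export
realign_nucleotide <- function(hit, spacer_seq, genome_seq, p_floor = 1e-10) {
  Ls <- nchar(spacer_seq); Lg <- nchar(genome_seq)
  sq <- hit$q_strand; st <- hit$t_strand
  s_or <- if (sq == "+") spacer_seq else revcomp(spacer_seq)
  g_or <- if (st == "+") genome_seq else revcomp(genome_seq)
  # oriented nt position of the alignment start on each side
  sq0 <- hit$q_orient_start + 3L * hit$q_aln_start
  st0 <- hit$t_orient_start + 3L * hit$t_aln_start
  g0 <- st0 - sq0                       # genome (oriented) offset of spacer pos 0
  a <- max(0L, -g0); b <- min(Ls, Lg - g0)
  if (b > a) {
    aln_s <- substring(s_or, a + 1L, b)
    aln_g <- substring(g_or, g0 + a + 1L, g0 + b)
    mm <- sum(utf8ToInt(aln_s) != utf8ToInt(aln_g))
    ident <- 1 - mm / (b - a)
    cov <- (b - a) / Ls
  } else {
    a <- b <- 0L; mm <- Ls; ident <- 0; cov <- 0
    aln_s <- ""; aln_g <- ""
  }
  hit$aln_spacer <- aln_s
  hit$aln_target <- aln_g
  near <- (mm <= 2L) && (cov >= 0.95)
  hit$nt_mismatches <- mm
  hit$nt_identity <- ident
  hit$nt_coverage <- cov
  hit$near_perfect <- near
  if (near) hit$p_hit <- min(hit$p_hit, p_floor)
  # protospacer coordinates on the forward strand of the genome
  if (st == "+") {
    hit$proto_start <- g0 + a; hit$proto_end <- g0 + b
  } else {
    hit$proto_start <- Lg - (g0 + b); hit$proto_end <- Lg - (g0 + a)
  }
  # genome strand on which the spacer sequence (as supplied) occurs
  hit$proto_strand <- if (sq == st) "+" else "-"
  # aligned region on the spacer as supplied (forward spacer coordinates)
  if (sq == "+") {
    hit$spacer_aln_start <- a; hit$spacer_aln_end <- b
  } else {
    hit$spacer_aln_start <- Ls - b; hit$spacer_aln_end <- Ls - a
  }
  hit
}

#' Search one query set against one target set
#'
#' Runs the spaced k-mer prefilter, aligns every candidate fragment pair
#' with [align_protein()] (keeping the single optimal alignment per pair),
#' assigns per-hit P-values, and re-aligns each hit at the nucleotide
#' level against the phage genome.
#'
#' @param Q query set (from [build_sets()]; must carry `spacers`).
#' @param T target set.
#' @param genome_seq nucleotide sequence of the target genome; `NULL`
#'   skips the nucleotide re-alignment stage (used when searching a null
#'   database, whose fragments have no meaningful genome context).
#' @param scheme a [scoring_scheme()].
#' @param p_floor near-perfect P-value floor, see [realign_nucleotide()].
#' @return data.frame of hits (possibly 0 rows): one row per candidate
#'   fragment pair with alignment score, coordinates, `p_hit` and the
#'   nucleotide re-alignment fields.
#' @export
search_sets <- function(Q, T, genome_seq, scheme = scoring_scheme(),
                        p_floor = 1e-10) {
  cand <- prefilter(Q, T, scheme)
  if (!nrow(cand)) return(empty_hits())
  qf <- Q$fragments; tf <- T$fragments
  spacer_seq <- setNames(Q$spacers$sequence, Q$spacers$accession)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    qi <- cand$q_idx[i]; ti <- cand$t_idx[i]
    al <- align_protein(qf$aa[qi], tf$aa[ti], scheme)
    m <- nchar(qf$aa[qi]); n <- nchar(tf$aa[ti])
    hit <- data.frame(
      spacer_accession = qf$parent_accession[qi],
      target_accession = tf$parent_accession[ti],
      q_idx = qi, t_idx = ti,
      aln_score = al$score,
      q_aln_start = al$q_start, q_aln_end = al$q_end,
      t_aln_start = al$t_start, t_aln_end = al$t_end,
      q_strand = qf$strand[qi], t_strand = tf$strand[ti],
      q_frame = qf$frame[qi], t_frame = tf$frame[ti],
      q_orient_start = oriented_start(qf[qi, ]),
      t_orient_start = oriented_start(tf[ti, ]),
      p_hit = hit_pvalue(al$score, m, n, scheme),
      stringsAsFactors = FALSE)
    if (is.null(genome_seq)) {
      hit$nt_mismatches <- NA_integer_; hit$nt_identity <- NA_real_
      hit$nt_coverage <- NA_real_; hit$near_perfect <- FALSE
      hit$proto_start <- NA_integer_; hit$proto_end <- NA_integer_
      hit$proto_strand <- NA_character_
      hit$spacer_aln_start <- NA_integer_
      hit$spacer_aln_end <- NA_integer_
      hit$aln_spacer <- ""; hit$aln_target <- ""
      hit
    } else {
      realign_nucleotide(hit, spacer_seq[[hit$spacer_accession]],
                         genome_seq, p_floor)
    }
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

empty_hits <- function() {
  data.frame(spacer_accession = character(), target_accession = character(),
             q_idx = integer(), t_idx = integer(), aln_score = integer(),
             q_aln_start = integer(), q_aln_end = integer(),
             t_aln_start = integer(), t_aln_end = integer(),
             q_strand = character(), t_strand = character(),
             q_frame = integer(), t_frame = integer(),
             q_orient_start = integer(), t_orient_start = integer(),
             p_hit = numeric(), nt_mismatches = integer(),
             nt_identity = numeric(), nt_coverage = numeric(),
             near_perfect = logical(), proto_start = integer(),
             proto_end = integer(), proto_strand = character(),
             spacer_aln_start = integer(), spacer_aln_end = integer(),
             stringsAsFactors = FALSE)
}
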