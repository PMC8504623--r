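# Independent oracles and small fixture builders used across the suite.
# Each oracle is deliberately written as a different algorithm than the
# implementation it checks.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE),
                               collapse = "")

random_dna_str <- function(n) paste(sample(c("A","C","G","T"), n,
                                           replace = TRUE), collapse = "")

# Brute-force affine-gap Smith-Waterman by explicit gap-length
# enumeration: H[i,j] = max(0, diag, max_k H[i-k,j]-cost(k),
# max_k H[i,j-k]-cost(k)); cost(k) = open + (k-1)*extend.
oracle_sw_score <- function(q, t, mat, open, extend) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  m <- length(qc); n <- length(tc)
  H <- matrix(0L, m + 1, n + 1)
  best <- 0L
  for (i in seq_len(m)) for (j in seq_len(n)) {
    v <- H[i, j] + mat[qc[i], tc[j]]
    for (k in seq_len(i - 1))
      v <- max(v, H[i - k + 1, j + 1] - (open + (k - 1) * extend))
    for (k in seq_len(j - 1))
      v <- max(v, H[i + 1, j - k + 1] - (open + (k - 1) * extend))
    H[i + 1, j + 1] <- max(0L, v)
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# Exhaustive spaced 6-mer intersection for the prefilter: two fragments
# are candidates iff some window of each agrees at the '1' offsets.
oracle_spaced_candidate <- function(qaa, taa, pattern = "10111011") {
  off <- which(strsplit(pattern, "")[[1]] == "1")
  w <- nchar(pattern)
  qc <- strsplit(qaa, "")[[1]]; tc <- strsplit(taa, "")[[1]]
  kmers <- function(x) {
    if (length(x) < w) return(character())
    vapply(seq_len(length(x) - w + 1), function(i)
      paste(x[i + off - 1], collapse = ""), "")
  }
  length(intersect(kmers(qc), kmers(tc))) > 0
}

# Exhaustive weighted-LCA oracle: test every node of the tree.
oracle_weighted_lca <- function(votes, tax, thr = 0.5) {
  total <- sum(votes$weight)
  ancestors <- function(x) {
    p <- setNames(tax$parent, tax$taxid)
    out <- x
    while (p[[as.character(x)]] != x) { x <- p[[as.character(x)]]; out <- c(out, x) }
    out
  }
  depth <- vapply(tax$taxid, function(t) length(ancestors(t)) - 1L, 0L)
  subtree_w <- vapply(tax$taxid, function(node)
    sum(votes$weight[vapply(votes$taxid, function(v)
      node %in% ancestors(v), TRUE)]), 0)
  ok <- (subtree_w - thr * total > 1e-12) | (total - subtree_w < 1e-12)
  cand <- tax$taxid[ok]
  cand[order(-depth[ok], cand)][1]
}

# random parent-pointer tree with n nodes (taxid = shuffled ints)
random_tree <- function(n) {
  taxid <- sample(2:(10 * n), n)
  parent <- c(taxid[1], vapply(2:n, function(i)
    taxid[sample.int(i - 1, 1)], 0))
  data.frame(taxid = taxid, parent = parent,
             rank = rep("clade", n), name = paste0("n", seq_len(n)),
             stringsAsFactors = FALSE)
}

# independent translation via Biostrings (used for coordinate audits)
bios_translate <- function(nt, table = "11") {
  as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode(table),
    no.init.codon = TRUE))
}

# a small planted scenario: one host, one phage, configurable mutations
tiny_benchmark <- function(seed, k = 0, j = 0, n_spacers = 3) {
  set.seed(seed)
  make_benchmark(n_hosts = 1, n_phages = 1, decoy_hosts = 1,
                 decoy_phages = 1, n_spacers_per_pair = n_spacers,
                 k = k, j = j, seed = seed)
}
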