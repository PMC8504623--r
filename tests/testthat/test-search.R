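# Prefilter, protein alignment, P-values and nucleotide re-alignment.

frag_set <- function(aas, id = "set") {
  frags <- data.frame(parent_accession = paste0("f", seq_along(aas)),
                      parent_kind = "spacer", frame = 0L, strand = "+",
                      nt_start = 0L, nt_end = 3L * nchar(aas),
                      aa = aas, nt = strrep("NNN", nchar(aas)),
                      parent_length = 3L * nchar(aas),
                      stringsAsFactors = FALSE)
  list(set_id = id, fragments = frags, n_fragments = length(aas))
}

test_that("prefilter candidacy follows spaced k-mer sharing", {
  scheme <- scoring_scheme()
  q <- frag_set("MKVLAQRST")
  expect_equal(nrow(prefilter(q, frag_set("MKVLAQRST"), scheme)), 1L)
  # differences confined to the '0' positions keep the pair a candidate
  t_aa <- "MAVLAARST"  # pattern 10111011: window positions 2 and 6 are '0'
  expect_equal(nrow(prefilter(q, frag_set(t_aa), scheme)), 1L)
  expect_true(oracle_spaced_candidate("MKVLAQRST", t_aa))
  # an exact ungapped 8-residue match embedded anywhere is always found
  set.seed(31)
  for (i in 1:10) {
    core <- random_aa(8)
    qa <- paste0(random_aa(3), core)
    ta <- paste0(core, random_aa(5))
    expect_equal(nrow(prefilter(frag_set(qa), frag_set(ta), scheme)), 1L)
  }
})

test_that("prefilter equals the exhaustive spaced 6-mer oracle", {
  scheme <- scoring_scheme()
  set.seed(11)
  for (i in 1:100) {
    qa <- random_aa(9)
    ta <- random_aa(sample(9:30, 1))
    got <- nrow(prefilter(frag_set(qa), frag_set(ta), scheme)) > 0
    expect_identical(got, oracle_spaced_candidate(qa, ta), info = paste(qa, ta))
  }
})

test_that("alignment scores match the brute-force DP oracle exactly", {
  scheme <- scoring_scheme()
  set.seed(5)
  for (i in 1:60) {
    qa <- random_aa(sample(8:14, 1))
    ta <- random_aa(sample(15:35, 1))
    got <- align_protein(qa, ta, scheme)$score
    expect_identical(as.integer(got),
                     as.integer(oracle_sw_score(qa, ta, scheme$matrix,
                                                scheme$gap_open,
                                                scheme$gap_extend)))
  }
  # self-alignment: sum of diagonal entries over the full fragment
  qa <- "MKVLAQRSTW"
  al <- align_protein(qa, qa, scheme)
  diag_sum <- sum(diag(scheme$matrix)[match(strsplit(qa, "")[[1]],
                                            rownames(scheme$matrix))])
  expect_equal(al$score, diag_sum)
  expect_equal(c(al$q_start, al$q_end), c(0L, 10L))
})

test_that("alignment score is invariant under joint sequence reversal", {
  scheme <- scoring_scheme()
  set.seed(17)
  revstr <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  for (i in 1:25) {
    qa <- random_aa(10); ta <- random_aa(25)
    expect_identical(align_protein(qa, ta, scheme)$score,
                     align_protein(revstr(qa), revstr(ta), scheme)$score)
  }
})

test_that("hit_pvalue is a proper monotone tail", {
  scheme <- scoring_scheme()
  expect_equal(hit_pvalue(0, 10, 100, scheme), 1)
  p <- hit_pvalue(seq(0, 200, by = 5), 10, 100, scheme)
  expect_true(all(diff(p) <= 0))
  expect_true(all(diff(p[p < 1 & p > 0]) < 0))  # strict once unclamped
  expect_lt(hit_pvalue(1e4, 10, 100, scheme), 1e-300)
  # increasing in m*n
  expect_gt(hit_pvalue(40, 14, 300, scheme), hit_pvalue(40, 9, 50, scheme))
  expect_error(scoring_scheme(lambda = -1), "positive")
})

test_that("nucleotide re-alignment flags near-perfect protospacers", {
  set.seed(23)
  # exact planted protospacer: near-perfect, P-value floored
  b0 <- tiny_benchmark(101, k = 0, j = 0)
  res0 <- phage_host_predict(b0$spacers, b0$phages)
  planted <- res0$hits[res0$hits$spacer_accession %in%
                         b0$truth$spacers$spacer_accession, ]
  expect_true(all(planted$near_perfect))
  expect_true(all(planted$nt_mismatches == 0))
  expect_true(all(planted$p_hit <= 1e-10))  # floored at p_floor
  # protein-conserving triple substitution: >2 mismatches, not near-perfect
  b3 <- tiny_benchmark(102, k = 3, j = 0)
  res3 <- phage_host_predict(b3$spacers, b3$phages)
  planted3 <- res3$hits[res3$hits$spacer_accession %in%
                          b3$truth$spacers$spacer_accession, ]
  expect_true(all(planted3$nt_mismatches == 3))
  expect_false(any(planted3$near_perfect))
  # recovered coordinates agree with the planted truth
  tr <- b3$truth$spacers[match(planted3$spacer_accession,
                               b3$truth$spacers$spacer_accession), ]
  expect_equal(planted3$proto_start, tr$proto_start)
  expect_equal(planted3$proto_end, tr$proto_end)
  expect_equal(planted3$proto_strand, tr$proto_strand)
})

test_that("an exact planted protospacer is always recovered as a hit", {
  for (seed in c(301, 302, 303)) {
    set.seed(seed)
    ph <- make_phage(2000)
    pl <- plant_protospacers(ph, n_spacers = 1, spacer_len = 33,
                             k = 0, j = 0, genome_id = "h")
    sets <- build_sets(pl$spacers,
                       data.frame(accession = pl$genome$accession,
                                  sequence = pl$genome$sequence))
    hits <- search_sets(sets$queries[[1]], sets$targets[[1]],
                        pl$genome$sequence)
    expect_gt(nrow(hits), 0L)
    expect_true(any(hits$near_perfect))
  }
})
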