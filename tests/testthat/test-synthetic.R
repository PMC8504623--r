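# Fixture generators: genome plans, planted protospacers, benchmarks.

test_that("generated phage genomes honor their coding plan", {
  ph <- make_phage(3000, coding_fraction = 0.8, seed = 1)
  expect_equal(nchar(ph$record$sequence), 3000L)
  expect_gte(nrow(ph$plan), 2L)
  expect_true(all(ph$plan$nt_end - ph$plan$nt_start >= 300))
  # planned regions are stop-free in their own frame
  for (i in seq_len(nrow(ph$plan))) {
    nt <- substring(ph$record$sequence, ph$plan$nt_start[i] + 1,
                    ph$plan$nt_end[i])
    if (ph$plan$strand[i] == "-") nt <- revcomp(nt)
    expect_false(grepl("\\*", bios_translate(nt)))
  }
  # determinism and degenerate input
  expect_identical(make_phage(3000, seed = 1)$record$sequence,
                   ph$record$sequence)
  expect_error(make_phage(0), "positive")
})

test_that("planted spacers differ from their source by the planned counts", {
  for (params in list(c(0, 0), c(2, 0), c(3, 0), c(1, 1))) {
    set.seed(500 + params[1] * 10 + params[2])
    ph <- make_phage(3000)
    pl <- plant_protospacers(ph, n_spacers = 4, k = params[1],
                             j = params[2], genome_id = "h")
    for (i in seq_len(nrow(pl$truth))) {
      tr <- pl$truth[i, ]
      region <- substring(pl$genome$sequence, tr$proto_start + 1,
                          tr$proto_end)
      if (tr$proto_strand == "-") region <- revcomp(region)
      sp <- pl$spacers$sequence[i]
      mm <- sum(strsplit(sp, "")[[1]] != strsplit(region, "")[[1]])
      expect_equal(mm, tr$nt_mismatches)
      if (params[1] > 0 && params[2] == 0) expect_equal(mm, params[1])
    }
  }
})

test_that("the aa-conserving model never changes the source-frame protein", {
  set.seed(601)
  ph <- make_phage(3000)
  pl <- plant_protospacers(ph, n_spacers = 5, k = 3, j = 0,
                           genome_id = "h")
  for (i in seq_len(nrow(pl$truth))) {
    tr <- pl$truth[i, ]
    orf <- ph$plan[which(ph$plan$nt_start <= tr$proto_start &
                           ph$plan$nt_end >= tr$proto_end &
                           ph$plan$strand == tr$orf_strand)[1], ]
    # genome protospacer and spacer, both oriented to the coding strand
    genome_w <- substring(pl$genome$sequence, tr$proto_start + 1,
                          tr$proto_end)
    if (orf$strand == "-") genome_w <- revcomp(genome_w)
    spacer_w <- pl$spacers$sequence[i]
    if (tr$proto_strand != tr$orf_strand) spacer_w <- revcomp(spacer_w)
    # compare the full codons of the ORF frame inside the window
    off <- if (orf$strand == "+") tr$proto_start - orf$nt_start else
      orf$nt_end - tr$proto_end
    lead <- (3 - off %% 3) %% 3
    len3 <- ((nchar(genome_w) - lead) %/% 3) * 3
    aa_g <- bios_translate(substring(genome_w, lead + 1, lead + len3))
    aa_s <- bios_translate(substring(spacer_w, lead + 1, lead + len3))
    expect_identical(aa_s, aa_g)
    expect_gt(sum(strsplit(spacer_w, "")[[1]] !=
                    strsplit(genome_w, "")[[1]]), 0)
  }
})

test_that("planted PAM instances flank the protospacer on the coding strand", {
  set.seed(602)
  ph <- make_phage(3000)
  pl <- plant_protospacers(ph, n_spacers = 4, k = 0, j = 0,
                           pam_motif = "NGG", genome_id = "h")
  for (i in seq_len(nrow(pl$truth))) {
    tr <- pl$truth[i, ]
    g <- pl$genome$sequence
    flank <- if (tr$orf_strand == "+")
      substring(g, tr$proto_end + 1, tr$proto_end + 3) else
        revcomp(substring(g, tr$proto_start - 2, tr$proto_start))
    expect_match(flank, "^.GG$")
  }
})

test_that("benchmarks wire hosts to phages per the pairing matrix", {
  b <- make_benchmark(n_hosts = 3, n_phages = 3, decoy_hosts = 2,
                      decoy_phages = 2, seed = 77)
  expect_equal(nrow(b$truth$pairs), 3L)
  expect_equal(sort(unique(b$spacers$genome_id)),
               sort(c(paste0("host", 1:3), paste0("decoy_host", 1:2))))
  expect_equal(nrow(b$phages), 5L)
  expect_true(all(b$truth$pairs$host == paste0("host", 1:3)))
  # same seed -> identical bundle
  b2 <- make_benchmark(n_hosts = 3, n_phages = 3, decoy_hosts = 2,
                       decoy_phages = 2, seed = 77)
  expect_identical(b, b2)
  # empty pairing -> all-null benchmark
  b0 <- make_benchmark(n_hosts = 2, n_phages = 2,
                       pairing = matrix(0L, 2, 2), decoy_hosts = 2,
                       decoy_phages = 0, seed = 78)
  expect_null(b0$truth$pairs)
  # labels cover every genome and validate
  expect_setequal(b$labels$mapping$accession,
                  c(unique(b$spacers$genome_id), b$phages$accession))
})

test_that("benchmark bundles can be written to disk and read back", {
  d <- withr::local_tempdir()
  b <- make_benchmark(n_hosts = 2, n_phages = 2, decoy_hosts = 1,
                      decoy_phages = 1, seed = 99, dir = d)
  sp <- read_spacer_fasta(file.path(d, "spacers", "host1.fasta"), "host1")
  expect_identical(sp$sequence,
                   b$spacers$sequence[b$spacers$genome_id == "host1"])
  ph <- read_genome_fasta(list.files(file.path(d, "phages"),
                                     full.names = TRUE))
  expect_setequal(ph$accession, b$phages$accession)
  lab <- read_tax_labels(file.path(d, "labels.tsv"),
                         file.path(d, "taxonomy.tsv"))
  expect_equal(nrow(lab$mapping), nrow(b$labels$mapping))
})
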