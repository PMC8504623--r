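# Weighted lowest-common-ancestor assignment and report building.

toy_tree <- function() {
  data.frame(
    taxid = c(1, 10, 20, 101, 102, 103, 201, 1011, 1012, 1021, 1031,
              2011),
    parent = c(1, 1, 1, 10, 10, 10, 20, 101, 101, 102, 103, 201),
    rank = c("root", "family", "family", "genus", "genus", "genus",
             "genus", "species", "species", "species", "species",
             "species"),
    name = c("root", "famA", "famB", "genA1", "genA2", "genA3", "genB1",
             "spA11", "spA12", "spA21", "spA31", "spB11"),
    stringsAsFactors = FALSE)
}

test_that("weighted LCA picks the lowest sufficiently supported node", {
  tax <- toy_tree()
  one <- weighted_lca(data.frame(taxid = 1011, weight = 1), tax)
  expect_equal(one$lca_taxid, 1011)
  expect_equal(one$support, 1)
  # two sibling species, equal weight -> their genus, support 1
  sib <- weighted_lca(data.frame(taxid = c(1011, 1012), weight = c(1, 1)),
                      tax)
  expect_equal(sib$lca_taxid, 101)
  expect_equal(sib$lca_rank, "genus")
  expect_equal(sib$support, 1)
  # 3:1 votes across two families -> majority family, support 0.75
  fam <- weighted_lca(data.frame(taxid = c(1011, 1021, 1031, 2011),
                                 weight = rep(1, 4)), tax)
  expect_equal(fam$lca_taxid, 10)
  expect_equal(fam$lca_rank, "family")
  expect_equal(fam$support, 0.75)
  expect_error(weighted_lca(data.frame(taxid = 999, weight = 1), tax),
               "999")
  expect_null(weighted_lca(data.frame(taxid = numeric(),
                                      weight = numeric()), tax))
})

test_that("weighted LCA equals the exhaustive per-node oracle", {
  set.seed(21)
  for (trial in 1:150) {
    tax <- random_tree(sample(5:50, 1))
    nv <- sample(1:20, 1)
    votes <- data.frame(taxid = sample(tax$taxid, nv, replace = TRUE),
                        weight = runif(nv, 0.1, 3))
    thr <- sample(c(0.5, 0.6, 0.8), 1)
    got <- weighted_lca(votes, tax, thr)
    expect_equal(got$lca_taxid, oracle_weighted_lca(votes, tax, thr))
  }
})

test_that("raising the support threshold never yields a deeper node", {
  set.seed(22)
  depth_of <- function(taxid, tax) {
    p <- setNames(tax$parent, tax$taxid); d <- 0
    while (p[[as.character(taxid)]] != taxid) {
      taxid <- p[[as.character(taxid)]]; d <- d + 1
    }
    d
  }
  for (trial in 1:30) {
    tax <- random_tree(20)
    votes <- data.frame(taxid = sample(tax$taxid, 6, replace = TRUE),
                        weight = runif(6))
    d <- vapply(c(0.5, 0.7, 0.9, 1.0), function(thr)
      depth_of(weighted_lca(votes, tax, thr)$lca_taxid, tax), 0)
    expect_true(all(diff(d) <= 0))
  }
})

test_that("reports aggregate retained matches into LCA votes", {
  tax <- toy_tree()
  labels <- list(
    mapping = data.frame(accession = c("h1", "h2", "ph1", "sA", "sB"),
                         taxid = c(1011, 1012, 2011, 1011, 1012)),
    taxonomy = tax)
  matches <- data.frame(query_set_id = c("h1", "h2"),
                        target_set_id = c("ph1", "ph1"),
                        s_comb = c(1e-6, 1e-6), stringsAsFactors = FALSE)
  hits <- data.frame(spacer_accession = c("sA", "sB"),
                     target_set_id = c("ph1", "ph1"),
                     query_set_id = c("h1", "h2"),
                     s_comb = c(1e-6, 1e-6), stringsAsFactors = FALSE)
  rep <- build_reports(matches, hits, labels)
  # two hosts in the same genus, different species -> genus-level host LCA
  expect_equal(rep$host_lca_per_phage$lca_taxid, 101)
  expect_equal(rep$host_lca_per_phage$lca_rank, "genus")
  # each spacer maps to the single phage species
  expect_equal(rep$phage_lca_per_spacer$lca_taxid, c(2011, 2011))
  # single retained match -> that host's own taxon
  rep1 <- build_reports(matches[1, ], hits[1, ], labels)
  expect_equal(rep1$host_lca_per_phage$lca_taxid, 1011)
  # votes without labels are skipped with a warning
  labels$mapping <- labels$mapping[-1, ]
  expect_warning(rep2 <- build_reports(matches, hits, labels), "h1")
  expect_equal(rep2$host_lca_per_phage$lca_taxid, 1012)
})
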