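# Weighted lowest-common-ancestor taxonomy: assign each phage a host
# taxon (and each spacer a phage taxon) from the taxa of its retained
# matches, weighted by match confidence.

# validate a taxonomy table: data.frame(taxid, parent, rank, name),
# parent-pointer tree with a single root (parent == taxid at the root)
validate_taxonomy <- function(tax) {
  stopifnot(all(c("taxid", "parent", "rank", "name") %in% names(tax)))
  if (anyDuplicated(tax$taxid)) stop("duplicate taxids in taxonomy")
  if (!all(tax$parent %in% tax$taxid))
    stop("parent taxids missing from taxonomy: ",
         paste(setdiff(tax$parent, tax$taxid), collapse = ", "))
  roots <- tax$taxid[tax$parent == tax$taxid]
  if (length(roots) != 1L)
    stop("taxonomy must have exactly one root, found ", length(roots))
  tax
}

# taxid -> vector of ancestors from the node itself up to the root
tax_lineage <- function(taxid, tax) {
  p <- setNames(tax$parent, tax$taxid)
  path <- taxid
  while (p[[as.character(taxid)]] != taxid) {
    taxid <- p[[as.character(taxid)]]
    path <- c(path, taxid)
  }
  path
}

#' Weighted lowest common ancestor of a set of taxon votes
#'
#' Chooses the lowest (deepest) node whose subtree carries strictly more
#' than `support_threshold` of the total vote weight (nodes carrying the
#' full weight always qualify, so the root is always a fallback). With
#' the strict majority rule two disjoint subtrees can never both qualify
#' at a threshold of 0.5 or more; any residual tie is broken by greater
#' depth, then smaller taxid.
#'
#' @param votes data.frame with columns `taxid`, `weight` (weights > 0;
#'   taxids must exist in `tax`).
#' @param tax taxonomy data.frame (`taxid`, `parent`, `rank`, `name`).
#' @param support_threshold fraction of total weight required, default 0.5.
#' @return one-row data.frame `lca_taxid`, `lca_rank`, `lca_name`,
#'   `support`, `n_votes`, or `NULL` when `votes` is empty.
#' @export
weighted_lca <- function(votes, tax, support_threshold = 0.5) {
  if (is.null(votes) || !nrow(votes)) return(NULL)
  tax <- validate_taxonomy(tax)
  stopifnot(all(votes$weight > 0))
  miss <- setdiff(votes$taxid, tax$taxid)
  if (length(miss)) stop("vote taxids missing from taxonomy: ",
                         paste(miss, collapse = ", "))
  total <- sum(votes$weight)
  # accumulate each vote's weight along its lineage
  cum <- setNames(numeric(nrow(tax)), tax$taxid)
  depth <- setNames(integer(nrow(tax)), tax$taxid)
  for (i in seq_len(nrow(votes))) {
    lin <- tax_lineage(votes$taxid[i], tax)
    cum[as.character(lin)] <- cum[as.character(lin)] + votes$weight[i]
  }
  for (t in tax$taxid)
    depth[as.character(t)] <- length(tax_lineage(t, tax)) - 1L
  ok <- (cum - support_threshold * total > 1e-12) | (total - cum < 1e-12)
  cand <- as.numeric(names(cum))[ok]
  d <- depth[ok]
  pick <- cand[order(-d, cand)][1L]
  row <- tax[tax$taxid == pick, ]
  data.frame(lca_taxid = pick, lca_rank = row$rank, lca_name = row$name,
             support = unname(cum[as.character(pick)]) / total,
             n_votes = nrow(votes), stringsAsFactors = FALSE)
}

# confidence weight of a match: -log10(s_comb) clipped to [1, 20]
lca_weight <- function(s_comb) pmin(20, pmax(1, -log10(s_comb)))

#' Weighted-LCA taxonomy reports for retained matches
#'
#' For each phage, the prokaryote taxids of all retained matches involving
#' it vote for a host LCA, weighted by `-log10(s_comb)` clipped to
#' `[1, 20]` (or uniformly when `uniform_weights`). Symmetrically, for
#' each spacer with a retained hit, the phage taxids vote for a phage LCA.
#'
#' @param matches retained match table (columns `query_set_id`,
#'   `target_set_id`, `s_comb`).
#' @param hits hit table of the retained matches (columns
#'   `spacer_accession`, `target_accession`, plus `query_set_id`,
#'   `target_set_id`, `s_comb` merged in).
#' @param labels a label table from [read_tax_labels()] (`mapping` +
#'   `taxonomy`).
#' @param support_threshold passed to [weighted_lca()].
#' @param uniform_weights use weight 1 for every vote.
#' @return list with data.frames `host_lca_per_phage` and
#'   `phage_lca_per_spacer`; subjects without any labelled vote are
#'   omitted (with a warning for votes lacking labels).
#' @export
build_reports <- function(matches, hits, labels, support_threshold = 0.5,
                          uniform_weights = FALSE) {
  tax <- validate_taxonomy(labels$taxonomy)
  map <- labels$mapping
  lookup <- setNames(map$taxid, map$accession)
  one_report <- function(subjects, voters, s_comb) {
    taxid <- lookup[voters]
    if (anyNA(taxid)) {
      warning("skipping votes without taxonomic label: ",
              paste(unique(voters[is.na(taxid)]), collapse = ", "),
              call. = FALSE)
    }
    keep <- !is.na(taxid)
    w <- if (uniform_weights) rep(1, sum(keep)) else lca_weight(s_comb[keep])
    v <- data.frame(subject = subjects[keep], taxid = taxid[keep],
                    weight = w, stringsAsFactors = FALSE)
    out <- lapply(split(v, v$subject), function(vv) {
      vv <- unique(vv)
      weighted_lca(vv[c("taxid", "weight")], tax, support_threshold)
    })
    out <- out[!vapply(out, is.null, TRUE)]
    if (!length(out))
      return(data.frame(subject = character(), lca_taxid = numeric(),
                        lca_rank = character(), lca_name = character(),
                        support = numeric(), n_votes = integer()))
    res <- cbind(subject = names(out), do.call(rbind, out))
    rownames(res) <- NULL
    res
  }
  host <- one_report(matches$target_set_id, matches$query_set_id,
                     matches$s_comb)
  phage <- one_report(hits$spacer_accession, hits$target_set_id,
                      hits$s_comb)
  list(host_lca_per_phage = host, phage_lca_per_spacer = phage)
}
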