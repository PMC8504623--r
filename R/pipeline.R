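# End-to-end pipeline: preprocess -> search -> combine -> null-model FDR
# -> PAM scan -> reports. Deterministic given its inputs; the only RNG in
# the package lives in the synthetic generators and the Gumbel
# calibration.

#' Invert genome sequences
#'
#' Character-reverses each genome (not reverse-complement: reversal
#' destroys codon structure and homology while preserving composition;
#' the reverse complement would keep real ORFs readable on the opposite
#' strand). Accessions get a `_rev` suffix. Useful for building
#' user-supplied null sets and for null-sanity checks; note that the
#' pipeline's default null database is built by [invert_target_sets()],
#' which reverses at the protein level instead.
#'
#' @param genomes genome data.frame (`accession`, `sequence`).
#' @return genome data.frame of kind `"null_target"`.
#' @export
invert_genomes <- function(genomes) {
  data.frame(accession = paste0(genomes$accession, "_rev"),
             sequence = vapply(genomes$sequence, function(s)
               intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE),
             kind = "null_target", stringsAsFactors = FALSE)
}

#' Build the null database by inverting translated target sequences
#'
#' Reverses the amino-acid sequence of every fragment of every target
#' set. Reversal destroys homology and reading-frame structure while
#' preserving, exactly, the per-set fragment counts, fragment lengths and
#' residue composition of the real target database — so the chance-hit
#' rate of the null search mirrors the real search and the empirical FDR
#' is calibrated.
#'
#' @param targets list of target sets from [build_sets()].
#' @return list of null target sets with `_rev`-suffixed ids.
#' @export
invert_target_sets <- function(targets) {
  out <- lapply(targets, function(T) {
    f <- T$fragments
    f$aa <- vapply(f$aa, function(s) intToUtf8(rev(utf8ToInt(s))), "",
                   USE.NAMES = FALSE)
    list(set_id = paste0(T$set_id, "_rev"), fragments = f,
         n_fragments = T$n_fragments)
  })
  names(out) <- paste0(names(out), "_rev")
  out
}

# search every query set against every target set; returns
# list(matches, hits) with one match row per (Q, T) with >= 1 hit
search_all <- function(queries, targets, genome_seqs, scheme, tau, p_floor) {
  match_rows <- list(); hit_rows <- list(); k <- 0L
  n_hits_total <- 0L
  for (Q in queries) {
    if (!Q$n_fragments) next
    for (T in targets) {
      if (!T$n_fragments) next
      hits <- search_sets(Q, T, genome_seqs[[T$set_id]], scheme, p_floor)
      if (!nrow(hits)) next
      n_hits_total <- n_hits_total + nrow(hits)
      st <- pair_statistics(hits, T$n_fragments, tau)
      k <- k + 1L
      bh <- st$best_hits
      bh$query_set_id <- Q$set_id
      bh$target_set_id <- T$set_id
      match_rows[[k]] <- data.frame(
        query_set_id = Q$set_id, target_set_id = T$set_id,
        s_comb = st$s_comb, n_hits = nrow(bh), stringsAsFactors = FALSE)
      hit_rows[[k]] <- bh
    }
  }
  matches <- if (k) do.call(rbind, match_rows) else
    data.frame(query_set_id = character(), target_set_id = character(),
               s_comb = numeric(), n_hits = integer(),
               stringsAsFactors = FALSE)
  hits <- if (k) do.call(rbind, hit_rows) else NULL
  rownames(matches) <- NULL
  list(matches = matches, hits = hits, n_raw_hits = n_hits_total)
}

#' Predict phage-host relationships from CRISPR spacers
#'
#' Runs the full pipeline: six-frame translation of spacers and phage
#' genomes into putative coding fragments, spaced k-mer prefilter and
#' Smith-Waterman protein search with nucleotide re-alignment, per-spacer
#' best-hit P-values, truncated-product combination into a per-pair score
#' `S_comb`, empirical FDR estimation against a null database (by default
#' the character-reversed phage genomes), retention at `fdr_threshold`,
#' and PAM scanning of retained protospacers.
#'
#' @param spacers spacer record data.frame (columns `accession`,
#'   `genome_id`, `sequence`), e.g. rbind of [read_spacer_fasta()] /
#'   [read_crispr_tool_output()] results; one query set per `genome_id`.
#' @param phages phage genome data.frame (`accession`, `sequence`).
#' @param null_genomes optional user-supplied null genome data.frame
#'   (preprocessed exactly like the real targets); by default the null
#'   database is [invert_target_sets()] applied to the real target sets,
#'   i.e. the inverted translated target sequences.
#' @param min_nt minimum coding-fragment length in nt (default 27).
#' @param table NCBI genetic code id for the spacer side (default
#'   `"11"`, bacteria/archaea and their phages).
#' @param table_targets genetic code id for the phage side (defaults to
#'   `table`).
#' @param scheme a [scoring_scheme()].
#' @param tau truncation threshold of the combined score (default 0.1).
#' @param fdr_threshold retention threshold (default 0.05; matches with
#'   estimated FDR below it are retained).
#' @param p_floor near-perfect nucleotide hit P-value floor (default
#'   1e-10).
#' @param catalog PAM catalog data.frame (default [pam_catalog()]).
#' @param pam_window PAM flank width in nt (default 10).
#' @param tax_labels optional label table from [read_tax_labels()];
#'   enables weighted-LCA reports.
#' @param support_threshold weighted-LCA support threshold (default 0.5).
#' @return object of class `phage_host_prediction`: list with `matches`
#'   (all scored pairs with `s_comb`, `empirical_p`, `fdr`, `retained`),
#'   `hits` (per-spacer best hits of every match, with PAM annotation on
#'   retained ones), `lca` (NULL or [build_reports()] output), `null`
#'   (null-score vector, pair count, size ratio), `counts`, and `params`.
#' @examples
#' bench <- make_benchmark(n_hosts = 1, n_phages = 1, decoy_hosts = 0,
#'                         decoy_phages = 0, seed = 7)
#' res <- phage_host_predict(bench$spacers, bench$phages)
#' res$matches
#' @export
phage_host_predict <- function(spacers, phages, null_genomes = NULL,
                               min_nt = 27L, table = "11",
                               table_targets = table,
                               scheme = scoring_scheme(), tau = 0.1,
                               fdr_threshold = 0.05, p_floor = 1e-10,
                               catalog = pam_catalog(), pam_window = 10L,
                               tax_labels = NULL,
                               support_threshold = 0.5) {
  stopifnot(is.data.frame(spacers), is.data.frame(phages))
  sets <- build_sets(spacers, phages, min_nt = min_nt, table = table,
                     table_targets = table_targets)
  null_sets <- if (is.null(null_genomes))
    invert_target_sets(sets$targets) else
      build_sets(spacers, null_genomes, min_nt = min_nt, table = table,
                 table_targets = table_targets)$targets
  genome_seqs <- setNames(as.list(phages$sequence), phages$accession)

  real <- search_all(sets$queries, sets$targets, genome_seqs, scheme,
                     tau, p_floor)
  null <- search_all(sets$queries, null_sets, NULL, scheme, tau, p_floor)
  n_null_pairs <- length(sets$queries) * length(null_sets)
  size_ratio <- length(sets$targets) / length(null_sets)

  matches <- real$matches
  if (nrow(matches))
    matches$empirical_p <- empirical_pvalue(matches$s_comb,
                                            null$matches$s_comb,
                                            n_null_pairs)
  else matches$empirical_p <- numeric(0)
  matches <- estimate_fdr(matches, null$matches$s_comb, size_ratio,
                          fdr_threshold)

  hits <- real$hits
  if (!is.null(hits) && nrow(hits)) {
    key <- paste(hits$query_set_id, hits$target_set_id)
    mkey <- paste(matches$query_set_id, matches$target_set_id)
    hits$s_comb <- matches$s_comb[match(key, mkey)]
    hits$retained <- matches$retained[match(key, mkey)]
    hits <- annotate_pam(hits, genome_seqs, catalog, pam_window)
  } else {
    hits <- empty_hits()
  }

  lca <- NULL
  if (!is.null(tax_labels) && nrow(tax_labels$mapping) &&
      any(matches$retained)) {
    rm_ <- matches[matches$retained, , drop = FALSE]
    rh <- hits[hits$retained, , drop = FALSE]
    lca <- build_reports(rm_, rh, tax_labels, support_threshold)
  }

  counts <- c(spacers_read = nrow(spacers),
              query_sets = length(sets$queries),
              query_fragments = sum(vapply(sets$queries,
                                           function(q) q$n_fragments, 0L)),
              target_sets = length(sets$targets),
              target_fragments = sum(vapply(sets$targets,
                                            function(t) t$n_fragments, 0L)),
              hits = real$n_raw_hits,
              matches_total = nrow(matches),
              matches_retained = sum(matches$retained),
              null_pairs = n_null_pairs,
              null_matches = nrow(null$matches))
  structure(list(matches = matches, hits = hits, lca = lca,
                 null = list(scores = null$matches$s_comb,
                             n_pairs = n_null_pairs,
                             size_ratio = size_ratio),
                 counts = counts,
                 params = list(min_nt = min_nt, table = table,
                               table_targets = table_targets, tau = tau,
                               fdr_threshold = fdr_threshold,
                               p_floor = p_floor, pam_window = pam_window,
                               support_threshold = support_threshold,
                               gap_open = scheme$gap_open,
                               gap_extend = scheme$gap_extend,
                               kmer_pattern = scheme$kmer_pattern,
                               lambda = scheme$lambda, K = scheme$K)),
            class = "phage_host_prediction")
}

# PAM columns for retained hits; "-" sentinels elsewhere.
annotate_pam <- function(hits, genome_seqs, catalog, window) {
  hits$pam_fwd <- "-"; hits$pam_rev <- "-"
  hits$upstream_flank <- ""; hits$downstream_flank <- ""
  for (i in which(hits$retained & hits$proto_end > hits$proto_start)) {
    g <- genome_seqs[[hits$target_set_id[i]]]
    pr <- scan_pam(g, hits$proto_start[i], hits$proto_end[i],
                   hits$proto_strand[i], catalog, window)
    pam_fmt <- function(motif, side) {
      if (motif == "-") "-" else paste0(motif, "(", sub("prime", "'", side),
                                        ")")
    }
    hits$pam_fwd[i] <- pam_fmt(pr$matched_motif_fwd, pr$motif_side_fwd)
    hits$pam_rev[i] <- pam_fmt(pr$matched_motif_rev, pr$motif_side_rev)
    hits$upstream_flank[i] <- pr$upstream_flank
    hits$downstream_flank[i] <- pr$downstream_flank
  }
  hits
}

#' @export
print.phage_host_prediction <- function(x, ...) {
  cat("Phage-host prediction\n")
  cat(sprintf("  %d spacers in %d query sets vs %d phage genomes\n",
              x$counts[["spacers_read"]], x$counts[["query_sets"]],
              x$counts[["target_sets"]]))
  cat(sprintf("  %d hits -> %d candidate matches; %d retained at FDR < %g\n",
              x$counts[["hits"]], x$counts[["matches_total"]],
              x$counts[["matches_retained"]], x$params$fdr_threshold))
  invisible(x)
}

#' @export
summary.phage_host_prediction <- function(object, ...) {
  print(object)
  ret <- object$matches[object$matches$retained, , drop = FALSE]
  if (nrow(ret)) {
    cat("\nRetained matches:\n")
    print(ret[c("query_set_id", "target_set_id", "s_comb", "empirical_p",
                "fdr", "n_hits")], row.names = FALSE)
  }
  invisible(object)
}

#' Write all result files of a prediction run
#'
#' Writes the match report (retained matches only), the run manifest
#' (JSON: parameters and per-stage counts), and, when taxonomy was
#' supplied, the two LCA reports.
#'
#' @param result a `phage_host_prediction`.
#' @param out_dir output directory (created if missing).
#' @param include_alignments passed to [write_match_report()].
#' @return named vector of written file paths, invisibly.
#' @export
write_prediction <- function(result, out_dir, include_alignments = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ret <- result$matches[result$matches$retained, , drop = FALSE]
  rh <- result$hits[result$hits$retained, , drop = FALSE]
  paths <- c(report = file.path(out_dir, "matches.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_match_report(ret, rh, paths[["report"]], include_alignments)
  jsonlite::write_json(list(params = result$params,
                            counts = as.list(result$counts)),
                       paths[["manifest"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(result$lca)) {
    paths["host_lca"] <- file.path(out_dir, "host_lca_per_phage.tsv")
    paths["phage_lca"] <- file.path(out_dir, "phage_lca_per_spacer.tsv")
    write_lca_report(result$lca$host_lca_per_phage, paths[["host_lca"]])
    write_lca_report(result$lca$phage_lca_per_spacer, paths[["phage_lca"]])
  }
  invisible(paths)
}
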