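# Input/output: spacer FASTA, CRISPR-detector report dialects, phage
# FASTA, taxonomy tables, and the two-tier '#'-prefixed TSV match report.

#' Read spacers from a FASTA file
#'
#' One FASTA file holds all spacers of a single prokaryotic genome. The
#' header up to the first whitespace becomes the spacer accession.
#' Sequences are upper-cased and `U` is mapped to `T`; characters outside
#' `A,C,G,T,N` are rejected.
#'
#' @param path FASTA file.
#' @param genome_id identifier of the source prokaryotic genome (default:
#'   file name without extension).
#' @return data.frame of spacer records: `accession`, `genome_id`,
#'   `sequence`, `source_tool`, `array_index`, `position_in_array`.
#' @export
read_spacer_fasta <- function(path, genome_id = NULL) {
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  fa <- read_fasta_chr(path)
  if (!nrow(fa)) stop("no spacers in ", path)
  make_spacer_records(fa$accession, fa$sequence, genome_id, "fasta",
                      array_index = 0L,
                      position_in_array = seq_len(nrow(fa)) - 1L)
}

make_spacer_records <- function(accession, sequence, genome_id, source_tool,
                                array_index, position_in_array) {
  sequence <- normalize_dna(sequence)
  bad <- !vapply(sequence, is_acgtn, TRUE) | nchar(sequence) == 0L
  if (any(bad))
    stop("invalid spacer sequence (non-ACGTN or empty) in record ",
         accession[bad][1L])
  if (anyDuplicated(accession))
    stop("duplicate spacer accession: ",
         accession[duplicated(accession)][1L])
  data.frame(accession = accession, genome_id = genome_id,
             sequence = unname(sequence), source_tool = source_tool,
             array_index = array_index,
             position_in_array = position_in_array,
             stringsAsFactors = FALSE)
}

#' Read phage (or null) genomes from FASTA files
#'
#' @param paths one or more FASTA files, each holding one or more genome
#'   records. Duplicate accessions across all files are rejected.
#' @param kind `"phage_target"` or `"null_target"`.
#' @return data.frame with `accession`, `sequence`, `kind`.
#' @export
read_genome_fasta <- function(paths, kind = c("phage_target", "null_target")) {
  kind <- match.arg(kind)
  fa <- do.call(rbind, lapply(paths, read_fasta_chr))
  if (!nrow(fa) || any(nchar(fa$sequence) == 0L))
    stop("empty genome record in input")
  if (anyDuplicated(fa$accession))
    stop("duplicate genome accession: ",
         fa$accession[duplicated(fa$accession)][1L])
  fa$sequence <- normalize_dna(fa$sequence)
  fa$kind <- kind
  fa
}

looks_dna <- function(x) nchar(x) >= 4L & !grepl("[^ACGTNacgtn]", x)

#' Read spacers from a CRISPR-detector report
#'
#' Parses the plain-text output of PILER-CR, CRT, MinCED (CRT grammar) or
#' CRISPRDetect. All arrays are extracted regardless of any detector
#' confidence flags; repeats are discarded. Within each data line, the
#' spacer is identified as the last DNA-like token whose length matches
#' the line's declared spacer length (PILER-CR, CRISPRDetect) or as the
#' second sequence token (CRT/MinCED).
#'
#' @param path report file.
#' @param dialect one of `"pilercr"`, `"crt"`, `"minced"`,
#'   `"crisprdetect"`.
#' @param genome_id source genome identifier (default: file name).
#' @return data.frame of spacer records as in [read_spacer_fasta()], with
#'   `array_index` / `position_in_array` filled in and accessions
#'   `<genome_id>_a<array>_s<pos>`.
#' @export
read_crispr_tool_output <- function(path, dialect = c("pilercr", "crt",
                                                      "minced",
                                                      "crisprdetect"),
                                    genome_id = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  array_re <- if (dialect %in% c("crt", "minced")) "^CRISPR\\s+\\d+" else
    "^Array\\s+\\d+"
  spacers <- character(); arrays <- integer(); pos <- integer()
  cur_array <- -1L; cur_pos <- 0L
  for (ln in lines) {
    if (grepl(array_re, ln)) {
      cur_array <- cur_array + 1L
      cur_pos <- 0L
      next
    }
    if (cur_array < 0L) next
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (!length(tok) || !grepl("^\\d+$", tok[1L])) next
    sp <- extract_spacer_token(tok, dialect)
    if (is.na(sp)) {
      if (sum(looks_dna(tok)) >= 2L)
        stop("unparseable ", dialect, " line: ", ln)
      next  # trailing repeat-only line
    }
    spacers <- c(spacers, sp)
    arrays <- c(arrays, cur_array)
    pos <- c(pos, cur_pos)
    cur_pos <- cur_pos + 1L
  }
  if (cur_array < 0L)
    stop("unparseable ", dialect, " file (no array header found): ", path)
  if (!length(spacers)) stop("no spacers in ", path)
  make_spacer_records(sprintf("%s_a%d_s%d", genome_id, arrays, pos),
                      spacers, genome_id, dialect, arrays, pos)
}

# tok: whitespace tokens of a numeric-led data line; NA if no spacer
extract_spacer_token <- function(tok, dialect) {
  dna <- looks_dna(tok)
  if (dialect %in% c("crt", "minced")) {
    # POSITION  REPEAT  [SPACER]  [ lengths... ]
    seqs <- tok[dna]
    if (length(seqs) >= 2L) return(seqs[2L])
    return(NA_character_)
  }
  # pilercr / crisprdetect: pos, repeat-len, %id, spacer-len, ...,
  # spacer sequence last; consensus dots may corrupt the repeat token
  if (length(tok) >= 4L && grepl("^\\d+$", tok[4L])) {
    want <- as.integer(tok[4L])
    cand <- which(dna & nchar(tok) == want)
    if (length(cand)) return(tok[max(cand)])
  }
  NA_character_
}

#' Write spacer records back to FASTA
#'
#' Round-trips the sequences of any supported input dialect exactly.
#'
#' @param spacers spacer record data.frame.
#' @param path output file.
#' @export
write_spacer_fasta <- function(spacers, path) {
  write_fasta_chr(spacers$accession, spacers$sequence, path)
}

fmt_num <- function(x) sprintf("%.2e", x)

#' Write the two-tier match report
#'
#' Each host-phage match spans two or more tab-separated lines. The first
#' starts with `#`: prokaryote accession, phage accession, combined score
#' `S_comb`, number of hits. Each following line describes one hit:
#' spacer accession, phage accession, best-hit P-value, spacer start/end,
#' phage start/end (1-based inclusive; phage start > end on the reverse
#' strand), possible 5' PAM|3' PAM, and the same on the reverse strand
#' (`-` when absent). With `include_alignments`, the aligned spacer and
#' phage nucleotide segments follow each hit line.
#'
#' @param matches match table (`query_set_id`, `target_set_id`, `s_comb`);
#'   one report block per row, in row order.
#' @param hits hit table carrying `query_set_id`, `target_set_id`,
#'   `p_bh`, coordinates and PAM columns (`pam_fwd`, `pam_rev`), as
#'   produced by [phage_host_predict()].
#' @param path output file.
#' @param include_alignments append alignment lines per hit.
#' @return `path`, invisibly. An empty match list yields an empty file.
#' @export
write_match_report <- function(matches, hits, path,
                               include_alignments = FALSE) {
  out <- character()
  for (i in seq_len(nrow(matches))) {
    m <- matches[i, ]
    h <- hits[hits$query_set_id == m$query_set_id &
                hits$target_set_id == m$target_set_id, , drop = FALSE]
    out <- c(out, paste("#", m$query_set_id, "\t", m$target_set_id, "\t",
                        fmt_num(m$s_comb), "\t", nrow(h), sep = ""))
    for (j in seq_len(nrow(h))) {
      hh <- h[j, ]
      ps <- if (hh$proto_strand == "+")
        c(hh$proto_start + 1L, hh$proto_end) else
          c(hh$proto_end, hh$proto_start + 1L)
      out <- c(out, paste(hh$spacer_accession, m$target_set_id,
                          fmt_num(hh$p_bh),
                          hh$spacer_aln_start + 1L, hh$spacer_aln_end,
                          ps[1L], ps[2L],
                          if (is.null(hh$pam_fwd)) "-" else hh$pam_fwd,
                          if (is.null(hh$pam_rev)) "-" else hh$pam_rev,
                          sep = "\t"))
      if (include_alignments && !is.null(hh$aln_spacer))
        out <- c(out, paste0(">", hh$aln_spacer), paste0(">", hh$aln_target))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a match report back into tables
#'
#' Inverse of [write_match_report()] (numeric fields at printed
#' precision); alignment lines are skipped.
#'
#' @param path report file.
#' @return list of data.frames `matches` and `hits`.
#' @export
read_match_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^>", lines) & nzchar(lines)]
  is_hdr <- grepl("^#", lines)
  split_tsv <- function(x) do.call(rbind, strsplit(x, "\t", fixed = TRUE))
  if (!length(lines))
    return(list(matches = data.frame(), hits = data.frame()))
  hd <- split_tsv(sub("^#", "", lines[is_hdr]))
  matches <- data.frame(query_set_id = hd[, 1L], target_set_id = hd[, 2L],
                        s_comb = as.numeric(hd[, 3L]),
                        n_hits = as.integer(hd[, 4L]),
                        stringsAsFactors = FALSE)
  hits <- data.frame()
  if (any(!is_hdr)) {
    ht <- split_tsv(lines[!is_hdr])
    hits <- data.frame(spacer_accession = ht[, 1L],
                       target_set_id = ht[, 2L],
                       p_bh = as.numeric(ht[, 3L]),
                       spacer_start = as.integer(ht[, 4L]),
                       spacer_end = as.integer(ht[, 5L]),
                       phage_start = as.integer(ht[, 6L]),
                       phage_end = as.integer(ht[, 7L]),
                       pam_fwd = ht[, 8L], pam_rev = ht[, 9L],
                       stringsAsFactors = FALSE)
  }
  list(matches = matches, hits = hits)
}

#' Read taxonomic labels and a taxonomy tree
#'
#' The mapping is a two-column TSV `accession<TAB>taxid`. The tree is
#' either a minimal four-column TSV (`taxid`, `parent`, `rank`, `name`,
#' with header) or an NCBI-taxdump-style directory containing `nodes.dmp`
#' and `names.dmp`.
#'
#' @param mapping_path TSV file (no header).
#' @param taxdump_path TSV file or taxdump directory.
#' @return list with `mapping` (data.frame `accession`, `taxid`) and
#'   `taxonomy` (data.frame `taxid`, `parent`, `rank`, `name`). An empty
#'   mapping file yields an empty table with a warning (LCA reporting is
#'   then disabled downstream).
#' @export
read_tax_labels <- function(mapping_path, taxdump_path) {
  mp <- tryCatch(
    utils::read.table(mapping_path, sep = "\t", header = FALSE,
                      col.names = c("accession", "taxid"),
                      stringsAsFactors = FALSE),
    error = function(e) data.frame(accession = character(),
                                   taxid = numeric()))
  tax <- if (dir.exists(taxdump_path)) read_taxdump(taxdump_path) else
    utils::read.table(taxdump_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE,
                      colClasses = c("numeric", "numeric", "character",
                                     "character"))
  tax <- validate_taxonomy(tax)
  if (!nrow(mp)) {
    warning("empty taxonomic mapping; LCA reporting disabled",
            call. = FALSE)
  } else {
    miss <- setdiff(mp$taxid, tax$taxid)
    if (length(miss))
      stop("taxids absent from taxonomy tree: ",
           paste(sort(miss), collapse = ", "))
  }
  list(mapping = mp, taxonomy = tax)
}

read_taxdump <- function(dir) {
  parse_dmp <- function(f) {
    lines <- readLines(file.path(dir, f), warn = FALSE)
    strsplit(sub("\\t\\|$", "", lines), "\t\\|\t")
  }
  nodes <- parse_dmp("nodes.dmp")
  names_ <- parse_dmp("names.dmp")
  tax <- data.frame(
    taxid = as.numeric(vapply(nodes, `[`, "", 1L)),
    parent = as.numeric(vapply(nodes, `[`, "", 2L)),
    rank = vapply(nodes, `[`, "", 3L), stringsAsFactors = FALSE)
  sci <- Filter(function(x) length(x) >= 4L && x[4L] == "scientific name",
                names_)
  nm <- setNames(vapply(sci, `[`, "", 2L),
                 vapply(sci, `[`, "", 1L))
  tax$name <- unname(nm[as.character(tax$taxid)])
  tax$name[is.na(tax$name)] <- ""
  tax
}

#' Write a weighted-LCA report
#'
#' One tab-separated row per subject: accession, LCA taxid, rank, name,
#' support fraction, number of votes.
#'
#' @param report data.frame from [build_reports()].
#' @param path output file.
#' @export
write_lca_report <- function(report, path) {
  df <- report
  df$support <- sprintf("%.3f", df$support)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
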