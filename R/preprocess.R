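# Six-frame scan: extract and translate all putative coding fragments.
#
# A "putative coding fragment" is a maximal stop-free codon run of at least
# `min_nt` nucleotides in one of the six reading frames. No start codon is
# required: spacers are sub-gene fragments, so demanding ATG would discard
# nearly every true protospacer. Ambiguous codons (any non-ACGT base)
# translate to 'X' and never terminate a run; only stop codons delimit runs.

# codon -> aa lookup for an NCBI translation table id (character or integer)
codon_table <- function(table = "11") {
  Biostrings::getGeneticCode(as.character(table))
}

translate_codons <- function(codons, code) {
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Extract translated coding fragments in six reading frames
#'
#' Scans `sequence` on both strands in all three frames and returns every
#' maximal stop-codon-free codon run of at least `min_nt` nucleotides,
#' translated with the given NCBI genetic code. Coordinates are 0-based
#' half-open on the forward strand of the parent sequence regardless of the
#' fragment's strand; `frame` is the frame offset (0, 1, 2) on the
#' fragment's own strand.
#'
#' @param sequence DNA string (A,C,G,T,N and IUPAC codes; ambiguous codons
#'   translate to `X`).
#' @param accession identifier of the parent sequence.
#' @param kind `"spacer"` or `"genome"`.
#' @param min_nt minimum fragment length in nucleotides (default 27, i.e.
#'   9 codons).
#' @param table NCBI genetic code id (default `"11"`, bacteria/archaea and
#'   their phages).
#' @return data.frame with one row per fragment: `parent_accession`,
#'   `parent_kind`, `frame`, `strand`, `nt_start`, `nt_end`, `aa`, `nt`,
#'   `parent_length`. A sequence shorter than `min_nt` yields zero rows.
#' @examples
#' extract_fragments(strrep("GCA", 11), "s1", "spacer")
#' @export
extract_fragments <- function(sequence, accession, kind = c("genome", "spacer"),
                              min_nt = 27L, table = "11") {
  kind <- match.arg(kind)
  sequence <- normalize_dna(sequence)
  L <- nchar(sequence)
  min_cod <- as.integer(ceiling(min_nt / 3))
  out <- vector("list", 6L)
  if (L >= min_nt) {
    code <- codon_table(table)
    k <- 0L
    for (strand in c("+", "-")) {
      s <- if (strand == "+") sequence else revcomp(sequence)
      for (frame in 0:2) {
        ncod <- (L - frame) %/% 3L
        if (ncod < min_cod) next
        starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
        codons <- substring(s, starts, starts + 2L)
        aa <- translate_codons(codons, code)
        runs <- stop_free_runs(aa, min_cod)
        if (!nrow(runs)) next
        # oriented nt coords of each run, then map to the forward strand
        o_start <- frame + 3L * (runs$from - 1L)
        o_end <- frame + 3L * runs$to
        if (strand == "+") {
          nt_start <- o_start; nt_end <- o_end
        } else {
          nt_start <- L - o_end; nt_end <- L - o_start
        }
        k <- k + 1L
        out[[k]] <- data.frame(
          parent_accession = accession, parent_kind = kind,
          frame = frame, strand = strand,
          nt_start = nt_start, nt_end = nt_end,
          aa = vapply(seq_len(nrow(runs)), function(i)
            paste(aa[runs$from[i]:runs$to[i]], collapse = ""), ""),
          nt = substring(s, o_start + 1L, o_end),
          parent_length = L, stringsAsFactors = FALSE)
      }
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(parent_accession = character(), parent_kind = character(),
                      frame = integer(), strand = character(),
                      nt_start = integer(), nt_end = integer(),
                      aa = character(), nt = character(),
                      parent_length = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# maximal runs of non-stop codons with length >= min_cod;
# returns data.frame(from, to) of 1-based codon indices (inclusive)
stop_free_runs <- function(aa, min_cod) {
  ok <- aa != "*"
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_cod
  data.frame(from = starts[keep], to = ends[keep])
}

#' Build query and target fragment sets
#'
#' Groups spacer fragments into one query set per prokaryotic genome and
#' genome fragments into one target set per phage.
#'
#' @param spacers data.frame of spacer records (`accession`, `genome_id`,
#'   `sequence`), e.g. from [read_spacer_fasta()].
#' @param genomes data.frame of genome records (`accession`, `sequence`),
#'   one phage per row.
#' @param min_nt,table passed to [extract_fragments()].
#' @param table_targets genetic code for the genome side (defaults to
#'   `table`, so each input side can use its own NCBI table).
#' @return list with `queries` (named list of query sets) and `targets`
#'   (named list of target sets). Each set is a list with `set_id`,
#'   `fragments` (fragment data.frame), `n_fragments`, and for query sets a
#'   `spacers` data.frame of the underlying records. A host whose spacers
#'   yield no fragment keeps an empty query set and triggers a warning; if
#'   every query set is empty, an error is thrown.
#' @export
build_sets <- function(spacers, genomes, min_nt = 27L, table = "11",
                       table_targets = table) {
  stopifnot(nrow(spacers) > 0L, nrow(genomes) > 0L)
  if (anyDuplicated(genomes$accession))
    stop("duplicate genome accession: ",
         genomes$accession[duplicated(genomes$accession)][1L])
  queries <- lapply(split(spacers, spacers$genome_id), function(sp) {
    frags <- do.call(rbind, lapply(seq_len(nrow(sp)), function(i)
      extract_fragments(sp$sequence[i], sp$accession[i], "spacer",
                        min_nt = min_nt, table = table)))
    if (is.null(frags) || !nrow(frags)) {
      warning("no translatable spacers for genome ", sp$genome_id[1L],
              call. = FALSE)
      frags <- extract_fragments(strrep("A", 0L), "none", "spacer")
    }
    list(set_id = sp$genome_id[1L], fragments = frags,
         n_fragments = nrow(frags), spacers = sp)
  })
  if (all(vapply(queries, function(q) q$n_fragments, 0L) == 0L))
    stop("no translatable spacers in any query set")
  targets <- lapply(seq_len(nrow(genomes)), function(i) {
    frags <- extract_fragments(genomes$sequence[i], genomes$accession[i],
                               "genome", min_nt = min_nt,
                               table = table_targets)
    list(set_id = genomes$accession[i], fragments = frags,
         n_fragments = nrow(frags))
  })
  names(targets) <- genomes$accession
  list(queries = queries, targets = targets)
}
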