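# PAM detection: scan 10 nt upstream and downstream of each protospacer
# for motifs from a catalog, on the protospacer strand and its reverse
# complement. Reported motifs are annotations only; they never affect
# scoring.

#' Default PAM catalog
#'
#' A small table of well-known PAMs (e.g. NGG 3' for SpCas9-like systems,
#' TTN / TTTV 5' for Cas12a-like systems). Shipped as a user-editable TSV
#' at `system.file("extdata", "pam_catalog.tsv", package = "crisphage")`;
#' when several motifs match, catalog order wins.
#'
#' @param path optional path to a two-column TSV (`motif`, `side` with
#'   side in `{5prime, 3prime}`) replacing the bundled catalog.
#' @return data.frame with columns `motif`, `side`.
#' @export
pam_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pam_catalog.tsv", package = "crisphage")
  cat <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("motif", "side") %in% names(cat)),
            all(cat$side %in% c("5prime", "3prime")))
  cat$motif <- normalize_dna(cat$motif)
  cat
}

# does `motif` (IUPAC) occur anywhere in `flank`? (both plain strings)
iupac_match <- function(motif, flank) {
  if (nchar(flank) < nchar(motif) || !nchar(motif)) return(FALSE)
  length(Biostrings::matchPattern(motif, Biostrings::DNAString(flank),
                                  fixed = FALSE)) > 0L
}

#' Scan protospacer flanks for a PAM
#'
#' Extracts up to `window` nt on each side of the protospacer (clipped at
#' the genome ends) and tests every catalog motif, IUPAC-aware, within the
#' flank on its annotated side: 5' motifs upstream of the protospacer, 3'
#' motifs downstream, on the given strand; the scan is repeated on the
#' reverse complement, where upstream and downstream swap. The first
#' matching motif per strand, in catalog order, is reported.
#'
#' @param genome_seq genome nucleotide sequence.
#' @param proto_start,proto_end protospacer coordinates, 0-based half-open
#'   on the forward strand.
#' @param strand strand carrying the protospacer (`"+"` or `"-"`).
#' @param catalog data.frame from [pam_catalog()] (may have 0 rows).
#' @param window flank width in nt, default 10.
#' @return list with `upstream_flank`, `downstream_flank` (on `strand`;
#'   5' and 3' of the protospacer respectively), `matched_motif_fwd`,
#'   `motif_side_fwd`, `matched_motif_rev`, `motif_side_rev` (motif name
#'   or `"-"`; side `"5prime"`, `"3prime"` or `"none"`).
#' @export
scan_pam <- function(genome_seq, proto_start, proto_end, strand = "+",
                     catalog = pam_catalog(), window = 10L) {
  Lg <- nchar(genome_seq)
  stopifnot(proto_start >= 0, proto_start < proto_end, proto_end <= Lg)
  left <- substring(genome_seq, max(0L, proto_start - window) + 1L,
                    proto_start)
  right <- substring(genome_seq, proto_end + 1L,
                     min(Lg, proto_end + window))
  if (strand == "+") {
    up <- left; down <- right
  } else {
    up <- revcomp(right); down <- revcomp(left)
  }
  first_match <- function(up, down) {
    for (i in seq_len(nrow(catalog))) {
      fl <- if (catalog$side[i] == "5prime") up else down
      if (iupac_match(catalog$motif[i], fl))
        return(list(motif = catalog$motif[i], side = catalog$side[i]))
    }
    list(motif = "-", side = "none")
  }
  fwd <- first_match(up, down)
  rev <- first_match(revcomp(down), revcomp(up))
  list(upstream_flank = up, downstream_flank = down,
       matched_motif_fwd = fwd$motif, motif_side_fwd = fwd$side,
       matched_motif_rev = rev$motif, motif_side_rev = rev$side)
}
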