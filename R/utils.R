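# Shared sequence helpers. All sequences are plain upper-case character
# scalars internally; coordinates are 0-based half-open on the forward
# strand until report time.

IUPAC_DNA <- "ACGTNRYSWKMBDHV"
IUPAC_DNA_COMP <- "TGCANYRSWMKVHDB"

#' Reverse-complement a DNA string
#'
#' IUPAC ambiguity codes are complemented to their mirror codes.
#'
#' @param x character scalar over the IUPAC DNA alphabet.
#' @return character scalar.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  intToUtf8(rev(utf8ToInt(chartr(IUPAC_DNA, IUPAC_DNA_COMP, x))))
}

# Upper-case, U->T (D-io-1); returns the normalized string.
normalize_dna <- function(x) chartr("U", "T", toupper(x))

# TRUE if x contains only A,C,G,T,N
is_acgtn <- function(x) !grepl("[^ACGTN]", x)

# Split a string into single characters (fast path for short strings).
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Minimal FASTA reader: returns data.frame(accession, sequence).
# Header up to first whitespace becomes the accession.
read_fasta_chr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1L])
    stop("not a FASTA file (no '>' header): ", path)
  idx <- cumsum(hdr)
  acc <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  # entries with no sequence lines at all
  seqs <- seqs[match(seq_along(acc), as.integer(names(seqs)))]
  seqs[is.na(seqs)] <- ""
  data.frame(accession = acc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

write_fasta_chr <- function(accessions, sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", accessions, "\n", sequences), con)
  invisible(path)
}
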