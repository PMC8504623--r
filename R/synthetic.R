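# Synthetic fixtures: toy phage genomes with coding-like regions, host
# spacer sets with planted protospacers under controlled mutation models,
# PAM flanks, decoy hosts/phages, and toy taxonomies. These generators
# define the study conditions of the package's own benchmarks; every
# fixture is reproducible from its seed.

sense_codons <- function(table = "11") {
  code <- codon_table(table)
  names(code)[code != "*"]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# sample() without the scalar-x surprise
resample <- function(x, size) x[sample.int(length(x), size)]

#' Generate a toy phage genome with coding-like regions
#'
#' Builds a random genome whose planned coding regions are stop-free
#' codon runs (sampled from sense codons, starting with ATG) on a random
#' strand, separated by non-coding gaps sized to reach roughly
#' `coding_fraction` of the genome. The plan records the regions for
#' downstream audit and protospacer planting.
#'
#' @param length genome length in nt (> 0).
#' @param coding_fraction target fraction of coding sequence (default
#'   0.8, coding-dense as typical for phages).
#' @param orf_codons range of ORF lengths in codons (default 100-200,
#'   i.e. 300-600 nt).
#' @param table NCBI genetic code id.
#' @param seed optional RNG seed; the same seed reproduces the genome
#'   exactly.
#' @param accession accession of the generated genome record.
#' @return list with `record` (one-row genome data.frame) and `plan`
#'   (data.frame `nt_start`, `nt_end`, `strand`, 0-based half-open,
#'   forward strand).
#' @export
make_phage <- function(length = 3000L, coding_fraction = 0.8,
                       orf_codons = 100:200, table = "11", seed = NULL,
                       accession = "phage1") {
  if (length <= 0) stop("genome length must be positive")
  if (!is.null(seed)) set.seed(seed)
  sense <- sense_codons(table)
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  mean_orf <- 3 * mean(orf_codons)
  mean_gap <- max(12, round(mean_orf * (1 - coding_fraction) /
                              coding_fraction))
  pos <- 0L
  plan <- list(); k <- 0L
  repeat {
    gap <- sample(max(6L, round(mean_gap / 2)):round(mean_gap * 1.5), 1L)
    pos <- pos + gap
    ncod <- sample(orf_codons, 1L)
    if (pos + 3L * ncod > length) break
    codons <- c("ATG", sample(sense, ncod - 1L, replace = TRUE))
    orf <- paste(codons, collapse = "")
    strand <- sample(c("+", "-"), 1L)
    ins <- if (strand == "+") orf else revcomp(orf)
    chars[(pos + 1L):(pos + 3L * ncod)] <- str_chars(ins)
    k <- k + 1L
    plan[[k]] <- data.frame(nt_start = pos, nt_end = pos + 3L * ncod,
                            strand = strand, stringsAsFactors = FALSE)
    pos <- pos + 3L * ncod
  }
  plan <- if (k) do.call(rbind, plan) else
    data.frame(nt_start = integer(), nt_end = integer(),
               strand = character())
  list(record = data.frame(accession = accession,
                           sequence = paste(chars, collapse = ""),
                           kind = "phage_target", stringsAsFactors = FALSE),
       plan = plan)
}

# single-nucleotide synonymous alternatives of a codon (same aa, 1 nt off)
synonymous_1nt <- function(codon, code) {
  aa <- code[[codon]]
  alts <- character()
  for (p in 1:3) for (b in c("A", "C", "G", "T")) {
    alt <- codon
    substr(alt, p, p) <- b
    if (alt != codon && !is.na(code[alt]) && code[[alt]] == aa)
      alts <- c(alts, alt)
  }
  unique(alts)
}

# random non-synonymous (non-stop) codon alternative
nonsyn_codon <- function(codon, code, sense) {
  aa <- code[[codon]]
  cand <- sense[code[sense] != aa]
  sample(cand, 1L)
}

#' Plant protospacers into a phage genome and emit host spacers
#'
#' Copies `n_spacers` windows out of the genome's planned coding regions
#' (on the coding strand), mutates each copy under a controlled model,
#' writes a PAM instance next to each protospacer in the genome, and
#' returns the spacers together with a ground-truth table. The mutation
#' model applies `k` amino-acid-conserving single-nucleotide codon
#' changes (so the spacer differs from the genome in exactly `k` nt while
#' the translated protein of the source frame is unchanged) and `j`
#' amino-acid substitutions (one codon replaced per substitution).
#' Spacers are emitted in a random orientation.
#'
#' @param phage list from [make_phage()] (`record` + `plan`).
#' @param n_spacers number of spacers to plant.
#' @param spacer_len integer range of spacer lengths (default 28:42 nt).
#' @param k amino-acid-conserving nucleotide substitutions per spacer.
#' @param j amino-acid substitutions per spacer.
#' @param pam_motif IUPAC motif written adjacent to each protospacer
#'   (default `"NGG"`), on the side given by `pam_side`.
#' @param pam_side `"3prime"` or `"5prime"`.
#' @param genome_id host genome id used in the spacer records.
#' @param table NCBI genetic code id.
#' @param seed optional RNG seed.
#' @return list with `spacers` (spacer record data.frame), `genome`
#'   (updated genome record, PAMs written in), and `truth` (data.frame
#'   with planted coordinates, strands and mutation counts).
#' @export
plant_protospacers <- function(phage, n_spacers, spacer_len = 28:42,
                               k = 0L, j = 0L, pam_motif = "NGG",
                               pam_side = "3prime", genome_id = "host1",
                               table = "11", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(phage$plan) > 0L, n_spacers >= 1L)
  code <- codon_table(table)
  sense <- sense_codons(table)
  gseq <- phage$record$sequence
  spacers <- list(); truth <- list()
  used <- vector("list", nrow(phage$plan))  # oriented intervals in use
  for (i in seq_len(n_spacers)) {
    orf_row <- ((i - 1L) %% nrow(phage$plan)) + 1L
    orf <- phage$plan[orf_row, ]
    olen <- orf$nt_end - orf$nt_start
    len <- if (length(spacer_len) > 1L) resample(spacer_len, 1L) else
      spacer_len
    # protospacer start within the ORF, in ORF-oriented coordinates,
    # leaving >= 3 nt on each side inside the ORF; avoid overlapping a
    # previously planted window (plus a PAM-sized margin) in this ORF
    smax <- olen - len - 3L
    if (smax < 3L) stop("ORF too short for spacer of length ", len)
    s0 <- NA_integer_
    for (try in 1:100) {
      cand <- resample(3:smax, 1L)
      margin <- nchar(pam_motif) + 1L
      clash <- any(vapply(used[[orf_row]], function(iv)
        cand - margin < iv[2L] && cand + len + margin > iv[1L], TRUE))
      if (!clash) { s0 <- cand; break }
    }
    if (is.na(s0)) stop("could not place non-overlapping protospacer")
    used[[orf_row]] <- c(used[[orf_row]], list(c(s0, s0 + len)))
    o_seq <- if (orf$strand == "+")
      substring(gseq, orf$nt_start + 1L, orf$nt_end) else
        revcomp(substring(gseq, orf$nt_start + 1L, orf$nt_end))
    window <- substring(o_seq, s0 + 1L, s0 + len)
    # full codons of the ORF frame inside the window
    c_first <- ceiling(s0 / 3)
    c_last <- (s0 + len) %/% 3L - 1L
    codon_idx <- seq(c_first, c_last)
    mutable <- codon_idx[vapply(codon_idx, function(ci) {
      cod <- substring(o_seq, 3L * ci + 1L, 3L * ci + 3L)
      length(synonymous_1nt(cod, code)) > 0L
    }, TRUE)]
    if (k > length(mutable))
      stop("not enough synonymously mutable codons in spacer window")
    syn_pick <- if (k > 0L) resample(mutable, k) else integer()
    aa_pick <- if (j > 0L) resample(setdiff(codon_idx, syn_pick), j) else
      integer()
    mut <- window
    n_mm <- 0L
    for (ci in syn_pick) {
      cod <- substring(o_seq, 3L * ci + 1L, 3L * ci + 3L)
      alt <- sample(synonymous_1nt(cod, code), 1L)
      off <- 3L * ci - s0           # window-local offset of the codon
      substr(mut, off + 1L, off + 3L) <- alt
      n_mm <- n_mm + 1L
    }
    for (ci in aa_pick) {
      cod <- substring(o_seq, 3L * ci + 1L, 3L * ci + 3L)
      alt <- nonsyn_codon(cod, code, sense)
      off <- 3L * ci - s0
      substr(mut, off + 1L, off + 3L) <- alt
      n_mm <- n_mm + sum(str_chars(alt) != str_chars(cod))
    }
    # protospacer coordinates on the forward strand
    if (orf$strand == "+") {
      p_start <- orf$nt_start + s0
    } else {
      p_start <- orf$nt_end - s0 - len
    }
    p_end <- p_start + len
    gseq <- write_pam(gseq, p_start, p_end, orf$strand, pam_motif,
                      pam_side, phage$plan, code)
    orient <- sample(c("+", "-"), 1L)
    spacer_seq <- if (orient == "+") mut else revcomp(mut)
    acc <- sprintf("%s_sp%d", genome_id, i)
    spacers[[i]] <- data.frame(
      accession = acc, genome_id = genome_id, sequence = spacer_seq,
      source_tool = "fasta", array_index = 0L,
      position_in_array = i - 1L, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      spacer_accession = acc, phage_accession = phage$record$accession,
      genome_id = genome_id, proto_start = p_start, proto_end = p_end,
      orf_strand = orf$strand,
      proto_strand = if (orient == "+") orf$strand else
        setdiff(c("+", "-"), orf$strand),
      k = k, j = j, nt_mismatches = n_mm, stringsAsFactors = FALSE)
  }
  genome <- phage$record
  genome$sequence <- gseq
  list(spacers = do.call(rbind, spacers), genome = genome,
       truth = do.call(rbind, truth))
}

# instantiate an IUPAC motif concretely and write it next to the
# protospacer on the coding strand; avoid creating in-frame stops inside
# any planned ORF (20 redraws, then accept)
write_pam <- function(gseq, p_start, p_end, strand, motif, side, plan,
                      code) {
  if (is.null(motif) || !nzchar(motif)) return(gseq)
  Lg <- nchar(gseq)
  mlen <- nchar(motif)
  iupac <- c(A = "A", C = "C", G = "G", T = "T", N = "ACGT", R = "AG",
             Y = "CT", S = "GC", W = "AT", K = "GT", M = "AC", B = "CGT",
             D = "AGT", H = "ACT", V = "ACG")
  # forward-strand coordinates of the flank on `strand`'s `side`
  if ((strand == "+") == (side == "3prime")) {
    f_start <- p_end; f_end <- p_end + mlen
  } else {
    f_start <- p_start - mlen; f_end <- p_start
  }
  if (f_start < 0L || f_end > Lg) return(gseq)
  for (try in 1:20) {
    inst <- paste(vapply(str_chars(motif), function(ch) {
      opts <- str_chars(iupac[[ch]])
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, ""), collapse = "")
    ins <- if (strand == "+") inst else revcomp(inst)
    cand <- gseq
    substr(cand, f_start + 1L, f_end) <- ins
    if (!creates_orf_stop(cand, plan, f_start, f_end, code))
      return(cand)
  }
  cand
}

# does the edited region introduce a stop codon into any planned ORF?
creates_orf_stop <- function(gseq, plan, e_start, e_end, code) {
  for (r in seq_len(nrow(plan))) {
    if (e_end <= plan$nt_start[r] || e_start >= plan$nt_end[r]) next
    o <- if (plan$strand[r] == "+")
      substring(gseq, plan$nt_start[r] + 1L, plan$nt_end[r]) else
        revcomp(substring(gseq, plan$nt_start[r] + 1L, plan$nt_end[r]))
    starts <- seq(1L, nchar(o) - 2L, by = 3L)
    aa <- translate_codons(substring(o, starts, starts + 2L), code)
    if (any(aa == "*")) return(TRUE)
  }
  FALSE
}

# toy taxonomy for a benchmark: species per host/phage, grouped in
# genera of two, under two domains
toy_taxonomy <- function(host_ids, phage_ids) {
  tax <- data.frame(taxid = c(1, 2, 3), parent = c(1, 1, 1),
                    rank = c("root", "superkingdom", "superkingdom"),
                    name = c("root", "Bacteria", "Viruses"),
                    stringsAsFactors = FALSE)
  add_side <- function(tax, ids, base_genus, base_species, parent, kind) {
    for (i in seq_along(ids)) {
      g <- base_genus + (i - 1L) %/% 2L
      if (!g %in% tax$taxid)
        tax <- rbind(tax, data.frame(taxid = g, parent = parent,
                                     rank = "genus",
                                     name = paste0(kind, "_genus_",
                                                   (i - 1L) %/% 2L),
                                     stringsAsFactors = FALSE))
      tax <- rbind(tax, data.frame(taxid = base_species + i,
                                   parent = g, rank = "species",
                                   name = ids[i], stringsAsFactors = FALSE))
    }
    tax
  }
  tax <- add_side(tax, host_ids, 100, 1000, 2, "host")
  tax <- add_side(tax, phage_ids, 200, 2000, 3, "phage")
  mapping <- data.frame(
    accession = c(host_ids, phage_ids),
    taxid = c(1000 + seq_along(host_ids), 2000 + seq_along(phage_ids)),
    stringsAsFactors = FALSE)
  list(mapping = mapping, taxonomy = tax)
}

#' Generate a full planted/decoy benchmark
#'
#' Builds `n_phages` phage genomes with planted protospacers wired to
#' `n_hosts` host spacer sets according to `pairing` (default: diagonal,
#' host i targets phage i), plus decoy hosts whose spacers are random
#' sequences and decoy phages with no planted protospacers. A toy
#' taxonomy labels every host and phage. Used by the package's recall and
#' FDR-calibration tests.
#'
#' @param n_hosts,n_phages numbers of true hosts and phages.
#' @param pairing binary `n_hosts x n_phages` matrix; default diagonal.
#' @param decoy_hosts,decoy_phages numbers of decoys (default 10 each).
#' @param n_spacers_per_pair spacers planted per true host-phage pair
#'   (default 4; multiple spacers against one phage are common through
#'   repeated infection or primed acquisition, and feed the
#'   truncated-product combination).
#' @param k,j,spacer_len,pam_motif passed to [plant_protospacers()].
#' @param phage_len,coding_fraction passed to [make_phage()].
#' @param seed RNG seed; the same seed reproduces the bundle exactly.
#' @param dir optional directory: writes per-host spacer FASTAs, per-phage
#'   genome FASTAs, `labels.tsv`, `taxonomy.tsv` and `truth.json`.
#' @return list with `spacers` (all hosts, one data.frame), `phages`
#'   (genome data.frame), `truth` (list with `pairs` and per-spacer
#'   `spacers` tables), `labels` (mapping + taxonomy), `pairing`.
#' @export
make_benchmark <- function(n_hosts = 5L, n_phages = 5L, pairing = NULL,
                           decoy_hosts = 10L, decoy_phages = 10L,
                           n_spacers_per_pair = 4L, k = 0L, j = 0L,
                           spacer_len = 28:42, pam_motif = "NGG",
                           phage_len = 3000L, coding_fraction = 0.8,
                           seed = NULL, dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pairing)) {
    pairing <- matrix(0L, n_hosts, n_phages)
    diag(pairing) <- 1L
  }
  stopifnot(nrow(pairing) == n_hosts, ncol(pairing) == n_phages)
  phages <- lapply(seq_len(n_phages + decoy_phages), function(i)
    make_phage(phage_len, coding_fraction,
               accession = if (i <= n_phages) sprintf("phage%d", i) else
                 sprintf("decoy_phage%d", i - n_phages)))
  spacers <- list(); truth_sp <- list(); pairs <- list()
  for (h in seq_len(n_hosts)) {
    hid <- sprintf("host%d", h)
    for (p in which(pairing[h, ] == 1L)) {
      pl <- plant_protospacers(phages[[p]], n_spacers_per_pair,
                               spacer_len, k = k, j = j,
                               pam_motif = pam_motif, genome_id = hid)
      pl$spacers$accession <- sprintf("%s_ph%d_sp%d", hid, p,
                                      seq_len(nrow(pl$spacers)))
      pl$truth$spacer_accession <- pl$spacers$accession
      phages[[p]]$record <- pl$genome
      spacers[[length(spacers) + 1L]] <- pl$spacers
      truth_sp[[length(truth_sp) + 1L]] <- pl$truth
      pairs[[length(pairs) + 1L]] <- data.frame(
        host = hid, phage = pl$genome$accession, stringsAsFactors = FALSE)
    }
  }
  for (d in seq_len(decoy_hosts)) {
    hid <- sprintf("decoy_host%d", d)
    n <- n_spacers_per_pair
    spacers[[length(spacers) + 1L]] <- data.frame(
      accession = sprintf("%s_sp%d", hid, seq_len(n)), genome_id = hid,
      sequence = vapply(sample(spacer_len, n, replace = TRUE),
                        random_dna, ""),
      source_tool = "fasta", array_index = 0L,
      position_in_array = seq_len(n) - 1L, stringsAsFactors = FALSE)
  }
  spacers <- do.call(rbind, spacers)
  phage_df <- do.call(rbind, lapply(phages, function(p) p$record))
  host_ids <- unique(spacers$genome_id)
  labels <- toy_taxonomy(host_ids, phage_df$accession)
  truth <- list(pairs = do.call(rbind, pairs),
                spacers = do.call(rbind, truth_sp))
  if (!is.null(dir)) {
    dir.create(file.path(dir, "spacers"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "phages"), showWarnings = FALSE)
    for (hid in host_ids) {
      sp <- spacers[spacers$genome_id == hid, ]
      write_fasta_chr(sp$accession, sp$sequence,
                      file.path(dir, "spacers", paste0(hid, ".fasta")))
    }
    for (i in seq_len(nrow(phage_df)))
      write_fasta_chr(phage_df$accession[i], phage_df$sequence[i],
                      file.path(dir, "phages",
                                paste0(phage_df$accession[i], ".fasta")))
    utils::write.table(labels$mapping, file.path(dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(labels$taxonomy, file.path(dir, "taxonomy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         dataframe = "rows", pretty = TRUE)
  }
  list(spacers = spacers, phages = phage_df, truth = truth,
       labels = labels, pairing = pairing)
}
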