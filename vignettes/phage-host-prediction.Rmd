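---
title: "Predicting phage-host pairs from CRISPR spacers at the protein level"
author: "crisphage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phage-host pairs from CRISPR spacers at the protein level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisphage)
```

## The problem

CRISPR arrays are genomic records of past infection: after surviving a
phage attack, many bacteria and archaea store a 28-42 nt fragment of the
invader (a *spacer*) in an array, and use its transcript to cleave that
invader on re-exposure. Matching spacers against phage genomes therefore
links phages to their hosts without culturing either. The classical
approach — nucleotide search with near-exact filters (at most a couple of
mismatches at high coverage) — only finds phages nearly identical to the
one that was archived. Phage reference collections are sparse, and phages
escape CRISPR immunity by mutating their genome while conserving their
proteins, so close nucleotide matches are exactly what real data lack.

crisphage instead compares spacers and phages as **proteins**. Phage
genomes are almost entirely coding, synonymous escape mutations are
invisible at the amino-acid level, and short peptide matches can be scored
with alignment statistics tuned for small evolutionary distance. Single
protein-level matches are individually weak, so the pipeline combines
evidence from all spacers of a host against each phage and controls the
false discovery rate empirically against a null database.

## The pipeline

Given one spacer FASTA per prokaryotic genome and one FASTA per phage:

0. **Preprocess.** Both sides are scanned in six reading frames; every
   maximal stop-codon-free codon run of at least `min_nt = 27`
   nucleotides is translated (genetic code 11 by default, configurable
   per NCBI table id). No start codon is required — spacers are sub-gene
   fragments. The translated spacer fragments of one prokaryote form a
   query set $Q$; the translated fragments of one phage form a target
   set $T$.
1. **Search.** Every query fragment is compared with every target
   fragment that shares at least one spaced 6-mer under the pattern
   `10111011` (positions marked `1` are compared; the pattern tolerates
   mismatches at its two `0` positions, and any exact 8-residue match is
   guaranteed to seed). Candidates are aligned by exact Smith-Waterman
   with affine gaps (open 16, extend 2; a length-$g$ gap costs
   $16 + 2(g-1)$) under a short-distance substitution matrix (PAM40 by
   default; any NCBI-format matrix such as VTML40 can be supplied via
   `read_score_matrix()`). Each protein hit is then re-compared at the
   nucleotide level: the full spacer is laid ungapped over the genome
   window implied by the alignment anchor. Hits with at most 2
   mismatches over at least 95% of the spacer are *near-perfect* and
   have their P-value floored at $10^{-10}$, so genuine protospacers
   always dominate chance protein hits.
2. **Best-hit P-value.** The per-hit P-value uses the Karlin-Altschul
   extreme-value tail $p = 1 - \exp(-K m n e^{-\lambda s})$ for a score
   $s$ between fragments of lengths $m$ and $n$. For one spacer against
   a target set of $n_T$ fragments, the best hit is the minimum of
   $n_T$ tries, giving $p_{bh} = 1 - (1 - p_{\min})^{n_T}$ (computed in
   log space).
3. **Combination.** The best-hit P-values of all spacers of $Q$ hitting
   $T$ are combined by a truncated product:
   $S_{comb} = \tau \prod_{p \le \tau} (p/\tau)$ with $\tau = 0.1$.
   A single P-value at $\tau$ scores $\tau$; each additional significant
   spacer multiplies by $p/\tau \le 1$. If no P-value reaches $\tau$ the
   minimum is reported, so a single weak hit still yields a (weak)
   candidate. Smaller is stronger; the score is used ordinally.
4. **FDR.** The same queries are searched against a null database and
   matches are retained while the estimated
   $\mathrm{FDR} = \mathrm{FP}/(\mathrm{TP}+\mathrm{FP})$ stays below
   0.05 (see below).
5. **PAM.** For every retained hit, the 10 nt upstream and downstream of
   the protospacer are scanned — IUPAC-aware, on the protospacer strand
   and its reverse complement — against a small editable catalog of
   known protospacer-adjacent motifs (NGG 3', TTTV 5', TTN 5',
   NNAGAAW 3'). Motifs are annotations only; they never affect scoring,
   and the raw flanks are kept so users can re-analyse them.

## Score statistics and their calibration

The Gumbel parameters $\lambda$ and $K$ are not free: they are calibrated
by `calibrate_gumbel()`, which aligns $10^5$ random fragment pairs
(query lengths 9-14 aa as produced by translated spacers, target lengths
50-300 aa, residues drawn from Robinson-Robinson background frequencies)
and fits the extreme-value model by maximum likelihood. Scores above the
90th percentile contribute an interval likelihood term that respects
score discreteness; lower scores enter as a censoring term, so the tail —
the only region that matters for small P-values — drives the fit, and the
half-integer continuity shift is folded into $K$ so that the closed form
evaluated at an integer score estimates $P(S \ge s)$. The shipped
constants ($\lambda = 0.3652$, $K = 0.3360$; seed 20210401) reproduce the
simulated exceedance probability at the $p \approx 0.01$ operating point
well within Monte-Carlo error. They are valid for the default matrix and
gap costs; changing either calls for re-calibration, which takes under a
minute.

The per-hit model treats fragments as random; candidates that passed the
prefilter are enriched for high scores, so absolute per-hit P-values are
optimistic for prefiltered pairs. This does not matter downstream: the
identical selection acts on the null database, and both the combined
score and the FDR are calibrated empirically, so only the ordering of
scores is consumed.

## The null model and empirical FDR

The default null database is the real target database with each
translated fragment's amino-acid sequence **reversed**. Reversal destroys
homology and reading-frame structure while preserving — exactly — the
per-set fragment counts, fragment lengths and residue composition, so the
chance-hit rate of the null search mirrors the real search. (Reversing
the genome DNA instead would fragment the stop-free codon runs and yield
a null with far fewer, shorter fragments, under-counting chance hits;
reverse-complementing would keep real genes readable on the opposite
strand.) A user-supplied null genome set is also accepted and is then
preprocessed exactly like the real targets.

Matches are sorted by $S_{comb}$; at the cutoff set by the $k$-th match,
$\widehat{\mathrm{FDR}}(k) = \min(1, r \cdot \#\{\text{null} \le c\}/k)$
where $r$ is the ratio of real to null target-set counts. Estimates are
monotonized by a cumulative minimum from the weakest cutoff downward
(q-value convention) before applying the 0.05 retention threshold.
Separately, each match is annotated with an add-one-smoothed empirical
P-value $(1 + \#\{\text{null} \le s\})/(1 + n_{\text{null pairs}})$,
where pairs that produced no hit still count in the denominator.

**Granularity.** The FDR estimate moves in steps of $r/k$. On small
datasets — few query sets, few phages — the null search may yield only a
handful of scored pairs, and a chance match that happens to undercut
every null score receives an estimate of exactly zero. The estimate is
then faithful to its definition but coarse: with $n$ null matches near a
cutoff, rates below about $1/n$ cannot be resolved. For small studies we
recommend enlarging the null side through the `null_genomes` argument
(e.g. several independently shuffled or unrelated genome sets; the
`size_ratio` scaling handles unequal sizes automatically). At the scale
the method is designed for — thousands of genomes — the null yields
thousands of matches and the granularity is negligible.

## Taxonomy reports

When accession-to-taxid labels and a taxonomy (NCBI-taxdump directory or
a minimal 4-column TSV) are provided, retained matches vote for taxa: for
each phage, the taxa of its matched hosts; for each spacer, the taxa of
its matched phages. Votes are weighted by $-\log_{10} S_{comb}$ clipped
to $[1, 20]$ — confident matches count more, but no single match can
dominate past the cap — with a uniform-weight option. The assignment is
the deepest node whose subtree holds a strict majority of the total
weight (threshold 0.5, configurable). The strict inequality is
deliberate: it makes disjoint candidates impossible at thresholds of 0.5
and above, and it places two equally weighted sibling species at their
parent rather than arbitrarily picking one.

## The synthetic benchmark generator

`make_phage()` builds genomes from stop-free codon runs (300-600 nt,
ATG-led, random strand, sampled from sense codons) separated by short
non-coding gaps, at a default length of 3 kb and coding fraction 0.8 —
coding-dense like real phages but small enough that a full benchmark run
takes seconds. `plant_protospacers()` copies spacer-sized windows
(28-42 nt) out of planned coding regions, applies `k` amino-acid-
conserving single-nucleotide codon changes and `j` amino-acid
substitutions to the spacer copy, writes a concrete PAM instance next to
the protospacer (re-drawn if it would introduce an in-frame stop), and
emits each spacer in a random orientation. `make_benchmark()` wires hosts
to phages through a pairing matrix (4 spacers per true pair by default —
multiple spacers against one phage are common through repeated infection
and primed acquisition, and they feed the combination step), adds decoy
hosts with random spacers and decoy phages with no planted protospacers,
and labels everything with a toy taxonomy. Every generator is
reproducible from its seed, and ground truth (coordinates, strands,
mutation counts) is returned for auditing.

What the generator does *not* emulate: real repeat/array structure and
detector artefacts, genuine phage gene content and codon usage,
inter-phage homology (decoys are independent, so cross-matches are purely
chance-level), spacer acquisition biases, or sequencing error. Passing
tests on this generator demonstrate the mechanics and calibration of the
statistics, not performance on real metagenomes.

## Numerical and design choices

* Sequences are upper-cased on input and `U` maps to `T`; other IUPAC
  codes are kept and score as mismatches. Ambiguous codons translate to
  `X` (scored via the matrix's `X` column) and never terminate a coding
  run — stops, not ambiguity, delimit fragments.
* Coordinates are 0-based half-open on the forward strand internally and
  1-based inclusive in reports; a protospacer on the reverse strand is
  printed with start > end.
* Smith-Waterman reports the single optimal alignment per fragment pair;
  among equal-scoring cells the endpoint earliest in the query, then the
  target, wins, and the traceback prefers match, then a gap in the
  target, then a gap in the query — fully deterministic.
* `S_comb` and $p_{bh}$ are printed in scientific notation with three
  significant digits; missing fields (e.g. no PAM) print as `-`, keeping
  the column count fixed.
* Detector parsers (PILER-CR, CRT, MinCED via the CRT grammar,
  CRISPRDetect) extract every array regardless of confidence flags;
  filtering is the caller's decision. Spacer tokens are validated against
  the line's declared spacer length where the format provides one.
* The pipeline itself is deterministic given its inputs; randomness only
  exists in the generators and the calibration, each governed by an
  explicit seed.

## Limitations

The search is a correctness-first reimplementation: exact Smith-Waterman
behind a single spaced-k-mer prefilter, quadratic in fragment lengths.
It is comfortable at tens of genomes and is not a performance substitute
for a k-mer-cascade search engine at reference-database scale. The per-
hit P-value model assumes independent random fragments; its absolute
accuracy degrades for fragments far outside the calibrated length
regime. And as discussed above, FDR estimates on very small inputs are
coarse — prefer a larger null when the real database is tiny.
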