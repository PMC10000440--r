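---
title: "Discovering neoantigens from noncoding somatic variants with noncneo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering neoantigens from noncoding somatic variants with noncneo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noncneo)
```

## The problem

Tumor neoantigens are mutation-derived peptides presented by MHC class I
molecules and recognizable by T cells. Pipelines that search only coding
exons miss the large majority of somatic mutations, which fall in
introns, UTRs, ncRNA exons, intergenic and up/downstream regions — yet
translation of such "noncoding" sequence demonstrably produces
MHC-presented peptides. `noncneo` implements a proteogenomic route to
these targets: genomic evidence (somatic variant calls) proposes mutant
peptides, mass-spectrometry evidence confirms which are actually
expressed, MHC binding prediction selects presentable 8–11-mers, and a
homology screen against experimentally immunogenic peptides prioritizes
candidates with precedent.

Because no transcript annotation can be trusted in noncoding territory,
the pipeline is deliberately annotation-free downstream of the variant
annotation itself: a fixed ±100 nt window around each variant is
translated in all six reading frames, and expression is decided by MS
evidence, not by ORF models.

## The procedure and its assumptions

**Variant selection.** Only calls whose VCF FILTER is exactly `PASS`
enter the pipeline; the variant caller's own filtering is trusted.
Multi-allelic records are split per ALT allele (each inherits the
record's FILTER), and the annotation join key is (contig, 1-based
position, REF, ALT); the annotation's end coordinate is redundant for
SNV/indel identity and is ignored. The noncoding definition is an exact,
case-sensitive membership test against the ten Annovar categories listed
in `noncoding_categories()`. Unknown or compound categories (e.g.
`"intergenic;exonic"`) are treated as coding and excluded rather than
rejected, for forward compatibility with annotation dialects. The
`splicing` category can affect coding transcripts, but it is retained
verbatim as part of the category set; six-frame translation makes the
distinction immaterial at the peptide level.

**Context extraction.** The window spans the REF allele plus `flank`
(default 100) nucleotides on each side, measured from the first REF base
leftward and the last REF base rightward — the symmetric generalization
for multi-base alleles. Windows are clipped at contig ends, never
padded, and contexts shorter than one codon are dropped with a warning.
The mutated interval within the mutant window is the ALT span for SNVs
and insertions; for a pure deletion (ALT is the single anchor base) it
spans the junction — the anchor plus the first base after the join when
present — because a deletion creates novel sequence only at the join.
Each variant yields its own context: nearby somatic variants are not
phased into a joint haplotype, an approximation that errs toward
reporting both single-mutant forms.

**Peptide generation.** Translation uses the standard genetic code;
stops become `*`, codons containing `N` become `X`, and the trailing
partial codon is dropped. Fragments are maximal `*`-free substrings;
a fragment survives if it contains at least one mutation-derived
residue (a residue whose codon overlaps the mutated interval) and is at
least `min_length = 7` residues long. The length floor matches the
shortest peptide the MS search is configured to report, so the database
contains no unmatchable entries. `X` is kept as an ordinary residue
during generation but `X`-containing entries are excluded at database
construction, since search engines cannot match them. Identical peptide
sequences arising from different frames or variants are written once
with merged provenance, avoiding artificial database redundancy.

**Database and decoys.** The search database concatenates reference
proteome, cRAP contaminants and the mutant peptides as free-standing
entries (mutant fragments are independent sequences, not patches of
reference proteins). Decoys follow the pseudo-reverse convention
standard in proteomics: each tryptic segment is reversed in place with
its C-terminal K/R kept anchored, preserving cleavage-site positions,
entry length and composition, so decoy peptides are statistically
matched to targets. FDR control itself belongs to the search engine;
the package only re-implements the flag-based exclusion of decoy and
contaminant rows when parsing its output.

**MS validation.** An identified peptide validates a mutant entry when
it occurs as a substring overlapping at least one mutated offset.
Peptides that also occur verbatim anywhere in the reference proteome are
excluded: a peptide present in the normal proteome cannot serve as
evidence for a tumor-specific product, even if the search engine
assigned it to a mutant entry.

**Binding selection.** All 8–11-mers containing a mutated residue are
scored per HLA allele. The predictor is a pluggable contract
`(peptide, allele) → percentile rank`; two built-ins cover the common
cases — an adapter over NetMHCpan 4.1 tabular output, and a seeded mock
whose planted pairs score below 0.5 and all others at 10 or above,
enabling fully offline testing. Ranks are computed once per unique
(sequence, allele) pair and fanned back out to all parents. Candidates
require %rank strictly below 2; bind levels use the NetMHCpan
convention (SB < 0.5, WB < 2), which the percentile-rank scale implies
but which remains configurable. Percentile rank is preferred over IC50
throughout.

**Homology screen.** Queries are 8–11-mers, so heuristic seeding has no
value and the screen uses an exact affine-gap Smith–Waterman with
BLOSUM62 and BLAST-style gap costs (a gap of length $k$ costs
$11 + k$). Percent identity is `100 * n_identical / alignment_length`,
the BLAST `pident` convention. High confidence requires the best hit's
identity to be strictly above 60%. The native aligner does not compute
E-values — Karlin–Altschul calibration for short peptides is out of
scope — so the E-value < 0.5 condition is applied only when external
BLASTp tabular hits are supplied; the native path uses identity alone.
This is a deliberate asymmetry and is worth remembering when comparing
the two paths: the native screen is slightly more permissive.

**Reporting.** Allele frequencies are computed per locus over 2n
chromosomes (homozygous alleles count twice). The per-allele neoantigen
normalization divides total candidate records by the number of carrier
samples by default; dividing by allele copies instead is available via
`per = "copies"`, since either reading of "normalizing by the count of
HLA alleles" is defensible.

## Numerical and tie-breaking choices

* Coordinates are 0-based half-open in every data frame the package
  emits (`window_start`, `mut_start`/`mut_end`, `fragment_start`,
  `match_offset`, mutated offsets), the BED convention; VCF positions
  are 1-based at the parsing boundary only.
* The aligner's tie-break among equal-score local alignments is: most
  identical positions, then smallest query start, then longest
  alignment. The last key keeps zero-scoring flanking pairs (e.g. A:T
  under BLOSUM62) inside the reported alignment, mirroring BLAST's
  extension behaviour; identity statistics are propagated through the
  dynamic program, so the reported identity count is the maximum over
  all optimal alignments rather than an artifact of one traceback.
* The Wilcoxon rank-sum test used by the positive-vs-random evaluation
  is exact when both groups have at most 10 observations and no ties,
  and otherwise uses the normal approximation with tie and continuity
  correction.
* Annotation-table duplicate keys resolve to the first occurrence with
  a warning; equal normalized neoantigen counts order stably by allele
  name; database accession collisions are renamed with a numeric
  suffix.
* Degenerate inputs: an empty VCF body, an empty mutant peptide set, a
  recall-zero MS table and a candidate list below the minimum k-mer
  length all produce empty, well-typed results rather than errors; an
  empty immunogenic reference set is a configuration error.

## What the synthetic fixtures emulate — and what they do not

`make_fixture_bundle()` generates a uniform-composition toy genome (2 ×
5000 nt), plants spaced somatic variants (≥ 250 nt apart, so ±100 nt
contexts never overlap and the one-variant-per-context assumption holds
by construction), writes a VCF mixing PASS and non-PASS calls and an
annotation table mixing noncoding and `exonic` decoys, simulates the MS
stage by emitting tryptic peptides of mutant entries at a configurable
recall (plus flagged decoy and contaminant rows that parsing must
drop), plants strong binders through the seeded mock predictor, and
engineers the immunogenic reference set so that every planted binder
has a partner at 2 substitutions (3 for 11-mers) — comfortably above
the 60% identity rule. Expected high-confidence neoantigens are derived
by forward simulation of the deterministic generation stages, so the
end-to-end test checks conservation and exactness of the plumbing: 100%
recovery, zero false positives, and byte-identical reports across
reruns.

The fixtures do not emulate: realistic mutation signatures or rates,
sequencing reads or spectra, search-engine scoring and FDR behaviour,
real MHC binding landscapes (the mock predictor's rank distribution is
binary by design), or the sequence statistics of real immunogenic
peptide databases. A green suite therefore demonstrates correctness of
the decision rules and bookkeeping, not predictive performance on real
cohorts — the latter depends entirely on the external engines the
package abstracts away.

One consequence of best-score local alignment deserves emphasis:
unrelated short peptides routinely share a 2–3 residue perfect segment,
whose percent identity is 100. The screen's identity rule therefore
only has discriminative power in combination with the upstream rank
filter (few candidates reach it) or, on the BLAST path, the E-value
condition. This is why the fixtures' planted-truth guarantee engineers
partners for all planted binders rather than relying on random
reference peptides falling below the identity threshold.

## Problem sizes and runtime

The shipped tests and the acceptance script run entirely on synthetic
data at deliberately modest scale: 100 random contexts (≤ 60 nt) for
the peptide-generation oracle, all parent lengths up to 15 for the
k-mer oracle, 100 random sequences (≤ 30 residues) for the digestion
oracle, 200 random peptide pairs (≤ 11 residues) for the aligner
oracle, and end-to-end runs over 10–12 planted variants on a 10 kb
genome. These sizes keep a full run in tens of seconds on one core
while exercising every rule; all generators scale up through their
arguments if heavier randomized testing is wanted.

## Known limitations

* One variant per context: compound haplotypes within 100 nt are not
  represented.
* The native screen applies no minimum alignment length, so a
  high-identity short segment can dominate a best hit (see above).
* E-values are available only through the external BLAST adapter.
* Modification-aware search settings (fixed/variable modifications)
  configure the external engine and have no counterpart here.
* The per-allele normalization treats candidate records as the unit of
  counting; it does not model peptide sharing across alleles.
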