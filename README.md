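# noncneo

Proteogenomic discovery of candidate neoantigens arising from somatic
variants in **noncoding** genomic regions.

Most neoantigen predictors look only at coding exons, yet the large
majority of somatic mutations in tumors fall outside them, and peptides
translated from allegedly noncoding sequence are known to reach MHC
class I presentation. For tumor types with a low coding mutational
burden (hepatocellular carcinoma being the canonical example), the
noncoding genome is therefore an attractive additional source of
immunotherapy targets. `noncneo` implements the bespoke computational
stages of such a pipeline for R, keeping the heavyweight external tools
(read aligner, variant caller, MS search engine, MHC binding predictor,
BLAST) behind file formats and pluggable interfaces.

## What the pipeline computes

Starting from somatic variant calls and ending at a homology-screened
candidate list:

1. **Variant selection** — parse a Mutect2-style VCF, keep calls with
   `FILTER == "PASS"`, split multi-allelic records per ALT, join an
   Annovar-style annotation table and retain the ten noncoding
   functional categories (`downstream`, `intergenic`, `intronic`,
   `ncRNA_exonic`, `ncRNA_intronic`, `ncRNA_splicing`, `splicing`,
   `upstream`, `UTR3`, `UTR5`).
2. **Context extraction** — take 100 nt of reference sequence on each
   side of the mutation, substitute REF → ALT, and track the mutated
   interval through the substitution.
3. **Peptide generation** — translate each mutant context in all six
   reading frames, replace stop codons with `*`, split on `*`, and keep
   fragments of ≥ 7 residues that contain at least one mutated residue.
4. **Customized search database** — reference proteome + laboratory
   contaminants (cRAP) + mutant peptides, with pseudo-reversed tryptic
   decoys (`REV_` entries; per-segment reversal keeps C-terminal K/R
   anchored so cleavage positions and composition are preserved).
5. **MS validation** — parse a MaxQuant `peptides.txt`-style table
   (dropping `Reverse` and `Potential contaminant` rows), match
   identified peptides back to mutant entries requiring overlap with a
   mutated residue, and discard peptides that also occur verbatim in the
   reference proteome (not cancer-specific).
6. **Binding selection** — enumerate all mutated 8–11-mers, score each
   (peptide, HLA allele) pair with a pluggable percentile-rank predictor
   (NetMHCpan 4.1 output files are supported; a seeded mock enables
   offline testing), label bind levels (SB < 0.5 ≤ WB < 2 ≤ NB) and
   retain candidates with %rank < 2 (strict).
7. **Homology screen** — align every candidate against a set of
   experimentally immunogenic peptides with an exact affine-gap
   Smith–Waterman (BLOSUM62, gap open 11 / extend 1) and flag
   **high-confidence** neoantigens whose best hit exceeds 60% identity
   (strict). External BLASTp `-outfmt 6` hits can substitute for the
   native aligner, in which case an E-value < 0.5 condition is enforced
   as well.
8. **Reporting** — per-locus HLA allele frequencies over 2n chromosomes,
   carrier-normalized neoantigen counts per allele, shared-item tables
   and per-stage record counts.

A deterministic fixtures module (`make_fixture_bundle()`) generates every
input synthetically, with planted ground truth, so the whole pipeline is
testable without any external data or tools.

## Worked example

```r
library(noncneo)

bundle <- make_fixture_bundle(seed = 3, dir = tempfile())
run <- run_fixture_pipeline(bundle)
print(run)
#> noncneo pipeline run, sample S1
#>   noncoding_variants           7
#>   contexts                     7
#>   mutant_peptides              37
#>   validated_peptides           115
#>   candidate_records            18
#>   high_confidence_neoantigens  7

head(run$report[, c("kmer", "allele", "percentile_rank", "bind_level",
                    "best_ref", "percent_identity", "high_confidence")], 3)
#>        kmer      allele percentile_rank bind_level  best_ref percent_identity high_confidence
#> 1 TLCCAVARQ HLA-B*35:01      0.01424358         SB TLCCIVYRQ         77.77778            TRUE
#> 2 TLCCAVARQ HLA-B*35:01      0.01424358         SB TLCCIVYRQ         77.77778            TRUE
#> 3 THVPTRSTP HLA-B*58:01      0.07398976         SB THIPTQSTP         77.77778            TRUE
```

Reading the output: of 12 planted variants, 7 are PASS noncoding
mutations (5 SNVs and 2 indels); six-frame translation yields 37 mutant
database entries; with full simulated MS recall, 115 distinct tryptic
peptides validate them; the planted strong binders give 18 candidate
(peptide, allele) records below %rank 2, and the homology screen
recovers exactly the 7 planted neoantigens — each matching an engineered
reference partner at 7/9 ≈ 77.8% identity. Real runs substitute a real
genome, VCF, proteome, MaxQuant table, HLA typings, NetMHCpan
predictions and an immunogenic peptide database (e.g. the 746-peptide
dbPepNeo2.0 set) through the same functions or the command-line wrapper
in `inst/cli/noncneo.R`.

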