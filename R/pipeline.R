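# End-to-end orchestration: files in, neoantigen report out.

#' Run the full noncoding-neoantigen pipeline
#'
#' Chains every stage: PASS-variant parsing, annotation join, noncoding
#' filtering, context extraction, six-frame mutant peptide generation,
#' customized database construction, MS-identified peptide matching,
#' mutated 8-11-mer enumeration, percentile-rank binding selection and the
#' homology screen.  All heavyweight external tools (aligner, variant
#' caller, search engine, MHC predictor) stay outside: their outputs enter
#' through the file formats parsed here, and the MHC predictor through the
#' `predictor` callable.
#'
#' @param vcf somatic VCF path ([parse_somatic_vcf()]).
#' @param annotation annotation table path or data frame
#'   ([read_annotation_table()]).
#' @param genome genome FASTA path or `DNAStringSet`.
#' @param reference_proteome,contaminants FASTA paths or data frames from
#'   [read_fasta_entries()].
#' @param ms_table MS search peptide table path
#'   ([parse_identified_peptides()]).
#' @param typing data frame with `sample_id`, `allele`
#'   ([read_allele_list()]).
#' @param predictor percentile-rank predictor callable
#'   ([predict_binding()]).
#' @param reference_set immunogenic reference peptides
#'   ([read_reference_set()] output, a character vector, or a path).
#' @param sample_id sample label.
#' @param flank context flank in nucleotides (default 100).
#' @param min_length minimum peptide length (default 7).
#' @param rank_threshold candidate percentile-rank cutoff (default 2).
#' @param identity_threshold homology-screen identity cutoff (default 60).
#' @param sb,wb bind-level thresholds (defaults 0.5, 2).
#' @return A `noncneo_run` object: list with every intermediate
#'   (`variants`, `annotated`, `noncoding_variants`, `contexts`,
#'   `mutant_peptides`, `database`, `identified`, `validated`, `kmers`,
#'   `predictions`, `candidates`, `report`) plus `stage_counts`.
#' @export
run_pipeline <- function(vcf, annotation, genome, reference_proteome,
                         contaminants, ms_table, typing, predictor,
                         reference_set, sample_id,
                         flank = 100L, min_length = 7L,
                         rank_threshold = 2.0, identity_threshold = 60.0,
                         sb = 0.5, wb = 2.0) {
  if (is.character(annotation)) annotation <- read_annotation_table(annotation)
  if (is.character(reference_proteome))
    reference_proteome <- read_fasta_entries(reference_proteome, "reference")
  if (is.character(contaminants))
    contaminants <- read_fasta_entries(contaminants, "contaminant")
  if (is.character(reference_set) && length(reference_set) == 1L &&
      file.exists(reference_set))
    reference_set <- read_reference_set(reference_set)

  run <- list(sample_id = sample_id)
  run$variants <- parse_somatic_vcf(vcf, sample_id)
  run$annotated <- join_annotations(run$variants, annotation)
  run$noncoding_variants <- filter_noncoding(run$annotated)
  run$contexts <- extract_context(genome, run$noncoding_variants, flank)
  run$mutant_peptides <- generate_mutant_peptides(run$contexts, min_length)
  run$database <- build_custom_database(reference_proteome, contaminants,
                                        run$mutant_peptides)
  run$identified <- parse_identified_peptides(ms_table)
  run$validated <- match_identified_to_mutant(
    run$identified,
    run$database[run$database$origin == "mutant", , drop = FALSE],
    run$database[run$database$origin == "reference", , drop = FALSE])
  run$kmers <- enumerate_kmers(run$validated)
  run$predictions <- predict_binding(run$kmers, typing, predictor,
                                     sb = sb, wb = wb)
  run$candidates <- filter_candidates(run$predictions, rank_threshold)
  run$report <- screen_candidates(run$candidates, reference_set,
                                  identity_threshold)
  class(run) <- "noncneo_run"
  run$stage_counts <- stage_counts(run)
  run
}

#' @export
print.noncneo_run <- function(x, ...) {
  cat("noncneo pipeline run, sample", x$sample_id, "\n")
  sc <- x$stage_counts
  for (i in seq_len(nrow(sc)))
    cat(sprintf("  %-28s %d\n", sc$stage[i], sc$count[i]))
  invisible(x)
}

#' Write a pipeline run as deterministic TSV reports
#'
#' Writes `neoantigens.tsv` (the screened report), `candidates.tsv` and
#' `stage_counts.tsv`.  Output bytes depend only on the run object, so
#' identical runs give identical files.
#'
#' @param run a `noncneo_run` object.
#' @param dir output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_run_report <- function(run, dir) {
  stopifnot(inherits(run, "noncneo_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "neoantigens.tsv"),
             file.path(dir, "candidates.tsv"),
             file.path(dir, "stage_counts.tsv"))
  rep <- run$report
  num <- vapply(rep, is.numeric, TRUE)
  rep[num] <- lapply(rep[num], function(v) formatC(v, digits = 6, format = "g"))
  write_tsv(rep, paths[1L])
  write_tsv(run$candidates, paths[2L])
  write_tsv(run$stage_counts, paths[3L])
  invisible(paths)
}
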