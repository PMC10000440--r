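# Cohort-level summaries: HLA allele frequencies, carrier-normalized
# neoantigen counts, shared items and per-stage record counts.

.hla_locus <- function(allele) sub("^HLA-([A-Z0-9]+)\\*.*$", "\\1", allele)

#' HLA class I allele frequencies over a cohort
#'
#' Frequencies are computed per locus over 2n chromosomes: the typing
#' table carries one row per chromosome, so a homozygous allele appears
#' twice per sample and counts twice.
#'
#' @param typings data frame with columns `sample_id` and `allele`
#'   (one row per chromosome).
#' @return Data frame with columns `allele`, `locus`, `occurrence`,
#'   `carrier_count` (samples carrying the allele) and `frequency`
#'   (occurrence / 2n samples), sorted by descending frequency then
#'   allele name.
#' @export
allele_frequencies <- function(typings) {
  if (is.null(typings) || nrow(typings) == 0L)
    stop("at least one sample typing is required")
  n <- length(unique(typings$sample_id))
  occ <- table(typings$allele)
  carriers <- vapply(names(occ), function(a)
    length(unique(typings$sample_id[typings$allele == a])), 1L)
  out <- data.frame(allele = names(occ), locus = .hla_locus(names(occ)),
                    occurrence = as.integer(occ),
                    carrier_count = as.integer(carriers),
                    frequency = as.integer(occ) / (2 * n),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Carrier-normalized neoantigen counts per HLA allele
#'
#' Counts candidate (peptide, allele) records per allele and divides by
#' the number of samples carrying the allele (default) or by the number
#' of allele copies, ranking alleles by normalized count (the top-10 view
#' is the usual cohort figure).  Ties order stably by allele name.
#'
#' @param candidates data frame with an `allele` column (one row per
#'   candidate record).
#' @param typings cohort typing table as in [allele_frequencies()].
#' @param per divide by `"carrier"` samples (default) or allele
#'   `"copies"`.
#' @return Data frame with columns `allele`, `carrier_count`,
#'   `candidate_count`, `normalized_count`, sorted descending.
#' @export
normalized_neoantigen_counts <- function(candidates, typings,
                                         per = c("carrier", "copies")) {
  per <- match.arg(per)
  freq <- allele_frequencies(typings)
  unknown <- setdiff(unique(candidates$allele), freq$allele)
  if (length(unknown))
    stop("consistency error: candidate allele(s) carried by no sample: ",
         paste(unknown, collapse = ", "))
  cc <- table(candidates$allele)
  out <- data.frame(allele = freq$allele, carrier_count = freq$carrier_count,
                    candidate_count = as.integer(
                      ifelse(freq$allele %in% names(cc),
                             cc[freq$allele], 0L)),
                    stringsAsFactors = FALSE)
  denom <- if (per == "carrier") out$carrier_count else freq$occurrence
  out$normalized_count <- out$candidate_count / denom
  out <- out[order(-out$normalized_count, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Items shared across samples
#'
#' Lists the items (neoantigen sequences, gene symbols, ...) present in
#' at least `min_samples` of the per-sample sets, with their carriers.
#'
#' @param per_sample_sets named list of character vectors, one per
#'   sample.
#' @param min_samples minimum number of carrying samples (default 2).
#' @return Data frame with columns `item`, `n_samples`, `samples`
#'   (semicolon-joined), sorted by descending `n_samples` then item.
#' @export
shared_items <- function(per_sample_sets, min_samples = 2L) {
  stopifnot(is.list(per_sample_sets), !is.null(names(per_sample_sets)))
  long <- data.frame(
    sample = rep(names(per_sample_sets),
                 vapply(per_sample_sets, function(x) length(unique(x)), 1L)),
    item = unlist(lapply(per_sample_sets, unique), use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(long) == 0L)
    return(.empty_df(item = character(), n_samples = integer(),
                     samples = character()))
  sp <- split(long$sample, long$item)
  out <- data.frame(item = names(sp),
                    n_samples = vapply(sp, length, 1L),
                    samples = vapply(sp, function(s)
                      paste(sort(s), collapse = ";"), character(1)),
                    stringsAsFactors = FALSE)
  out <- out[out$n_samples >= min_samples, , drop = FALSE]
  out <- out[order(-out$n_samples, out$item), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-stage record counts of a pipeline run
#'
#' @param run a `noncneo_run` object from [run_pipeline()].
#' @return Data frame with one row per stage (`stage`, `count`), in
#'   pipeline order: noncoding mutations, extracted contexts, mutant
#'   peptides, MS-validated peptides, candidate records and
#'   high-confidence neoantigens.
#' @export
stage_counts <- function(run) {
  stopifnot(inherits(run, "noncneo_run"))
  data.frame(
    stage = c("noncoding_variants", "contexts", "mutant_peptides",
              "validated_peptides", "candidate_records",
              "high_confidence_neoantigens"),
    count = c(nrow(run$noncoding_variants), nrow(run$contexts),
              sum(run$database$origin == "mutant"),
              length(unique(run$validated$sequence)),
              nrow(run$candidates),
              length(unique(run$report$kmer[run$report$high_confidence]))),
    stringsAsFactors = FALSE)
}
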