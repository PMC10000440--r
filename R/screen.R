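# Homology screen of candidate neoantigens against a reference set of
# experimentally immunogenic peptides, and the positive-vs-random
# similarity evaluation.

.as_ref_set <- function(reference_set) {
  if (is.data.frame(reference_set)) reference_set <- reference_set$sequence
  reference_set <- toupper(as.character(reference_set))
  if (length(reference_set) == 0L)
    stop("configuration error: reference peptide set is empty")
  unique(reference_set)
}

#' Read a reference peptide set
#'
#' One peptide per line, or FASTA when the first non-blank line starts
#' with `>`.
#'
#' @param path text or FASTA file.
#' @return Character vector of peptide sequences.
#' @export
read_reference_set <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1L], ">"))
    return(unname(toupper(as.character(Biostrings::readAAStringSet(path)))))
  toupper(lines)
}

# best hit of one peptide against the reference set via the native
# aligner: best score, then most identities, then reference order
.best_hit <- function(peptide, refs) {
  best <- NULL
  for (r in refs) {
    a <- local_align(peptide, r)
    if (is.null(best) ||
        a$score > best$score ||
        (a$score == best$score && a$n_identical > best$n_identical)) best <- a
  }
  best
}

#' Parse BLASTp tabular output (-outfmt 6)
#'
#' Standard 12-column tabular format; used as the external-aligner
#' adapter, and the only path on which the E-value condition can be
#' applied (the native aligner does not compute E-values).
#'
#' @param path tabular BLAST output file (no header).
#' @return Data frame with the standard columns `qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`.
#' @export
parse_blast_outfmt6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 12L)
    stop("BLAST tabular format error: expected 12 columns")
  tab <- tab[, 1:12]
  names(tab) <- cols
  tab
}

# per-peptide similarity indicator against a reference set.
# native path: best-hit identity only; with BLAST hits: identity and
# E-value condition together.
.similar_to_set <- function(peptides, refs, identity_threshold,
                            hits = NULL, evalue_max = 0.5) {
  if (!is.null(hits)) {
    ok <- hits$pident > identity_threshold & hits$evalue < evalue_max
    return(peptides %in% unique(hits$qseqid[ok]))
  }
  vapply(peptides, function(p)
    .best_hit(p, refs)$percent_identity > identity_threshold, TRUE,
    USE.NAMES = FALSE)
}

#' Screen candidates against immunogenic reference peptides
#'
#' Aligns every candidate peptide against every reference peptide, keeps
#' the best hit (highest score, then most identities) and flags the
#' candidate high-confidence when the best hit's percent identity is
#' strictly above `identity_threshold`.  When external BLAST tabular hits
#' are supplied they replace the native aligner, and the E-value
#' condition (`evalue < evalue_max`) is additionally enforced.
#'
#' @param candidates data frame from [filter_candidates()] (column
#'   `kmer`, plus provenance columns carried through).
#' @param reference_set character vector (or data frame with a `sequence`
#'   column) of immunogenic reference peptides.
#' @param identity_threshold percent-identity cutoff, strict (default 60).
#' @param blast_hits optional data frame from [parse_blast_outfmt6()]
#'   with `qseqid` equal to the candidate peptide sequences.
#' @param evalue_max E-value cutoff used only with `blast_hits`
#'   (default 0.5).
#' @return `candidates` with appended columns `best_ref`, `score`,
#'   `n_identical`, `alignment_length`, `percent_identity`, `evalue`,
#'   `high_confidence`; rows sorted by percentile rank then identity
#'   (descending).
#' @export
screen_candidates <- function(candidates, reference_set,
                              identity_threshold = 60.0,
                              blast_hits = NULL, evalue_max = 0.5) {
  refs <- .as_ref_set(reference_set)
  peptides <- unique(candidates$kmer)
  if (is.null(blast_hits)) {
    info <- lapply(peptides, function(p) {
      h <- .best_hit(p, refs)
      data.frame(kmer = p, best_ref = if (h$score > 0) h$target else NA_character_,
                 score = h$score, n_identical = h$n_identical,
                 alignment_length = h$alignment_length,
                 percent_identity = h$percent_identity, evalue = NA_real_,
                 stringsAsFactors = FALSE)
    })
    info <- do.call(rbind, info)
    info$high_confidence <- info$percent_identity > identity_threshold
  } else {
    info <- data.frame(kmer = peptides, best_ref = NA_character_, score = NA_real_,
                       n_identical = NA_integer_, alignment_length = NA_integer_,
                       percent_identity = 0, evalue = NA_real_,
                       stringsAsFactors = FALSE)
    for (i in seq_along(peptides)) {
      h <- blast_hits[blast_hits$qseqid == peptides[i], , drop = FALSE]
      if (nrow(h)) {
        h <- h[order(-h$bitscore, -h$pident), , drop = FALSE][1L, ]
        info$best_ref[i] <- h$sseqid
        info$score[i] <- h$bitscore
        info$n_identical[i] <- as.integer(round(h$pident * h$length / 100))
        info$alignment_length[i] <- h$length
        info$percent_identity[i] <- h$pident
        info$evalue[i] <- h$evalue
      }
    }
    info$high_confidence <- .similar_to_set(peptides, refs, identity_threshold,
                                            hits = blast_hits,
                                            evalue_max = evalue_max)
  }
  out <- merge(candidates, info, by = "kmer", sort = FALSE)
  ord <- order(out$percentile_rank, -out$percent_identity, out$kmer, out$allele)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum test for similarity proportions
#'
#' Two-sided rank-sum test: exact enumeration when both groups have at
#' most 10 observations and there are no ties, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y numeric vectors of per-group similarity proportions.
#' @return An `htest` object from [stats::wilcox.test()].
#' @examples
#' similarity_wilcoxon(c(1, 2, 3), c(4, 5, 6))$p.value   # exactly 0.1
#' @export
similarity_wilcoxon <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L)
    stop("each group needs at least one observation")
  exact <- length(x) <= 10L && length(y) <= 10L && !anyDuplicated(c(x, y))
  suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
}

#' Positive-vs-random similarity evaluation
#'
#' Compares, per sample, the proportion of candidate peptides similar to
#' an experimentally immunogenic positive set against the proportion
#' similar to a random background set, and tests the two proportion
#' distributions with a two-sided Wilcoxon rank-sum test
#' ([similarity_wilcoxon()]).  Similarity means best-hit identity strictly
#' above `identity_threshold`; when BLAST tabular hits are supplied the
#' E-value condition (`evalue < evalue_max`) is enforced as well.
#'
#' @param candidates data frame with columns `kmer` and `sample_id`.
#' @param positive_set,random_set peptide sets (character vectors or data
#'   frames with a `sequence` column).
#' @param identity_threshold percent-identity cutoff, strict (default 60).
#' @param evalue_max E-value cutoff, applied on the BLAST path
#'   (default 0.5).
#' @param positive_hits,random_hits optional [parse_blast_outfmt6()]
#'   tables for the two sets.
#' @return List with elements `proportions` (data frame: `sample_id`,
#'   `prop_positive`, `prop_random`), `p.value`, `statistic`, `test`
#'   (the full `htest`).
#' @export
evaluate_positive_vs_random <- function(candidates, positive_set, random_set,
                                        identity_threshold = 60.0,
                                        evalue_max = 0.5,
                                        positive_hits = NULL,
                                        random_hits = NULL) {
  stopifnot(all(c("kmer", "sample_id") %in% names(candidates)))
  pos <- .as_ref_set(positive_set)
  rnd <- .as_ref_set(random_set)
  peptides <- unique(candidates$kmer)
  sim_pos <- .similar_to_set(peptides, pos, identity_threshold,
                             hits = positive_hits, evalue_max = evalue_max)
  sim_rnd <- .similar_to_set(peptides, rnd, identity_threshold,
                             hits = random_hits, evalue_max = evalue_max)
  names(sim_pos) <- names(sim_rnd) <- peptides
  sp <- split(candidates$kmer, candidates$sample_id)
  props <- do.call(rbind, lapply(names(sp), function(s) {
    u <- unique(sp[[s]])
    data.frame(sample_id = s,
               prop_positive = mean(sim_pos[u]),
               prop_random = mean(sim_rnd[u]),
               stringsAsFactors = FALSE)
  }))
  ht <- similarity_wilcoxon(props$prop_positive, props$prop_random)
  list(proportions = props, p.value = ht$p.value,
       statistic = unname(ht$statistic), test = ht)
}
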