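# Six-frame translation of mutant contexts and assembly of stop-free,
# mutation-containing peptide fragments.

.FRAMES <- c(1L, 2L, 3L, -1L, -2L, -3L)

.check_frame <- function(frame) {
  if (length(frame) != 1L || !frame %in% .FRAMES)
    stop("invalid frame label: must be one of +1,+2,+3,-1,-2,-3")
}

#' Translate one reading frame
#'
#' Translates `nt_seq` in the requested frame under the standard genetic
#' code.  Stop codons become `*`; codons containing `N` become `X`; the
#' trailing partial codon is ignored.  Minus frames translate the reverse
#' complement at the corresponding offset, so frame -1 starts at the first
#' base of the reverse complement.
#'
#' @param nt_seq nucleotide string over A/C/G/T/N.
#' @param frame integer in `{1, 2, 3, -1, -2, -3}`.
#' @return Amino-acid string (possibly containing `*` and `X`).
#' @examples
#' translate_frame("ATGAAATAG", 1)   # "MK*"
#' translate_frame("ATGAAATAG", -1)  # "LFH"
#' @export
translate_frame <- function(nt_seq, frame) {
  .check_frame(frame)
  stopifnot(is.character(nt_seq), length(nt_seq) == 1L)
  if (grepl("[^ACGTN]", nt_seq))
    stop("alphabet error: sequence contains characters outside A/C/G/T/N")
  s <- if (frame < 0L) reverse_complement(nt_seq) else nt_seq
  off <- abs(frame) - 1L
  L <- nchar(s)
  naa <- (L - off) %/% 3L
  if (naa <= 0L) return("")
  starts <- off + 1L + 3L * (seq_len(naa) - 1L)
  codons <- substring(s, starts, starts + 2L)
  aa <- .codon_table()[codons]
  aa[is.na(aa)] <- "X"          # codons containing N
  paste(aa, collapse = "")
}

# standard genetic code as a codon -> residue lookup, cached
.translate_env <- new.env(parent = emptyenv())

.codon_table <- function() {
  if (is.null(.translate_env$code))
    .translate_env$code <- Biostrings::GENETIC_CODE
  .translate_env$code
}

#' Map a mutated nucleotide interval to residue indices
#'
#' Given the 0-based half-open mutated interval `[a, b)` within a sequence
#' of length `seq_len`, returns the 0-based indices of the residues of the
#' frame translation whose codons overlap the interval.  For minus frames
#' the interval is first mapped into reverse-complement coordinates
#' `[seq_len - b, seq_len - a)`.
#'
#' @param mut_interval integer vector `c(a, b)`, 0-based half-open.
#' @param seq_len length of the nucleotide sequence.
#' @param frame integer in `{1, 2, 3, -1, -2, -3}`.
#' @return Sorted integer vector of 0-based residue indices.
#' @export
map_mutated_residues <- function(mut_interval, seq_len, frame) {
  .check_frame(frame)
  a <- mut_interval[1L]
  b <- mut_interval[2L]
  stopifnot(a >= 0L, b > a, b <= seq_len)
  if (frame < 0L) {
    tmp <- seq_len - b
    b <- seq_len - a
    a <- tmp
  }
  off <- abs(frame) - 1L
  naa <- (seq_len - off) %/% 3L
  res <- (seq(a, b - 1L) - off) %/% 3L
  sort(unique(res[res >= 0L & res < naa]))
}

#' Split a frame translation on stop codons
#'
#' Fragments are the maximal `*`-free substrings of the translation, each
#' carrying the mutated residue indices that fall inside it, re-indexed to
#' fragment coordinates.
#'
#' @param aa_seq amino-acid string possibly containing `*`.
#' @param mutated_residues integer vector of 0-based residue indices.
#' @return Data frame with columns `fragment`, `fragment_start` (0-based
#'   offset within `aa_seq`) and `mutated_offsets` (comma-separated 0-based
#'   indices within the fragment, `""` when none).
#' @export
fragment_on_stops <- function(aa_seq, mutated_residues = integer(0)) {
  stopifnot(is.character(aa_seq), length(aa_seq) == 1L)
  m <- gregexpr("[^*]+", aa_seq)[[1]]
  if (m[1L] == -1L)
    return(.empty_df(fragment = character(), fragment_start = integer(),
                     mutated_offsets = character()))
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  frag <- substring(aa_seq, starts + 1L, starts + lens)
  muts <- vapply(seq_along(starts), function(i) {
    inside <- mutated_residues[mutated_residues >= starts[i] &
                                 mutated_residues < starts[i] + lens[i]]
    .offsets_chr(inside - starts[i])
  }, character(1))
  data.frame(fragment = frag, fragment_start = starts,
             mutated_offsets = muts, stringsAsFactors = FALSE)
}

#' Generate mutant peptides from one or more contexts
#'
#' Composes six-frame translation, mutated-residue mapping and stop-codon
#' fragmentation for every context row, then keeps fragments that contain
#' at least one mutated residue and are at least `min_length` residues
#' long.  Identical peptide sequences arising from different frames or
#' variants are emitted once, with the provenance of every contributing
#' (variant, frame, fragment) retained.  Fragments may contain `X`
#' (ambiguous codons); these are excluded later, at database construction.
#'
#' @param contexts data frame from [extract_context()].
#' @param min_length minimum fragment length in residues (default 7, the
#'   shortest peptide the downstream MS search is configured to report).
#' @return Data frame with columns `sequence`, `variant_id`, `frame`,
#'   `fragment_start`, `mutated_offsets` (0-based, within `sequence`),
#'   `gene`, `sample_id`, `provenance`
#'   (semicolon-joined `variant|frame|fragment_start` for every source)
#'   and `n_sources`.
#' @export
generate_mutant_peptides <- function(contexts, min_length = 7L) {
  rows <- list()
  for (i in seq_len(nrow(contexts))) {
    ctx <- contexts[i, ]
    L <- nchar(ctx$mut_window)
    for (f in .FRAMES) {
      aa <- translate_frame(ctx$mut_window, f)
      if (!nzchar(aa)) next
      mres <- map_mutated_residues(c(ctx$mut_start, ctx$mut_end), L, f)
      frags <- fragment_on_stops(aa, mres)
      keep <- nzchar(frags$mutated_offsets) & nchar(frags$fragment) >= min_length
      if (!any(keep)) next
      frags <- frags[keep, , drop = FALSE]
      frags$variant_id <- ctx$variant_id
      frags$frame <- f
      frags$gene <- if ("gene" %in% names(ctx)) ctx$gene else NA_character_
      frags$sample_id <- if ("sample_id" %in% names(ctx)) ctx$sample_id else NA_character_
      rows[[length(rows) + 1L]] <- frags
    }
  }
  if (!length(rows))
    return(.empty_df(sequence = character(), variant_id = character(),
                     frame = integer(), fragment_start = integer(),
                     mutated_offsets = character(), gene = character(),
                     sample_id = character(), provenance = character(),
                     n_sources = integer()))
  all <- do.call(rbind, rows)
  all$provenance <- sprintf("%s|F%+d|%d", all$variant_id, all$frame,
                            all$fragment_start)
  # deduplicate on sequence, merging provenance; first occurrence is primary
  first <- !duplicated(all$fragment)
  out <- all[first, , drop = FALSE]
  prov <- vapply(split(all$provenance, all$fragment), paste, character(1),
                 collapse = ";")
  nsrc <- vapply(split(all$provenance, all$fragment), length, 1L)
  out$provenance <- unname(prov[out$fragment])
  out$n_sources <- unname(nsrc[out$fragment])
  names(out)[names(out) == "fragment"] <- "sequence"
  rownames(out) <- NULL
  out[, c("sequence", "variant_id", "frame", "fragment_start",
          "mutated_offsets", "gene", "sample_id", "provenance", "n_sources")]
}

#' Write mutant peptides as FASTA
#'
#' Headers follow `<variant_id>|F<frame>|frag<fragment_start>|mut=<offsets>`.
#'
#' @param peptides data frame from [generate_mutant_peptides()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(peptides, path) {
  seqs <- Biostrings::AAStringSet(peptides$sequence)
  names(seqs) <- sprintf("%s|F%+d|frag%d|mut=%s", peptides$variant_id,
                         peptides$frame, peptides$fragment_start,
                         peptides$mutated_offsets)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
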