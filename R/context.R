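# Mutant sequence context extraction: the +/-100 nt window around each
# noncoding variant with the REF allele replaced by ALT, tracking which
# bases of the mutant window are mutation-derived.

.load_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    g <- Biostrings::readDNAStringSet(genome)
    # keep only the first whitespace-delimited token of each FASTA header
    names(g) <- sub("\\s.*", "", names(g))
    return(g)
  }
  stop("genome must be a DNAStringSet or a path to a FASTA file")
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq character vector of sequences over A/C/G/T/N.
#' @return Character vector of reverse complements (`N` maps to `N`).
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("alphabet error: sequence contains characters outside A/C/G/T/N")
  out <- character(length(seq))
  nz <- nzchar(seq)
  if (any(nz))
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[nz])))
  out
}

#' Extract mutant sequence contexts around variants
#'
#' For each variant a reference window of `flank` nucleotides on each side
#' of the REF allele is extracted (0-based half-open genomic interval
#' `[pos-1-flank, pos-1+nchar(ref)+flank)`, clipped to the contig), the
#' REF substring is replaced by ALT, and the mutation-derived interval
#' within the mutant window is recorded as a 0-based half-open interval
#' `[mut_start, mut_end)`.  For a pure deletion (ALT is the single anchor
#' base) the interval spans the junction: the anchor base plus the first
#' base after the join, when available.  Windows shorter than one codon
#' after clipping are dropped with a warning.
#'
#' Genome bases are uppercased before comparison; a mismatch between the
#' genome and the REF allele is an error naming the contig and position.
#'
#' @param genome `DNAStringSet` or path to a (optionally soft-masked)
#'   genome FASTA.
#' @param variants data frame with columns `variant_id`, `contig`, `pos`,
#'   `ref`, `alt` (e.g. from [filter_noncoding()]).
#' @param flank nucleotides to take on each side of the REF allele
#'   (default 100).
#' @return Data frame with columns `variant_id`, `contig`, `window_start`
#'   (0-based), `ref_window`, `mut_window`, `mut_start`, `mut_end`,
#'   `flank`, plus `gene` and `sample_id` when present in the input.
#' @export
extract_context <- function(genome, variants, flank = 100L) {
  stopifnot(flank >= 1L)
  g <- .load_genome(genome)
  n <- nrow(variants)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    if (!v$contig %in% names(g))
      stop("lookup error: contig '", v$contig, "' absent from genome")
    ctg <- g[[v$contig]]
    L <- length(ctg)
    nref <- nchar(v$ref)
    start1 <- max(1L, v$pos - flank)
    end1 <- min(L, v$pos + nref - 1L + flank)
    ref_window <- toupper(as.character(Biostrings::subseq(ctg, start1, end1)))
    voff <- v$pos - start1                       # 0-based offset of REF in window
    seen <- substr(ref_window, voff + 1L, voff + nref)
    if (!identical(seen, toupper(v$ref)))
      stop("reference mismatch at ", v$contig, ":", v$pos,
           ": genome has '", seen, "', variant REF is '", v$ref, "'")
    mut_window <- paste0(substr(ref_window, 1L, voff), v$alt,
                         substr(ref_window, voff + nref + 1L, nchar(ref_window)))
    a <- voff
    nalt <- nchar(v$alt)
    if (nref > nalt && nalt == 1L) {
      # deletion junction: anchor base plus one base past the join if present
      b <- min(a + 2L, nchar(mut_window))
    } else {
      b <- a + nalt
    }
    rows[[i]] <- data.frame(
      variant_id = v$variant_id, contig = v$contig,
      window_start = start1 - 1L,
      ref_window = ref_window, mut_window = mut_window,
      mut_start = a, mut_end = b, flank = as.integer(flank),
      gene = if ("gene" %in% names(v)) v$gene else NA_character_,
      sample_id = if ("sample_id" %in% names(v)) v$sample_id else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- .empty_df(variant_id = character(), contig = character(),
                     window_start = integer(), ref_window = character(),
                     mut_window = character(), mut_start = integer(),
                     mut_end = integer(), flank = integer(),
                     gene = character(), sample_id = character())
  short <- nchar(out$mut_window) < 3L
  if (any(short)) {
    warning(sum(short), " context(s) shorter than one codon dropped")
    out <- out[!short, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write mutant contexts as FASTA
#'
#' Headers follow
#' `<variant_id>|<contig>:<window_start>|mut=<mut_start>-<mut_end>`.
#'
#' @param contexts data frame from [extract_context()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_context_fasta <- function(contexts, path) {
  seqs <- Biostrings::DNAStringSet(contexts$mut_window)
  names(seqs) <- sprintf("%s|%s:%d|mut=%d-%d", contexts$variant_id,
                         contexts$contig, contexts$window_start,
                         contexts$mut_start, contexts$mut_end)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
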