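# Customized proteomic search database: reference proteome + laboratory
# contaminants + mutant peptides, with pseudo-reversed tryptic decoys and
# in-silico tryptic digestion.

#' Read FASTA entries as database records
#'
#' @param path FASTA file.
#' @param origin origin label for every entry (`"reference"`,
#'   `"contaminant"`, ...).
#' @return Data frame with columns `accession` (first header token),
#'   `sequence`, `origin`.
#' @export
read_fasta_entries <- function(path, origin = "reference") {
  s <- Biostrings::readAAStringSet(path)
  data.frame(accession = sub("\\s.*", "", names(s)),
             sequence = toupper(as.character(s)),
             origin = origin, stringsAsFactors = FALSE, row.names = NULL)
}

# 0-based half-open boundaries of tryptic segments: cleave after K/R
# unless the next residue is P
.tryptic_boundaries <- function(sequence) {
  L <- nchar(sequence)
  if (L == 0L) return(integer(0))
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cut <- which(res[-L] %in% c("K", "R") & res[-1L] != "P")
  c(0L, cut, L)
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P and returns all
#' peptides with up to `max_missed` missed cleavage sites and at least
#' `min_length` residues, with their positions.
#'
#' @param sequence amino-acid string.
#' @param max_missed maximum internal (missed) cleavage sites (default 2).
#' @param min_length minimum peptide length (default 7).
#' @return Data frame with columns `peptide`, `start` (0-based), `end`
#'   (half-open) and `missed`.
#' @examples
#' digest_tryptic("AAAKBBBRCCC", max_missed = 2, min_length = 3)
#' @export
digest_tryptic <- function(sequence, max_missed = 2L, min_length = 7L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  bnd <- .tryptic_boundaries(sequence)
  nseg <- length(bnd) - 1L
  out <- list()
  for (i in seq_len(nseg)) {
    for (j in i:min(nseg, i + max_missed)) {
      a <- bnd[i]
      b <- bnd[j + 1L]
      if (b - a >= min_length)
        out[[length(out) + 1L]] <- data.frame(
          peptide = substr(sequence, a + 1L, b), start = a, end = b,
          missed = j - i, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(.empty_df(peptide = character(), start = integer(),
                     end = integer(), missed = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the customized search database
#'
#' Concatenates reference proteins, contaminant proteins and mutant
#' peptides into a single target database with origin tags.  Mutant
#' peptides are deduplicated by sequence; entries containing `X` or `*`
#' are excluded with a warning (a search engine cannot match them);
#' accessions duplicated across sections are renamed with a numeric
#' suffix, with a warning.  Mutant accessions are derived
#' deterministically from the peptide provenance.
#'
#' @param reference_entries,contaminant_entries data frames from
#'   [read_fasta_entries()] (or `NULL`).
#' @param mutant_peptides data frame from [generate_mutant_peptides()]
#'   (or `NULL`).
#' @param with_decoys append pseudo-reversed tryptic decoys
#'   ([generate_reversed_tryptic_decoys()]) after the targets.
#' @return Data frame with columns `accession`, `sequence`, `origin` and,
#'   for mutant entries, `mutated_offsets`, `variant_id`, `gene`,
#'   `sample_id` (NA elsewhere).
#' @export
build_custom_database <- function(reference_entries = NULL,
                                  contaminant_entries = NULL,
                                  mutant_peptides = NULL,
                                  with_decoys = FALSE) {
  blank <- function(df, origin) {
    if (is.null(df) || nrow(df) == 0L)
      return(NULL)
    data.frame(accession = df$accession, sequence = toupper(df$sequence),
               origin = origin, mutated_offsets = NA_character_,
               variant_id = NA_character_, gene = NA_character_,
               sample_id = NA_character_, stringsAsFactors = FALSE)
  }
  parts <- list(blank(reference_entries, "reference"),
                blank(contaminant_entries, "contaminant"))
  if (!is.null(mutant_peptides) && nrow(mutant_peptides) > 0L) {
    mp <- mutant_peptides[!duplicated(mutant_peptides$sequence), , drop = FALSE]
    parts[[3L]] <- data.frame(
      accession = sprintf("MUT|%s|F%+d|%d", mp$variant_id, mp$frame,
                          mp$fragment_start),
      sequence = toupper(mp$sequence), origin = "mutant",
      mutated_offsets = mp$mutated_offsets, variant_id = mp$variant_id,
      gene = if ("gene" %in% names(mp)) mp$gene else NA_character_,
      sample_id = if ("sample_id" %in% names(mp)) mp$sample_id else NA_character_,
      stringsAsFactors = FALSE)
  }
  db <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  if (is.null(db))
    stop("empty database: no reference, contaminant or mutant entries")
  bad <- grepl("[X*]", db$sequence)
  if (any(bad)) {
    warning(sum(bad), " entr(ies) containing 'X' or '*' excluded from database")
    db <- db[!bad, , drop = FALSE]
  }
  if (anyDuplicated(db$accession)) {
    warning("duplicate accessions renamed with numeric suffix")
    db$accession <- make.unique(db$accession, sep = ".")
  }
  rownames(db) <- NULL
  if (with_decoys)
    db <- rbind(db, generate_reversed_tryptic_decoys(db))
  rownames(db) <- NULL
  db
}

.pseudo_reverse <- function(sequence) {
  bnd <- .tryptic_boundaries(sequence)
  nseg <- length(bnd) - 1L
  segs <- character(nseg)
  for (i in seq_len(nseg)) {
    seg <- substr(sequence, bnd[i] + 1L, bnd[i + 1L])
    n <- nchar(seg)
    last <- substr(seg, n, n)
    if (last %in% c("K", "R") && n > 1L) {
      head <- substr(seg, 1L, n - 1L)
      segs[i] <- paste0(paste(rev(strsplit(head, "", fixed = TRUE)[[1]]),
                              collapse = ""), last)
    } else {
      segs[i] <- paste(rev(strsplit(seg, "", fixed = TRUE)[[1]]), collapse = "")
    }
  }
  paste(segs, collapse = "")
}

#' Pseudo-reversed tryptic decoys
#'
#' One decoy per target entry: each tryptic segment is reversed in place
#' with its C-terminal K/R kept at the segment end, so cleavage-site
#' positions, entry length and amino-acid composition are preserved.
#' Decoy accessions carry the prefix `REV_`.
#'
#' @param entries target database data frame ([build_custom_database()]).
#' @return Data frame of decoy entries with `origin = "decoy"`.
#' @examples
#' generate_reversed_tryptic_decoys(
#'   data.frame(accession = "P1", sequence = "MABCKDEFR"))
#' @export
generate_reversed_tryptic_decoys <- function(entries) {
  out <- data.frame(
    accession = paste0("REV_", entries$accession),
    sequence = vapply(entries$sequence, .pseudo_reverse, character(1),
                      USE.NAMES = FALSE),
    origin = "decoy", stringsAsFactors = FALSE)
  for (col in setdiff(names(entries), names(out)))
    out[[col]] <- NA_character_
  rownames(out) <- NULL
  out
}

#' Write a database as FASTA
#'
#' Deterministic: same input rows give byte-identical output.
#'
#' @param db data frame with `accession` and `sequence` columns.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_database_fasta <- function(db, path) {
  s <- Biostrings::AAStringSet(db$sequence)
  names(s) <- db$accession
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}
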