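# Matching MS-identified peptides back to mutant database entries.

#' Parse an MS search peptide table
#'
#' Reads a MaxQuant `peptides.txt`-style tab-separated table and drops the
#' rows flagged as decoy (`Reverse`) or contaminant
#' (`Potential contaminant`), which are not cancer-specific evidence.
#' Sequences are uppercased.
#'
#' @param path tab-separated file with a header row.
#' @param col_map named character vector mapping the logical columns
#'   (`sequence`, `proteins`, `reverse`, `contaminant`) to the file's
#'   column names.  Only `sequence` is mandatory; a missing flag column is
#'   treated as all-unflagged.
#' @return Data frame with columns `sequence`, `proteins` (may be `NA`)
#'   and `score` when a `Score` column is present.
#' @export
parse_identified_peptides <- function(path,
                                      col_map = c(sequence = "Sequence",
                                                  proteins = "Proteins",
                                                  reverse = "Reverse",
                                                  contaminant = "Potential contaminant")) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!col_map[["sequence"]] %in% names(tab))
    stop("peptide table format error: missing column '",
         col_map[["sequence"]], "'")
  flag <- function(key) {
    nm <- col_map[key]
    if (!is.na(nm) && nm %in% names(tab)) {
      v <- tab[[nm]]
      !is.na(v) & trimws(as.character(v)) == "+"
    } else rep(FALSE, nrow(tab))
  }
  drop <- flag("reverse") | flag("contaminant")
  tab <- tab[!drop, , drop = FALSE]
  out <- data.frame(sequence = toupper(tab[[col_map[["sequence"]]]]),
                    stringsAsFactors = FALSE)
  out$proteins <- if (!is.na(col_map["proteins"]) &&
                      col_map[["proteins"]] %in% names(tab))
    as.character(tab[[col_map[["proteins"]]]]) else NA_character_
  out$score <- if ("Score" %in% names(tab))
    suppressWarnings(as.numeric(tab[["Score"]])) else NA_real_
  rownames(out) <- NULL
  out
}

#' Match identified peptides to mutant database entries
#'
#' An identified peptide validates a mutant entry when its sequence occurs
#' as a substring of the entry and the match window overlaps at least one
#' mutated offset.  Peptides that also occur verbatim in any reference
#' proteome entry are excluded: they are not cancer-specific.  All
#' validating (peptide, entry) pairs are reported, with the first
#' overlapping match offset and the mutated offsets covered by that
#' window, re-indexed to the identified peptide.
#'
#' @param identified data frame from [parse_identified_peptides()].
#' @param mutant_entries mutant rows of a [build_custom_database()] result
#'   (`origin == "mutant"`, with `mutated_offsets`).
#' @param reference_entries optional data frame of reference proteome
#'   entries used for the cancer-specificity exclusion.
#' @return Data frame with columns `sequence`, `accession`, `match_offset`
#'   (0-based offset of the peptide within the entry), `covered_offsets`
#'   (0-based, within the identified peptide), `variant_id`, `gene`,
#'   `sample_id`.
#' @export
match_identified_to_mutant <- function(identified, mutant_entries,
                                       reference_entries = NULL) {
  peps <- unique(identified$sequence)
  if (!is.null(reference_entries) && nrow(reference_entries) > 0L &&
      length(peps) > 0L) {
    in_ref <- vapply(peps, function(p)
      any(grepl(p, reference_entries$sequence, fixed = TRUE)), TRUE)
    peps <- peps[!in_ref]
  }
  out <- list()
  for (p in peps) {
    np <- nchar(p)
    hit <- grep(p, mutant_entries$sequence, fixed = TRUE)
    for (i in hit) {
      entry <- mutant_entries[i, ]
      moff <- .offsets_int(entry$mutated_offsets)
      starts <- as.integer(gregexpr(p, entry$sequence, fixed = TRUE)[[1]]) - 1L
      for (s in starts) {
        covered <- moff[moff >= s & moff < s + np]
        if (length(covered)) {
          out[[length(out) + 1L]] <- data.frame(
            sequence = p, accession = entry$accession, match_offset = s,
            covered_offsets = .offsets_chr(covered - s),
            variant_id = entry$variant_id, gene = entry$gene,
            sample_id = entry$sample_id, stringsAsFactors = FALSE)
          break   # first overlapping occurrence per (peptide, entry)
        }
      }
    }
  }
  if (!length(out))
    return(.empty_df(sequence = character(), accession = character(),
                     match_offset = integer(), covered_offsets = character(),
                     variant_id = character(), gene = character(),
                     sample_id = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$sequence, res$accession), , drop = FALSE]
  rownames(res) <- NULL
  res
}
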