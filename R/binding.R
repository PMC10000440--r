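# MHC class I binding selection: mutated 8-11-mer enumeration, pluggable
# percentile-rank predictors, bind-level labels and the %rank < 2 filter.

#' Enumerate mutated 8-11-mers
#'
#' All substrings of length `kmin`..`kmax` of each validated peptide that
#' contain at least one mutated residue, matching the lengths presented by
#' MHC class I molecules.
#'
#' @param validated data frame from [match_identified_to_mutant()]
#'   (columns `sequence`, `covered_offsets`, plus provenance columns).
#' @param kmin,kmax k-mer length bounds (defaults 8 and 11).
#' @return Data frame with columns `kmer`, `parent`, `start` (0-based
#'   offset in the parent), `mutated_offsets` (0-based, within the k-mer)
#'   and the provenance columns present in the input (`variant_id`,
#'   `gene`, `sample_id`, `accession`).
#' @export
enumerate_kmers <- function(validated, kmin = 8L, kmax = 11L) {
  out <- list()
  prov_cols <- intersect(c("accession", "variant_id", "gene", "sample_id"),
                         names(validated))
  for (i in seq_len(nrow(validated))) {
    v <- validated[i, ]
    L <- nchar(v$sequence)
    moff <- .offsets_int(v$covered_offsets)
    for (k in seq.int(kmin, kmax)) {
      if (L < k) next
      for (s in 0:(L - k)) {
        inside <- moff[moff >= s & moff < s + k]
        if (!length(inside)) next
        row <- data.frame(kmer = substr(v$sequence, s + 1L, s + k),
                          parent = v$sequence, start = s,
                          mutated_offsets = .offsets_chr(inside - s),
                          stringsAsFactors = FALSE)
        for (pc in prov_cols) row[[pc]] <- v[[pc]]
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (!length(out)) {
    res <- .empty_df(kmer = character(), parent = character(),
                     start = integer(), mutated_offsets = character())
    for (pc in prov_cols) res[[pc]] <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read an HLA class I allele list
#'
#' One allele per line, `HLA-A*02:01` nomenclature.  Lines failing the
#' nomenclature pattern are rejected.
#'
#' @param path text file.
#' @param sample_id sample the typing belongs to.
#' @return Data frame with columns `sample_id`, `allele`.
#' @export
read_allele_list <- function(path, sample_id) {
  alleles <- trimws(readLines(path, warn = FALSE))
  alleles <- alleles[nzchar(alleles)]
  bad <- !grepl("^HLA-[A-C]\\*[0-9]+:[0-9]+$", alleles)
  if (any(bad))
    stop("invalid HLA allele name(s): ", paste(alleles[bad], collapse = ", "))
  if (length(alleles) < 1L || length(alleles) > 6L)
    stop("a class I typing must list between 1 and 6 alleles")
  data.frame(sample_id = sample_id, allele = alleles, stringsAsFactors = FALSE)
}

#' Predict binding percentile ranks for k-mers
#'
#' Calls a pluggable predictor for every unique (k-mer sequence, allele)
#' pair and fans the ranks back out to all parent records, so a peptide
#' shared by several parents is scored once.  Predictor failures (errors
#' or `NA` ranks) are recorded in the `"failures"` attribute and the pair
#' is skipped.
#'
#' @param kmers data frame from [enumerate_kmers()].
#' @param typing data frame with an `allele` column
#'   ([read_allele_list()]); predictions are made for each allele.
#' @param predictor function `(peptide, allele) -> percentile rank`
#'   (scalar), e.g. [mock_predictor()] or [netmhcpan_file_predictor()].
#' @param sb,wb strong/weak bind-level thresholds passed to
#'   [assign_bind_level()].
#' @return Data frame: the k-mer columns plus `allele`,
#'   `percentile_rank`, `bind_level`.
#' @export
predict_binding <- function(kmers, typing, predictor, sb = 0.5, wb = 2.0) {
  if (!is.function(predictor))
    stop("environment error: no predictor available; supply mock_predictor() ",
         "or netmhcpan_file_predictor() over an external prediction file")
  alleles <- sort(unique(typing$allele))
  pairs <- expand.grid(kmer = sort(unique(kmers$kmer)), allele = alleles,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ranks <- rep(NA_real_, nrow(pairs))
  fail <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r <- tryCatch(predictor(pairs$kmer[i], pairs$allele[i]),
                  error = function(e) NA_real_)
    if (is.null(r) || length(r) != 1L || is.na(r)) fail[i] <- TRUE
    else ranks[i] <- as.numeric(r)
  }
  pairs$percentile_rank <- ranks
  failures <- pairs[fail, c("kmer", "allele"), drop = FALSE]
  pairs <- pairs[!fail, , drop = FALSE]
  out <- merge(kmers, pairs, by = "kmer", sort = FALSE)
  out$bind_level <- assign_bind_level(out$percentile_rank, sb = sb, wb = wb)
  out <- out[order(out$kmer, out$allele, out$parent, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Bind level from a percentile rank
#'
#' NetMHCpan-style labels: strong binder (`SB`) below `sb`, weak binder
#' (`WB`) in `[sb, wb)`, non-binder (`NB`) otherwise.
#'
#' @param percentile_rank numeric vector of percentile ranks (>= 0).
#' @param sb,wb thresholds (defaults 0.5 and 2.0).
#' @return Character vector of `"SB"`, `"WB"`, `"NB"`.
#' @examples
#' assign_bind_level(c(0.009, 0.48, 1.5, 2.5))
#' @export
assign_bind_level <- function(percentile_rank, sb = 0.5, wb = 2.0) {
  if (any(is.na(percentile_rank)) || any(percentile_rank < 0))
    stop("value error: percentile ranks must be non-negative")
  ifelse(percentile_rank < sb, "SB",
         ifelse(percentile_rank < wb, "WB", "NB"))
}

#' Retain candidate neoantigens by percentile rank
#'
#' Strict comparison: a record is kept when `percentile_rank < threshold`.
#' One record is kept per (k-mer, allele, parent) -- the same peptide may
#' appear for several alleles.
#'
#' @param predictions data frame from [predict_binding()].
#' @param threshold percentile-rank cutoff (default 2).
#' @return Subset of `predictions`.
#' @export
filter_candidates <- function(predictions, threshold = 2.0) {
  out <- predictions[predictions$percentile_rank < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate candidates by peptide
#'
#' Convenience view: one row per candidate peptide with its best (lowest)
#' percentile rank and the alleles it binds.
#'
#' @param candidates data frame from [filter_candidates()].
#' @return Data frame with columns `kmer`, `best_rank`, `n_alleles`,
#'   `alleles`.
#' @export
aggregate_candidates <- function(candidates) {
  if (nrow(candidates) == 0L)
    return(.empty_df(kmer = character(), best_rank = numeric(),
                     n_alleles = integer(), alleles = character()))
  sp <- split(candidates, candidates$kmer)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    kmer = d$kmer[1L], best_rank = min(d$percentile_rank),
    n_alleles = length(unique(d$allele)),
    alleles = paste(sort(unique(d$allele)), collapse = ";"),
    stringsAsFactors = FALSE)))
  out <- out[order(out$best_rank, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse NetMHCpan 4.1 tabular output
#'
#' Tolerant reader for the long-format tab-separated export: the header
#' must contain a peptide column, an allele column (`MHC`, `allele` or
#' `HLA`) and a percentile-rank column (first column whose name contains
#' `rank`, case-insensitively; `EL_Rank` and `%Rank` both qualify).
#'
#' @param path tab-separated prediction file.
#' @return Data frame with columns `kmer`, `allele`, `percentile_rank`.
#' @export
parse_netmhcpan <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(tab))
  pep <- which(nm == "peptide")[1L]
  all_col <- which(nm %in% c("mhc", "allele", "hla"))[1L]
  rank <- grep("rank", nm)[1L]
  if (is.na(pep) || is.na(all_col) || is.na(rank))
    stop("prediction file format error: need Peptide, MHC/allele and ",
         "a rank column")
  data.frame(kmer = toupper(tab[[pep]]),
             allele = as.character(tab[[all_col]]),
             percentile_rank = as.numeric(tab[[rank]]),
             stringsAsFactors = FALSE)
}

#' Predictor backed by an external prediction file
#'
#' Wraps a parsed NetMHCpan-style table as the predictor contract used by
#' [predict_binding()]: lookup by (peptide, allele), `NA` (a recorded
#' failure) for pairs absent from the file.
#'
#' @param path prediction file for [parse_netmhcpan()].
#' @return Function `(peptide, allele) -> percentile rank`.
#' @export
netmhcpan_file_predictor <- function(path) {
  tab <- parse_netmhcpan(path)
  key <- paste(tab$kmer, tab$allele, sep = "\r")
  ranks <- tab$percentile_rank
  function(peptide, allele) {
    i <- match(paste(toupper(peptide), allele, sep = "\r"), key)
    if (is.na(i)) NA_real_ else ranks[i]
  }
}
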