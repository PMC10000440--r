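# Exact Smith-Waterman local alignment for short peptides.
#
# The homology screen compares 8-11-mer candidates against a reference set
# of immunogenic peptides.  At these query lengths heuristic seeding buys
# nothing, so the screen uses an exact affine-gap (Gotoh) Smith-Waterman
# with BLOSUM62 and BLAST-style gap costs (a gap of length k costs
# gap_open + k * gap_extend).  An adapter for external BLASTp tabular
# output is provided for parity (see parse_blast_outfmt6).

.aligner_env <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.aligner_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .aligner_env$BLOSUM62 <- e$BLOSUM62
  }
  .aligner_env$BLOSUM62
}

.AA20 <- "ACDEFGHIKLMNPQRSTVWY"

# lexicographic comparison of alignment keys
# key = c(score, n_identical, -query_start, alignment_length)
.key_gt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

#' Optimal local alignment of two short peptides
#'
#' Affine-gap Smith-Waterman with a deterministic tie-break: among
#' equal-score alignments the one with the most identical positions wins,
#' then the smallest query start, then the longest alignment.  The last
#' key keeps zero-scoring flanking pairs (e.g. A:T under BLOSUM62) inside
#' the reported alignment, mirroring how BLAST extends through
#' zero-contribution columns.  Identity statistics are propagated through
#' the dynamic program, so the reported `n_identical` is the maximum over
#' all optimal-score alignments.
#'
#' @param query,target peptide strings over the standard 20-letter
#'   alphabet.
#' @param matrix substitution matrix (default BLOSUM62 from Biostrings).
#' @param gap_open,gap_extend gap costs as positive numbers (defaults 11
#'   and 1; a length-k gap costs `gap_open + k * gap_extend`).
#' @return One-row data frame with columns `query`, `target`, `score`,
#'   `n_identical`, `alignment_length`, `percent_identity` (0-100;
#'   `100 * n_identical / alignment_length`), `query_start` (1-based; 0
#'   when there is no positive-scoring alignment) and `evalue` (`NA`: the
#'   native aligner does not compute E-values).
#' @examples
#' local_align("KTDAQAISL", "KTDAQAISL")$percent_identity   # 100
#' local_align("AAAAAAAAA", "AAAAAAAAT")$percent_identity   # 88.9
#' @export
local_align <- function(query, target, matrix = NULL,
                        gap_open = 11, gap_extend = 1) {
  stopifnot(is.character(query), is.character(target),
            nzchar(query), nzchar(target))
  if (grepl(sprintf("[^%s]", .AA20), query) ||
      grepl(sprintf("[^%s]", .AA20), target))
    stop("alphabet error: peptides must use the standard 20-letter alphabet")
  if (is.null(matrix)) matrix <- .blosum62()
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  t <- strsplit(target, "", fixed = TRUE)[[1]]
  n <- length(q)
  m <- length(t)
  NEG <- -1e9
  # per-state key components: score, matches, length, query start
  mk <- function() base::matrix(NEG, n + 1L, m + 1L)
  Ms <- mk(); Mm <- mk(); Ml <- mk(); Mq <- mk()
  Xs <- mk(); Xm <- mk(); Xl <- mk(); Xq <- mk()
  Ys <- mk(); Ym <- mk(); Yl <- mk(); Yq <- mk()
  best <- c(0, 0, 0, 0)   # score, matches, -qstart, length
  gi <- gap_open + gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- matrix[q[i], t[j]]
      idn <- as.numeric(q[i] == t[j])
      # ending with q[i] ~ t[j]: predecessor is any state at (i-1, j-1),
      # or a fresh start
      cand <- list(c(0, 0, i, 0),
                   c(Ms[i, j], Mm[i, j], Mq[i, j], Ml[i, j]),
                   c(Xs[i, j], Xm[i, j], Xq[i, j], Xl[i, j]),
                   c(Ys[i, j], Ym[i, j], Yq[i, j], Yl[i, j]))
      pick <- cand[[1L]]
      for (cc in cand[-1L])
        if (.key_gt(c(cc[1L], cc[2L], -cc[3L], cc[4L]),
                    c(pick[1L], pick[2L], -pick[3L], pick[4L]))) pick <- cc
      Ms[i + 1L, j + 1L] <- pick[1L] + s
      Mm[i + 1L, j + 1L] <- pick[2L] + idn
      Mq[i + 1L, j + 1L] <- pick[3L]
      Ml[i + 1L, j + 1L] <- pick[4L] + 1
      # gap consuming q[i] (insertion relative to target)
      c1 <- c(Ms[i, j + 1L] - gi, Mm[i, j + 1L], Mq[i, j + 1L], Ml[i, j + 1L] + 1)
      c2 <- c(Xs[i, j + 1L] - gap_extend, Xm[i, j + 1L], Xq[i, j + 1L],
              Xl[i, j + 1L] + 1)
      px <- if (.key_gt(c(c2[1L], c2[2L], -c2[3L], c2[4L]),
                        c(c1[1L], c1[2L], -c1[3L], c1[4L]))) c2 else c1
      Xs[i + 1L, j + 1L] <- px[1L]; Xm[i + 1L, j + 1L] <- px[2L]
      Xq[i + 1L, j + 1L] <- px[3L]; Xl[i + 1L, j + 1L] <- px[4L]
      # gap consuming t[j]
      c1 <- c(Ms[i + 1L, j] - gi, Mm[i + 1L, j], Mq[i + 1L, j], Ml[i + 1L, j] + 1)
      c2 <- c(Ys[i + 1L, j] - gap_extend, Ym[i + 1L, j], Yq[i + 1L, j],
              Yl[i + 1L, j] + 1)
      py <- if (.key_gt(c(c2[1L], c2[2L], -c2[3L], c2[4L]),
                        c(c1[1L], c1[2L], -c1[3L], c1[4L]))) c2 else c1
      Ys[i + 1L, j + 1L] <- py[1L]; Ym[i + 1L, j + 1L] <- py[2L]
      Yq[i + 1L, j + 1L] <- py[3L]; Yl[i + 1L, j + 1L] <- py[4L]
      # local alignments end on an aligned pair
      key <- c(Ms[i + 1L, j + 1L], Mm[i + 1L, j + 1L], -Mq[i + 1L, j + 1L],
               Ml[i + 1L, j + 1L])
      if (.key_gt(key, best)) best <- key
    }
  }
  if (best[1L] <= 0)
    return(data.frame(query = query, target = target, score = 0,
                      n_identical = 0L, alignment_length = 0L,
                      percent_identity = 0, query_start = 0L,
                      evalue = NA_real_, stringsAsFactors = FALSE))
  data.frame(query = query, target = target, score = best[1L],
             n_identical = as.integer(best[2L]),
             alignment_length = as.integer(best[4L]),
             percent_identity = 100 * best[2L] / best[4L],
             query_start = as.integer(-best[3L]),
             evalue = NA_real_, stringsAsFactors = FALSE)
}
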