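# Independent oracles used to cross-check the package implementation.
# Translation goes through seqinr; everything else is written as direct
# brute-force enumeration of the stated rules, deliberately avoiding the
# package's own code paths.

orc_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

orc_translate <- function(nt, frame) {
  s <- if (frame < 0) orc_revcomp(nt) else nt
  off <- abs(frame) - 1L
  if (nchar(s) - off < 3L) return("")
  paste(seqinr::translate(seqinr::s2c(s), frame = off), collapse = "")
}

# map the mutated nucleotide interval [a, b) into the coordinates of the
# strand actually translated for this frame
orc_map_interval <- function(a, b, L, frame) {
  if (frame < 0) c(L - b, L - a) else c(a, b)
}

# residues whose codon nucleotide span intersects the mutated interval
orc_mut_residues <- function(a, b, L, frame) {
  ab <- orc_map_interval(a, b, L, frame)
  off <- abs(frame) - 1L
  naa <- (L - off) %/% 3L
  r <- seq_len(naa) - 1L
  lo <- off + 3L * r
  r[lo < ab[2L] & lo + 3L > ab[1L]]
}

# brute-force enumeration of mutation-containing stop-free fragments over
# all six frames; returns the sorted unique fragment sequences
orc_six_frame_peptides <- function(mut_window, a, b, min_length = 7L) {
  L <- nchar(mut_window)
  out <- character(0)
  for (f in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    aa <- orc_translate(mut_window, f)
    if (!nzchar(aa)) next
    ab <- orc_map_interval(a, b, L, f)
    off <- abs(f) - 1L
    m <- gregexpr("[^*]+", aa)[[1]]
    if (m[1L] == -1L) next
    for (k in seq_along(m)) {
      fs <- as.integer(m[k]) - 1L
      len <- attr(m, "match.length")[k]
      span <- c(off + 3L * fs, off + 3L * (fs + len))
      if (span[1L] < ab[2L] && span[2L] > ab[1L] && len >= min_length)
        out <- c(out, substr(aa, fs + 1L, fs + len))
    }
  }
  sort(unique(out))
}

# brute-force tryptic digestion: all substrings whose boundaries sit at
# valid cleavage points with at most max_missed internal sites
orc_digest <- function(seq, max_missed = 2L, min_length = 7L) {
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(res)
  site <- function(i) i == 0L || i == L ||
    (res[i] %in% c("K", "R") && res[i + 1L] != "P")
  out <- character(0)
  for (s in 0:(L - 1L)) {
    for (e in (s + 1L):L) {
      if (!site(s) || !site(e)) next
      internal <- if (e - s <= 1L) 0L else
        sum(vapply((s + 1L):(e - 1L), site, TRUE))
      if (e - s >= min_length && internal <= max_missed)
        out <- c(out, substr(seq, s + 1L, e))
    }
  }
  sort(out)
}

# brute-force mutated k-mer windows
orc_kmers <- function(parent, moffs, kmin = 8L, kmax = 11L) {
  L <- nchar(parent)
  out <- character(0)
  for (k in kmin:kmax) {
    if (L < k) next
    for (s in 0:(L - k))
      if (any(moffs >= s & moffs < s + k))
        out <- c(out, substr(parent, s + 1L, s + k))
  }
  out
}

# reference Smith-Waterman: plain score DP plus exhaustive traceback over
# all optimal paths to find the maximum identity count
sw_ref <- function(q, t, gap_open = 11, gap_extend = 1) {
  B <- noncneo:::.blosum62()
  qs <- strsplit(q, "", fixed = TRUE)[[1]]
  ts <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(qs); m <- length(ts)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  gi <- gap_open + gap_extend
  for (i in 1:n) for (j in 1:m) {
    s <- B[qs[i], ts[j]]
    M[i + 1L, j + 1L] <- s + max(0, M[i, j], X[i, j], Y[i, j])
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gi, X[i, j + 1L] - gap_extend)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gi, Y[i + 1L, j] - gap_extend)
  }
  best <- max(M)
  if (best <= 0) return(list(score = 0, n_identical = 0L))
  # DFS over all optimal tracebacks, maximizing the identity count
  dfs <- function(state, i, j) {
    if (state == "M") {
      idn <- as.integer(qs[i - 1L] == ts[j - 1L])
      v <- M[i, j] - B[qs[i - 1L], ts[j - 1L]]   # value of predecessor max
      cand <- integer(0)
      if (v == 0) cand <- c(cand, idn)
      if (i > 1L && j > 1L) {
        if (isTRUE(M[i - 1L, j - 1L] == v)) cand <- c(cand, idn + dfs("M", i - 1L, j - 1L))
        if (isTRUE(X[i - 1L, j - 1L] == v)) cand <- c(cand, idn + dfs("X", i - 1L, j - 1L))
        if (isTRUE(Y[i - 1L, j - 1L] == v)) cand <- c(cand, idn + dfs("Y", i - 1L, j - 1L))
      }
      return(max(cand))
    }
    if (state == "X") {
      cand <- integer(0)
      if (isTRUE(M[i - 1L, j] - gi == X[i, j])) cand <- c(cand, dfs("M", i - 1L, j))
      if (isTRUE(X[i - 1L, j] - gap_extend == X[i, j])) cand <- c(cand, dfs("X", i - 1L, j))
      return(max(cand))
    }
    cand <- integer(0)
    if (isTRUE(M[i, j - 1L] - gi == Y[i, j])) cand <- c(cand, dfs("M", i, j - 1L))
    if (isTRUE(Y[i, j - 1L] - gap_extend == Y[i, j])) cand <- c(cand, dfs("Y", i, j - 1L))
    max(cand)
  }
  ids <- integer(0)
  for (i in 2:(n + 1L)) for (j in 2:(m + 1L))
    if (M[i, j] == best) ids <- c(ids, dfs("M", i, j))
  list(score = best, n_identical = max(ids))
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]

random_peptide <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

random_context <- function(max_len = 60L) {
  L <- sample(10:max_len, 1L)
  nt <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  a <- sample(0:(L - 1L), 1L)
  b <- min(L, a + sample(1:3, 1L))
  data.frame(variant_id = "v1", contig = "ctg1", window_start = 0L,
             ref_window = nt, mut_window = nt, mut_start = a, mut_end = b,
             flank = 100L, gene = "G1", sample_id = "S1",
             stringsAsFactors = FALSE)
}
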