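# Customized database construction, tryptic digestion, pseudo-reverse
# decoys and MS peptide matching.

ref2 <- data.frame(accession = c("REFP01", "REFP02"),
                   sequence = c("MKTAYIAKQRQISFVK", "MSSSSWLLLSLVAVTAAQSTIEEQAK"),
                   stringsAsFactors = FALSE)
cont1 <- data.frame(accession = "CONT01", sequence = "MKWVTFISLLLLFSSAYSR",
                    stringsAsFactors = FALSE)

mut3 <- data.frame(sequence = c("LLLLLLK", "AAAAAWAAAK", "LLLLLLK"),
                   variant_id = c("v1", "v2", "v3"),
                   frame = c(1L, 2L, -1L), fragment_start = c(0L, 3L, 2L),
                   mutated_offsets = c("2", "5", "2"),
                   gene = "G1", sample_id = "S1", stringsAsFactors = FALSE)

test_that("database concatenates sections and deduplicates mutants", {
  db <- build_custom_database(ref2, cont1, mut3)
  expect_equal(nrow(db), 5L)                         # 2 + 1 + 2 unique mutants
  expect_equal(sum(db$origin == "mutant"), 2L)
  expect_true(all(!duplicated(db$accession)))
  # idempotent and deterministic
  expect_identical(db, build_custom_database(ref2, cont1, mut3))
  empty <- build_custom_database(ref2, cont1, NULL)
  expect_equal(nrow(empty), 3L)
})

test_that("entries with X or * and duplicate accessions are handled", {
  mutx <- mut3
  mutx$sequence[1] <- "LLLXLLK"
  expect_warning(db <- build_custom_database(ref2, cont1, mutx), "'X' or '\\*'")
  expect_false(any(grepl("X", db$sequence)))
  refdup <- rbind(ref2, data.frame(accession = "REFP01", sequence = "MAAAAAA"))
  expect_warning(db2 <- build_custom_database(refdup, NULL, NULL), "duplicate")
  expect_false(anyDuplicated(db2$accession) > 0L)
})

test_that("tryptic digestion enumerates missed cleavages with the KP rule", {
  expect_setequal(digest_tryptic("AAAKBBBRCCC", 2L, 3L)$peptide,
                  c("AAAK", "BBBR", "CCC", "AAAKBBBR", "BBBRCCC",
                    "AAAKBBBRCCC"))
  expect_equal(digest_tryptic("AAKPBBR", 2L, 3L)$peptide, "AAKPBBR")
  expect_equal(digest_tryptic("KRK", 0L, 1L)$peptide, c("K", "R", "K"))
})

test_that("digestion equals the brute-force oracle on random sequences", {
  set.seed(21)
  for (i in 1:40) {
    s <- random_peptide(sample(5:30, 1L))
    got <- digest_tryptic(s, 2L, 7L)
    expect_equal(sort(got$peptide), orc_digest(s, 2L, 7L))
    # positions re-verify
    if (nrow(got))
      expect_true(all(substring(s, got$start + 1L, got$end) == got$peptide))
  }
})

test_that("pseudo-reverse decoys keep tryptic anchors and composition", {
  expect_equal(generate_reversed_tryptic_decoys(
    data.frame(accession = "P1", sequence = "MABCKDEFR"))$sequence,
    "CBAMKFEDR")
  expect_equal(generate_reversed_tryptic_decoys(
    data.frame(accession = "P2", sequence = "AAAA"))$sequence, "AAAA")
  db <- build_custom_database(ref2, cont1, mut3)
  dec <- generate_reversed_tryptic_decoys(db)
  expect_equal(nrow(dec), nrow(db))                  # bijection
  expect_true(all(startsWith(dec$accession, "REV_")))
  expect_equal(nchar(dec$sequence), nchar(db$sequence))
  for (i in seq_len(nrow(db)))
    expect_equal(sort(strsplit(dec$sequence[i], "")[[1]]),
                 sort(strsplit(db$sequence[i], "")[[1]]))
  # appending decoys doubles the database
  expect_equal(nrow(build_custom_database(ref2, cont1, mut3,
                                          with_decoys = TRUE)), 2L * nrow(db))
})

test_that("decoy segments preserve cleavage sites under re-digestion", {
  set.seed(22)
  for (i in 1:15) {
    s <- random_peptide(sample(10:30, 1L))
    d <- generate_reversed_tryptic_decoys(
      data.frame(accession = "P", sequence = s))$sequence
    # segment boundaries coincide unless a reversal created/removed a KP pair
    if (!grepl("[KR]P", s) && !grepl("[KR]P", d))
      expect_equal(digest_tryptic(d, 0L, 1L)$end, digest_tryptic(s, 0L, 1L)$end)
  }
})

write_peptides_txt <- function(rows, path = tempfile(fileext = ".tsv")) {
  write_tsv(rows, path)
  path
}

test_that("peptide-table parsing drops reverse and contaminant rows", {
  tab <- data.frame(Sequence = c("AAAAAAK", "CCCCCCK", "DDDDDDK", "EEEEEEK",
                                 "FFFFFFK"),
                    Proteins = "P1", Reverse = c("", "", "+", "", ""),
                    `Potential contaminant` = c("", "+", "", "", ""),
                    Score = 1:5, check.names = FALSE)
  got <- parse_identified_peptides(write_peptides_txt(tab))
  expect_equal(got$sequence, c("AAAAAAK", "DDDDDDK", "EEEEEEK", "FFFFFFK")[-2])
  expect_equal(nrow(got), 3L)
  empty <- parse_identified_peptides(write_peptides_txt(tab[0, ]))
  expect_equal(nrow(empty), 0L)
  noseq <- write_peptides_txt(data.frame(Pep = "AAAA"))
  expect_error(parse_identified_peptides(noseq), "Sequence")
})

test_that("identified peptides validate mutant entries only via mutated residues", {
  mutdb <- data.frame(accession = c("M1", "M2"),
                      sequence = c("LLLLLLK", "AAAAAWAAAK"),
                      origin = "mutant", mutated_offsets = c("2", "5"),
                      variant_id = c("v1", "v2"), gene = "G", sample_id = "S",
                      stringsAsFactors = FALSE)
  idf <- function(seqs) data.frame(sequence = seqs, proteins = NA, score = NA)
  full <- match_identified_to_mutant(idf("LLLLLLK"), mutdb)
  expect_equal(full$accession, "M1")
  expect_equal(full$match_offset, 0L)
  expect_equal(full$covered_offsets, "2")
  # match window misses the mutated residue
  expect_equal(nrow(match_identified_to_mutant(idf("AAAK"), mutdb)), 0L)
  # peptide present in the reference proteome is not cancer-specific
  refhit <- match_identified_to_mutant(idf("LLLLLLK"), mutdb,
                                       data.frame(accession = "R",
                                                  sequence = "AALLLLLLKAA"))
  expect_equal(nrow(refhit), 0L)
})

test_that("match offsets re-verify by direct substring search", {
  set.seed(23)
  b <- make_fixture_bundle(seed = 23, dir = tempfile("mdb-"), n_snv = 4L,
                           n_nonpass = 1L, n_exonic = 1L, n_indel = 0L)
  run_db <- local({
    v <- parse_somatic_vcf(b$paths$vcf, "S1")
    nc <- filter_noncoding(join_annotations(
      v, read_annotation_table(b$paths$annotation)))
    pep <- generate_mutant_peptides(extract_context(b$paths$genome, nc))
    build_custom_database(read_fasta_entries(b$paths$proteome),
                          read_fasta_entries(b$paths$contaminants), pep)
  })
  val <- match_identified_to_mutant(
    parse_identified_peptides(b$paths$ms_table),
    run_db[run_db$origin == "mutant", ],
    run_db[run_db$origin == "reference", ])
  expect_gt(nrow(val), 0L)
  for (i in seq_len(nrow(val))) {
    entry <- run_db$sequence[run_db$accession == val$accession[i]]
    expect_equal(substr(entry, val$match_offset[i] + 1L,
                        val$match_offset[i] + nchar(val$sequence[i])),
                 val$sequence[i])
  }
})
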