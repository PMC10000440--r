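# Deterministic synthetic fixtures with planted ground truth.  Every
# stage of the pipeline -- and the whole of it -- can be exercised
# offline: a seeded toy genome, planted somatic variants with known PASS
# and annotation fates, a simulated MS peptide table with tunable recall,
# a seeded mock MHC predictor with planted binders, and an engineered
# immunogenic reference set that the planted binders must match.

# evaluate code under a temporary RNG state, restoring the caller's
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded toy genome
#'
#' Uniform A/C/G/T contigs; byte-deterministic for a given seed.
#'
#' @param seed integer seed.
#' @param n_contigs number of contigs (default 2).
#' @param length contig length in nucleotides (default 5000, minimum
#'   300).
#' @return Named `DNAStringSet` (`ctg1`, `ctg2`, ...).
#' @export
make_toy_genome <- function(seed, n_contigs = 2L, length = 5000L) {
  stopifnot(length >= 300L)
  .with_seed(seed, {
    seqs <- vapply(seq_len(n_contigs), function(i)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = ""), character(1))
    g <- Biostrings::DNAStringSet(seqs)
    names(g) <- paste0("ctg", seq_len(n_contigs))
    g
  })
}

.sample_protein <- function(len) {
  paste(sample(strsplit(.AA20, "", fixed = TRUE)[[1]], len, replace = TRUE),
        collapse = "")
}

#' Seeded toy reference proteome
#'
#' @param seed integer seed.
#' @param n_entries,length number and length of protein entries.
#' @return Data frame with `accession`, `sequence`, `origin =
#'   "reference"`.
#' @export
make_toy_proteome <- function(seed, n_entries = 5L, length = 300L) {
  .with_seed(seed, data.frame(
    accession = sprintf("REFP%02d", seq_len(n_entries)),
    sequence = vapply(seq_len(n_entries), function(i) .sample_protein(length),
                      character(1)),
    origin = "reference", stringsAsFactors = FALSE))
}

#' Seeded toy contaminant proteins
#'
#' @param seed integer seed.
#' @param n_entries,length number and length of contaminant entries.
#' @return Data frame with `accession`, `sequence`, `origin =
#'   "contaminant"`.
#' @export
make_toy_contaminants <- function(seed, n_entries = 2L, length = 150L) {
  .with_seed(seed, data.frame(
    accession = sprintf("CONT%02d", seq_len(n_entries)),
    sequence = vapply(seq_len(n_entries), function(i) .sample_protein(length),
                      character(1)),
    origin = "contaminant", stringsAsFactors = FALSE))
}

.HLA_POOL <- list(
  A = c("HLA-A*02:01", "HLA-A*11:01", "HLA-A*24:02", "HLA-A*33:03"),
  B = c("HLA-B*13:02", "HLA-B*15:01", "HLA-B*35:01", "HLA-B*58:01"),
  C = c("HLA-C*03:04", "HLA-C*04:03", "HLA-C*06:02", "HLA-C*07:02"))

#' Seeded HLA class I typings
#'
#' Two alleles per locus (A, B, C) drawn with replacement from a small
#' pool, so homozygous loci occur and contribute two identical rows.
#'
#' @param sample_ids character vector of sample labels.
#' @param seed integer seed.
#' @return Data frame with `sample_id`, `allele` (one row per
#'   chromosome).
#' @export
make_hla_typings <- function(sample_ids, seed) {
  .with_seed(seed, do.call(rbind, lapply(sample_ids, function(s) {
    alleles <- unlist(lapply(.HLA_POOL, sample, size = 2L, replace = TRUE))
    data.frame(sample_id = s, allele = unname(alleles),
               stringsAsFactors = FALSE)
  })))
}

.write_vcf <- function(variants, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FILTER=<ID=PASS,Description=\"All filters passed\">",
           "##FILTER=<ID=germline,Description=\"Germline evidence\">",
           sprintf("##contig=<ID=%s,length=%d>", names(genome),
                   Biostrings::width(genome)),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  v <- variants[order(variants$contig, variants$pos), , drop = FALSE]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.",
                  v$contig, v$pos, v$ref, v$alt, v$filter_status)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Plant somatic variants in a toy genome
#'
#' Places SNVs (and optionally indels) at least `spacing` nucleotides
#' apart, with REF read from the genome so reference mismatches cannot
#' occur.  Among the `n_snv` SNVs, `n_nonpass` receive a non-PASS FILTER
#' and `n_exonic` receive the decoy functional category `"exonic"`; all
#' other variants are PASS and draw their category from the ten noncoding
#' categories.  Writes a VCF and an annotation table and returns the
#' planted truth.
#'
#' @param genome `DNAStringSet` from [make_toy_genome()].
#' @param n_snv total SNVs, including the non-PASS and exonic decoys.
#' @param n_indel additional PASS noncoding indels (alternating
#'   insertion/deletion).
#' @param n_nonpass,n_exonic decoy counts among the SNVs.
#' @param seed integer seed.
#' @param dir output directory for `variants.vcf` and `annotation.tsv`.
#' @param flank context flank the positions must accommodate.
#' @param spacing minimum distance between planted variants (default 250,
#'   so +/-100 nt contexts never overlap).
#' @return List with `vcf`, `annotation` (paths) and `truth` (data frame
#'   of all planted variants with `filter_status`, `func_category`,
#'   `gene` and `expected_survivor`).
#' @export
plant_variants <- function(genome, n_snv = 10L, n_indel = 0L,
                           n_nonpass = 3L, n_exonic = 2L, seed = 1L,
                           dir = tempdir(), flank = 100L, spacing = 250L) {
  stopifnot(n_nonpass + n_exonic <= n_snv)
  n_total <- n_snv + n_indel
  slots <- do.call(rbind, lapply(names(genome), function(ctg) {
    L <- length(genome[[ctg]])
    pos <- seq.int(flank + 20L, L - flank - 20L, by = spacing)
    data.frame(contig = ctg, pos = pos, stringsAsFactors = FALSE)
  }))
  if (nrow(slots) < n_total)
    stop("capacity error: genome too short for ", n_total,
         " variants at spacing ", spacing)
  .with_seed(seed, {
    take <- slots[sort(sample.int(nrow(slots), n_total)), , drop = FALSE]
    base_at <- function(ctg, at, n = 1L)
      toupper(as.character(Biostrings::subseq(genome[[ctg]], at, at + n - 1L)))
    ref <- character(n_total)
    alt <- character(n_total)
    is_indel <- rep(FALSE, n_total)
    if (n_indel > 0L)
      is_indel[sample.int(n_total, n_indel)] <- TRUE
    ins <- TRUE
    for (i in seq_len(n_total)) {
      anchor <- base_at(take$contig[i], take$pos[i])
      if (!is_indel[i]) {
        ref[i] <- anchor
        alt[i] <- sample(setdiff(c("A", "C", "G", "T"), anchor), 1L)
      } else if (ins) {
        ref[i] <- anchor
        alt[i] <- paste0(anchor, paste(sample(c("A", "C", "G", "T"), 2L,
                                              replace = TRUE), collapse = ""))
        ins <- FALSE
      } else {
        ref[i] <- base_at(take$contig[i], take$pos[i], 3L)
        alt[i] <- anchor
        ins <- TRUE
      }
    }
    filter_status <- rep("PASS", n_total)
    func <- character(n_total)
    snv_idx <- which(!is_indel)
    decoys <- snv_idx[sample.int(length(snv_idx), n_nonpass + n_exonic)]
    filter_status[decoys[seq_len(n_nonpass)]] <- "germline"
    exonic <- if (n_exonic > 0L)
      decoys[n_nonpass + seq_len(n_exonic)] else integer(0)
    func[exonic] <- "exonic"
    rest <- setdiff(seq_len(n_total), exonic)
    func[rest] <- sample(noncoding_categories(), length(rest), replace = TRUE)
    truth <- data.frame(
      contig = take$contig, pos = take$pos, ref = ref, alt = alt,
      filter_status = filter_status, func_category = func,
      gene = sprintf("GENE%03d", seq_len(n_total)),
      stringsAsFactors = FALSE)
    truth$variant_id <- .variant_id(truth$contig, truth$pos, truth$ref,
                                    truth$alt)
    truth$expected_survivor <- truth$filter_status == "PASS" &
      classify_noncoding(truth$func_category)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    vcf <- file.path(dir, "variants.vcf")
    .write_vcf(truth, genome, vcf)
    ann <- file.path(dir, "annotation.tsv")
    ann_tab <- data.frame(Chr = truth$contig, Start = truth$pos,
                          End = truth$pos + nchar(truth$ref) - 1L,
                          Ref = truth$ref, Alt = truth$alt,
                          Func = truth$func_category, Gene = truth$gene,
                          stringsAsFactors = FALSE)
    write_tsv(ann_tab, ann)
    list(vcf = vcf, annotation = ann, truth = truth)
  })
}

#' Simulate an MS search peptide table
#'
#' Emits, as identified rows, a fraction `recall` of the tryptic peptides
#' (up to 2 missed cleavages, length >= 7) of the mutant database entries
#' that overlap a mutated offset, plus decoy rows flagged `Reverse` and
#' contaminant rows flagged `Potential contaminant`, which downstream
#' parsing must drop.
#'
#' @param db customized database from [build_custom_database()].
#' @param recall fraction of qualifying mutant tryptic peptides emitted
#'   (0..1).
#' @param seed integer seed.
#' @param path output TSV path.
#' @return `path`, invisibly, with attribute `"emitted"`: the mutant
#'   peptide sequences written as unflagged rows.
#' @export
simulate_ms_table <- function(db, recall = 1.0, seed = 1L, path) {
  stopifnot(recall >= 0, recall <= 1)
  mut <- db[db$origin == "mutant", , drop = FALSE]
  qual <- list()
  for (i in seq_len(nrow(mut))) {
    moff <- .offsets_int(mut$mutated_offsets[i])
    dg <- digest_tryptic(mut$sequence[i], max_missed = 2L, min_length = 7L)
    hit <- vapply(seq_len(nrow(dg)), function(k)
      any(moff >= dg$start[k] & moff < dg$end[k]), TRUE)
    if (any(hit))
      qual[[length(qual) + 1L]] <- data.frame(
        Sequence = dg$peptide[hit], Proteins = mut$accession[i],
        stringsAsFactors = FALSE)
  }
  qual <- if (length(qual)) do.call(rbind, qual) else
    data.frame(Sequence = character(), Proteins = character(),
               stringsAsFactors = FALSE)
  # one row per peptide sequence, protein accessions merged
  if (nrow(qual)) {
    sp <- split(qual$Proteins, qual$Sequence)
    qual <- data.frame(Sequence = names(sp),
                       Proteins = vapply(sp, function(p)
                         paste(sort(unique(p)), collapse = ";"), character(1)),
                       stringsAsFactors = FALSE)
  }
  .with_seed(seed, {
    keep <- sample.int(nrow(qual), round(recall * nrow(qual)))
    qual <- qual[sort(keep), , drop = FALSE]
    rows <- qual
    rows$Reverse <- rep("", nrow(qual))
    rows$`Potential contaminant` <- rep("", nrow(qual))
    rows$Score <- rep(100, nrow(qual))
    # decoy rows: reversed emitted peptides
    if (nrow(qual)) {
      dec <- utils::head(qual$Sequence, 2L)
      rows <- rbind(rows, data.frame(
        Sequence = vapply(dec, function(s)
          paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
          character(1), USE.NAMES = FALSE),
        Proteins = "REV_decoy", Reverse = "+",
        `Potential contaminant` = "", Score = 10,
        check.names = FALSE, stringsAsFactors = FALSE))
    }
    cont <- db[db$origin == "contaminant", , drop = FALSE]
    if (nrow(cont)) {
      cp <- digest_tryptic(cont$sequence[1L], max_missed = 0L, min_length = 7L)
      if (nrow(cp))
        rows <- rbind(rows, data.frame(
          Sequence = utils::head(cp$peptide, 2L),
          Proteins = cont$accession[1L], Reverse = "",
          `Potential contaminant` = "+", Score = 50,
          check.names = FALSE, stringsAsFactors = FALSE))
    }
    write_tsv(rows, path)
    out <- path
    attr(out, "emitted") <- qual$Sequence
    invisible(out)
  })
}

# deterministic hash of a string to [0, 1)
.hash01 <- function(key, seed) {
  x <- utf8ToInt(key)
  ((sum(x * seq_along(x)) * 7919 + seed * 104729) %% 99991) / 99991
}

#' Seeded mock MHC percentile-rank predictor
#'
#' Deterministic stand-in for an external class I binding predictor:
#' planted (peptide, allele) pairs receive percentile ranks below 0.5
#' (strong binders) and every other pair receives a rank of at least 10
#' (filtered out at any sensible threshold).  Ranks depend only on the
#' pair and the seed.
#'
#' @param planted data frame with columns `kmer`, `allele` (may have zero
#'   rows).
#' @param seed integer seed.
#' @return Function `(peptide, allele) -> percentile rank` implementing
#'   the predictor contract of [predict_binding()].
#' @export
mock_predictor <- function(planted = NULL, seed = 1L) {
  keys <- if (!is.null(planted) && nrow(planted))
    paste(planted$kmer, planted$allele, sep = "\r") else character(0)
  function(peptide, allele) {
    key <- paste(peptide, allele, sep = "\r")
    u <- .hash01(key, seed)
    if (key %in% keys) 0.01 + 0.48 * u else 10 + 40 * u
  }
}

#' Choose planted binders from enumerated k-mers
#'
#' For each variant contributing k-mers, one k-mer (9-mers preferred) and
#' one allele from the typing are chosen, deterministically under the
#' seed.
#'
#' @param kmers data frame from [enumerate_kmers()].
#' @param typing typing data frame (`allele` column).
#' @param seed integer seed.
#' @return Data frame with columns `kmer`, `allele`, `variant_id`.
#' @export
plant_binders <- function(kmers, typing, seed = 1L) {
  alleles <- sort(unique(typing$allele))
  .with_seed(seed, {
    rows <- lapply(sort(unique(kmers$variant_id)), function(v) {
      k <- kmers[kmers$variant_id == v, , drop = FALSE]
      nine <- k[nchar(k$kmer) == 9L, , drop = FALSE]
      pool <- if (nrow(nine)) sort(unique(nine$kmer)) else sort(unique(k$kmer))
      data.frame(kmer = pool[sample.int(length(pool), 1L)],
                 allele = alleles[sample.int(length(alleles), 1L)],
                 variant_id = v, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- .empty_df(kmer = character(), allele = character(),
                       variant_id = character())
    # the same peptide may be planted for one allele only
    out[!duplicated(out$kmer), , drop = FALSE]
  })
}

#' Engineered immunogenic reference set
#'
#' For every planted k-mer a partner peptide is built by substituting 2
#' residues (3 for 11-mers) at interior positions, guaranteeing a best
#' hit above 60% identity; unrelated random 9-mers are appended.
#'
#' @param planted_kmers character vector of planted k-mer sequences.
#' @param seed integer seed.
#' @param n_unrelated number of random unrelated peptides (default 20).
#' @return Character vector of reference peptides (engineered partners
#'   first).
#' @export
make_reference_set <- function(planted_kmers, seed = 1L, n_unrelated = 20L) {
  aa <- strsplit(.AA20, "", fixed = TRUE)[[1]]
  .with_seed(seed, {
    partners <- vapply(planted_kmers, function(k) {
      res <- strsplit(k, "", fixed = TRUE)[[1]]
      nmut <- if (length(res) <= 10L) 2L else 3L
      at <- sample(2:(length(res) - 1L), nmut)
      for (i in at) res[i] <- sample(setdiff(aa, res[i]), 1L)
      paste(res, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    unrelated <- vapply(seq_len(n_unrelated), function(i)
      paste(sample(aa, 9L, replace = TRUE), collapse = ""), character(1))
    c(partners, unrelated)
  })
}

#' Generate a complete fixture bundle
#'
#' One call produces every input the pipeline needs, written as
#' plain-text files under `dir`, together with the planted truth:
#' genome, VCF with PASS/non-PASS and noncoding/exonic decoys, annotation
#' table, reference proteome, contaminants, simulated MS peptide table,
#' HLA allele list, engineered immunogenic reference set, and a seeded
#' mock predictor whose planted binders are the expected high-confidence
#' neoantigens.
#'
#' @param seed integer seed driving every random choice.
#' @param dir output directory.
#' @param n_snv,n_indel,n_nonpass,n_exonic passed to [plant_variants()].
#' @param recall passed to [simulate_ms_table()].
#' @param sample_id sample label.
#' @return List with `paths` (named file paths), `typing`, `predictor`,
#'   `planted` (planted binder pairs), `variant_truth` and
#'   `expected_high_confidence` (data frame of `kmer`, `allele` pairs the
#'   final report must flag, and nothing else).
#' @export
make_fixture_bundle <- function(seed, dir = tempfile("noncneo-fixture-"),
                                n_snv = 10L, n_indel = 2L, n_nonpass = 3L,
                                n_exonic = 2L, recall = 1.0,
                                sample_id = "S1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_toy_genome(seed)
  genome_fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, genome_fa)
  planted_var <- plant_variants(genome, n_snv = n_snv, n_indel = n_indel,
                                n_nonpass = n_nonpass, n_exonic = n_exonic,
                                seed = seed + 1L, dir = dir)
  proteome <- make_toy_proteome(seed + 2L)
  proteome_fa <- file.path(dir, "proteome.fa")
  write_database_fasta(proteome, proteome_fa)
  contaminants <- make_toy_contaminants(seed + 3L)
  contaminants_fa <- file.path(dir, "contaminants.fa")
  write_database_fasta(contaminants, contaminants_fa)
  typing <- make_hla_typings(sample_id, seed + 4L)
  hla_txt <- file.path(dir, "hla.txt")
  writeLines(typing$allele, hla_txt)

  # forward-simulate the deterministic generation stages to derive the
  # planted truth
  variants <- parse_somatic_vcf(planted_var$vcf, sample_id)
  nc <- filter_noncoding(join_annotations(
    variants, read_annotation_table(planted_var$annotation)))
  contexts <- extract_context(genome, nc)
  peptides <- generate_mutant_peptides(contexts)
  db <- build_custom_database(proteome, contaminants, peptides)
  ms_tsv <- simulate_ms_table(db, recall = recall, seed = seed + 5L,
                              path = file.path(dir, "peptides.tsv"))
  validated <- match_identified_to_mutant(
    parse_identified_peptides(ms_tsv),
    db[db$origin == "mutant", , drop = FALSE],
    db[db$origin == "reference", , drop = FALSE])
  kmers <- enumerate_kmers(validated)
  planted <- plant_binders(kmers, typing, seed = seed + 6L)
  refset <- make_reference_set(planted$kmer, seed = seed + 7L)
  reference_txt <- file.path(dir, "reference_peptides.txt")
  writeLines(refset, reference_txt)

  list(paths = list(genome = genome_fa, vcf = planted_var$vcf,
                    annotation = planted_var$annotation,
                    proteome = proteome_fa, contaminants = contaminants_fa,
                    ms_table = file.path(dir, "peptides.tsv"),
                    hla = hla_txt, reference_set = reference_txt),
       typing = typing,
       predictor = mock_predictor(planted, seed = seed),
       planted = planted,
       variant_truth = planted_var$truth,
       expected_high_confidence = planted[, c("kmer", "allele"), drop = FALSE],
       sample_id = sample_id)
}

#' Run the pipeline on a fixture bundle
#'
#' @param bundle list from [make_fixture_bundle()].
#' @param ... further arguments to [run_pipeline()].
#' @return A `noncneo_run` object.
#' @export
run_fixture_pipeline <- function(bundle, ...) {
  run_pipeline(vcf = bundle$paths$vcf, annotation = bundle$paths$annotation,
               genome = bundle$paths$genome,
               reference_proteome = bundle$paths$proteome,
               contaminants = bundle$paths$contaminants,
               ms_table = bundle$paths$ms_table, typing = bundle$typing,
               predictor = bundle$predictor,
               reference_set = bundle$paths$reference_set,
               sample_id = bundle$sample_id, ...)
}
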