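# PASS filtering, multi-allelic splitting and noncoding selection.

write_test_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                           header_cols = c("#CHROM", "POS", "ID", "REF",
                                           "ALT", "QUAL", "FILTER", "INFO")) {
  writeLines(c("##fileformat=VCFv4.2",
               "##FILTER=<ID=PASS,Description=\"ok\">",
               "##FILTER=<ID=germline,Description=\"no\">",
               "##contig=<ID=chr1,length=100000>",
               paste(header_cols, collapse = "\t"),
               records), path)
  path
}

test_that("PASS records are retained, others dropped, multi-allelics split", {
  vcf <- write_test_vcf(c(
    "chr1\t100\t.\tC\tG\t.\tPASS\t.",
    "chr1\t200\t.\tT\tA\t.\tgermline\t.",
    "chr1\t300\t.\tA\tG,T\t.\tPASS\t.",
    "chr1\t400\t.\tAT\tA\t.\tPASS\t.",
    "chr1\t500\t.\tG\tGCC\t.\tPASS\t."))
  v <- parse_somatic_vcf(vcf, "S1")
  expect_true(all(v$filter_status == "PASS"))
  expect_false(any(v$pos == 200))
  split3 <- v[v$pos == 300, ]
  expect_equal(nrow(split3), 2L)                      # allele count conserved
  expect_setequal(split3$alt, c("G", "T"))
  expect_true(all(split3$variant_class == "SNV"))
  expect_equal(v$variant_class[v$pos == 400], "deletion")
  expect_equal(v$variant_class[v$pos == 500], "insertion")
  expect_equal(v$sample_id, rep("S1", nrow(v)))
})

test_that("empty VCF body gives an empty variant table", {
  vcf <- write_test_vcf(character(0))
  expect_equal(nrow(parse_somatic_vcf(vcf, "S1")), 0L)
})

test_that("malformed VCF lines and missing FILTER column are format errors", {
  bad <- write_test_vcf(c("chr1\t100\t.\tC\tG\t.\tPASS\t.",
                          "chr1\t200\tC\tG"))
  expect_error(parse_somatic_vcf(bad, "S1"), "malformed VCF line 7")
  nof <- write_test_vcf("chr1\t100\t.\tC\tG\t.\t.",
                        header_cols = c("#CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "INFO"))
  expect_error(parse_somatic_vcf(nof, "S1"), "FILTER")
})

test_that("the ten noncoding categories match exactly and case-sensitively", {
  expect_length(noncoding_categories(), 10L)
  expect_true(all(classify_noncoding(noncoding_categories())))
  expect_true(classify_noncoding("ncRNA_exonic"))
  expect_true(classify_noncoding(" UTR5 "))          # whitespace trimmed
  expect_false(classify_noncoding("exonic"))
  expect_false(classify_noncoding("utr5"))
  expect_false(classify_noncoding("ncRNA_exonic;splicing"))
})

make_variants <- function(pos, ref = "A", alt = "G") {
  data.frame(variant_id = paste("chr1", pos, ref, alt, sep = ":"),
             contig = "chr1", pos = pos, ref = ref, alt = alt,
             filter_status = "PASS", variant_class = "SNV",
             sample_id = "S1", stringsAsFactors = FALSE)
}

make_annotation <- function(pos, func, gene = paste0("G", seq_along(pos)),
                            ref = "A", alt = "G") {
  data.frame(contig = "chr1", pos = pos, ref = ref, alt = alt,
             func_category = func, gene = gene, stringsAsFactors = FALSE)
}

test_that("annotation join matches on (contig, pos, ref, alt)", {
  v <- make_variants(c(10L, 20L, 30L))
  a <- make_annotation(c(30L, 10L, 20L), c("intronic", "UTR3", "exonic"))
  j <- join_annotations(v, a)
  expect_equal(j$pos, c(10L, 20L, 30L))              # input order preserved
  expect_equal(j$func_category, c("UTR3", "exonic", "intronic"))
  expect_equal(j$gene, c("G2", "G3", "G1"))
})

test_that("unmatched variants are excluded and duplicates use first row", {
  v <- make_variants(c(10L, 20L))
  a <- make_annotation(10L, "intronic")
  expect_message(j <- join_annotations(v, a), "without annotation")
  expect_equal(j$pos, 10L)
  dup <- make_annotation(c(10L, 10L), c("UTR5", "intergenic"))
  expect_warning(j2 <- join_annotations(make_variants(10L), dup), "duplicated")
  expect_equal(j2$func_category, "UTR5")
})

test_that("missing annotation columns are a format error", {
  v <- make_variants(10L)
  a <- make_annotation(10L, "intronic")
  expect_error(join_annotations(v, a[, -5]), "missing column")
})

test_that("noncoding filtering keeps exactly the noncoding categories", {
  v <- make_variants(c(1L, 2L, 3L))
  a <- make_annotation(c(1L, 2L, 3L), c("intronic", "exonic", "UTR3"))
  j <- join_annotations(v, a)
  f <- filter_noncoding(j)
  expect_equal(f$func_category, c("intronic", "UTR3"))
  expect_true(all(f$variant_id %in% j$variant_id))   # subset of input
  expect_equal(nrow(filter_noncoding(j[0, ])), 0L)
  all_exonic <- join_annotations(v, make_annotation(c(1L, 2L, 3L),
                                                    rep("exonic", 3)))
  expect_equal(nrow(filter_noncoding(all_exonic)), 0L)
})

test_that("filtering commutes with the annotation join", {
  set.seed(11)
  pos <- sample(1000L, 20L)
  v <- make_variants(pos)
  cats <- sample(c(noncoding_categories(), "exonic", "intergenic;exonic"),
                 20L, replace = TRUE)
  a <- make_annotation(pos, cats)
  path1 <- filter_noncoding(join_annotations(v, a))
  a_pre <- a[classify_noncoding(a$func_category), ]
  path2 <- suppressMessages(join_annotations(v, a_pre))
  expect_equal(path1, path2)
})
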