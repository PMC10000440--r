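# Somatic variant ingestion: PASS filtering, functional-category
# classification, and the annotation join that selects noncoding mutations.

#' Functional categories treated as noncoding
#'
#' The ten Annovar functional categories from which mutant peptide contexts
#' are derived.  Matching is exact (after whitespace trimming) and
#' case-sensitive; any category outside this set -- including "exonic" --
#' is treated as coding and excluded.
#'
#' @return Character vector of the ten category names.
#' @export
noncoding_categories <- function() {
  c("downstream", "intergenic", "intronic", "ncRNA_exonic", "ncRNA_intronic",
    "ncRNA_splicing", "splicing", "upstream", "UTR3", "UTR5")
}

#' Is a functional category noncoding?
#'
#' @param func_category character vector of Annovar-style functional
#'   categories.
#' @return Logical vector: `TRUE` where the trimmed category is one of
#'   [noncoding_categories()].
#' @examples
#' classify_noncoding(c("ncRNA_exonic", "exonic", "UTR5", "utr5"))
#' @export
classify_noncoding <- function(func_category) {
  stopifnot(is.character(func_category))
  trimws(func_category) %in% noncoding_categories()
}

.variant_class <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  ifelse(nr == 1L & na == 1L, "SNV",
         ifelse(na > nr, "insertion",
                ifelse(nr > na, "deletion", "complex")))
}

.variant_id <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

# quick structural scan of a plain-text VCF so that malformed lines are
# reported with their line number (delegated parsers give opaque errors)
.prescan_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#CHROM\t", lines)
  if (length(header) == 0L)
    stop("VCF format error: no #CHROM header line in '", path, "'")
  cols <- strsplit(lines[header[1L]], "\t", fixed = TRUE)[[1]]
  if (!"FILTER" %in% cols)
    stop("VCF format error: missing FILTER column in '", path, "'")
  body <- which(!startsWith(lines, "#"))
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
  bad <- body[nfield < 8L]
  if (length(bad))
    stop("malformed VCF line ", bad[1L], " in '", path,
         "': fewer than 8 tab-separated fields")
  invisible(TRUE)
}

#' Parse a somatic VCF and keep PASS calls
#'
#' Reads a Mutect2-style somatic VCF (plain or bgzipped), splits
#' multi-allelic records into one row per ALT allele, and retains only the
#' records whose FILTER is exactly `"PASS"`.  Each retained allele is
#' classified as SNV, insertion, deletion or complex from the REF/ALT
#' lengths.  ALT alleles that are not plain A/C/G/T strings (symbolic or
#' spanning-deletion alleles) are dropped with a warning.
#'
#' @param vcf path to a VCF 4.x file.
#' @param sample_id sample label attached to every variant.
#' @return Data frame of somatic variants with columns `variant_id`,
#'   `contig`, `pos` (1-based position of the first REF base), `ref`,
#'   `alt`, `filter_status` (always `"PASS"`), `variant_class`,
#'   `sample_id`.
#' @export
parse_somatic_vcf <- function(vcf, sample_id) {
  stopifnot(is.character(vcf), length(vcf) == 1L, file.exists(vcf))
  if (!grepl("\\.(gz|bgz)$", vcf)) .prescan_vcf(vcf)
  v <- VariantAnnotation::readVcf(vcf, genome = "custom")
  v <- VariantAnnotation::expand(v)    # one row per ALT allele
  rr <- SummarizedExperiment::rowRanges(v)
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = as.character(VariantAnnotation::alt(v)),
    filter_status = VariantAnnotation::filt(v),
    stringsAsFactors = FALSE
  )
  out <- out[out$filter_status == "PASS", , drop = FALSE]
  ok <- grepl("^[ACGT]+$", out$ref) & grepl("^[ACGT]+$", out$alt) &
    out$ref != out$alt
  if (any(!ok))
    warning(sum(!ok), " PASS record(s) with non-ACGT or degenerate alleles dropped")
  out <- out[ok, , drop = FALSE]
  out$variant_class <- if (nrow(out)) .variant_class(out$ref, out$alt)
    else character(0)
  out$sample_id <- rep(sample_id, nrow(out))
  out$variant_id <- .variant_id(out$contig, out$pos, out$ref, out$alt)
  rownames(out) <- NULL
  out[, c("variant_id", "contig", "pos", "ref", "alt", "filter_status",
          "variant_class", "sample_id")]
}

#' Read an Annovar-style annotation table
#'
#' @param path tab-separated file with a header row.
#' @param col_map named character vector mapping the required logical
#'   columns (`contig`, `pos`, `ref`, `alt`, `func`, `gene`) to the column
#'   names used in the file.  Defaults to the Annovar multianno convention.
#' @return Data frame with normalized columns `contig`, `pos`, `ref`,
#'   `alt`, `func_category`, `gene`.
#' @export
read_annotation_table <- function(path,
                                  col_map = c(contig = "Chr", pos = "Start",
                                              ref = "Ref", alt = "Alt",
                                              func = "Func", gene = "Gene")) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(col_map), names(tab))
  if (length(missing))
    stop("annotation table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  data.frame(
    contig = as.character(tab[[col_map[["contig"]]]]),
    pos = as.integer(tab[[col_map[["pos"]]]]),
    ref = as.character(tab[[col_map[["ref"]]]]),
    alt = as.character(tab[[col_map[["alt"]]]]),
    func_category = as.character(tab[[col_map[["func"]]]]),
    gene = as.character(tab[[col_map[["gene"]]]]),
    stringsAsFactors = FALSE
  )
}

#' Join variants with their functional annotation
#'
#' Variants are matched to annotation rows on the key
#' (`contig`, `pos`, `ref`, `alt`) after per-ALT splitting; the Annovar end
#' coordinate plays no role.  Unmatched variants are excluded with a
#' message; duplicated annotation keys use the first occurrence with a
#' warning.  Output row order follows the input variant order.
#'
#' @param variants data frame from [parse_somatic_vcf()].
#' @param annotation data frame from [read_annotation_table()] (or any data
#'   frame with columns `contig`, `pos`, `ref`, `alt`, `func_category`,
#'   `gene`).
#' @return The variant data frame with `func_category` and `gene` appended.
#' @export
join_annotations <- function(variants, annotation) {
  need <- c("contig", "pos", "ref", "alt", "func_category", "gene")
  missing <- setdiff(need, names(annotation))
  if (length(missing))
    stop("annotation table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  akey <- .variant_id(annotation$contig, annotation$pos,
                      annotation$ref, annotation$alt)
  if (anyDuplicated(akey)) {
    warning("annotation table has duplicated variant keys; first occurrence used")
    keep <- !duplicated(akey)
    annotation <- annotation[keep, , drop = FALSE]
    akey <- akey[keep]
  }
  idx <- match(variants$variant_id, akey)
  if (anyNA(idx)) {
    dropped <- variants$variant_id[is.na(idx)]
    message(length(dropped), " variant(s) without annotation excluded: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  }
  keep <- !is.na(idx)
  out <- variants[keep, , drop = FALSE]
  out$func_category <- annotation$func_category[idx[keep]]
  out$gene <- annotation$gene[idx[keep]]
  rownames(out) <- NULL
  out
}

#' Retain noncoding variants
#'
#' Keeps exactly the annotated variants whose functional category is in
#' [noncoding_categories()].
#'
#' @param annotated_variants data frame from [join_annotations()].
#' @return Subset of the input, original order preserved.
#' @export
filter_noncoding <- function(annotated_variants) {
  stopifnot("func_category" %in% names(annotated_variants))
  out <- annotated_variants[classify_noncoding(annotated_variants$func_category), ,
                            drop = FALSE]
  rownames(out) <- NULL
  out
}
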