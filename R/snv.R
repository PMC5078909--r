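#' Per-gene single-nucleotide-variant profile
#'
#' Holds, for each gene, the number of variant calls falling in the gene
#' model and the gene-model length in bp. The filtering statistic is the
#' rate `variant_count * 1000 / length_bp` (variants per kilobase).
#'
#' @param gene character vector of gene symbols.
#' @param variant_count non-negative integer counts.
#' @param length_bp positive interval lengths in bp.
#' @return an `snv_profile` data frame with columns `gene`, `variant_count`,
#'   `length_bp`, `rate`.
#' @export
snv_profile <- function(gene, variant_count, length_bp) {
  gene <- normalize_gene(gene)
  variant_count <- as.integer(variant_count)
  length_bp <- as.integer(length_bp)
  stopifnot(length(gene) == length(variant_count),
            length(gene) == length(length_bp))
  if (any(variant_count < 0)) stop("negative variant count", call. = FALSE)
  zero <- length_bp <= 0L
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero-length interval excluded",
            call. = FALSE)
    gene <- gene[!zero]; variant_count <- variant_count[!zero]
    length_bp <- length_bp[!zero]
  }
  if (anyDuplicated(gene)) stop("duplicate gene in SNV profile", call. = FALSE)
  out <- data.frame(gene = gene, variant_count = variant_count,
                    length_bp = length_bp,
                    rate = variant_count * 1000 / length_bp,
                    stringsAsFactors = FALSE)
  class(out) <- c("snv_profile", "data.frame")
  out
}

#' Read a precomputed per-gene SNV profile from TSV
#'
#' Columns `gene`, `variant_count`, `length_bp` (header required). This is the
#' variant-file-free route into the SNV filter.
#'
#' @param path TSV file path.
#' @return an `snv_profile`.
#' @export
read_snv_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "variant_count", "length_bp")
  if (!all(need %in% names(df)))
    stop("SNV TSV needs columns gene, variant_count, length_bp: ", path,
         call. = FALSE)
  snv_profile(df$gene, df$variant_count, df$length_bp)
}

#' Count variant calls per gene from a VCF and gene intervals
#'
#' Counts, for each gene, the VCF records whose position falls inside the
#' gene's union of BED intervals, and takes the union length as the gene-model
#' length. BED is 0-based half-open; VCF POS is 1-based; the conversion
#' happens here and nowhere else, so a record at the half-open interval end is
#' not counted. Multi-allelic records count once (one record, one call site).
#' Genes whose interval union is empty are excluded with a warning.
#'
#' @param vcf path to a VCF 4.x file (plain text or bgzipped).
#' @param intervals path to a BED file whose 4th column is the gene symbol.
#' @return an `snv_profile`.
#' @export
read_snv_profile <- function(vcf, intervals) {
  for (pkg in c("vcfR", "GenomicRanges", "IRanges", "rtracklayer"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("package '", pkg, "' is required to read VCF/BED input",
           call. = FALSE)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  bed <- rtracklayer::import(intervals, format = "BED")  # 1-based GRanges
  if (is.null(bed$name) || anyNA(bed$name))
    stop("BED file must carry gene symbols in column 4: ", intervals,
         call. = FALSE)
  names(bed) <- NULL
  bed$name <- normalize_gene(bed$name)
  by_gene <- GenomicRanges::reduce(
    GenomicRanges::split(bed, bed$name))  # union of intervals per gene
  lens <- sum(GenomicRanges::width(by_gene))
  if (nrow(fix) > 0L) {
    snv <- GenomicRanges::GRanges(
      seqnames = fix[, "CHROM"],
      ranges = IRanges::IRanges(start = as.integer(fix[, "POS"]), width = 1L))
    counts <- GenomicRanges::countOverlaps(by_gene, snv)
  } else {
    counts <- stats::setNames(rep(0L, length(by_gene)), names(by_gene))
  }
  snv_profile(names(by_gene), as.integer(counts), as.integer(lens))
}
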