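#' Read a biallelic SNP VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via vcfR) and converts GT fields into ALT-allele
#' dosages. Only biallelic SNP records are accepted; multi-allelic records
#' raise an error unless `drop_multiallelic = TRUE`. Missing genotypes
#' (`./.`) become `NA`; half-calls (e.g. `./1`) are set to `NA` with a
#' warning. Depth-based genotype quality filters (minDP and the like) belong
#' upstream of this package, which starts from called genotypes.
#'
#' The RAD locus a SNP belongs to (`locus_tag`) is parsed from the ID column
#' when it looks like `tag:column` or `tag_column` (the layout used by
#' STACKS); otherwise the CHROM field is used as the tag.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param locus_tag_from `"id"` (default) to parse the ID column, `"chrom"`
#'   to use CHROM directly.
#' @param drop_multiallelic Drop non-biallelic records instead of erroring.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, locus_tag_from = c("id", "chrom"),
                     drop_multiallelic = FALSE) {
  locus_tag_from <- match.arg(locus_tag_from)
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path, call. = FALSE)
  multi <- grepl(",", fix$ALT) | fix$ALT == "" | is.na(fix$ALT)
  if (any(multi)) {
    if (!drop_multiallelic) {
      stop(sum(multi), " non-biallelic record(s); ",
           "set drop_multiallelic = TRUE to drop them", call. = FALSE)
    }
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # rows = loci, cols = samples; strip phasing
  alleles1 <- substr(gt, 1, 1)
  alleles2 <- substr(gt, 3, 3)
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  known <- function(a) a %in% c("0", "1")
  full <- known(alleles1) & known(alleles2)
  d[full] <- (alleles1[full] == "1") + (alleles2[full] == "1")
  half <- xor(known(alleles1), known(alleles2))
  if (any(half, na.rm = TRUE)) {
    warning(sum(half, na.rm = TRUE), " half-called genotype(s) set to NA")
  }
  ids <- fix$ID
  tag <- fix$CHROM
  col <- rep(NA_integer_, nrow(fix))
  if (locus_tag_from == "id" && !all(is.na(ids) | ids == ".")) {
    m <- regmatches(ids, regexec("^([^:_]+)[:_]([0-9]+)$", ids))
    hit <- lengths(m) == 3
    tag[hit] <- vapply(m[hit], `[`, "", 2)
    col[hit] <- as.integer(vapply(m[hit], `[`, "", 3))
  }
  locus_id <- ifelse(is.na(ids) | ids == ".",
                     paste0(fix$CHROM, "_", fix$POS), ids)
  tab <- tibble::tibble(
    locus_id = locus_id,
    locus_tag = tag,
    snp_column = col,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  message("read_vcf: ", ncol(gt), " samples, ", nrow(gt), " biallelic SNPs")
  geno_matrix(t(d), tab, colnames(gt))
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits unphased GT-only records (`0/0`, `0/1`, `1/1`, `./.`), one per
#' locus, preserving chromosome, position, alleles and the locus id in the
#' ID column. `read_vcf()` reproduces the dosage matrix exactly from the
#' output.
#'
#' @param g A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  d <- g$dosages
  tab <- g$loci
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  idx <- !is.na(t(d))
  gt[idx] <- gt_codes[t(d)[idx] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=genoffset",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t")
  )
  body <- paste(
    tab$chrom, tab$pos, tab$locus_id, tab$ref, tab$alt, ".", "PASS", ".",
    "GT", apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  message("write_vcf: wrote ", nrow(tab), " records for ", nrow(d),
          " samples to ", path)
  invisible(path)
}
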