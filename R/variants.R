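#' Read variant records from a VCF
#'
#' Parses a (plain-text) VCF through vcfR into the flat record table the
#' filter and annotation stages consume. Only the first ALT allele is kept;
#' records are typed `snp` when REF and ALT are single bases, `indel`
#' otherwise. Zygosity derives from the GT field (`1/1` or `1|1` is
#' homozygous alt), MQ from INFO, DP from the sample FORMAT field.
#'
#' @param path VCF file.
#' @param genotype genotype label for the records (default: sample name in
#'   the VCF).
#' @return Data frame: `chrom`, `pos` (1-based), `ref`, `alt`, `type`,
#'   `mq`, `dp`, `zygosity`, `genotype`.
#' @export
read_variant_records <- function(path, genotype = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(chrom = character(), pos = numeric(), ref = character(),
                      alt = character(), type = character(), mq = numeric(),
                      dp = numeric(), zygosity = character(),
                      genotype = character(), stringsAsFactors = FALSE))
  }
  alt1 <- sub(",.*$", "", fix$ALT)
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  dp <- suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "DP")[, 1]))
  if (is.null(genotype)) genotype <- colnames(v@gt)[2]
  data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
             ref = fix$REF, alt = alt1,
             type = ifelse(nchar(fix$REF) == 1 & nchar(alt1) == 1,
                           "snp", "indel"),
             mq = mq, dp = dp,
             zygosity = ifelse(gt %in% c("1/1", "1|1"), "hom", "het"),
             genotype = genotype, stringsAsFactors = FALSE, row.names = NULL)
}

#' Write variant records as a minimal VCF
#'
#' Serializes the simulator's (or the pipeline's) record table into a
#' minimal VCF v4.2: `CHROM POS ID REF ALT QUAL FILTER INFO FORMAT sample`
#' with `MQ` in INFO and `GT:DP` per sample.
#'
#' @param records record table (see [read_variant_records()]).
#' @param path output path.
#' @param sample sample column name.
#' @export
write_variant_records <- function(records, path, sample = NULL) {
  sample <- sample %||%
    (if (nrow(records) > 0) records$genotype[1] else "sample")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=capcnv",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"snp or indel\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  body <- character(0)
  if (nrow(records) > 0) {
    ord <- order(records$chrom, records$pos)
    records <- records[ord, , drop = FALSE]
    gt <- ifelse(records$zygosity == "hom", "1/1", "0/1")
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tMQ=%g;TYPE=%s\tGT:DP\t%s:%d",
                    records$chrom, as.integer(records$pos),
                    records$id %||% ".", records$ref, records$alt,
                    records$mq, records$type, gt, as.integer(records$dp))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Filter SNP and InDel records on mapping quality and depth
#'
#' SNPs are kept with MQ >= 50 and DP >= 10; InDels with MQ >= 30 and
#' DP >= 10 (threshold defaults).
#'
#' @param records record table.
#' @param thresholds a [threshold_config()].
#' @return The retained subset of `records`.
#' @export
filter_variants <- function(records, thresholds = threshold_config()) {
  th <- as_threshold_config(thresholds)
  keep <- ifelse(records$type == "snp",
                 records$mq >= th$snp_min_mq & records$dp >= th$snp_min_dp,
                 records$mq >= th$indel_min_mq & records$dp >= th$indel_min_dp)
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}

#' Heterozygosity statistics and the homozygous "true variant" subset
#'
#' Reports the heterozygous fraction among SNPs, among InDels and combined
#' (per the convention that only homozygous variants count as true
#' variants downstream), optionally restricted to target regions.
#'
#' @param records record table with a `zygosity` column.
#' @param regions optional interval data frame restricting the counting to
#'   target regions.
#' @return List: `n`, `het_fraction_snp`, `het_fraction_indel`,
#'   `het_fraction_total` (as fractions, `NA` on empty classes), and
#'   `homozygous` (the homozygous-only subset).
#' @export
heterozygosity_stats <- function(records, regions = NULL) {
  if (!is.null(regions) && nrow(records) > 0) {
    keep <- vapply(seq_len(nrow(records)), function(i) {
      any(regions$chrom == records$chrom[i] &
            regions$start < records$pos[i] &
            records$pos[i] <= regions$end)
    }, logical(1))
    records <- records[keep, , drop = FALSE]
  }
  frac <- function(sub) {
    if (nrow(sub) == 0) return(NA_real_)
    mean(sub$zygosity == "het")
  }
  list(n = nrow(records),
       het_fraction_snp = frac(records[records$type == "snp", , drop = FALSE]),
       het_fraction_indel = frac(records[records$type == "indel", , drop = FALSE]),
       het_fraction_total = frac(records),
       homozygous = records[records$zygosity == "hom", , drop = FALSE])
}
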