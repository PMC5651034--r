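#' Analysis thresholds
#'
#' Bundles every numeric cutoff used by the pipeline into one validated list,
#' so each stage logs and receives the same configuration. Defaults follow the
#' published capture-analysis protocol this package implements:
#' regions must reach a normalized coverage of 10 and be covered by at least
#' two overlapping reads; a coverage ratio of at least 1.5 between genotypes
#' flags a CNV; below 30% of the other genotype (or of the population mean)
#' a deletion is assumed; SNPs require MQ >= 50 and DP >= 10, InDels MQ >= 30
#' and DP >= 10; gapped short-read mapping resolves InDels up to 18 bp, so
#' larger deletions are sought as zero-coverage windows of at least 19 bp.
#'
#' @param min_region_nc minimum normalized coverage for an analyzable region.
#' @param min_overlap_reads minimum read depth defining a covered base.
#' @param unbalance_factor high/low coverage ratio that flags a CNV.
#' @param deletion_ratio low/high ratio below which a deletion is called.
#' @param pop_deletion_ratio low/population-mean ratio below which the
#'   population tiebreak calls a deletion.
#' @param snp_min_mq,snp_min_dp SNP filter: minimum mapping quality and depth.
#' @param indel_min_mq,indel_min_dp InDel filter: minimum mapping quality and
#'   depth.
#' @param zero_window minimum length (bp) of a zero-coverage window reported
#'   as a large-deletion candidate.
#' @param max_short_indel largest InDel (bp) the gapped mapping can span.
#' @param strong_cov_min mean depth in the other genotype required to call a
#'   zero window "strongly covered elsewhere".
#' @param low_cov_max maximum mean gapped-mapping depth tolerated in the
#'   candidate's own genotype.
#' @param diploid_expected_pct expected diploid-on-tetraploid coverage
#'   percentage (two subgenomes, equal read numbers).
#' @param absent_pct,present_pct,exchange_pct cross-species coverage bands
#'   (percent of the population mean): below `absent_pct` a copy is absent,
#'   at or above `present_pct` present, and support at or above
#'   `exchange_pct` from the opposite subgenome indicates a homoeologous
#'   exchange.
#' @param bootstrap_reps bootstrap replicates for tree support.
#'
#' @return An object of class `threshold_config` (a named list).
#' @examples
#' th <- threshold_config()
#' th$zero_window
#' @export
threshold_config <- function(min_region_nc = 10,
                             min_overlap_reads = 2,
                             unbalance_factor = 1.5,
                             deletion_ratio = 0.3,
                             pop_deletion_ratio = 0.3,
                             snp_min_mq = 50,
                             snp_min_dp = 10,
                             indel_min_mq = 30,
                             indel_min_dp = 10,
                             zero_window = 19,
                             max_short_indel = 18,
                             strong_cov_min = 10,
                             low_cov_max = 2,
                             diploid_expected_pct = 200,
                             absent_pct = 30,
                             present_pct = 60,
                             exchange_pct = 120,
                             bootstrap_reps = 100) {
  th <- list(
    min_region_nc = min_region_nc,
    min_overlap_reads = min_overlap_reads,
    unbalance_factor = unbalance_factor,
    deletion_ratio = deletion_ratio,
    pop_deletion_ratio = pop_deletion_ratio,
    snp_min_mq = snp_min_mq,
    snp_min_dp = snp_min_dp,
    indel_min_mq = indel_min_mq,
    indel_min_dp = indel_min_dp,
    zero_window = zero_window,
    max_short_indel = max_short_indel,
    strong_cov_min = strong_cov_min,
    low_cov_max = low_cov_max,
    diploid_expected_pct = diploid_expected_pct,
    absent_pct = absent_pct,
    present_pct = present_pct,
    exchange_pct = exchange_pct,
    bootstrap_reps = bootstrap_reps
  )
  nums <- unlist(th)
  if (any(!is.finite(nums)) || any(nums <= 0)) {
    stop("all thresholds must be positive finite numbers")
  }
  # deletion calls must be strictly inside the unbalanced zone
  if (th$deletion_ratio >= 1 / th$unbalance_factor) {
    stop("deletion_ratio must be < 1/unbalance_factor")
  }
  structure(th, class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("Analysis thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

as_threshold_config <- function(x) {
  if (inherits(x, "threshold_config")) return(x)
  if (is.null(x)) return(threshold_config())
  do.call(threshold_config, as.list(x))
}
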