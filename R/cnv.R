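#' Classify a copy-number variant between two genotypes
#'
#' Three-step decision rule on normalized coverages of the same region in
#' two genotypes of one species:
#' \enumerate{
#'   \item if the higher coverage is not at least `unbalance_factor` (1.5)
#'     times the lower, the ratio is balanced and no CNV is called;
#'   \item if the lower coverage is below `deletion_ratio` (30%) of the
#'     higher, a deletion in the low genotype is called outright;
#'   \item otherwise the low genotype is compared to the population mean
#'     coverage of the orthologous region: below `pop_deletion_ratio` (30%)
#'     of it the call is still a deletion in the low genotype, otherwise a
#'     duplication in the high genotype.
#' }
#' With no population mean available at step 3 the call is `unresolved`.
#'
#' @param rec_g1,rec_g2 one-row coverage records (see [gene_coverage()]) or
#'   lists with `genotype` and `nc`.
#' @param pop_mean population mean normalized coverage for the region
#'   (`NA` if unavailable).
#' @param thresholds a [threshold_config()].
#' @return One-row data frame: `low_genotype`, `high_genotype`, `nc_low`,
#'   `nc_high`, `ratio_low_high`, `pop_ratio`, `call` (one of `none`,
#'   `deletion_in_low`, `duplication_in_high`, `unresolved`), `carrier`
#'   (genotype carrying the event, `NA` for none/unresolved) and `evidence`.
#' @examples
#' a <- list(genotype = "L58", nc = 1833.2)
#' b <- list(genotype = "other", nc = 1049.4)
#' classify_cnv_pair(a, b, pop_mean = 1561.9)
#' @export
classify_cnv_pair <- function(rec_g1, rec_g2, pop_mean = NA,
                              thresholds = threshold_config()) {
  th <- as_threshold_config(thresholds)
  g <- c(rec_g1$genotype, rec_g2$genotype)
  nc <- c(rec_g1$nc, rec_g2$nc)
  if (any(is.na(nc)) || any(nc < 0)) stop("normalized coverages must be >= 0")
  lo <- which.min(nc)
  hi <- 3 - lo
  res <- data.frame(low_genotype = g[lo], high_genotype = g[hi],
                    nc_low = nc[lo], nc_high = nc[hi],
                    ratio_low_high = if (nc[hi] > 0) nc[lo] / nc[hi] else NA,
                    pop_ratio = if (!is.na(pop_mean) && pop_mean > 0)
                      nc[lo] / pop_mean else NA,
                    call = "none", carrier = NA_character_,
                    evidence = "", stringsAsFactors = FALSE)
  if (nc[hi] == 0) {
    res$evidence <- "no coverage in either genotype"
    return(res)
  }
  if (nc[hi] / max(nc[lo], .Machine$double.xmin) < th$unbalance_factor) {
    res$evidence <- sprintf("balanced ratio high/low = %.2f < %.2f",
                            nc[hi] / nc[lo], th$unbalance_factor)
    return(res)
  }
  if (res$ratio_low_high < th$deletion_ratio) {
    res$call <- "deletion_in_low"
    res$carrier <- g[lo]
    res$evidence <- sprintf("low/high = %.3f < %.2f",
                            res$ratio_low_high, th$deletion_ratio)
    return(res)
  }
  if (is.na(res$pop_ratio)) {
    res$call <- "unresolved"
    res$evidence <- "unbalanced but no population mean for tiebreak"
    return(res)
  }
  if (res$pop_ratio < th$pop_deletion_ratio) {
    res$call <- "deletion_in_low"
    res$carrier <- g[lo]
    res$evidence <- sprintf("low/pop = %.3f < %.2f",
                            res$pop_ratio, th$pop_deletion_ratio)
  } else {
    res$call <- "duplication_in_high"
    res$carrier <- g[hi]
    res$evidence <- sprintf("low/pop = %.3f >= %.2f",
                            res$pop_ratio, th$pop_deletion_ratio)
  }
  res
}

#' Classify CNVs for all genes shared by two coverage tables
#'
#' @param cov1,cov2 coverage tables from [coverage_table()] for the two
#'   genotypes (same reference).
#' @param pop population reference table with `gene_id` and `mean_nc`
#'   (see [simulate_population_reference()]); gene ids may be translated
#'   beforehand through an ortholog map.
#' @param thresholds a [threshold_config()].
#' @return Data frame with one row per shared gene.
#' @export
classify_cnv_table <- function(cov1, cov2, pop = NULL,
                               thresholds = threshold_config()) {
  shared <- intersect(cov1$gene_id, cov2$gene_id)
  out <- lapply(shared, function(gid) {
    r1 <- cov1[cov1$gene_id == gid, ]
    r2 <- cov2[cov2$gene_id == gid, ]
    pm <- if (!is.null(pop) && gid %in% pop$gene_id)
      pop$mean_nc[pop$gene_id == gid][1] else NA
    cbind(gene_id = gid, classify_cnv_pair(r1, r2, pm, thresholds),
          stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cross-species copy status from diploid-on-tetraploid coverage
#'
#' Each tetraploid gene copy belongs to one subgenome; the matching diploid
#' progenitor's coverages at the locus (as percent of the tetraploid
#' population mean) decide its status: all below `absent_pct` (30%) —
#' `absent`; all at or above `present_pct` (60%) — `present`; otherwise
#' `reduced_ambiguous`. When the matching progenitor is absent or reduced
#' while every genotype of the other progenitor reaches `exchange_pct`
#' (120%), the copy is classified as a homoeologous `exchanged` copy
#' supplied by the other subgenome. The diploid-on-tetraploid expectation
#' for a retained copy is around 200%.
#'
#' @param pcts_progenitor_A,pcts_progenitor_C coverage percentages (one per
#'   sequenced genotype) for the A-genome and C-genome progenitor.
#' @param copy_subgenome `"A"` or `"C"`: subgenome the copy resides on.
#' @param thresholds a [threshold_config()].
#' @return One-row data frame: `subgenome`, `status`, `direction` (the
#'   progenitor genome that supplied an exchanged copy, else `NA`),
#'   `matching_pcts`, `other_pcts` (semicolon-collapsed).
#' @examples
#' classify_cross_species(c(2, 13), c(169, 159), "A")  # exchanged, C origin
#' @export
classify_cross_species <- function(pcts_progenitor_A, pcts_progenitor_C,
                                   copy_subgenome,
                                   thresholds = threshold_config()) {
  th <- as_threshold_config(thresholds)
  stopifnot(copy_subgenome %in% c("A", "C"))
  if (length(pcts_progenitor_A) == 0 || length(pcts_progenitor_C) == 0) {
    stop("need at least one coverage percentage per progenitor")
  }
  matching <- if (copy_subgenome == "A") pcts_progenitor_A else pcts_progenitor_C
  other <- if (copy_subgenome == "A") pcts_progenitor_C else pcts_progenitor_A
  status <- if (all(matching < th$absent_pct)) "absent"
            else if (all(matching >= th$present_pct)) "present"
            else "reduced_ambiguous"
  direction <- NA_character_
  if (status %in% c("absent", "reduced_ambiguous") &&
      all(other >= th$exchange_pct)) {
    status <- "exchanged"
    direction <- if (copy_subgenome == "A") "C" else "A"
  }
  data.frame(subgenome = copy_subgenome, status = status,
             direction = direction,
             matching_pcts = paste(matching, collapse = ";"),
             other_pcts = paste(other, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Reconcile tetraploid and diploid copy sets
#'
#' Labels every copy of the ortholog map by its fate after
#' allopolyploidisation: `retained`, `lost_in_napus` (diploid-annotated and
#' covered, no tetraploid ortholog), `gained_in_napus` (tetraploid copy
#' without diploid annotation or coverage), `exchanged` (cross-species call
#' propagates), or `covered_but_unannotated_in_diploid` (tetraploid copy
#' with diploid coverage but no diploid gene annotation).
#'
#' @param ortholog_map data frame with columns `napus_copy`, `diploid_copy`
#'   (either may be `NA`) and `diploid_covered` (logical: significant
#'   diploid coverage at the locus).
#' @param cross_calls data frame with `copy_name` plus the columns of
#'   [classify_cross_species()] for every non-`NA` `napus_copy`.
#' @return The map with a `label` column appended.
#' @export
reconcile_copy_sets <- function(ortholog_map, cross_calls) {
  needed <- !is.na(ortholog_map$napus_copy)
  missing <- setdiff(ortholog_map$napus_copy[needed], cross_calls$copy_name)
  if (length(missing) > 0) {
    stop("no cross-species call for: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(cross_calls$copy_name,
                   ortholog_map$napus_copy[needed])
  if (length(extra) > 0) {
    stop("copy in calls but not in ortholog map: ",
         paste(extra, collapse = ", "))
  }
  label <- character(nrow(ortholog_map))
  for (i in seq_len(nrow(ortholog_map))) {
    row <- ortholog_map[i, ]
    if (is.na(row$napus_copy)) {
      label[i] <- if (isTRUE(row$diploid_covered)) "lost_in_napus" else "retained"
      next
    }
    call <- cross_calls[cross_calls$copy_name == row$napus_copy, ][1, ]
    if (call$status == "exchanged") {
      label[i] <- "exchanged"
    } else if (is.na(row$diploid_copy)) {
      # no diploid annotation: coverage decides gained vs unannotated
      label[i] <- if (call$status == "absent") "gained_in_napus"
                  else "covered_but_unannotated_in_diploid"
    } else {
      label[i] <- "retained"
    }
  }
  ortholog_map$label <- label
  ortholog_map
}

#' Scan for large deletions as zero-coverage windows
#'
#' Large deletions exceed what gapped short-read mapping can span, so they
#' leave windows of exactly zero strict-mapping depth in the carrier. The
#' scan reports maximal runs of at least `zero_window` (19) bases with zero
#' strict depth in the candidate genotype that are strongly covered in the
#' other genotype (mean strict depth at least `strong_cov_min`) while the
#' carrier's own gapped mapping stays low (mean at most `low_cov_max`),
#' excluding plain reference-mapping dropouts.
#'
#' @param strict_own,strict_other strict-mode [depth_track()]s of the
#'   candidate and the comparison genotype.
#' @param gapped_own gapped-mode track of the candidate genotype.
#' @param thresholds a [threshold_config()].
#' @param genes optional `gene_set` to flag candidates overlapping genes.
#' @return Data frame: `genotype`, `chrom`, `start`, `end`, `length`,
#'   `other_mean_depth`, `own_gapped_mean`, `overlaps_gene`.
#' @export
scan_large_deletions <- function(strict_own, strict_other, gapped_own,
                                 thresholds = threshold_config(),
                                 genes = NULL) {
  th <- as_threshold_config(thresholds)
  if (!identical(names(strict_own$depth), names(strict_other$depth)) ||
      !identical(names(strict_own$depth), names(gapped_own$depth)) ||
      strict_own$reference != strict_other$reference) {
    stop("all three tracks must be on the same reference")
  }
  gene_tab <- if (!is.null(genes)) gene_table(genes) else NULL
  out <- list()
  for (ch in names(strict_own$depth)) {
    own <- strict_own$depth[[ch]]
    mask <- own == 0
    if (!any(mask)) next
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    for (k in which(r$values & r$lengths >= th$zero_window)) {
      s <- starts[k]
      e <- ends[k]
      other_mean <- mean(strict_other$depth[[ch]][(s + 1):e])
      gapped_mean <- mean(gapped_own$depth[[ch]][(s + 1):e])
      if (other_mean >= th$strong_cov_min && gapped_mean <= th$low_cov_max) {
        og <- !is.null(gene_tab) &&
          any(gene_tab$chrom == ch & gene_tab$start < e & gene_tab$end > s)
        out[[length(out) + 1]] <- data.frame(
          genotype = strict_own$genotype, chrom = ch, start = s, end = e,
          length = e - s, other_mean_depth = other_mean,
          own_gapped_mean = gapped_mean, overlaps_gene = og,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(genotype = character(), chrom = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      other_mean_depth = numeric(), own_gapped_mean = numeric(),
                      overlaps_gene = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Short-InDel calls from gapped-mapping junction support
#'
#' The gapped-mapping InDel pathway can only call events that reads span in
#' one gapped alignment; with 100 bp reads and the configured gap limit this
#' caps recoverable InDels at `max_short_indel` (18) bp. An injected InDel
#' is emitted as a call when at least `min_overlap_reads` mapped gapped
#' reads span its junction.
#'
#' @param gapped_track gapped-mode [depth_track()] of the genotype (must
#'   carry simulator junction counts).
#' @param truth truth ledger of the genotype (`sim_genotype$truth`).
#' @param thresholds a [threshold_config()].
#' @return Data frame: `id`, `type`, `size`, `junction_reads`, `called`.
#' @export
call_short_indels <- function(gapped_track, truth,
                              thresholds = threshold_config()) {
  th <- as_threshold_config(thresholds)
  if (gapped_track$mode != "gapped") stop("short-InDel calling needs a gapped track")
  ev <- truth[truth$type %in% c("small_insertion", "small_deletion",
                                "large_deletion", "gene_loss"), , drop = FALSE]
  jr <- gapped_track$junction_reads[ev$id]
  jr[is.na(jr)] <- 0
  data.frame(id = ev$id, type = ev$type, size = ev$size,
             junction_reads = as.numeric(jr),
             called = as.numeric(jr) >= th$min_overlap_reads,
             stringsAsFactors = FALSE, row.names = NULL)
}
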