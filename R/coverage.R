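#' Normalized coverage
#'
#' Scales a region's read count by region length, sequencing effort and
#' reference size:
#' `nc = (read_count / region_length) * (genome_size / total_mapped_reads)`.
#' The value is dimensionless, invariant under joint rescaling of read count
#' and library size, and directly comparable across genotypes and
#' references of different sizes — mapping a diploid progenitor's library
#' onto the tetraploid reference doubles on-target nc (the "around 200%"
#' expectation), since the same reads concentrate on half the target space.
#'
#' @param read_count reads assigned to the region.
#' @param region_length region length in bases.
#' @param total_mapped_reads mapped reads of the genotype's library.
#' @param genome_size size of the mapping reference in bases.
#' @return Normalized coverage (vectorized).
#' @examples
#' normalize_coverage(1000, 1000, 1e6, 1e8)  # 100
#' @export
normalize_coverage <- function(read_count, region_length, total_mapped_reads,
                               genome_size) {
  if (any(region_length <= 0) || any(total_mapped_reads <= 0) ||
      any(genome_size <= 0)) {
    stop("region_length, total_mapped_reads and genome_size must be positive")
  }
  (read_count / region_length) * (genome_size / total_mapped_reads)
}

region_read_count <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$depth)) {
    stop("chromosome missing from track: ", chrom)
  }
  d <- track$depth[[chrom]]
  if (start < 0 || end > length(d)) stop("region outside track bounds")
  sum(d[(start + 1):end]) / track$read_length
}

#' Discover analyzable covered regions
#'
#' Finds maximal intervals where depth reaches at least
#' `min_overlap_reads` (a base covered by two overlapping reads), then
#' keeps those whose normalized coverage reaches `min_region_nc`.
#'
#' @param track a [depth_track()].
#' @param genome_size size of the mapping reference.
#' @param thresholds a [threshold_config()].
#' @return Sorted disjoint data frame `region_id`, `chrom`, `start`, `end`,
#'   `read_count`, `nc`.
#' @export
discover_covered_regions <- function(track, genome_size,
                                     thresholds = threshold_config()) {
  thresholds <- as_threshold_config(thresholds)
  out <- list()
  for (ch in names(track$depth)) {
    d <- track$depth[[ch]]
    mask <- d >= thresholds$min_overlap_reads
    if (!any(mask)) next
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- which(r$values)
    for (k in keep) {
      s <- starts[k]
      e <- ends[k]
      rc <- sum(d[(s + 1):e]) / track$read_length
      nc <- normalize_coverage(rc, e - s, track$total_mapped_reads, genome_size)
      if (nc >= thresholds$min_region_nc) {
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = s, end = e,
                                             read_count = rc, nc = nc,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      read_count = numeric(), nc = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res <- cbind(region_id = sprintf("region_%04d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Coverage record for one gene
#'
#' Counts reads over the annotated gene span (depth mass divided by read
#' length, so partial overlaps count fractionally) and normalizes.
#'
#' @param track a [depth_track()].
#' @param gene a `gene_model`.
#' @param genome_size size of the mapping reference.
#' @return One-row data frame: `genotype`, `reference`, `chrom`, `start`,
#'   `end`, `gene_id`, `read_count`, `nc`.
#' @export
gene_coverage <- function(track, gene, genome_size) {
  stopifnot(inherits(track, "depth_track"), inherits(gene, "gene_model"))
  rc <- region_read_count(track, gene$chrom, gene$start, gene$end)
  data.frame(genotype = track$genotype, reference = track$reference,
             chrom = gene$chrom, start = gene$start, end = gene$end,
             gene_id = gene$gene_id,
             read_count = rc,
             nc = normalize_coverage(rc, gene$end - gene$start,
                                     track$total_mapped_reads, genome_size),
             stringsAsFactors = FALSE)
}

#' @rdname gene_coverage
#' @param genes a `gene_set`.
#' @export
coverage_table <- function(track, genes, genome_size) {
  do.call(rbind, lapply(genes, gene_coverage, track = track,
                        genome_size = genome_size))
}

# ---- track I/O --------------------------------------------------------------

#' Write / read depth tracks as BedGraph plus a sidecar TSV
#'
#' The BedGraph holds non-zero depth runs (0-based half-open); the sidecar
#' TSV carries the metadata a BedGraph cannot: genotype, reference, mode,
#' read length, total mapped reads and chromosome lengths.
#'
#' @param track a [depth_track()].
#' @param path BedGraph path; the sidecar is written to `<path>.meta.tsv`.
#' @return `read_depth_track()` returns a [depth_track()].
#' @export
write_depth_track <- function(track, path) {
  rows <- list()
  for (ch in names(track$depth)) {
    r <- rle(track$depth[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    nz <- r$values != 0
    if (any(nz)) {
      rows[[ch]] <- data.frame(chrom = ch, start = starts[nz], end = ends[nz],
                               score = r$values[nz], stringsAsFactors = FALSE)
    }
  }
  bg <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               score = numeric())
  utils::write.table(bg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- data.frame(chrom = names(track$depth),
                     chrom_length = vapply(track$depth, length, integer(1)),
                     genotype = track$genotype, reference = track$reference,
                     mode = track$mode, read_length = track$read_length,
                     total_mapped_reads = track$total_mapped_reads,
                     stringsAsFactors = FALSE)
  utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(track$junction_reads) > 0) {
    utils::write.table(
      data.frame(event = names(track$junction_reads),
                 reads = as.numeric(track$junction_reads)),
      paste0(path, ".junctions.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_depth_track
#' @export
read_depth_track <- function(path) {
  meta <- utils::read.table(paste0(path, ".meta.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  depth <- lapply(stats::setNames(meta$chrom_length, meta$chrom),
                  function(L) integer(L))
  info <- file.info(path)
  if (!is.na(info$size) && info$size > 0) {
    bg <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "score"),
                            stringsAsFactors = FALSE)
    for (ch in unique(bg$chrom)) {
      part <- bg[bg$chrom == ch, , drop = FALSE]
      L <- length(depth[[ch]])
      delta <- numeric(L + 1)
      delta[part$start + 1] <- delta[part$start + 1] + part$score
      delta[part$end + 1] <- delta[part$end + 1] - part$score
      depth[[ch]] <- as.integer(round(cumsum(delta)[seq_len(L)]))
    }
  }
  junctions <- NULL
  jpath <- paste0(path, ".junctions.tsv")
  if (file.exists(jpath)) {
    j <- utils::read.table(jpath, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    junctions <- stats::setNames(j$reads, j$event)
  }
  depth_track(depth, reference = meta$reference[1], mode = meta$mode[1],
              genotype = meta$genotype[1],
              total_mapped_reads = meta$total_mapped_reads[1],
              read_length = meta$read_length[1],
              junction_reads = junctions)
}
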