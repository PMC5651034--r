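#' Genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' (0-based, half-open) and optionally `strand`. The half-open convention is
#' used everywhere inside the package; conversion to the 1-based inclusive
#' dialects of VCF/GFF3 happens only at file boundaries.
#'
#' @param chrom chromosome / sequence identifiers.
#' @param start 0-based inclusive start offsets.
#' @param end exclusive end offsets.
#' @param strand `"+"`, `"-"` or `"*"` (unspecified).
#' @return A validated data frame of intervals.
#' @examples
#' genomic_interval("A01", 0, 100)
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  strand = as.character(strand),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    stop("interval chrom must be non-empty")
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    stop("intervals require 0 <= start < end")
  }
  invisible(x)
}

#' Overlap length of two intervals
#'
#' @param a,b single-row interval data frames (see [genomic_interval()]).
#' @return Overlap length in bases; 0 for different chromosomes or abutting
#'   half-open intervals.
#' @examples
#' interval_overlap(genomic_interval("c", 0, 10), genomic_interval("c", 5, 20))
#' @export
interval_overlap <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

#' Merge overlapping or abutting intervals
#'
#' Returns the minimal sorted disjoint set covering the same bases, merging
#' abutting intervals. The union is computed per chromosome with
#' [IRanges::reduce()].
#'
#' @param x interval data frame.
#' @return Sorted disjoint interval data frame (strand dropped).
#' @examples
#' merge_overlapping_intervals(genomic_interval("c", c(0, 3), c(5, 8)))
#' @export
merge_overlapping_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(x, x$chrom), function(part) {
    ir <- IRanges::reduce(IRanges::IRanges(start = part$start + 1,
                                           end = part$end))
    data.frame(chrom = part$chrom[1],
               start = IRanges::start(ir) - 1,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out
}

#' Associate covered regions with annotated genes and capture targets
#'
#' A region enters the CNV analysis if it overlaps an annotated gene on its
#' own reference, or has a hit in the externally supplied region-to-target
#' table (a sequence-similarity surrogate), or both; purely non-genic regions
#' are excluded. When several genes overlap one region the gene with the
#' largest overlap wins, ties broken by lexicographic `gene_id`.
#'
#' @param regions interval data frame with a `region_id` column (unique).
#' @param genes a `gene_set` (see [gene_model()]).
#' @param target_map data frame with columns `region_id`, `target_gene`
#'   (may be `NULL` for none).
#' @return Data frame: `region_id`, `chrom`, `start`, `end`, `gene_id`,
#'   `target_gene`, `excluded`.
#' @export
assign_regions_to_genes <- function(regions, genes, target_map = NULL) {
  validate_intervals(regions)
  if (is.null(regions$region_id)) {
    regions$region_id <- sprintf("region_%04d", seq_len(nrow(regions)))
  }
  if (anyDuplicated(regions$region_id)) {
    stop("duplicate region identifiers")
  }
  gene_tab <- gene_table(genes)
  hit_gene <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    cand <- gene_tab[gene_tab$chrom == regions$chrom[i] &
                       gene_tab$start < regions$end[i] &
                       gene_tab$end > regions$start[i], , drop = FALSE]
    if (nrow(cand) == 0) {
      hit_gene[i] <- NA_character_
    } else {
      ov <- pmin(cand$end, regions$end[i]) - pmax(cand$start, regions$start[i])
      cand <- cand[order(-ov, cand$gene_id), , drop = FALSE]
      hit_gene[i] <- cand$gene_id[1]
    }
  }
  tg <- rep(NA_character_, nrow(regions))
  if (!is.null(target_map) && nrow(target_map) > 0) {
    m <- match(regions$region_id, target_map$region_id)
    tg <- as.character(target_map$target_gene[m])
  }
  data.frame(region_id = regions$region_id,
             chrom = regions$chrom, start = regions$start, end = regions$end,
             gene_id = hit_gene, target_gene = tg,
             excluded = is.na(hit_gene) & is.na(tg),
             stringsAsFactors = FALSE)
}
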