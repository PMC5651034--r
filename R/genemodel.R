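#' Gene models
#'
#' A gene model carries an annotation identifier, the dotted copy name used
#' for cross-species bookkeeping (`Genus.GENE.Chrom`, e.g. `Bna.ZTL.A02`,
#' with optional `a`/`b` suffixes for co-located duplicates), the gene span,
#' and ordered exon and CDS intervals, all 0-based half-open.
#'
#' Exons must be sorted and non-overlapping and the CDS must lie inside the
#' exons. A CDS length not divisible by three is reported via the
#' `frame_ok` flag rather than rejected — pseudogenes are part of the data.
#'
#' @param gene_id annotation identifier (e.g. `Bra020445`).
#' @param copy_name dotted copy name (e.g. `Bna.ZTL.A02`).
#' @param chrom chromosome.
#' @param start,end gene span, 0-based half-open.
#' @param exons,cds two-column matrices (start, end) of ordered intervals.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, copy_name, chrom, start, end,
                       exons, cds, strand = "+") {
  exons <- as_interval_matrix(exons)
  cds <- as_interval_matrix(cds)
  stopifnot(start >= 0, start < end, strand %in% c("+", "-"))
  if (nrow(exons) == 0) stop("gene model needs at least one exon")
  if (is.unsorted(exons[, 1], strictly = TRUE) && nrow(exons) > 1) {
    stop("exons must be sorted")
  }
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    stop("exons must be non-overlapping")
  }
  if (any(exons[, 1] < start) || any(exons[, 2] > end)) {
    stop("exons outside gene span")
  }
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2])
    if (!inside) stop("CDS interval not contained in an exon")
  }
  cds_len <- sum(cds[, 2] - cds[, 1])
  structure(list(gene_id = gene_id, copy_name = copy_name, chrom = chrom,
                 start = start, end = end, exons = exons, cds = cds,
                 strand = strand, cds_length = cds_len,
                 frame_ok = cds_len > 0 && cds_len %% 3 == 0),
            class = "gene_model")
}

as_interval_matrix <- function(x) {
  m <- matrix(as.numeric(unlist(x)), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  if (nrow(m) > 0 && any(m[, 1] >= m[, 2])) stop("empty or inverted interval")
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) %s:%d-%d [%s] %d exon(s), CDS %d bp%s\n",
              x$gene_id, x$copy_name, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons), x$cds_length,
              if (x$frame_ok) "" else " (out of frame)"))
  invisible(x)
}

#' @param genes list of `gene_model` objects.
#' @rdname gene_model
#' @export
gene_set <- function(genes) {
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_model")))
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene_id in gene set")
  names(genes) <- ids
  structure(genes, class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set with %d gene model(s)\n", length(x)))
  invisible(x)
}

gene_table <- function(genes) {
  if (inherits(genes, "gene_model")) genes <- gene_set(list(genes))
  do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g$gene_id, copy_name = g$copy_name, chrom = g$chrom,
               start = g$start, end = g$end, strand = g$strand,
               stringsAsFactors = FALSE)
  }))
}

#' Gene spans as capture-target intervals
#'
#' @param genes a `gene_set` (or single `gene_model`).
#' @return Interval data frame (`chrom`, `start`, `end`, `region_id`),
#'   0-based half-open, usable as a capture-target set.
#' @export
gene_spans <- function(genes) {
  tab <- gene_table(genes)
  data.frame(chrom = tab$chrom, start = tab$start, end = tab$end,
             region_id = tab$gene_id, stringsAsFactors = FALSE)
}

#' Parse a dotted copy name
#'
#' Splits `Genus.GENE.Chrom[suffix]` names such as `Bna.ZTL.A02` or
#' `Bol.FLC.C09a` into their components. Gene symbols containing dots or
#' dashes (e.g. `CO-li`) are kept intact: the first and last dot delimit the
#' fields.
#'
#' @param x character vector of copy names.
#' @return Data frame with `genus`, `gene`, `chrom`, `suffix`, `subgenome`
#'   (first letter of the chromosome field).
#' @examples
#' parse_copy_name(c("Bna.ZTL.A02", "Bol.FLC.C09a"))
#' @export
parse_copy_name <- function(x) {
  m <- regmatches(x, regexec("^([^.]+)\\.(.+)\\.([A-Za-z]+[0-9n]+)([a-z]?)$", x))
  bad <- vapply(m, length, integer(1)) != 5
  if (any(bad)) stop("unparseable copy name(s): ", paste(x[bad], collapse = ", "))
  out <- do.call(rbind, lapply(m, function(p) {
    data.frame(genus = p[2], gene = p[3], chrom = p[4], suffix = p[5],
               stringsAsFactors = FALSE)
  }))
  out$subgenome <- toupper(substr(out$chrom, 1, 1))
  out
}

#' Read / write gene models as GFF3
#'
#' Uses `gene`, `exon` and `CDS` features; the copy name travels in the
#' `Name` attribute of the gene feature. Coordinates follow the 1-based
#' inclusive GFF3 dialect on disk.
#'
#' @param genes a `gene_set`.
#' @param path GFF3 file path.
#' @return `read_gene_models()` returns a `gene_set`.
#' @export
write_gene_models <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    feat <- function(type, s, e, id, parent = NULL) {
      attrs <- paste0("ID=", id)
      if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
      if (type == "gene") attrs <- paste0(attrs, ";Name=", g$copy_name)
      sprintf("%s\tcapcnv\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, s + 1, e, g$strand, attrs)
    }
    rows[[length(rows) + 1]] <- feat("gene", g$start, g$end, g$gene_id)
    for (i in seq_len(nrow(g$exons))) {
      rows[[length(rows) + 1]] <- feat("exon", g$exons[i, 1], g$exons[i, 2],
                                       paste0(g$gene_id, ".exon", i), g$gene_id)
    }
    for (i in seq_len(nrow(g$cds))) {
      rows[[length(rows) + 1]] <- feat("CDS", g$cds[i, 1], g$cds[i, 2],
                                       paste0(g$gene_id, ".cds", i), g$gene_id)
    }
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  genes <- lapply(seq_len(nrow(gene_rows)), function(i) {
    gid <- gene_rows$ID[i]
    kids <- df[!is.na(df$Parent) & vapply(df$Parent, function(p) gid %in% p,
                                          logical(1)), , drop = FALSE]
    ex <- kids[kids$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cd <- kids[kids$type == "CDS", , drop = FALSE]
    cd <- cd[order(cd$start), , drop = FALSE]
    gene_model(gene_id = gid,
               copy_name = if (!is.null(gene_rows$Name)) gene_rows$Name[i] else gid,
               chrom = as.character(gene_rows$seqnames[i]),
               start = gene_rows$start[i] - 1, end = gene_rows$end[i],
               exons = cbind(ex$start - 1, ex$end),
               cds = cbind(cd$start - 1, cd$end),
               strand = as.character(gene_rows$strand[i]))
  })
  gene_set(genes)
}
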