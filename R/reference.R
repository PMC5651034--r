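#' Reference sequence sets
#'
#' A `reference_set` holds named nucleotide sequences (alphabet ACGTN) as
#' plain character strings plus the total genome size used by coverage
#' normalization. FASTA input/output goes through Biostrings.
#'
#' @param sequences named character vector of nucleotide sequences.
#' @param name optional display name for the reference.
#' @return An object of class `reference_set`.
#' @examples
#' ref <- reference_set(c(chr1 = "ACGTACGT"))
#' genome_size(ref)
#' @export
reference_set <- function(sequences, name = "reference") {
  stopifnot(is.character(sequences), length(sequences) > 0,
            !is.null(names(sequences)), all(nzchar(names(sequences))))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) stop("reference alphabet must be ACGTN")
  structure(list(sequences = sequences, name = name),
            class = "reference_set")
}

#' @rdname reference_set
#' @param ref a `reference_set`.
#' @export
genome_size <- function(ref) {
  stopifnot(inherits(ref, "reference_set"))
  sum(nchar(ref$sequences))
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set '%s': %d sequence(s), %d bp total\n",
              x$name, length(x$sequences), genome_size(x)))
  invisible(x)
}

chrom_lengths <- function(ref) {
  stats::setNames(nchar(ref$sequences), names(ref$sequences))
}

#' Read / write references as FASTA
#'
#' @param path FASTA file path.
#' @param name display name for the loaded reference.
#' @return `read_reference_fasta()` returns a `reference_set`;
#'   `write_reference_fasta()` returns `path` invisibly.
#' @export
read_reference_fasta <- function(path, name = basename(path)) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  reference_set(seqs, name = name)
}

#' @rdname read_reference_fasta
#' @param ref a `reference_set`.
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "reference_set"))
  ss <- Biostrings::DNAStringSet(ref$sequences)
  Biostrings::writeXStringSet(ss, path, width = 80)
  invisible(path)
}

#' Excise or replace spans of a reference
#'
#' Mirrors the reference-patching step applied when a misassembled gene copy
#' is removed from a mapping target or swapped for an externally sequenced
#' allele: listed spans are excised, spans with a replacement sequence are
#' substituted, and a coordinate lift table translating surviving old
#' offsets to new offsets is returned alongside the patched reference.
#'
#' @param ref a `reference_set`.
#' @param excise interval data frame of spans to remove (may be empty).
#' @param replace optional named list: names are `"chrom:start-end"`
#'   (0-based half-open) spans to substitute, values replacement sequences.
#' @return List with elements `reference` (patched `reference_set`) and
#'   `lift` (data frame `chrom`, `old_start`, `old_end`, `shift` giving, for
#'   each surviving segment, the offset to add to an old coordinate).
#' @examples
#' ref <- reference_set(c(c1 = "AAAACCCCGGGGTTTT"))
#' patch_reference(ref, excise = genomic_interval("c1", 4, 8))
#' @export
patch_reference <- function(ref, excise = NULL, replace = NULL) {
  stopifnot(inherits(ref, "reference_set"))
  edits <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      seq = character(), stringsAsFactors = FALSE)
  if (!is.null(excise) && nrow(excise) > 0) {
    validate_intervals(excise)
    edits <- rbind(edits, data.frame(chrom = excise$chrom, start = excise$start,
                                     end = excise$end, seq = "",
                                     stringsAsFactors = FALSE))
  }
  if (!is.null(replace) && length(replace) > 0) {
    spans <- do.call(rbind, lapply(names(replace), parse_span))
    if (any(grepl("[^ACGTN]", unlist(replace)))) {
      stop("replacement sequences must use the ACGTN alphabet")
    }
    edits <- rbind(edits, data.frame(chrom = spans$chrom, start = spans$start,
                                     end = spans$end,
                                     seq = unlist(replace, use.names = FALSE),
                                     stringsAsFactors = FALSE))
  }
  if (nrow(edits) == 0) {
    lift <- data.frame(chrom = names(ref$sequences), old_start = 0,
                       old_end = nchar(ref$sequences), shift = 0,
                       stringsAsFactors = FALSE)
    rownames(lift) <- NULL
    return(list(reference = ref, lift = lift))
  }
  edits <- edits[order(edits$chrom, edits$start), , drop = FALSE]
  if (any(duplicated(edits[c("chrom", "start", "end")]))) {
    stop("duplicate edit spans")
  }
  for (ch in unique(edits$chrom)) {
    e <- edits[edits$chrom == ch, , drop = FALSE]
    if (!ch %in% names(ref$sequences)) stop("edit span on unknown chrom: ", ch)
    if (any(e$end > nchar(ref$sequences[[ch]]))) {
      stop("edit span outside reference: ", ch)
    }
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      stop("edit spans must be disjoint")
    }
  }
  seqs <- ref$sequences
  lift <- list()
  for (ch in names(seqs)) {
    e <- edits[edits$chrom == ch, , drop = FALSE]
    old <- seqs[[ch]]
    if (nrow(e) == 0) {
      lift[[ch]] <- data.frame(chrom = ch, old_start = 0,
                               old_end = nchar(old), shift = 0,
                               stringsAsFactors = FALSE)
      next
    }
    pieces <- character(0)
    cursor <- 0   # old coordinate of next unconsumed base
    new_pos <- 0  # new coordinate where the next piece lands
    segs <- list()
    for (i in seq_len(nrow(e))) {
      keep <- substr(old, cursor + 1, e$start[i])
      if (nchar(keep) > 0) {
        segs[[length(segs) + 1]] <- data.frame(
          chrom = ch, old_start = cursor, old_end = e$start[i],
          shift = new_pos - cursor, stringsAsFactors = FALSE)
      }
      pieces <- c(pieces, keep, e$seq[i])
      new_pos <- new_pos + nchar(keep) + nchar(e$seq[i])
      cursor <- e$end[i]
    }
    keep <- substr(old, cursor + 1, nchar(old))
    if (nchar(keep) > 0) {
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ch, old_start = cursor, old_end = nchar(old),
        shift = new_pos - cursor, stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, keep)
    seqs[[ch]] <- paste(pieces, collapse = "")
    lift[[ch]] <- do.call(rbind, segs)
  }
  seqs <- seqs[nchar(seqs) > 0]
  lift <- do.call(rbind, lift)
  rownames(lift) <- NULL
  list(reference = reference_set(seqs, name = paste0(ref$name, ".patched")),
       lift = lift)
}

#' Lift an old coordinate through a patch lift table
#'
#' @param lift lift table from [patch_reference()].
#' @param chrom,pos old chromosome and 0-based offset.
#' @return New 0-based offset, or `NA` if the base was excised/replaced.
#' @export
lift_coordinate <- function(lift, chrom, pos) {
  hit <- lift[lift$chrom == chrom & lift$old_start <= pos & pos < lift$old_end, ]
  if (nrow(hit) == 0) return(NA_real_)
  pos + hit$shift[1]
}

parse_span <- function(s) {
  m <- regmatches(s, regexec("^(.+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4) stop("span must be 'chrom:start-end': ", s)
  data.frame(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]),
             stringsAsFactors = FALSE)
}
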