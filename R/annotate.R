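#' Annotate the functional consequence of a variant on a gene copy
#'
#' Re-derives the consequence vocabulary used for capture-target genes:
#' substitutions in the CDS are translated strand-aware to `synonymous`,
#' `nonsynonymous` (with Grantham distance and radicality), `stop_gain`
#' (an alternate stop before the natural end) or `stop_loss` (the natural
#' stop destroyed, producing a longer peptide); CDS InDels become
#' `inframe_indel` or `frameshift_indel` by length modulo 3; substitutions
#' in the first or last two intron bases are `splice_donor` /
#' `splice_acceptor`; everything else inside the gene span (UTR/intron) is
#' `silent`. Genes whose CDS length is not divisible by three are flagged
#' as pseudogene candidates and translation-dependent categories are
#' skipped.
#'
#' @param record one-row variant record (1-based `pos`, `ref`, `alt`,
#'   `type`).
#' @param gene a `gene_model`.
#' @param ref the `reference_set` the record is called against.
#' @return One-row data frame: `gene_id`, `copy_name`, `category`,
#'   `protein_change`, `grantham_distance`, `radicality`, `pseudogene`.
#' @export
annotate_variant <- function(record, gene, ref) {
  stopifnot(inherits(gene, "gene_model"), inherits(ref, "reference_set"))
  pos0 <- record$pos - 1
  if (record$chrom != gene$chrom || pos0 < gene$start || pos0 >= gene$end) {
    stop("record outside the gene span of ", record$gene_id %||% gene$gene_id)
  }
  ann <- data.frame(gene_id = gene$gene_id, copy_name = gene$copy_name,
                    category = NA_character_,
                    protein_change = NA_character_,
                    grantham_distance = NA_integer_,
                    radicality = "none", pseudogene = !gene$frame_ok,
                    stringsAsFactors = FALSE)
  indel_size <- abs(nchar(record$ref) - nchar(record$alt))
  in_cds <- any(gene$cds[, 1] <= pos0 & pos0 < gene$cds[, 2])

  if (record$type == "indel") {
    if (in_cds) {
      ann$category <- if (indel_size %% 3 == 0) "inframe_indel"
                      else "frameshift_indel"
    } else {
      sp <- splice_site_class(gene, pos0)
      ann$category <- if (!is.na(sp)) sp else "silent"
    }
    return(ann)
  }

  # substitutions
  if (!in_cds) {
    sp <- splice_site_class(gene, pos0)
    ann$category <- if (!is.na(sp)) sp else "silent"
    return(ann)
  }
  if (!gene$frame_ok) return(ann)  # pseudogene: cannot translate

  cds_len <- gene$cds_length
  lens <- gene$cds[, 2] - gene$cds[, 1]
  k <- which(gene$cds[, 1] <= pos0 & pos0 < gene$cds[, 2])
  fwd_off <- sum(lens[seq_len(k - 1)]) + (pos0 - gene$cds[k, 1])
  cpos <- if (gene$strand == "+") fwd_off else cds_len - 1 - fwd_off

  coding <- paste(vapply(seq_len(nrow(gene$cds)), function(i) {
    substr0(ref$sequences[[gene$chrom]], gene$cds[i, 1], gene$cds[i, 2])
  }, character(1)), collapse = "")
  if (gene$strand == "-") coding <- revcomp(coding)

  ci <- cpos %/% 3
  codon <- substr(coding, ci * 3 + 1, ci * 3 + 3)
  alt_base <- if (gene$strand == "+") record$alt else
    chartr("ACGT", "TGCA", record$alt)
  alt_codon <- codon
  substr(alt_codon, cpos %% 3 + 1, cpos %% 3 + 1) <- alt_base
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon])
  aa_alt <- unname(code[alt_codon])
  if (is.na(aa_ref) || is.na(aa_alt)) stop("untranslatable codon at ", record$pos)

  ann$protein_change <- paste0(aa_ref, ci + 1, aa_alt)
  if (aa_ref == aa_alt) {
    ann$category <- "synonymous"
  } else if (aa_alt == "*") {
    ann$category <- "stop_gain"
  } else if (aa_ref == "*") {
    ann$category <- "stop_loss"
  } else {
    g <- grantham_class(aa_ref, aa_alt)
    ann$category <- "nonsynonymous"
    ann$grantham_distance <- g$distance
    ann$radicality <- g$radicality
  }
  ann
}

# donor = first two intron bases in transcription direction, acceptor the
# last two; returns NA when pos0 is not a splice site
splice_site_class <- function(gene, pos0) {
  n_ex <- nrow(gene$exons)
  if (n_ex < 2) return(NA_character_)
  for (i in seq_len(n_ex - 1)) {
    int_s <- gene$exons[i, 2]
    int_e <- gene$exons[i + 1, 1]
    if (int_e - int_s < 4) next
    left2 <- pos0 >= int_s && pos0 < int_s + 2
    right2 <- pos0 >= int_e - 2 && pos0 < int_e
    if (left2) return(if (gene$strand == "+") "splice_donor" else "splice_acceptor")
    if (right2) return(if (gene$strand == "+") "splice_acceptor" else "splice_donor")
  }
  NA_character_
}

#' Annotate a record table against a gene set
#'
#' Each record is annotated against every gene copy it overlaps,
#' independently (no worst-across-genes collapsing); records overlapping no
#' gene are dropped.
#'
#' @param records variant record table.
#' @param genes a `gene_set`.
#' @param ref the matching `reference_set`.
#' @return Data frame of annotations joined to the record columns.
#' @export
annotate_variants <- function(records, genes, ref) {
  tab <- gene_table(genes)
  out <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    hit <- tab$gene_id[tab$chrom == rec$chrom &
                         tab$start <= rec$pos - 1 & rec$pos - 1 < tab$end]
    for (gid in hit) {
      ann <- annotate_variant(rec, genes[[gid]], ref)
      out[[length(out) + 1]] <- cbind(rec, ann, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.severity_levels <- c(silent = 1, synonymous = 2, inframe_indel = 3,
                      nonsyn_conservative = 4,
                      nonsyn_moderately_conservative = 5,
                      nonsyn_moderately_radical = 6, nonsyn_radical = 7,
                      splice_donor = 8, splice_acceptor = 8,
                      stop_gain = 9, stop_loss = 9, frameshift_indel = 10)

severity_score <- function(category, radicality = "none") {
  key <- ifelse(category == "nonsynonymous",
                paste0("nonsyn_", radicality), category)
  s <- .severity_levels[key]
  s[is.na(s)] <- 0
  unname(s)
}

#' Rank consequence annotations by severity
#'
#' Implements the hierarchic display convention of the pathway reports:
#' frameshift > stop gain/loss > splice > nonsynonymous (radical down to
#' conservative) > in-frame InDel > synonymous > silent. Less severe
#' categories are masked by more severe ones when one copy is summarized.
#'
#' @param annotations annotation data frame for one gene copy (columns
#'   `category`, `radicality`).
#' @return List with `most_severe` (category string, `NA` on empty input)
#'   and `ordered` (the annotations sorted most-severe first).
#' @export
severity_rank <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0) {
    return(list(most_severe = NA_character_, ordered = annotations))
  }
  sc <- severity_score(annotations$category, annotations$radicality)
  ord <- order(-sc)
  list(most_severe = annotations$category[ord[1]],
       ordered = annotations[ord, , drop = FALSE])
}
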