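#' Summarize variant classes per genotype
#'
#' Counts, per genotype and variant type, the totals and their breakdown
#' into silent, synonymous/non-synonymous (SNPs) or in-frame/frameshift
#' (InDels), splice and stop categories, plus the homozygous/heterozygous
#' partition. When a record is annotated against several gene copies its
#' most severe category is counted once.
#'
#' @param annotations output of [annotate_variants()] (may be empty).
#' @param records the full record table the annotations derive from.
#' @return Data frame, one row per genotype x variant type.
#' @export
variant_class_summary <- function(annotations, records) {
  if (nrow(records) == 0) {
    return(data.frame(genotype = character(), variant_type = character(),
                      total = numeric(), hom = numeric(), het = numeric(),
                      silent = numeric(), synonymous = numeric(),
                      nonsynonymous = numeric(), inframe = numeric(),
                      frameshift = numeric(), splice = numeric(),
                      stop = numeric(), stringsAsFactors = FALSE))
  }
  key <- function(d) paste(d$genotype, d$chrom, d$pos, d$ref, d$alt)
  records$category <- "silent"   # records outside annotated genes
  if (!is.null(annotations) && nrow(annotations) > 0) {
    ak <- key(annotations)
    sc <- severity_score(annotations$category, annotations$radicality)
    for (k in unique(ak)) {
      rows <- which(ak == k)
      best <- annotations$category[rows[which.max(sc[rows])]]
      records$category[key(records) == k] <- best
    }
  }
  out <- list()
  for (g in unique(records$genotype)) {
    for (vt in c("snp", "indel")) {
      r <- records[records$genotype == g & records$type == vt, , drop = FALSE]
      cat_n <- function(...) sum(r$category %in% c(...))
      out[[length(out) + 1]] <- data.frame(
        genotype = g, variant_type = vt, total = nrow(r),
        hom = sum(r$zygosity == "hom"), het = sum(r$zygosity == "het"),
        silent = cat_n("silent"),
        synonymous = cat_n("synonymous"),
        nonsynonymous = cat_n("nonsynonymous"),
        inframe = cat_n("inframe_indel"),
        frameshift = cat_n("frameshift_indel"),
        splice = cat_n("splice_donor", "splice_acceptor"),
        stop = cat_n("stop_gain", "stop_loss"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-pathway gene family report
#'
#' One row per gene copy and genotype: the most severe variant category
#' (hierarchic masking, see [severity_rank()]), the CNV status of the copy
#' in that genotype, and the presence frame (`found`, `not_found`,
#' `unannotated`) from the cross-species calls when supplied.
#'
#' @param annotations annotation table (with `gene_id`, `genotype`,
#'   `category`, `radicality`).
#' @param cnv_calls output of [classify_cnv_table()] (with `gene_id`,
#'   `call`, `carrier`).
#' @param groups membership table: `gene_id`, `copy_name`, `family`.
#' @param genotypes genotypes to report (default: those in the inputs).
#' @param cross_calls optional cross-species calls with `copy_name` and
#'   `status`.
#' @return Data frame: `family`, `copy_name`, `gene_id`, `genotype`,
#'   `most_severe`, `cnv`, `presence`.
#' @export
pathway_report <- function(annotations, cnv_calls, groups, genotypes = NULL,
                           cross_calls = NULL) {
  known <- unique(groups$gene_id)
  bad <- setdiff(unique(cnv_calls$gene_id), known)
  if (length(bad) > 0) {
    stop("copy in calls but not in group table: ", paste(bad, collapse = ", "))
  }
  genotypes <- genotypes %||%
    unique(c(annotations$genotype, cnv_calls$carrier))
  genotypes <- genotypes[!is.na(genotypes)]
  out <- list()
  for (i in seq_len(nrow(groups))) {
    grp <- groups[i, ]
    for (g in genotypes) {
      ann <- annotations[!is.na(annotations$gene_id) &
                           annotations$gene_id == grp$gene_id &
                           annotations$genotype == g, , drop = FALSE]
      sev <- severity_rank(ann)$most_severe
      call_row <- cnv_calls[cnv_calls$gene_id == grp$gene_id, , drop = FALSE]
      cnv <- "none"
      if (nrow(call_row) > 0 && !is.na(call_row$carrier[1]) &&
          call_row$carrier[1] == g) {
        cnv <- if (call_row$call[1] == "deletion_in_low") "deletion"
               else "duplication"
      }
      presence <- "found"
      if (!is.null(cross_calls) && grp$copy_name %in% cross_calls$copy_name) {
        st <- cross_calls$status[cross_calls$copy_name == grp$copy_name][1]
        presence <- switch(st, absent = "not_found",
                           reduced_ambiguous = "unannotated",
                           exchanged = "exchanged", "found")
      }
      out[[length(out) + 1]] <- data.frame(
        family = grp$family, copy_name = grp$copy_name,
        gene_id = grp$gene_id, genotype = g,
        most_severe = if (is.na(sev)) "none" else sev,
        cnv = cnv, presence = presence, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare CNV calls with the injected truth
#'
#' Reduces the truth ledgers of a two-genotype species to the expected
#' gene-level CNV events (gene losses as deletions, tandem duplications as
#' duplications; events shared identically by both genotypes carry no
#' relative signal and are excluded), then scores the calls by precision
#' and recall on (gene, event type, carrier genotype).
#'
#' @param calls output of [classify_cnv_table()].
#' @param truths named list of truth ledgers, one per genotype.
#' @return List: `truth` (expected events), `called` (positive calls),
#'   `tp`, `precision`, `recall`.
#' @export
evaluate_cnv_recovery <- function(calls, truths) {
  expected <- list()
  for (g in names(truths)) {
    tr <- truths[[g]]
    tr <- tr[tr$type %in% c("gene_loss", "duplication") &
               tr$zygosity == "hom", , drop = FALSE]
    if (nrow(tr) > 0) {
      expected[[g]] <- data.frame(
        gene_id = tr$gene_id, carrier = g,
        event = ifelse(tr$type == "gene_loss", "deletion", "duplication"),
        stringsAsFactors = FALSE)
    }
  }
  expected <- do.call(rbind, expected)
  if (!is.null(expected)) {
    shared <- table(paste(expected$gene_id, expected$event))
    both <- names(shared[shared >= 2])
    expected <- expected[!(paste(expected$gene_id, expected$event) %in% both), ,
                         drop = FALSE]
  } else {
    expected <- data.frame(gene_id = character(), carrier = character(),
                           event = character(), stringsAsFactors = FALSE)
  }
  pos <- calls[calls$call %in% c("deletion_in_low", "duplication_in_high"), ,
               drop = FALSE]
  called <- data.frame(
    gene_id = pos$gene_id, carrier = pos$carrier,
    event = ifelse(pos$call == "deletion_in_low", "deletion", "duplication"),
    stringsAsFactors = FALSE)
  keyfun <- function(d) paste(d$gene_id, d$event, d$carrier)
  tp <- sum(keyfun(called) %in% keyfun(expected))
  list(truth = expected, called = called, tp = tp,
       precision = if (nrow(called) > 0) tp / nrow(called) else NA_real_,
       recall = if (nrow(expected) > 0) tp / nrow(expected) else NA_real_)
}

# consensus gene sequence of a genotype: reference span with its homozygous
# SNPs applied (InDels ignored so sequences stay alignable column-wise)
genotype_gene_sequence <- function(ref, gene, truth = NULL) {
  s <- substr0(ref$sequences[[gene$chrom]], gene$start, gene$end)
  if (!is.null(truth) && nrow(truth) > 0) {
    snps <- truth[truth$type == "snp" & truth$zygosity == "hom" &
                    truth$chrom == gene$chrom &
                    truth$ref_start >= gene$start &
                    truth$ref_start < gene$end, , drop = FALSE]
    for (i in seq_len(nrow(snps))) {
      off <- snps$ref_start[i] - gene$start
      substr(s, off + 1, off + 1) <- snps$alt[i]
    }
  }
  s
}

#' Run the full analysis pipeline on a written dataset
#'
#' Executes every stage on the files produced by [write_dataset()] and
#' writes a report bundle: per-genotype coverage and region tables, CNV
#' calls with the population tiebreak, cross-species copy status and copy
#' reconciliation, large-deletion candidates, short-InDel calls, filtered
#' and homozygous-only variants, consequence annotations, variant class
#' summaries, per-family NJ trees with bootstrap support, the pathway
#' report, a truth-recovery report and a manifest logging every threshold.
#'
#' @param input_dir dataset directory from [write_dataset()].
#' @param output_dir output directory (created if missing).
#' @param thresholds a [threshold_config()].
#' @param seed integer seed (bootstrap resampling).
#' @param tree_families number of gene families to build trees for
#'   (default 5; `Inf` for all).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         thresholds = threshold_config(), seed = 1,
                         tree_families = 5) {
  th <- as_threshold_config(thresholds)
  ds <- read_dataset(input_dir)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  p <- function(...) file.path(output_dir, ...)
  tsv <- function(d, f) utils::write.table(d, p(f), sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  species_of <- function(g) if (g %in% ds$meta$species$A) "A" else "C"
  own_ref <- function(g) if (species_of(g) == "A") "diploid_A" else "diploid_C"

  # --- coverage ---------------------------------------------------------
  coverage <- list()
  regions <- list()
  for (g in ds$meta$genotypes) {
    ref <- ds$refs[[own_ref(g)]]
    genes <- ds$genes[[own_ref(g)]]
    track <- ds$tracks[[g]]$strict_own
    coverage[[g]] <- coverage_table(track, genes, genome_size(ref))
    tsv(coverage[[g]], sprintf("coverage_%s.tsv", g))
    regions[[g]] <- discover_covered_regions(track, genome_size(ref), th)
    tsv(regions[[g]], sprintf("regions_%s.tsv", g))
  }

  # --- CNV calls with population tiebreak -------------------------------
  cnv <- list()
  for (sp in names(ds$meta$species)) {
    gg <- unlist(ds$meta$species[[sp]])
    cnv[[sp]] <- classify_cnv_table(coverage[[gg[1]]], coverage[[gg[2]]],
                                    pop = ds$pop_cnv, thresholds = th)
  }
  cnv_calls <- do.call(rbind, cnv)
  rownames(cnv_calls) <- NULL
  tsv(cnv_calls, "cnv_calls.tsv")

  # --- cross-species copy status ----------------------------------------
  tet_genes <- ds$genes$tetraploid
  tet_size <- genome_size(ds$refs$tetraploid_hx)
  tet_cov <- lapply(ds$meta$genotypes, function(g) {
    coverage_table(ds$tracks[[g]]$strict_tet, tet_genes, tet_size)
  })
  names(tet_cov) <- ds$meta$genotypes
  cross <- list()
  for (gid in names(tet_genes)) {
    gm <- tet_genes[[gid]]
    pop_mean <- ds$pop_cross$mean_nc[ds$pop_cross$gene_id == gid][1]
    pct <- function(g) {
      nc <- tet_cov[[g]]$nc[tet_cov[[g]]$gene_id == gid][1]
      100 * nc / pop_mean
    }
    pcts_A <- vapply(unlist(ds$meta$species$A), pct, numeric(1))
    pcts_C <- vapply(unlist(ds$meta$species$C), pct, numeric(1))
    sub <- parse_copy_name(gm$copy_name)$subgenome
    cc <- classify_cross_species(round(pcts_A, 1), round(pcts_C, 1), sub, th)
    cross[[length(cross) + 1]] <- cbind(
      copy_name = gm$copy_name, gene_id = gid, cc, stringsAsFactors = FALSE)
  }
  cross_calls <- do.call(rbind, cross)
  tsv(cross_calls, "cross_species.tsv")

  # copy reconciliation: tetraploid copies vs their diploid orthologs
  dip_copy <- function(gid) {
    for (ref in c("diploid_A", "diploid_C")) {
      if (gid %in% names(ds$genes[[ref]])) {
        return(ds$genes[[ref]][[gid]]$copy_name)
      }
    }
    NA_character_
  }
  omap <- data.frame(
    napus_copy = cross_calls$copy_name,
    diploid_copy = vapply(cross_calls$gene_id, dip_copy, character(1)),
    diploid_covered = cross_calls$status != "absent",
    stringsAsFactors = FALSE)
  reconciliation <- reconcile_copy_sets(omap, cross_calls)
  tsv(reconciliation, "reconciliation.tsv")

  # --- large deletions and short InDels ---------------------------------
  bigdel <- list()
  short_indels <- list()
  for (sp in names(ds$meta$species)) {
    gg <- unlist(ds$meta$species[[sp]])
    for (k in 1:2) {
      g <- gg[k]
      other <- gg[3 - k]
      genes <- ds$genes[[own_ref(g)]]
      cand <- scan_large_deletions(ds$tracks[[g]]$strict_own,
                                   ds$tracks[[other]]$strict_own,
                                   ds$tracks[[g]]$gapped_own, th, genes)
      bigdel[[g]] <- cand
      tr <- ds$truth[[g]]
      if (!is.null(tr) && nrow(tr) > 0) {
        si <- call_short_indels(ds$tracks[[g]]$gapped_own, tr, th)
        if (nrow(si) > 0) {
          short_indels[[g]] <- cbind(genotype = g, si,
                                     stringsAsFactors = FALSE)
        }
      }
    }
  }
  bigdel_all <- do.call(rbind, bigdel)
  rownames(bigdel_all) <- NULL
  tsv(bigdel_all, "large_deletions.tsv")
  utils::write.table(
    bigdel_all[, c("chrom", "start", "end", "genotype")],
    p("large_deletions.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  short_all <- do.call(rbind, short_indels)
  rownames(short_all) <- NULL
  tsv(short_all, "short_indel_calls.tsv")

  # --- variants: filter, zygosity, annotate -----------------------------
  all_records <- do.call(rbind, ds$records)
  retained <- filter_variants(all_records, th)
  het <- heterozygosity_stats(retained)
  tsv(data.frame(n = het$n,
                 het_fraction_snp = het$het_fraction_snp,
                 het_fraction_indel = het$het_fraction_indel,
                 het_fraction_total = het$het_fraction_total),
      "heterozygosity.tsv")
  hom <- het$homozygous
  write_variant_records(hom, p("variants_homozygous.vcf"), sample = "pooled")
  ann <- list()
  for (g in ds$meta$genotypes) {
    r <- hom[hom$genotype == g, , drop = FALSE]
    if (nrow(r) == 0) next
    a <- annotate_variants(r, ds$genes[[own_ref(g)]], ds$refs[[own_ref(g)]])
    if (nrow(a) > 0) ann[[g]] <- a
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else data.frame()
  rownames(annotations) <- NULL
  tsv(annotations, "annotations.tsv")
  tsv(variant_class_summary(annotations, retained), "variant_summary.tsv")

  # --- NJ trees per gene family -----------------------------------------
  fams <- ds$homoeologs
  n_tree <- min(nrow(fams), tree_families)
  tree_lines <- character(0)
  for (i in seq_len(n_tree)) {
    fam <- fams[i, ]
    ga <- ds$genes$tetraploid[[fam$a_gene]]
    gc <- ds$genes$tetraploid[[fam$c_gene]]
    seqs <- c(TetA = genotype_gene_sequence(ds$refs$tetraploid, ga),
              TetC = genotype_gene_sequence(ds$refs$tetraploid, gc))
    for (g in ds$meta$genotypes) {
      ref <- ds$refs[[own_ref(g)]]
      gid <- if (species_of(g) == "A") fam$a_gene else fam$c_gene
      gm <- ds$genes[[own_ref(g)]][[gid]]
      seqs[[g]] <- genotype_gene_sequence(ref, gm, ds$truth[[g]])
    }
    aln <- dna_alignment(seqs)
    tree <- bootstrap_support(aln, reps = th$bootstrap_reps,
                              seed = seed + i)
    tree_lines <- c(tree_lines,
                    paste0(fam$family, "\t", ape::write.tree(tree)))
  }
  writeLines(tree_lines, p("trees.nwk.tsv"))

  # --- pathway report and recovery --------------------------------------
  groups <- do.call(rbind, lapply(c("diploid_A", "diploid_C"), function(ref) {
    tab <- gene_table(ds$genes[[ref]])
    data.frame(gene_id = tab$gene_id, copy_name = tab$copy_name,
               family = parse_copy_name(tab$copy_name)$gene,
               stringsAsFactors = FALSE)
  }))
  report <- pathway_report(annotations, cnv_calls, groups,
                           genotypes = ds$meta$genotypes)
  tsv(report, "pathway_report.tsv")

  recovery <- evaluate_cnv_recovery(cnv_calls, ds$truth)
  tsv(data.frame(n_truth = nrow(recovery$truth),
                 n_called = nrow(recovery$called), tp = recovery$tp,
                 precision = recovery$precision, recall = recovery$recall),
      "cnv_recovery.tsv")

  manifest <- list(input_dir = normalizePath(input_dir),
                   genotypes = ds$meta$genotypes,
                   thresholds = unclass(th), seed = seed,
                   package_version = as.character(utils::packageVersion("capcnv")),
                   r_version = R.version.string,
                   outputs = list.files(output_dir))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(coverage = coverage, regions = regions,
                 cnv_calls = cnv_calls, cross_calls = cross_calls,
                 reconciliation = reconciliation, large_deletions = bigdel_all,
                 short_indels = short_all, heterozygosity = het,
                 annotations = annotations, pathway = report,
                 recovery = recovery))
}
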