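#' The default synthetic capture study
#'
#' Assembles the full desk-scale study the pipeline is exercised on:
#' \itemize{
#' \item a tetraploid reference whose A-subgenome copy of one gene family
#'   has been replaced by its C homoeolog (a fixed-in-reference
#'   homoeologous exchange), with the donor/acceptor loci registered as a
#'   near-identical duplicate pair for read placement;
#' \item two genotypes per diploid progenitor, with injected gene losses,
#'   tandem duplications, a 57 bp homozygous deletion spanning an
#'   intron/exon boundary, and a mixture of homozygous and heterozygous
#'   SNPs and short InDels;
#' \item capture-enriched depth tracks per genotype: strict and gapped
#'   mapping on the own-species reference, strict mapping on the tetraploid;
#' \item two population baselines of CNV-free tetraploid genotypes: one on
#'   the clean tetraploid (CNV tiebreak) and one on the exchanged
#'   tetraploid in which only a fraction of genotypes carry the exchange
#'   (cross-species baseline);
#' \item per-genotype VCF-style records of the injected small variants with
#'   noisy MQ/DP, and the machine-readable truth ledger.
#' }
#'
#' @param config a [sim_config()] (needs at least 18 genes per subgenome).
#'   The default study widens gene spacing to 48 kb and raises capture
#'   enrichment to 2000:1 so that the target fraction of the genome, the
#'   on-target read fraction (~98%) and the resulting normalized-coverage
#'   magnitudes resemble a real capture experiment, at ~48x on-target depth.
#' @param seed master seed; all stage seeds derive from it.
#' @param n_population genotypes per population baseline.
#' @param hx_carrier_fraction fraction of the cross-species baseline
#'   population carrying the homoeologous exchange.
#' @return A list of class `sim_dataset`; see Details.
#' @export
simulate_dataset <- function(config = sim_config(intergenic_length = 48000,
                                                 n_reads = 2e4,
                                                 on_target_enrichment = 2000),
                             seed = config$seed,
                             n_population = 12, hx_carrier_fraction = 1/6) {
  n <- config$n_genes_per_subgenome
  if (n < 18) stop("the default study needs at least 18 genes per subgenome")
  refpair <- simulate_reference_pair(config)
  gid <- function(p, i) sprintf("g%s%02d", p, i)

  hx_idx <- n - 2
  gA_hx <- refpair$genes_tetraploid[[gid("A", hx_idx)]]
  gC_hx <- refpair$genes_tetraploid[[gid("C", hx_idx)]]
  hx_seq <- substr0(refpair$tetraploid$sequences[["C01"]],
                    gC_hx$start, gC_hx$end)
  patched <- patch_reference(
    refpair$tetraploid,
    replace = stats::setNames(list(hx_seq),
                              sprintf("A01:%d-%d", gA_hx$start, gA_hx$end)))
  tet_x <- patched$reference
  tet_x$name <- "tetraploid_hx"
  duplicate_loci <- data.frame(chrom1 = "A01", start1 = gA_hx$start,
                               end1 = gA_hx$end, chrom2 = "C01",
                               start2 = gC_hx$start, stringsAsFactors = FALSE)

  exon <- config$exon_length
  intron <- config$intron_length
  ga <- function(i) refpair$genes_diploid_A[[gid("A", i)]]

  specs_S1 <- rbind(
    variant_spec("gene_loss", gid("A", 1)),
    variant_spec("gene_loss", gid("A", 2)),
    variant_spec("gene_loss", gid("A", 3)),
    variant_spec("gene_loss", gid("A", hx_idx)),
    variant_spec("duplication", gid("A", 4)),
    variant_spec("duplication", gid("A", 5)),
    variant_spec("duplication", gid("A", 6)),
    variant_spec("snp", gid("A", 13), start = ga(13)$start + 33),
    variant_spec("snp", gid("A", 14), start = ga(14)$start + 60),
    variant_spec("snp", gid("A", 15), start = ga(15)$start + 45,
                 zygosity = "het"),
    variant_spec("small_deletion", gid("A", 12), start = ga(12)$start + 303,
                 size = 6),
    variant_spec("small_insertion", gid("A", 16), start = ga(16)$start + 150,
                 size = 4, zygosity = "het"))
  specs_S2 <- rbind(
    variant_spec("gene_loss", gid("A", 7)),
    variant_spec("gene_loss", gid("A", 8)),
    variant_spec("gene_loss", gid("A", hx_idx)),
    variant_spec("duplication", gid("A", 9)),
    variant_spec("duplication", gid("A", 10)),
    variant_spec("large_deletion", gid("A", 11),
                 start = ga(11)$start + exon + intron - 20, size = 57),
    variant_spec("snp", gid("A", 14), start = ga(14)$start + 90),
    variant_spec("snp", gid("A", 15), start = ga(15)$start + 48,
                 zygosity = "het"),
    variant_spec("small_deletion", gid("A", 17), start = ga(17)$start + 210,
                 size = 3),
    variant_spec("small_insertion", gid("A", 12), start = ga(12)$start + 1500,
                 size = 12))
  specs_O1 <- rbind(
    variant_spec("duplication", gid("C", 5)),
    variant_spec("snp", gid("C", 13),
                 start = refpair$genes_diploid_C[[gid("C", 13)]]$start + 33))
  specs_O2 <- rbind(
    variant_spec("gene_loss", gid("C", 7)),
    variant_spec("snp", gid("C", 3),
                 start = refpair$genes_diploid_C[[gid("C", 3)]]$start + 90),
    variant_spec("snp", gid("C", 14),
                 start = refpair$genes_diploid_C[[gid("C", 14)]]$start + 60,
                 zygosity = "het"))

  genotypes <- list(
    S1 = inject_variants(refpair$diploid_A, refpair$genes_diploid_A, specs_S1,
                         seed = seed + 11, genotype_id = "S1"),
    S2 = inject_variants(refpair$diploid_A, refpair$genes_diploid_A, specs_S2,
                         seed = seed + 12, genotype_id = "S2"),
    O1 = inject_variants(refpair$diploid_C, refpair$genes_diploid_C, specs_O1,
                         seed = seed + 13, genotype_id = "O1"),
    O2 = inject_variants(refpair$diploid_C, refpair$genes_diploid_C, specs_O2,
                         seed = seed + 14, genotype_id = "O2"))

  tracks <- list()
  for (g in names(genotypes)) {
    off <- match(g, names(genotypes))
    tracks[[g]] <- list(
      strict_own = simulate_depth(genotypes[[g]], "strict", config,
                                  seed = seed + 20 + off),
      gapped_own = simulate_depth(genotypes[[g]], "gapped", config,
                                  seed = seed + 30 + off),
      strict_tet = simulate_depth(genotypes[[g]], "strict", config,
                                  seed = seed + 40 + off, mapping_ref = tet_x,
                                  targets = gene_spans(refpair$genes_tetraploid),
                                  duplicate_loci = duplicate_loci))
  }

  pop_cnv <- simulate_population_reference(refpair, n_population,
                                           seed = seed + 100)
  pop_cross <- simulate_cross_population(refpair, tet_x, duplicate_loci,
                                         n_population, hx_carrier_fraction,
                                         seed = seed + 200, config = config)

  records <- lapply(names(genotypes), function(g) {
    truth_to_records(genotypes[[g]], config, seed = seed + 300 +
                       match(g, names(genotypes)))
  })
  names(records) <- names(genotypes)

  structure(list(config = config, seed = seed, refpair = refpair,
                 tet_x = tet_x, duplicate_loci = duplicate_loci,
                 hx = list(family = sprintf("G%02d", hx_idx),
                           a_gene = gid("A", hx_idx),
                           c_gene = gid("C", hx_idx)),
                 species = list(A = c("S1", "S2"), C = c("O1", "O2")),
                 genotypes = genotypes, tracks = tracks,
                 pop_cnv = pop_cnv, pop_cross = pop_cross,
                 records = records),
            class = "sim_dataset")
}

# cross-species baseline: CNV-free tetraploid genotypes on the exchanged
# tetraploid reference; only `carrier_fraction` of them carry the exchange
# (the rest are ancestral and their reads fail the mismatch gate there)
simulate_cross_population <- function(refpair, tet_x, duplicate_loci,
                                      n_genotypes, carrier_fraction, seed,
                                      config) {
  empty <- variant_spec("snp")[0, ]
  carrier <- inject_variants(tet_x, refpair$genes_tetraploid, empty,
                             seed = seed, genotype_id = "pop_carrier")
  ancestral <- inject_variants(refpair$tetraploid, refpair$genes_tetraploid,
                               empty, seed = seed,
                               genotype_id = "pop_ancestral")
  n_carrier <- round(n_genotypes * carrier_fraction)
  tab <- gene_table(refpair$genes_tetraploid)
  ncs <- matrix(NA_real_, nrow = nrow(tab), ncol = n_genotypes)
  for (g in seq_len(n_genotypes)) {
    base <- if (g <= n_carrier) carrier else ancestral
    track <- simulate_depth(base, "strict", config, seed = seed + g,
                            mapping_ref = tet_x,
                            targets = gene_spans(refpair$genes_tetraploid),
                            duplicate_loci = duplicate_loci)
    cov <- coverage_table(track, refpair$genes_tetraploid, genome_size(tet_x))
    ncs[, g] <- cov$nc[match(tab$gene_id, cov$gene_id)]
  }
  out <- data.frame(gene_id = tab$gene_id, chrom = tab$chrom,
                    start = tab$start, end = tab$end,
                    mean_nc = rowMeans(ncs), stringsAsFactors = FALSE)
  attr(out, "n_genotypes") <- n_genotypes
  out
}

# VCF-bound records for the injected small variants, with noisy MQ/DP
truth_to_records <- function(genotype, config, seed) {
  truth <- genotype$truth
  small <- truth[truth$type %in% c("snp", "small_insertion",
                                   "small_deletion"), , drop = FALSE]
  if (nrow(small) == 0) {
    return(data.frame(chrom = character(), pos = numeric(), id = character(),
                      ref = character(), alt = character(), type = character(),
                      mq = numeric(), dp = numeric(), zygosity = character(),
                      genotype = character(), stringsAsFactors = FALSE))
  }
  seqs <- genotype$ref$sequences
  rows <- lapply(seq_len(nrow(small)), function(i) {
    e <- small[i, ]
    s <- seqs[[e$chrom]]
    if (e$type == "snp") {
      pos <- e$ref_start + 1
      ref <- substr0(s, e$ref_start, e$ref_start + 1)
      alt <- e$alt
    } else if (e$type == "small_deletion") {
      pos <- e$ref_start            # 1-based anchor = base before deletion
      anchor <- substr0(s, e$ref_start - 1, e$ref_start)
      ref <- paste0(anchor, substr0(s, e$ref_start, e$ref_end))
      alt <- anchor
    } else {
      pos <- e$ref_start
      anchor <- substr0(s, e$ref_start - 1, e$ref_start)
      ref <- anchor
      alt <- paste0(anchor, e$content)
    }
    data.frame(chrom = e$chrom, pos = pos, id = e$id, ref = ref, alt = alt,
               type = if (e$type == "snp") "snp" else "indel",
               zygosity = e$zygosity, genotype = genotype$genotype_id,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  with_seed(seed, {
    mu <- ifelse(rec$type == "snp", config$vcf_snp_mq, config$vcf_indel_mq)
    rec$mq <- pmax(0, pmin(60, round(stats::rnorm(nrow(rec), mu,
                                                  config$vcf_mq_sd))))
    rec$dp <- stats::rpois(nrow(rec), config$vcf_dp_mean)
  })
  rec[order(rec$chrom, rec$pos), c("chrom", "pos", "id", "ref", "alt", "type",
                                   "mq", "dp", "zygosity", "genotype")]
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d genes/subgenome, genotypes %s, seed %d\n",
              x$config$n_genes_per_subgenome,
              paste(names(x$genotypes), collapse = "/"), x$seed))
  invisible(x)
}

#' Write / read a simulated dataset as plain-text files
#'
#' Emits FASTA references, GFF3 gene models, BED capture targets, BedGraph
#' depth tracks (with sidecar metadata), per-genotype VCFs, population
#' baseline TSVs, the homoeolog and duplicate-locus tables, the truth
#' ledger as JSON and the simulation configuration as JSON. The directory
#' round-trips through [read_dataset()].
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  rp <- dataset$refpair
  write_reference_fasta(rp$tetraploid, p("tetraploid.fa"))
  write_reference_fasta(dataset$tet_x, p("tetraploid_hx.fa"))
  write_reference_fasta(rp$diploid_A, p("diploid_A.fa"))
  write_reference_fasta(rp$diploid_C, p("diploid_C.fa"))
  write_gene_models(rp$genes_tetraploid, p("tetraploid.gff3"))
  write_gene_models(rp$genes_diploid_A, p("diploid_A.gff3"))
  write_gene_models(rp$genes_diploid_C, p("diploid_C.gff3"))
  for (ref in c("tetraploid", "diploid_A", "diploid_C")) {
    genes <- rp[[paste0("genes_", ref)]] %||% rp$genes_tetraploid
    sp <- gene_spans(if (ref == "tetraploid") rp$genes_tetraploid else genes)
    utils::write.table(sp[, c("chrom", "start", "end", "region_id")],
                       p(paste0("targets_", ref, ".bed")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  for (g in names(dataset$tracks)) {
    for (tr in names(dataset$tracks[[g]])) {
      write_depth_track(dataset$tracks[[g]][[tr]],
                        p(sprintf("%s_%s.bedgraph", g, tr)))
    }
  }
  for (g in names(dataset$records)) {
    write_variant_records(dataset$records[[g]], p(paste0(g, ".vcf")),
                          sample = g)
  }
  utils::write.table(dataset$pop_cnv, p("pop_cnv.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$pop_cross, p("pop_cross.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rp$homoeologs, p("homoeologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$duplicate_loci, p("duplicate_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- lapply(dataset$genotypes, `[[`, "truth")
  jsonlite::write_json(truth, p("truth.json"), dataframe = "rows",
                       na = "null", digits = NA)
  meta <- list(config = unclass(dataset$config), seed = dataset$seed,
               hx = dataset$hx, species = dataset$species,
               genotypes = names(dataset$genotypes))
  jsonlite::write_json(meta, p("dataset.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  p <- function(...) file.path(dir, ...)
  meta <- jsonlite::read_json(p("dataset.json"), simplifyVector = TRUE)
  refs <- list(tetraploid = read_reference_fasta(p("tetraploid.fa"), "tetraploid"),
               tetraploid_hx = read_reference_fasta(p("tetraploid_hx.fa"),
                                                    "tetraploid_hx"),
               diploid_A = read_reference_fasta(p("diploid_A.fa"), "diploid_A"),
               diploid_C = read_reference_fasta(p("diploid_C.fa"), "diploid_C"))
  genes <- list(tetraploid = read_gene_models(p("tetraploid.gff3")),
                diploid_A = read_gene_models(p("diploid_A.gff3")),
                diploid_C = read_gene_models(p("diploid_C.gff3")))
  tracks <- list()
  for (g in meta$genotypes) {
    tracks[[g]] <- list(
      strict_own = read_depth_track(p(sprintf("%s_strict_own.bedgraph", g))),
      gapped_own = read_depth_track(p(sprintf("%s_gapped_own.bedgraph", g))),
      strict_tet = read_depth_track(p(sprintf("%s_strict_tet.bedgraph", g))))
  }
  records <- lapply(meta$genotypes, function(g) {
    read_variant_records(p(paste0(g, ".vcf")), genotype = g)
  })
  names(records) <- meta$genotypes
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  list(meta = meta, refs = refs, genes = genes, tracks = tracks,
       records = records,
       pop_cnv = utils::read.table(p("pop_cnv.tsv"), sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE),
       pop_cross = utils::read.table(p("pop_cross.tsv"), sep = "\t",
                                     header = TRUE, stringsAsFactors = FALSE),
       homoeologs = utils::read.table(p("homoeologs.tsv"), sep = "\t",
                                      header = TRUE, stringsAsFactors = FALSE),
       truth = truth)
}
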