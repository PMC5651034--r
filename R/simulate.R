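#' Simulation configuration
#'
#' Parameters of the synthetic allotetraploid study the package is exercised
#' on: a "napus-like" tetraploid made of an A-like and a C-like subgenome,
#' plus one diploid progenitor genome per subgenome. Defaults describe a
#' desk-scale capture experiment: 20 target genes per subgenome on a 200 kb
#' chromosome, 5% A/C divergence, 100 bp single-end reads and 100:1
#' on-target capture enrichment.
#'
#' @param n_genes_per_subgenome number of target genes per subgenome.
#' @param gene_length gene length in bases (two exons flanking one intron).
#' @param intergenic_length spacer length between consecutive genes.
#' @param subgenome_divergence per-base substitution probability between the
#'   A and C subgenomes (start/stop/splice motifs are preserved).
#' @param read_length read length in bases (single-end).
#' @param n_reads reads sampled per genotype and mapping.
#' @param on_target_enrichment sampling weight of on-target vs off-target
#'   start positions.
#' @param max_mismatch_strict,max_mismatch_gapped mismatch budget of a read
#'   placement under strict and gapped mapping; placements exceeding it are
#'   discarded, which is what keeps reads from one subgenome off the
#'   diverged homoeologous loci.
#' @param vcf_snp_mq,vcf_indel_mq,vcf_mq_sd,vcf_dp_mean mean mapping quality
#'   for SNP/InDel records, its s.d., and the mean depth, used when emitting
#'   synthetic VCF records (constants plus noise, so the downstream MQ/DP
#'   filter has records to reject).
#' @param seed integer seed for reference construction.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(n_genes_per_subgenome = 5)
#' @export
sim_config <- function(n_genes_per_subgenome = 20,
                       gene_length = 2000,
                       intergenic_length = 8000,
                       subgenome_divergence = 0.05,
                       read_length = 100,
                       n_reads = 1e5,
                       on_target_enrichment = 100,
                       max_mismatch_strict = 2,
                       max_mismatch_gapped = 5,
                       vcf_snp_mq = 60,
                       vcf_indel_mq = 40,
                       vcf_mq_sd = 12,
                       vcf_dp_mean = 30,
                       seed = 1) {
  stopifnot(n_genes_per_subgenome >= 1,
            subgenome_divergence >= 0, subgenome_divergence < 0.5,
            read_length >= 1, n_reads >= 0, on_target_enrichment >= 1)
  exon_length <- 3 * floor(gene_length * 0.45 / 3)
  intron_length <- gene_length - 2 * exon_length
  if (intron_length < 20) stop("gene_length too short for a two-exon model")
  structure(list(n_genes_per_subgenome = n_genes_per_subgenome,
                 gene_length = gene_length,
                 exon_length = exon_length,
                 intron_length = intron_length,
                 intergenic_length = intergenic_length,
                 subgenome_divergence = subgenome_divergence,
                 read_length = read_length,
                 n_reads = n_reads,
                 on_target_enrichment = on_target_enrichment,
                 max_mismatch_strict = max_mismatch_strict,
                 max_mismatch_gapped = max_mismatch_gapped,
                 vcf_snp_mq = vcf_snp_mq,
                 vcf_indel_mq = vcf_indel_mq,
                 vcf_mq_sd = vcf_mq_sd,
                 vcf_dp_mean = vcf_dp_mean,
                 seed = seed),
            class = "sim_config")
}

stop_codons <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  coding <- setdiff(all_codons, stop_codons)
  paste0("ATG",
         paste(sample(coding, n_codons - 2, replace = TRUE), collapse = ""),
         sample(stop_codons, 1))
}

# Build one two-exon gene; returns genomic sequence and exon layout relative
# to the gene start (0-based half-open), already strand-oriented.
build_gene_sequence <- function(config, strand) {
  el <- config$exon_length
  il <- config$intron_length
  cds <- random_cds((2 * el) / 3)
  exon1 <- substr0(cds, 0, el)
  exon2 <- substr0(cds, el, 2 * el)
  intron <- paste0("GT", random_dna(il - 4), "AG")
  genomic <- paste0(exon1, intron, exon2)
  if (strand == "-") genomic <- revcomp(genomic)
  # genomic exon intervals are the same for both strands by symmetry
  list(seq = genomic,
       exons = rbind(c(0, el), c(el + il, 2 * el + il)))
}

#' Simulate the tetraploid reference and its diploid progenitors
#'
#' Builds one A-like chromosome of evenly spaced two-exon genes, derives the
#' C-like homoeologous chromosome by random substitution at the configured
#' divergence (sparing start/stop codons and splice motifs), and assembles
#' three references: the tetraploid (both chromosomes) and one diploid per
#' subgenome (single chromosome, byte-identical to the corresponding
#' subgenome). Gene models carry dotted copy names (`Tet.G01.A01`,
#' `DipA.G01.A01`, ...) and a homoeolog table links A and C copies.
#'
#' @param config a [sim_config()].
#' @return List with `tetraploid`, `diploid_A`, `diploid_C`
#'   (`reference_set`s), matching `gene_set`s (`genes_tetraploid`,
#'   `genes_diploid_A`, `genes_diploid_C`), the `homoeologs` table and the
#'   `config`.
#' @export
simulate_reference_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes_per_subgenome
    gl <- config$gene_length
    il <- config$intergenic_length
    lead <- il %/% 2
    chrom_len <- n * (gl + il)

    gene_start <- lead + (seq_len(n) - 1) * (gl + il)
    strands <- ifelse(seq_len(n) %% 2 == 1, "+", "-")

    pieces <- character(0)
    cursor <- 0
    layouts <- vector("list", n)
    for (i in seq_len(n)) {
      pieces <- c(pieces, random_dna(gene_start[i] - cursor))
      layouts[[i]] <- build_gene_sequence(config, strands[i])
      pieces <- c(pieces, layouts[[i]]$seq)
      cursor <- gene_start[i] + gl
    }
    pieces <- c(pieces, random_dna(chrom_len - cursor))
    chromA <- paste(pieces, collapse = "")

    # C-like homoeolog: substitutions outside protected motifs
    protected <- logical(chrom_len)
    for (i in seq_len(n)) {
      s <- gene_start[i]
      ex <- layouts[[i]]$exons
      motif <- c(s + 0:2, s + gl - 3 + 0:2,                 # terminal codons
                 s + ex[1, 2] + 0:1, s + ex[2, 1] - 2 + 0:1) # splice motifs
      protected[motif + 1] <- TRUE
    }
    mut <- which(stats::runif(chrom_len) < config$subgenome_divergence &
                   !protected)
    chromC <- chromA
    if (length(mut) > 0) {
      bases <- c("A", "C", "G", "T")
      old <- strsplit(chromC, NULL)[[1]]
      for (p in mut) old[p] <- sample(setdiff(bases, old[p]), 1)
      chromC <- paste(old, collapse = "")
    }

    make_genes <- function(chrom, prefix, genus) {
      gene_set(lapply(seq_len(n), function(i) {
        s <- gene_start[i]
        ex <- layouts[[i]]$exons + s
        gene_model(gene_id = sprintf("%s%02d", prefix, i),
                   copy_name = sprintf("%s.G%02d.%s", genus, i, chrom),
                   chrom = chrom, start = s, end = s + gl,
                   exons = ex, cds = ex, strand = strands[i])
      }))
    }
    genes_A <- make_genes("A01", "gA", "Tet")
    genes_C <- make_genes("C01", "gC", "Tet")
    dip_genes_A <- make_genes("A01", "gA", "DipA")
    dip_genes_C <- make_genes("C01", "gC", "DipC")

    list(tetraploid = reference_set(c(A01 = chromA, C01 = chromC),
                                    name = "tetraploid"),
         diploid_A = reference_set(c(A01 = chromA), name = "diploid_A"),
         diploid_C = reference_set(c(C01 = chromC), name = "diploid_C"),
         genes_tetraploid = gene_set(c(unclass(genes_A), unclass(genes_C))),
         genes_diploid_A = dip_genes_A,
         genes_diploid_C = dip_genes_C,
         homoeologs = data.frame(family = sprintf("G%02d", seq_len(n)),
                                 a_gene = sprintf("gA%02d", seq_len(n)),
                                 c_gene = sprintf("gC%02d", seq_len(n)),
                                 stringsAsFactors = FALSE),
         config = config)
  })
}

#' Declare variants to inject
#'
#' @param type one of `snp`, `small_insertion`, `small_deletion`,
#'   `large_deletion`, `duplication`, `gene_loss`, `homoeologous_exchange`.
#' @param gene_id gene the event concerns (required for `duplication`,
#'   `gene_loss`, `homoeologous_exchange`; used for automatic placement
#'   otherwise).
#' @param chrom,start explicit placement (0-based on the base reference);
#'   `NA` to place automatically inside the gene.
#' @param size event size in bases (1 for SNPs; ignored for whole-gene
#'   events).
#' @param zygosity `"hom"` or `"het"`.
#' @param alt alternate base for SNPs (random if `NA`).
#' @return One-row data frame; `rbind()` rows to build a spec table.
#' @export
variant_spec <- function(type, gene_id = NA, chrom = NA, start = NA,
                         size = NA, zygosity = "hom", alt = NA) {
  types <- c("snp", "small_insertion", "small_deletion", "large_deletion",
             "duplication", "gene_loss", "homoeologous_exchange")
  stopifnot(type %in% types, zygosity %in% c("hom", "het"))
  data.frame(type = type, gene_id = as.character(gene_id),
             chrom = as.character(chrom), start = as.numeric(start),
             size = as.numeric(size), zygosity = zygosity,
             alt = as.character(alt), stringsAsFactors = FALSE)
}

resolve_specs <- function(ref, genes, specs, max_short_indel = 18) {
  if (nrow(specs) == 0) {
    return(data.frame(id = character(), type = character(),
                      chrom = character(), ref_start = numeric(),
                      ref_end = numeric(), size = numeric(),
                      zygosity = character(), gene_id = character(),
                      alt = character(), content = character(),
                      map_chrom = character(), map_start = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- gene_table(genes)
  out <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    g <- if (!is.na(sp$gene_id)) genes[[sp$gene_id]] else NULL
    size <- sp$size
    if (sp$type == "snp") size <- 1
    if (sp$type %in% c("small_insertion", "small_deletion")) {
      if (is.na(size) || size < 1 || size > max_short_indel) {
        stop("small events must have size in 1..", max_short_indel)
      }
    }
    if (sp$type == "large_deletion" && (is.na(size) || size <= max_short_indel)) {
      stop("large_deletion must be longer than ", max_short_indel, " bp")
    }
    chrom <- sp$chrom
    start <- sp$start
    if (sp$type %in% c("duplication", "gene_loss", "homoeologous_exchange")) {
      if (is.null(g)) stop("whole-gene event needs gene_id: row ", i)
      chrom <- g$chrom
      start <- if (sp$type == "duplication") g$end else g$start
      size <- g$end - g$start
    } else {
      if (is.na(chrom)) {
        if (is.null(g)) stop("spec row ", i, " needs gene_id or chrom/start")
        chrom <- g$chrom
      }
      if (is.na(start)) {
        if (is.null(g)) stop("spec row ", i, " needs gene_id or chrom/start")
        room <- (g$end - g$start) - size - 20
        if (room < 1) stop("gene too short for event of size ", size)
        start <- g$start + 10 + sample.int(room, 1)
      }
    }
    ref_end <- switch(sp$type,
                      small_insertion = start,
                      duplication = start,
                      start + size)
    content <- ""
    map_chrom <- NA_character_
    map_start <- NA_real_
    if (sp$type == "small_insertion") content <- random_dna(size)
    if (sp$type == "duplication") {
      content <- substr0(ref$sequences[[chrom]], g$start, g$end)
      map_chrom <- chrom
      map_start <- g$start
    }
    # homoeologous_exchange content is filled in by inject_variants()
    alt <- sp$alt
    if (sp$type == "snp") {
      refb <- substr0(ref$sequences[[chrom]], start, start + 1)
      if (is.na(alt)) alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      if (alt == refb) stop("SNP alt equals reference base at row ", i)
      content <- alt
    }
    out[[i]] <- data.frame(id = sprintf("ev%03d", i), type = sp$type,
                           chrom = chrom, ref_start = start, ref_end = ref_end,
                           size = size, zygosity = sp$zygosity,
                           gene_id = sp$gene_id, alt = alt, content = content,
                           map_chrom = map_chrom, map_start = map_start,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Inject variants into a reference to build a synthetic genotype
#'
#' Applies the given variant specifications to the base reference and
#' returns the genotype as two haplotype sequence sets (haplotype 1 carries
#' every event, haplotype 2 only the homozygous ones) together with the
#' truth ledger of realized coordinates. Duplications append a tandem copy
#' of the gene span; `homoeologous_exchange` replaces a gene span by its
#' homoeolog from the other subgenome (tetraploid references only). Because
#' each diploid reference is byte-identical to its subgenome in the
#' tetraploid, truth coordinates are valid on both.
#'
#' @param ref base `reference_set` the genotype derives from.
#' @param genes `gene_set` annotated on `ref`.
#' @param specs spec table built from [variant_spec()] rows.
#' @param seed integer seed (used for automatic placement and alleles).
#' @param genotype_id genotype label.
#' @param homoeologs homoeolog table (needed for exchanges), as returned by
#'   [simulate_reference_pair()].
#' @param max_short_indel boundary between small and large InDels.
#' @return An object of class `sim_genotype`.
#' @export
inject_variants <- function(ref, genes, specs, seed = 1,
                            genotype_id = "genotype1", homoeologs = NULL,
                            max_short_indel = 18) {
  stopifnot(inherits(ref, "reference_set"), inherits(genes, "gene_set"))
  truth <- with_seed(seed, resolve_specs(ref, genes, specs, max_short_indel))

  # homoeologous exchange content: the other subgenome's gene span
  hx <- which(truth$type == "homoeologous_exchange")
  for (i in hx) {
    if (is.null(homoeologs)) stop("homoeologous_exchange needs a homoeolog table")
    gid <- truth$gene_id[i]
    row <- homoeologs[homoeologs$a_gene == gid | homoeologs$c_gene == gid, ]
    if (nrow(row) != 1) stop("no homoeolog for gene ", gid)
    other <- if (row$a_gene == gid) row$c_gene else row$a_gene
    og <- genes[[other]]
    if (is.null(og) || !og$chrom %in% names(ref$sequences)) {
      stop("homoeologous_exchange requires both subgenomes in the reference")
    }
    truth$content[i] <- substr0(ref$sequences[[og$chrom]], og$start, og$end)
    truth$map_chrom[i] <- og$chrom
    truth$map_start[i] <- og$start
  }

  # reject overlapping events (per chromosome, on reference coordinates)
  if (nrow(truth) > 1) {
    for (ch in unique(truth$chrom)) {
      tt <- truth[truth$chrom == ch, ]
      tt <- tt[order(tt$ref_start, tt$ref_end), ]
      if (nrow(tt) > 1 &&
          any(tt$ref_start[-1] < tt$ref_end[-nrow(tt)])) {
        stop("overlapping variant specs on ", ch)
      }
    }
  }

  apply_events <- function(events) {
    seqs <- ref$sequences
    if (nrow(events) == 0) return(seqs)
    events <- events[order(events$chrom, -events$ref_start), ]
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      s <- seqs[[e$chrom]]
      repl <- switch(e$type,
                     snp = e$alt,
                     small_insertion = e$content,
                     duplication = e$content,
                     homoeologous_exchange = e$content,
                     small_deletion = "",
                     large_deletion = "",
                     gene_loss = "")
      seqs[[e$chrom]] <- paste0(substr0(s, 0, e$ref_start), repl,
                                substr0(s, e$ref_end, nchar(s)))
    }
    seqs
  }

  hap1 <- apply_events(truth)
  hom <- truth[truth$zygosity == "hom", , drop = FALSE]
  hap2 <- if (nrow(hom) == nrow(truth)) hap1 else apply_events(hom)

  structure(list(genotype_id = genotype_id, ref = ref, genes = genes,
                 haplotypes = list(hap1 = hap1, hap2 = hap2),
                 truth = truth),
            class = "sim_genotype")
}

#' @export
print.sim_genotype <- function(x, ...) {
  cat(sprintf("sim_genotype '%s' on %s: %d injected event(s)\n",
              x$genotype_id, x$ref$name, nrow(x$truth)))
  invisible(x)
}
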