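# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# five genes on one 50 kb subgenome; ~190x on-target depth
small_config <- function(...) {
  args <- utils::modifyList(list(n_genes_per_subgenome = 5, n_reads = 2e4,
                                 seed = 3), list(...))
  do.call(sim_config, args)
}

fix_refpair <- function() {
  if (is.null(.fixtures$rp)) {
    .fixtures$rp <- simulate_reference_pair(small_config())
  }
  .fixtures$rp
}

# the package's default synthetic study (20 genes/subgenome, 4 genotypes)
fix_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    .fixtures$ds <- simulate_dataset(seed = 42)
  }
  .fixtures$ds
}

empty_specs <- function() variant_spec("snp")[0, ]

clean_genotype <- function(refpair = fix_refpair(), id = "clean") {
  inject_variants(refpair$diploid_A, refpair$genes_diploid_A, empty_specs(),
                  seed = 1, genotype_id = id)
}

# depth track built directly from per-chrom vectors (for rule-level tests)
manual_track <- function(depth, genotype = "g", reference = "ref",
                         mode = "strict", total = 1000, read_length = 100,
                         junction_reads = NULL) {
  depth_track(depth, reference = reference, mode = mode, genotype = genotype,
              total_mapped_reads = total, read_length = read_length,
              junction_reads = junction_reads)
}

# a hand-built two-exon gene on a synthetic chromosome, returning the gene,
# its reference and the coding sequence used
manual_gene <- function(n_codons = 200, strand = "+", chrom = "chrT",
                        gene_start = 100, intron_len = 50, seed = 5,
                        cds = NULL) {
  stopifnot(n_codons >= 4, n_codons %% 2 == 0)  # equal exon halves
  with_seed(seed, {
    if (is.null(cds)) {
      bases <- c("A", "C", "G", "T")
      all_codons <- as.vector(outer(outer(bases, bases, paste0), bases,
                                    paste0))
      coding <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
      cds <- paste0("ATG",
                    paste(sample(coding, n_codons - 2, replace = TRUE),
                          collapse = ""),
                    "TAA")
    }
    half <- 3 * floor(nchar(cds) / 6)
    exon1 <- substr(cds, 1, half)
    exon2 <- substr(cds, half + 1, nchar(cds))
    intron <- paste0("GT", paste(sample(c("A", "C", "G", "T"),
                                        intron_len - 4, replace = TRUE),
                                 collapse = ""), "AG")
    genomic <- paste0(exon1, intron, exon2)
    if (strand == "-") {
      genomic <- chartr("ACGT", "TGCA", genomic)
      genomic <- paste(rev(strsplit(genomic, NULL)[[1]]), collapse = "")
    }
    flank <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
    seq_full <- paste0(flank(gene_start), genomic, flank(80))
    gene_end <- gene_start + nchar(genomic)
    exons <- rbind(c(gene_start, gene_start + half),
                   c(gene_end - (nchar(cds) - half), gene_end))
    ref <- reference_set(stats::setNames(seq_full, chrom), name = "manual")
    gene <- gene_model("gene1", "Tst.GENE.X01", chrom, gene_start, gene_end,
                       exons = exons, cds = exons, strand = strand)
    list(gene = gene, ref = ref, cds = cds,
         exon_halves = c(half, nchar(cds) - half))
  })
}

# map a coding-strand CDS offset (0-based) to a genomic 1-based position
cds_pos_to_genomic <- function(mg, cds_off) {
  g <- mg$gene
  half <- mg$exon_halves[1]
  if (g$strand == "+") {
    if (cds_off < half) g$exons[1, 1] + cds_off + 1
    else g$exons[2, 1] + (cds_off - half) + 1
  } else {
    total <- sum(mg$exon_halves)
    fwd <- total - 1 - cds_off
    if (fwd < mg$exon_halves[2]) g$exons[1, 1] + fwd + 1
    else g$exons[2, 1] + (fwd - mg$exon_halves[2]) + 1
  }
}
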