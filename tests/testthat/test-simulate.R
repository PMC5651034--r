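test_that("zero divergence gives identical subgenomes; generation is deterministic", {
  cfg <- sim_config(n_genes_per_subgenome = 3, subgenome_divergence = 0,
                    seed = 9)
  rp <- simulate_reference_pair(cfg)
  expect_identical(rp$tetraploid$sequences[["A01"]],
                   rp$tetraploid$sequences[["C01"]])
  rp2 <- simulate_reference_pair(cfg)
  expect_identical(rp$tetraploid$sequences, rp2$tetraploid$sequences)
  expect_identical(rp$diploid_A$sequences[["A01"]],
                   rp$tetraploid$sequences[["A01"]])
})

test_that("observed A/C divergence is within 3 sigma of the binomial target", {
  cfg <- sim_config(n_genes_per_subgenome = 10, subgenome_divergence = 0.03,
                    seed = 13)
  rp <- simulate_reference_pair(cfg)
  a <- strsplit(rp$tetraploid$sequences[["A01"]], NULL)[[1]]
  c2 <- strsplit(rp$tetraploid$sequences[["C01"]], NULL)[[1]]
  n <- length(a)
  # substituted bases change with probability 3/4 of the 0.03 draws at
  # unprotected sites; the realized rate must sit near 0.03 regardless
  obs <- mean(a != c2)
  sigma <- sqrt(0.03 * 0.97 / n)
  expect_lt(abs(obs - 0.03), 3 * sigma + 0.002)
})

test_that("simulated gene models are two-exon, in frame, stop-terminated", {
  rp <- fix_refpair()
  for (g in rp$genes_diploid_A) {
    expect_equal(nrow(g$exons), 2)
    expect_true(g$frame_ok)
    cds <- paste0(
      substr(rp$diploid_A$sequences[[g$chrom]], g$cds[1, 1] + 1, g$cds[1, 2]),
      substr(rp$diploid_A$sequences[[g$chrom]], g$cds[2, 1] + 1, g$cds[2, 2]))
    if (g$strand == "-") {
      cds <- chartr("ACGT", "TGCA", cds)
      cds <- paste(rev(strsplit(cds, NULL)[[1]]), collapse = "")
    }
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
  }
})

test_that("injection with an empty spec list reproduces the reference", {
  gt <- clean_genotype()
  expect_identical(gt$haplotypes$hap1, gt$ref$sequences)
  expect_identical(gt$haplotypes$hap2, gt$ref$sequences)
  expect_equal(nrow(gt$truth), 0)
})

test_that("a 57 bp deletion shortens the carrier and lands in the ledger", {
  rp <- fix_refpair()
  g <- rp$genes_diploid_A[["gA02"]]
  boundary <- g$start + 900 + 200 - 20  # exon/intron boundary region
  gt <- inject_variants(rp$diploid_A, rp$genes_diploid_A,
                        variant_spec("large_deletion", "gA02",
                                     start = boundary, size = 57),
                        seed = 2, genotype_id = "del57")
  expect_equal(nchar(gt$haplotypes$hap1[["A01"]]),
               nchar(rp$diploid_A$sequences[["A01"]]) - 57)
  expect_equal(gt$truth$type, "large_deletion")
  expect_equal(gt$truth$ref_end - gt$truth$ref_start, 57)
})

test_that("duplication extends the genotype by one gene length", {
  rp <- fix_refpair()
  gt <- inject_variants(rp$diploid_A, rp$genes_diploid_A,
                        variant_spec("duplication", "gA03"),
                        seed = 2, genotype_id = "dup")
  gl <- small_config()$gene_length
  expect_equal(nchar(gt$haplotypes$hap1[["A01"]]),
               nchar(rp$diploid_A$sequences[["A01"]]) + gl)
  g <- rp$genes_diploid_A[["gA03"]]
  span <- substr(rp$diploid_A$sequences[["A01"]], g$start + 1, g$end)
  expect_equal(substr(gt$haplotypes$hap1[["A01"]], g$end + 1, g$end + gl),
               span)
})

test_that("homoeologous exchange swaps in the other subgenome's copy", {
  rp <- fix_refpair()
  gt <- inject_variants(rp$tetraploid, rp$genes_tetraploid,
                        variant_spec("homoeologous_exchange", "gA02"),
                        seed = 2, genotype_id = "hx",
                        homoeologs = rp$homoeologs)
  ga <- rp$genes_tetraploid[["gA02"]]
  gc <- rp$genes_tetraploid[["gC02"]]
  expect_equal(substr(gt$haplotypes$hap1[["A01"]], ga$start + 1, ga$end),
               substr(rp$tetraploid$sequences[["C01"]], gc$start + 1, gc$end))
  # exchanges need both subgenomes
  expect_error(
    inject_variants(rp$diploid_A, rp$genes_diploid_A,
                    variant_spec("homoeologous_exchange", "gA02"),
                    seed = 2, homoeologs = rp$homoeologs),
    "both subgenomes")
})

test_that("heterozygous events touch only one haplotype", {
  rp <- fix_refpair()
  g <- rp$genes_diploid_A[["gA04"]]
  gt <- inject_variants(rp$diploid_A, rp$genes_diploid_A,
                        rbind(variant_spec("snp", "gA01",
                                           start = rp$genes_diploid_A[["gA01"]]$start + 50),
                              variant_spec("small_deletion", "gA04",
                                           start = g$start + 100, size = 5,
                                           zygosity = "het")),
                        seed = 2, genotype_id = "het")
  expect_equal(nchar(gt$haplotypes$hap1[["A01"]]),
               nchar(rp$diploid_A$sequences[["A01"]]) - 5)
  expect_equal(nchar(gt$haplotypes$hap2[["A01"]]),
               nchar(rp$diploid_A$sequences[["A01"]]))
})

test_that("overlapping specs are rejected", {
  rp <- fix_refpair()
  g <- rp$genes_diploid_A[["gA01"]]
  expect_error(
    inject_variants(rp$diploid_A, rp$genes_diploid_A,
                    rbind(variant_spec("gene_loss", "gA01"),
                          variant_spec("snp", "gA01", start = g$start + 10)),
                    seed = 2),
    "overlapping")
})

test_that("small/large event sizes are policed at the 18 bp boundary", {
  rp <- fix_refpair()
  g <- rp$genes_diploid_A[["gA01"]]
  expect_error(
    inject_variants(rp$diploid_A, rp$genes_diploid_A,
                    variant_spec("small_deletion", "gA01",
                                 start = g$start + 10, size = 19), seed = 1),
    "1..18")
  expect_error(
    inject_variants(rp$diploid_A, rp$genes_diploid_A,
                    variant_spec("large_deletion", "gA01",
                                 start = g$start + 10, size = 12), seed = 1),
    "longer than 18")
})
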