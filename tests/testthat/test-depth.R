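test_that("zero reads yield an all-zero track", {
  cfg <- small_config(n_reads = 0)
  gt <- clean_genotype()
  tr <- simulate_depth(gt, "strict", cfg, seed = 1)
  expect_equal(sum(vapply(tr$depth, sum, numeric(1))), 0)
  expect_equal(tr$total_mapped_reads, 0)
})

test_that("strict-mode depth mass conserves mapped reads x read length", {
  cfg <- small_config()
  gt <- clean_genotype()
  tr <- simulate_depth(gt, "strict", cfg, seed = 4)
  expect_equal(sum(vapply(tr$depth, sum, numeric(1))),
               tr$total_mapped_reads * tr$read_length)
  expect_equal(tr$total_mapped_reads, cfg$n_reads)  # clean genotype: all map
})

test_that("same seed reproduces the track byte for byte", {
  cfg <- small_config()
  gt <- clean_genotype()
  t1 <- simulate_depth(gt, "strict", cfg, seed = 8)
  t2 <- simulate_depth(gt, "strict", cfg, seed = 8)
  expect_identical(t1$depth, t2$depth)
  expect_identical(t1$total_mapped_reads, t2$total_mapped_reads)
})

test_that("unknown mapping mode is rejected", {
  expect_error(simulate_depth(clean_genotype(), "semi", small_config()),
               "unknown mapping mode")
})

test_that("a homozygous 57 bp deletion leaves a zero window under strict mapping", {
  rp <- fix_refpair()
  cfg <- small_config()
  g <- rp$genes_diploid_A[["gA02"]]
  start <- g$start + 1080
  gt <- inject_variants(rp$diploid_A, rp$genes_diploid_A,
                        variant_spec("large_deletion", "gA02",
                                     start = start, size = 57),
                        seed = 2, genotype_id = "del57")
  tr <- simulate_depth(gt, "strict", cfg, seed = 5)
  d <- tr$depth[["A01"]]
  expect_equal(max(d[(start + 1):(start + 57)]), 0)
  expect_gte(min(d[(start - 30):(start - 20)]), 20)     # left flank covered
  expect_gte(min(d[(start + 57 + 20):(start + 57 + 30)]), 20)
  # gapped mapping cannot span 57 bp either: still zero, no junction support
  gp <- simulate_depth(gt, "gapped", cfg, seed = 5)
  expect_equal(max(gp$depth[["A01"]][(start + 1):(start + 57)]), 0)
  expect_equal(unname(gp$junction_reads[gt$truth$id]), 0)
})

test_that("short deletions are spanned by gapped reads but not strict reads", {
  rp <- fix_refpair()
  cfg <- small_config()
  g <- rp$genes_diploid_A[["gA03"]]
  gt <- inject_variants(rp$diploid_A, rp$genes_diploid_A,
                        variant_spec("small_deletion", "gA03",
                                     start = g$start + 400, size = 10),
                        seed = 2, genotype_id = "del10")
  st <- simulate_depth(gt, "strict", cfg, seed = 6)
  gp <- simulate_depth(gt, "gapped", cfg, seed = 6)
  ev <- gt$truth$id
  expect_equal(unname(st$junction_reads[ev]), 0)
  expect_gt(unname(gp$junction_reads[ev]), 20)
  # the zero stretch under strict mapping is too short for the 19 bp window
  d <- st$depth[["A01"]]
  r <- rle(d[(g$start + 1):g$end] == 0)
  expect_lt(max(c(0, r$lengths[r$values])), 19)
})

test_that("homozygous duplication doubles depth over the gene span", {
  rp <- fix_refpair()
  cfg <- small_config()
  gt <- inject_variants(rp$diploid_A, rp$genes_diploid_A,
                        variant_spec("duplication", "gA04"),
                        seed = 2, genotype_id = "dup")
  tr <- simulate_depth(gt, "strict", cfg, seed = 7)
  g <- rp$genes_diploid_A[["gA04"]]
  other <- rp$genes_diploid_A[["gA01"]]
  # trim read-length edges where the tandem junction loses reads
  core <- function(gm) mean(tr$depth[[gm$chrom]][(gm$start + 150):(gm$end - 150)])
  ratio <- core(g) / core(other)
  # Poisson oracle: ratio of two means at >100x depth, 3 sigma margin
  expect_lt(abs(ratio - 2), 3 * 0.1)
})

test_that("heterozygous duplication raises depth by about half", {
  rp <- fix_refpair()
  cfg <- small_config()
  gt <- inject_variants(rp$diploid_A, rp$genes_diploid_A,
                        variant_spec("duplication", "gA04", zygosity = "het"),
                        seed = 2, genotype_id = "duphet")
  tr <- simulate_depth(gt, "strict", cfg, seed = 7)
  g <- rp$genes_diploid_A[["gA04"]]
  other <- rp$genes_diploid_A[["gA01"]]
  core <- function(gm) mean(tr$depth[[gm$chrom]][(gm$start + 150):(gm$end - 150)])
  expect_lt(abs(core(g) / core(other) - 1.5), 3 * 0.08)
})

test_that("tracks round-trip through BedGraph with sidecar metadata", {
  cfg <- small_config(n_reads = 5000)
  gt <- clean_genotype()
  tr <- simulate_depth(gt, "gapped", cfg, seed = 9)
  tmp <- withr::local_tempfile(fileext = ".bedgraph")
  write_depth_track(tr, tmp)
  back <- read_depth_track(tmp)
  expect_identical(back$depth, tr$depth)
  expect_equal(back$total_mapped_reads, tr$total_mapped_reads)
  expect_equal(back$mode, "gapped")
  # BedGraph mass equals the track's depth mass
  bg <- read.table(tmp, sep = "\t",
                   col.names = c("chrom", "start", "end", "score"))
  expect_equal(sum((bg$end - bg$start) * bg$score),
               sum(vapply(tr$depth, sum, numeric(1))))
})

test_that("population baseline is tight across genotypes and matches n = 1", {
  rp <- fix_refpair()
  cfg <- small_config()
  pop1 <- simulate_population_reference(rp, n_genotypes = 1, seed = 30,
                                        config = cfg)
  base <- inject_variants(rp$tetraploid, rp$genes_tetraploid, empty_specs(),
                          seed = 30, genotype_id = "pop")
  tr <- simulate_depth(base, "strict", cfg, seed = 31)
  cov <- coverage_table(tr, rp$genes_tetraploid, genome_size(rp$tetraploid))
  expect_equal(pop1$mean_nc, cov$nc[match(pop1$gene_id, cov$gene_id)])
  pop <- simulate_population_reference(rp, n_genotypes = 8, seed = 30,
                                       config = cfg)
  expect_true(all(pop$mean_nc > 0))
  # depth is ~100x here; per-gene means vary by far less than 20%
  expect_lt(stats::sd(pop$mean_nc) / mean(pop$mean_nc), 0.2)
})
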