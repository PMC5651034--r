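snp_record <- function(chrom, pos, ref, alt, genotype = "g1",
                       type = "snp", mq = 60, dp = 30, zygosity = "hom") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, type = type,
             mq = mq, dp = dp, zygosity = zygosity, genotype = genotype,
             stringsAsFactors = FALSE)
}

test_that("a TGG->TGC substitution at codon 170 is a radical W170C", {
  cds <- paste0("ATG", strrep("GCT", 168), "TGG", strrep("GCT", 29), "TAA")
  mg <- manual_gene(n_codons = 200, cds = cds)
  pos <- cds_pos_to_genomic(mg, (170 - 1) * 3 + 2)  # third base of codon 170
  rec <- snp_record("chrT", pos, "G", "C")
  ann <- annotate_variant(rec, mg$gene, mg$ref)
  expect_equal(ann$category, "nonsynonymous")
  expect_equal(ann$protein_change, "W170C")
  expect_equal(ann$grantham_distance, 215L)
  expect_equal(ann$radicality, "radical")
})

test_that("third-position wobble substitutions are synonymous", {
  cds <- paste0("ATG", strrep("CTA", 198), "TAA")  # leucine repeats
  mg <- manual_gene(n_codons = 200, cds = cds)
  pos <- cds_pos_to_genomic(mg, 3 * 10 + 2)  # CTA -> CTG at codon 11
  ann <- annotate_variant(snp_record("chrT", pos, "A", "G"), mg$gene, mg$ref)
  expect_equal(ann$category, "synonymous")
  expect_equal(ann$radicality, "none")
})

test_that("stop codon gain and loss are recognized", {
  cds <- paste0("ATG", strrep("TGC", 198), "TAA")
  mg <- manual_gene(n_codons = 200, cds = cds)
  # TGC -> TGA at an internal codon: premature stop
  pos <- cds_pos_to_genomic(mg, 3 * 50 + 2)
  gain <- annotate_variant(snp_record("chrT", pos, "C", "A"), mg$gene, mg$ref)
  expect_equal(gain$category, "stop_gain")
  # natural TAA -> CAA: read-through, longer peptide
  pos_stop <- cds_pos_to_genomic(mg, 3 * 199)
  loss <- annotate_variant(snp_record("chrT", pos_stop, "T", "C"),
                           mg$gene, mg$ref)
  expect_equal(loss$category, "stop_loss")
})

test_that("CDS InDels split into frameshift and in-frame by length", {
  mg <- manual_gene(n_codons = 200)
  pos <- cds_pos_to_genomic(mg, 30)
  base <- substr(mg$ref$sequences[["chrT"]], pos, pos)
  fs <- annotate_variant(snp_record("chrT", pos, paste0(base, "AC"), base,
                                    type = "indel"), mg$gene, mg$ref)
  expect_equal(fs$category, "frameshift_indel")
  inf <- annotate_variant(snp_record("chrT", pos, paste0(base, "ACT"), base,
                                     type = "indel"), mg$gene, mg$ref)
  expect_equal(inf$category, "inframe_indel")
})

test_that("intron boundary substitutions are splice variants, interior silent", {
  mg <- manual_gene(n_codons = 200)
  g <- mg$gene
  intron_s <- g$exons[1, 2]
  intron_e <- g$exons[2, 1]
  donor <- annotate_variant(snp_record("chrT", intron_s + 1, "G", "A"),
                            g, mg$ref)
  expect_equal(donor$category, "splice_donor")
  acceptor <- annotate_variant(snp_record("chrT", intron_e, "G", "A"),
                               g, mg$ref)
  expect_equal(acceptor$category, "splice_acceptor")
  mid <- annotate_variant(snp_record("chrT", intron_s + 10, "A", "C"),
                          g, mg$ref)
  expect_equal(mid$category, "silent")
  expect_error(annotate_variant(snp_record("chrT", 5, "A", "C"), g, mg$ref),
               "outside")
})

test_that("reverse-strand annotation equals the forward-strand construct", {
  cds <- paste0("ATG", strrep("GCT", 168), "TGG", strrep("GCT", 29), "TAA")
  fwd <- manual_gene(n_codons = 200, cds = cds, strand = "+", seed = 6)
  rev <- manual_gene(n_codons = 200, cds = cds, strand = "-", seed = 6)
  for (cds_off in c(0, 10, 100, (170 - 1) * 3 + 2, 3 * 199)) {
    pf <- cds_pos_to_genomic(fwd, cds_off)
    pr <- cds_pos_to_genomic(rev, cds_off)
    ref_f <- substr(fwd$ref$sequences[["chrT"]], pf, pf)
    ref_r <- substr(rev$ref$sequences[["chrT"]], pr, pr)
    expect_equal(ref_r, chartr("ACGT", "TGCA", ref_f))
    alt_f <- setdiff(c("A", "C", "G", "T"), ref_f)[1]
    alt_r <- chartr("ACGT", "TGCA", alt_f)
    a_f <- annotate_variant(snp_record("chrT", pf, ref_f, alt_f),
                            fwd$gene, fwd$ref)
    a_r <- annotate_variant(snp_record("chrT", pr, ref_r, alt_r),
                            rev$gene, rev$ref)
    expect_equal(a_r$category, a_f$category)
    expect_equal(a_r$protein_change, a_f$protein_change)
  }
})

test_that("every CDS substitution gets exactly one coding category", {
  mg <- manual_gene(n_codons = 60)
  coding_cats <- c("synonymous", "nonsynonymous", "stop_gain", "stop_loss")
  for (cds_off in seq(0, 3 * 60 - 1, by = 7)) {
    pos <- cds_pos_to_genomic(mg, cds_off)
    ref <- substr(mg$ref$sequences[["chrT"]], pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      ann <- annotate_variant(snp_record("chrT", pos, ref, alt),
                              mg$gene, mg$ref)
      expect_true(ann$category %in% coding_cats)
      expect_equal(ann$radicality != "none",
                   ann$category == "nonsynonymous")
    }
  }
})

test_that("out-of-frame CDS flags a pseudogene and skips translation", {
  gene <- gene_model("g1", "Tst.G.X01", "c1", 10, 110,
                     exons = rbind(c(10, 50), c(70, 110)),
                     cds = rbind(c(10, 50), c(70, 109)))
  ref <- reference_set(c(c1 = strrep("ACGT", 50)))
  ann <- annotate_variant(snp_record("c1", 21, "A", "C"), gene, ref)
  expect_true(ann$pseudogene)
  expect_true(is.na(ann$category))
})

test_that("severity ranking is hierarchic and permutation invariant", {
  ann <- data.frame(category = c("synonymous", "nonsynonymous"),
                    radicality = c("none", "conservative"),
                    stringsAsFactors = FALSE)
  expect_equal(severity_rank(ann)$most_severe, "nonsynonymous")
  expect_equal(severity_rank(ann[1, ])$most_severe, "synonymous")
  expect_true(is.na(severity_rank(ann[0, ])$most_severe))
  full <- data.frame(
    category = c("silent", "synonymous", "inframe_indel", "nonsynonymous",
                 "nonsynonymous", "splice_donor", "stop_gain",
                 "frameshift_indel"),
    radicality = c("none", "none", "none", "conservative", "radical",
                   "none", "none", "none"), stringsAsFactors = FALSE)
  set.seed(2)
  for (i in 1:10) {
    perm <- full[sample.int(nrow(full)), ]
    expect_equal(severity_rank(perm)$most_severe, "frameshift_indel")
  }
  # radical nonsynonymous outranks splice? no: splice outranks nonsynonymous
  sub <- full[full$category %in% c("nonsynonymous", "splice_donor"), ]
  expect_equal(severity_rank(sub)$most_severe, "splice_donor")
})

test_that("annotating a record table hits every overlapping copy", {
  rp <- fix_refpair()
  ref <- rp$diploid_A
  g <- rp$genes_diploid_A[["gA01"]]
  pos <- g$start + 15  # inside exon 1
  refb <- substr(ref$sequences[["A01"]], pos + 1, pos + 1)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  rec <- snp_record("A01", pos + 1, refb, alt)
  res <- annotate_variants(rec, rp$genes_diploid_A, ref)
  expect_equal(nrow(res), 1)
  expect_equal(res$gene_id, "gA01")
  none <- annotate_variants(snp_record("A01", 5, "A", "C"),
                            rp$genes_diploid_A, ref)
  expect_equal(nrow(none), 0)
})
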