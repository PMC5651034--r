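# Scenario builders shared by the acceptance-style checks.

# Diploid-vs-tetraploid mapping experiment: equal read numbers placed on the
# tetraploid reference; returns the diploid's mean on-target nc as percent
# of the tetraploid control over the same (A-subgenome) targets.
diploid_on_tetraploid_pct <- function(seed, n_reads = 1e5) {
  cfg <- sim_config(n_reads = n_reads, seed = seed)
  rp <- simulate_reference_pair(cfg)
  no_variants <- variant_spec("snp")[0, ]
  dip <- inject_variants(rp$diploid_A, rp$genes_diploid_A, no_variants,
                         seed = seed, genotype_id = "diploid")
  tet <- inject_variants(rp$tetraploid, rp$genes_tetraploid, no_variants,
                         seed = seed, genotype_id = "tetraploid")
  targets <- gene_spans(rp$genes_tetraploid)
  tr_dip <- simulate_depth(dip, "strict", cfg, seed = seed + 1,
                           mapping_ref = rp$tetraploid, targets = targets)
  tr_tet <- simulate_depth(tet, "strict", cfg, seed = seed + 2,
                           mapping_ref = rp$tetraploid, targets = targets)
  gs <- genome_size(rp$tetraploid)
  nc_dip <- coverage_table(tr_dip, rp$genes_diploid_A, gs)$nc
  cov_tet <- coverage_table(tr_tet, rp$genes_tetraploid, gs)
  nc_tet <- cov_tet$nc[cov_tet$chrom == "A01"]
  100 * mean(nc_dip) / mean(nc_tet)
}

# Two-genotype deletion experiment at ~30x: returns the large-deletion
# candidates of the carrier and its truth ledger.
deletion_scan_experiment <- function(seed, del_size, n_reads = 3500) {
  cfg <- sim_config(n_genes_per_subgenome = 5, n_reads = n_reads, seed = seed)
  rp <- simulate_reference_pair(cfg)
  g <- rp$genes_diploid_A[["gA02"]]
  boundary <- g$start + cfg$exon_length + cfg$intron_length - 20
  spec <- if (del_size > 18) {
    variant_spec("large_deletion", "gA02", start = boundary, size = del_size)
  } else {
    variant_spec("small_deletion", "gA02", start = boundary, size = del_size)
  }
  carrier <- inject_variants(rp$diploid_A, rp$genes_diploid_A, spec,
                             seed = seed, genotype_id = "carrier")
  other <- inject_variants(rp$diploid_A, rp$genes_diploid_A,
                           variant_spec("snp")[0, ], seed = seed,
                           genotype_id = "other")
  strict_own <- simulate_depth(carrier, "strict", cfg, seed = seed + 1)
  gapped_own <- simulate_depth(carrier, "gapped", cfg, seed = seed + 1)
  strict_other <- simulate_depth(other, "strict", cfg, seed = seed + 2)
  list(candidates = scan_large_deletions(strict_own, strict_other, gapped_own,
                                         threshold_config(),
                                         rp$genes_diploid_A),
       truth = carrier$truth)
}

# Single homozygous deletions of every length in `lengths`, one per gene,
# under gapped mapping; returns the short-InDel call table.
indel_length_sweep <- function(seed, lengths = 1:30, n_reads = 2e4) {
  cfg <- sim_config(n_genes_per_subgenome = length(lengths),
                    n_reads = n_reads, seed = seed)
  rp <- simulate_reference_pair(cfg)
  specs <- do.call(rbind, lapply(seq_along(lengths), function(i) {
    g <- rp$genes_diploid_A[[sprintf("gA%02d", i)]]
    type <- if (lengths[i] > 18) "large_deletion" else "small_deletion"
    variant_spec(type, g$gene_id, start = g$start + 400, size = lengths[i])
  }))
  gt <- inject_variants(rp$diploid_A, rp$genes_diploid_A, specs,
                        seed = seed, genotype_id = "sweep")
  gapped <- simulate_depth(gt, "gapped", cfg, seed = seed + 1)
  calls <- call_short_indels(gapped, gt$truth)
  merge(calls, gt$truth[, c("id", "gene_id")], by = "id")
}
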