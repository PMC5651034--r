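# the four reconcilable worked examples from the published coverage tables;
# the unprinted second genotype's nc derives from the printed two-genotype
# mean as 2*mean - printed
published_rows <- data.frame(
  gene = c("Bna.VIN3.A02", "Bna.GA3ox.A09", "Bol.FT.C02", "Bna.CO.C09"),
  printed = c(1833.2, 425.4, 0.6, 2.7),
  mean_both = c(1441.3, 594.5, 51.4, 1004.9),
  pop = c(1561.9, 1675.6, 95.2, 1466.0),
  printed_genotype = c("L58", "L58", "BRA1398", "Kashirka"),
  expected_call = c("duplication_in_high", "deletion_in_low",
                    "deletion_in_low", "deletion_in_low"),
  expected_carrier = c("L58", "L58", "BRA1398", "Kashirka"),
  stringsAsFactors = FALSE)

test_that("published coverage-table rows reproduce the printed CNV nature", {
  for (i in seq_len(nrow(published_rows))) {
    row <- published_rows[i, ]
    other_nc <- 2 * row$mean_both - row$printed
    call <- classify_cnv_pair(
      list(genotype = row$printed_genotype, nc = row$printed),
      list(genotype = "other", nc = other_nc),
      pop_mean = row$pop)
    expect_equal(call$call, row$expected_call, label = row$gene)
    expect_equal(call$carrier, row$expected_carrier, label = row$gene)
  }
})

test_that("balanced coverage and double-zero coverage yield no call", {
  none <- classify_cnv_pair(list(genotype = "a", nc = 100),
                            list(genotype = "b", nc = 110), pop_mean = 100)
  expect_equal(none$call, "none")
  zz <- classify_cnv_pair(list(genotype = "a", nc = 0),
                          list(genotype = "b", nc = 0), pop_mean = 100)
  expect_equal(zz$call, "none")
  expect_match(zz$evidence, "no coverage")
})

test_that("an unbalanced ratio without a population mean is unresolved", {
  call <- classify_cnv_pair(list(genotype = "a", nc = 50),
                            list(genotype = "b", nc = 100), pop_mean = NA)
  expect_equal(call$call, "unresolved")
})

test_that("classification is symmetric in genotype order", {
  set.seed(5)
  for (i in 1:50) {
    nc1 <- runif(1, 0, 200)
    nc2 <- runif(1, 0, 200)
    pop <- runif(1, 10, 200)
    a <- classify_cnv_pair(list(genotype = "g1", nc = nc1),
                           list(genotype = "g2", nc = nc2), pop)
    b <- classify_cnv_pair(list(genotype = "g2", nc = nc2),
                           list(genotype = "g1", nc = nc1), pop)
    expect_equal(a$call, b$call)
    expect_equal(a$carrier, b$carrier)
    expect_equal(a$low_genotype, b$low_genotype)
  }
})

test_that("lowering the low coverage never weakens a deletion call", {
  # monotonicity: once deletion_in_low, staying lower keeps deletion_in_low
  pop <- 100
  nc_high <- 100
  calls <- vapply(seq(95, 0, by = -5), function(nc_low) {
    classify_cnv_pair(list(genotype = "lo", nc = nc_low),
                      list(genotype = "hi", nc = nc_high), pop)$call
  }, character(1))
  first_del <- match("deletion_in_low", calls)
  expect_false(is.na(first_del))
  expect_true(all(calls[first_del:length(calls)] == "deletion_in_low"))
  expect_false(any(calls[seq_len(first_del - 1)] == "deletion_in_low" &
                     c(calls[-1], "")[seq_len(first_del - 1)] != "deletion_in_low"))
})

test_that("the zero-coverage window scan applies all three track conditions", {
  th <- threshold_config()
  own <- rep(30L, 500)
  own[101:160] <- 0L          # 60-base zero window
  own[301:310] <- 0L          # too short (10 < 19)
  other <- rep(30L, 500)
  gap <- rep(0L, 500)
  mk <- function(d, mode = "strict", g = "g1") {
    manual_track(list(c1 = d), genotype = g, mode = mode)
  }
  cand <- scan_large_deletions(mk(own), mk(other, g = "g2"), mk(gap, "gapped"),
                               th)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 100)
  expect_equal(cand$end, 160)
  expect_equal(cand$length, 60)
  # identical genotypes: nothing to report
  expect_equal(nrow(scan_large_deletions(mk(other), mk(other, g = "g2"),
                                         mk(gap, "gapped"), th)), 0)
  # weakly covered in the other genotype: rejected
  weak <- rep(3L, 500)
  expect_equal(nrow(scan_large_deletions(mk(own), mk(weak, g = "g2"),
                                         mk(gap, "gapped"), th)), 0)
  # high gapped coverage in the carrier (mapping artifact): rejected
  gap_hi <- rep(25L, 500)
  expect_equal(nrow(scan_large_deletions(mk(own), mk(other, g = "g2"),
                                         mk(gap_hi, "gapped"), th)), 0)
})

test_that("scan output never overlaps bases with positive own strict depth", {
  th <- threshold_config()
  set.seed(44)
  own <- rpois(3000, 2)
  own[501:700] <- 0L
  other <- rpois(3000, 30)
  gap <- rep(0L, 3000)
  cand <- scan_large_deletions(
    manual_track(list(c1 = own)), manual_track(list(c1 = other), genotype = "o"),
    manual_track(list(c1 = gap), mode = "gapped"), th)
  for (i in seq_len(nrow(cand))) {
    expect_equal(max(own[(cand$start[i] + 1):cand$end[i]]), 0)
  }
})

test_that("short-InDel calls require junction-spanning gapped reads", {
  truth <- data.frame(id = c("e1", "e2", "e3"),
                      type = c("small_deletion", "large_deletion",
                               "small_insertion"),
                      size = c(6, 57, 4), stringsAsFactors = FALSE)
  tr <- manual_track(list(c1 = rep(10L, 100)), mode = "gapped",
                     junction_reads = c(e1 = 40, e2 = 0, e3 = 1))
  calls <- call_short_indels(tr, truth)
  expect_equal(calls$called, c(TRUE, FALSE, FALSE))
  expect_error(call_short_indels(manual_track(list(c1 = 1L)), truth),
               "gapped")
})
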