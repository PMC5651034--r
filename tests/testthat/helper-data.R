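# Shared reference data and record generators.

# the 29 flowering-regulator substitutions with the radicality the study
# printed for each
paper_substitutions <- data.frame(
  change = c("L49I", "W170C", "H81Y", "R21Q", "E59D",
             "R193P", "T20P", "G110V", "K79N", "I173V", "T176N", "S168N",
             "R24Q", "A75D",
             "A60E", "C237S", "D16G", "P130Q", "H167Q", "Q181E",
             "F146S", "A20D", "Q92L", "E33G", "I192V",
             "Y100S", "K145I", "G223R", "E71Q"),
  printed = c("conservative", "radical", "moderately_radical",
              "conservative", "conservative",
              "moderately_radical", "conservative", "moderately_radical",
              "moderately_conservative", "conservative",
              "moderately_radical", "conservative",
              "conservative", "moderately_radical",
              "moderately_radical", "moderately_radical",
              "moderately_conservative", "moderately_conservative",
              "conservative", "conservative",
              "radical", "moderately_radical", "moderately_radical",
              "moderately_conservative", "conservative",
              "moderately_radical", "moderately_radical",
              "moderately_radical", "conservative"),
  stringsAsFactors = FALSE)

random_records <- function(n, seed = 1) {
  with_seed(seed, data.frame(
    chrom = "c1", pos = sample.int(1e6, n),
    ref = sample(c("A", "C", "G", "T", "AT", "ACG"), n, replace = TRUE),
    alt = "T",
    type = sample(c("snp", "indel"), n, replace = TRUE),
    mq = sample(0:60, n, replace = TRUE),
    dp = sample(0:40, n, replace = TRUE),
    zygosity = sample(c("hom", "het"), n, replace = TRUE, prob = c(0.8, 0.2)),
    genotype = sample(c("g1", "g2"), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# exhaustive-search neighbor joining: at every step Q is recomputed by a
# double loop and the global minimum joined (lowest pair on ties); the
# independent oracle for the vectorized implementation
nj_brute_force <- function(dm) {
  D <- dm
  nodes <- rownames(D)
  fmt <- function(x) formatC(x, format = "g", digits = 12)
  while (length(nodes) > 3) {
    m <- nrow(D)
    best <- NULL
    best_q <- Inf
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * D[i, j] - sum(D[i, ]) - sum(D[j, ])
        if (q < best_q - 1e-12) {
          best_q <- q
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    r <- rowSums(D)
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    lab <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li), nodes[j], fmt(lj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nodes <- c(nodes[keep], lab)
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- D[1, 2] - l1
  l3 <- D[1, 3] - l1
  ape::read.tree(text = sprintf("(%s:%s,%s:%s,%s:%s);",
                                nodes[1], fmt(l1), nodes[2], fmt(l2),
                                nodes[3], fmt(l3)))
}
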