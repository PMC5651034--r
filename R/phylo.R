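#' Aligned sequences
#'
#' A minimal multiple-alignment container: named, equal-length, gapped
#' (`-`) nucleotide sequences. Alignment construction itself is outside the
#' package's scope; aligned FASTA is read as-is.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return Object of class `dna_alignment`.
#' @export
dna_alignment <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 3, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("taxon names must be unique")
  if (length(unique(nchar(seqs))) != 1) {
    stop("aligned sequences must have equal length")
  }
  structure(list(seqs = toupper(seqs)), class = "dna_alignment")
}

#' @rdname dna_alignment
#' @param path aligned FASTA file.
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  dna_alignment(seqs)
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("dna_alignment: %d taxa x %d columns\n",
              length(x$seqs), nchar(x$seqs[1])))
  invisible(x)
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, NULL))
}

#' Pairwise p-distance matrix
#'
#' `d(i, j)` is the fraction of mismatching sites among sites where neither
#' sequence carries a gap (`-`) or `N`. A pair without comparable sites is
#' an error.
#'
#' @param aln a [dna_alignment()] (or a character matrix of aligned bases,
#'   rows = taxa).
#' @return Symmetric distance matrix with taxon dimnames.
#' @export
p_distance_matrix <- function(aln) {
  m <- if (inherits(aln, "dna_alignment")) alignment_matrix(aln) else aln
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  valid <- m != "-" & m != "N"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- valid[i, ] & valid[j, ]
      if (!any(comp)) stop("no comparable sites between taxa ", i, " and ", j)
      d[i, j] <- d[j, i] <- mean(m[i, comp] != m[j, comp])
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i, j) = (m - 2) d(i, j) - r(i) - r(j)` is joined (ties broken by the
#' lowest pair index, for determinism), branch lengths follow the usual
#' closed forms, and the final three nodes are resolved by the three-point
#' formulas. On an additive distance matrix the generating topology and
#' branch lengths are recovered exactly. Negative branch lengths are
#' clamped to zero and flagged via `attr(tree, "clamped")`.
#'
#' @param dm symmetric distance matrix with dimnames (n >= 3).
#' @return An unrooted [ape::phylo] tree.
#' @examples
#' dm <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'              dimnames = list(letters[1:3], letters[1:3]))
#' nj_tree(dm)
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("distance matrix must be symmetric")
  labs <- rownames(dm) %||% paste0("t", seq_len(n))
  nodes <- labs  # newick fragments of active nodes
  D <- dm
  fmt <- function(x) formatC(x, format = "g", digits = 12)
  while (length(nodes) > 3) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    pick <- which(Q == min(Q), arr.ind = TRUE)
    pick <- pick[pick[, 1] < pick[, 2], , drop = FALSE]
    pick <- pick[order(pick[, 1], pick[, 2]), , drop = FALSE]
    i <- pick[1, 1]
    j <- pick[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_lab <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li), nodes[j], fmt(lj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], new_lab)
    D <- D2
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nodes[1], fmt(l1), nodes[2], fmt(l2), nodes[3], fmt(l3))
  tree <- ape::read.tree(text = nwk)
  clamped <- any(tree$edge.length < 0)
  if (clamped) tree$edge.length <- pmax(tree$edge.length, 0)
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and scores each internal bipartition of the full-data tree by
#' the percentage of replicates containing it (via [ape::boot.phylo()]).
#' Supports are stored as integer node labels (0-100).
#'
#' @param aln a [dna_alignment()].
#' @param reps bootstrap replicates (the protocol default is 100).
#' @param seed integer seed for the resampling.
#' @param outgroup optional taxon name used to root the returned tree for
#'   display.
#' @return The full-data NJ tree with `node.label` support values and the
#'   replicate count in `attr(tree, "bootstrap_reps")`.
#' @export
bootstrap_support <- function(aln, reps = 100, seed = 1, outgroup = NULL) {
  stopifnot(inherits(aln, "dna_alignment"), reps >= 1)
  m <- alignment_matrix(aln)
  build <- function(x) nj_tree(p_distance_matrix(x))
  full <- build(m)
  counts <- with_seed(seed, {
    ape::boot.phylo(full, m, build, B = reps, quiet = TRUE, rooted = FALSE)
  })
  support <- round(100 * counts / reps)
  full$node.label <- ifelse(is.na(support), "", as.character(support))
  if (!is.null(outgroup)) {
    full <- ape::root(full, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  attr(full, "bootstrap_reps") <- reps
  full
}

#' Write a tree with support labels as Newick
#'
#' @param tree an [ape::phylo] object.
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
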