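#' Per-base depth tracks
#'
#' A `depth_track` stores per-chromosome read-depth arrays for one genotype
#' placed on one reference under one mapping mode, together with the total
#' mapped read count and read length needed for coverage normalization.
#'
#' @param depth named list of non-negative integer vectors (one per chrom).
#' @param reference reference name.
#' @param mode `"strict"` or `"gapped"`.
#' @param genotype genotype identifier.
#' @param total_mapped_reads number of mapped reads.
#' @param read_length read length in bases.
#' @param junction_reads optional named count of gapped reads spanning each
#'   injected InDel (simulator provenance; used by the short-InDel caller).
#' @return An object of class `depth_track`.
#' @export
depth_track <- function(depth, reference, mode, genotype,
                        total_mapped_reads, read_length,
                        junction_reads = NULL) {
  stopifnot(mode %in% c("strict", "gapped"), is.list(depth),
            !is.null(names(depth)), total_mapped_reads >= 0, read_length >= 1)
  if (any(vapply(depth, function(d) any(d < 0), logical(1)))) {
    stop("depth must be non-negative")
  }
  structure(list(depth = depth, reference = reference, mode = mode,
                 genotype = genotype, total_mapped_reads = total_mapped_reads,
                 read_length = read_length,
                 junction_reads = junction_reads %||% numeric(0)),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("depth_track %s on %s (%s): %d mapped reads, %d chrom(s)\n",
              x$genotype, x$reference, x$mode, x$total_mapped_reads,
              length(x$depth)))
  invisible(x)
}

depth_mass <- function(track) sum(vapply(track$depth, sum, numeric(1)))

# ---- genotype -> reference segment maps -------------------------------------

# Piecewise alignment of one haplotype to the base and mapping references.
# Returns per base-chromosome a list(segments, boundaries):
#   segments: g_start, g_end (genotype coords), b_chrom/b_start (base
#     reference home; NA for novel insertions), m_chrom/m_start (mapping
#     reference home; NA if the homing chromosome is absent there)
#   boundaries: between segments k and k+1 - type (adj|del|ins|dup|hx),
#     gap (deleted bases for del), event id
haplotype_segments <- function(genotype, hap = c("hap1", "hap2"),
                               mapping_ref = NULL) {
  hap <- match.arg(hap)
  mapping_ref <- mapping_ref %||% genotype$ref
  events <- genotype$truth
  if (hap == "hap2") events <- events[events$zygosity == "hom", , drop = FALSE]
  events <- events[events$type != "snp", , drop = FALSE]
  out <- list()
  for (ch in names(genotype$ref$sequences)) {
    ev <- events[events$chrom == ch, , drop = FALSE]
    ev <- ev[order(ev$ref_start), , drop = FALSE]
    chrom_len <- nchar(genotype$ref$sequences[[ch]])
    map_home <- function(chrom, start) {
      if (chrom %in% names(mapping_ref$sequences)) {
        list(chrom = chrom, start = start)
      } else {
        list(chrom = NA_character_, start = NA_real_)
      }
    }
    segs <- list()
    bounds <- list()
    add_seg <- function(g_start, len, b_chrom, b_start) {
      mh <- if (is.na(b_chrom)) list(chrom = NA_character_, start = NA_real_)
            else map_home(b_chrom, b_start)
      segs[[length(segs) + 1]] <<- data.frame(
        g_start = g_start, g_end = g_start + len,
        b_chrom = b_chrom, b_start = b_start,
        m_chrom = mh$chrom, m_start = mh$start, stringsAsFactors = FALSE)
    }
    add_bound <- function(type, gap, event) {
      bounds[[length(bounds) + 1]] <<- data.frame(
        after_seg = length(segs), type = type, gap = gap, event = event,
        stringsAsFactors = FALSE)
    }
    cursor <- 0
    g <- 0
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      pre <- e$ref_start - cursor
      if (pre > 0) {
        add_seg(g, pre, ch, cursor)
        g <- g + pre
      }
      cursor <- e$ref_start
      if (e$type %in% c("small_deletion", "large_deletion", "gene_loss")) {
        add_bound("del", e$size, e$id)
        cursor <- e$ref_end
      } else if (e$type == "small_insertion") {
        add_bound("ins", e$size, e$id)
        add_seg(g, e$size, NA_character_, NA_real_)
        g <- g + e$size
        add_bound("ins", e$size, e$id)
      } else if (e$type == "duplication") {
        add_bound("dup", 0, e$id)
        add_seg(g, e$size, e$map_chrom, e$map_start)
        g <- g + e$size
        add_bound("dup", 0, e$id)
      } else if (e$type == "homoeologous_exchange") {
        add_bound("hx", 0, e$id)
        add_seg(g, e$size, e$map_chrom, e$map_start)
        g <- g + e$size
        add_bound("hx", 0, e$id)
        cursor <- e$ref_end
      }
    }
    if (chrom_len - cursor > 0) add_seg(g, chrom_len - cursor, ch, cursor)
    segs <- do.call(rbind, segs)
    bounds <- if (length(bounds)) do.call(rbind, bounds) else
      data.frame(after_seg = integer(), type = character(), gap = numeric(),
                 event = character(), stringsAsFactors = FALSE)
    # collapse duplicate boundary records (keep the event-bearing one per gap)
    out[[ch]] <- list(segments = segs, boundaries = bounds,
                      g_length = segs$g_end[nrow(segs)])
  }
  out
}

boundary_between <- function(bounds, k) {
  # boundary between segment k and k+1
  hit <- bounds[bounds$after_seg == k, , drop = FALSE]
  if (nrow(hit) == 0) {
    data.frame(after_seg = k, type = "adj", gap = 0, event = NA_character_,
               stringsAsFactors = FALSE)
  } else {
    hit[1, ]
  }
}

# ---- enrichment-weighted start sampling -------------------------------------

# Build the weighted start-position pieces for one haplotype chromosome:
# positions whose read would overlap a capture target get weight `enrich`.
start_pieces <- function(segmap, targets, read_length, enrich) {
  segs <- segmap$segments
  g_len <- segmap$g_length
  n_starts <- g_len - read_length + 1
  if (n_starts <= 0) return(NULL)
  zones <- list()
  for (k in seq_len(nrow(segs))) {
    s <- segs[k, ]
    if (is.na(s$b_chrom)) next
    tt <- targets[targets$chrom == s$b_chrom, , drop = FALSE]
    if (nrow(tt) == 0) next
    b_end <- s$b_start + (s$g_end - s$g_start)
    ov_s <- pmax(tt$start, s$b_start)
    ov_e <- pmin(tt$end, b_end)
    keep <- ov_s < ov_e
    if (!any(keep)) next
    zones[[length(zones) + 1]] <- data.frame(
      start = s$g_start + (ov_s[keep] - s$b_start),
      end = s$g_start + (ov_e[keep] - s$b_start))
  }
  if (length(zones) == 0) {
    return(data.frame(start = 0, end = n_starts, weight = 1))
  }
  z <- do.call(rbind, zones)
  z$start <- pmax(0, z$start - (read_length - 1))  # starts overlapping target
  z$end <- pmin(z$end, n_starts)
  z <- z[z$start < z$end, , drop = FALSE]
  if (nrow(z) == 0) {
    return(data.frame(start = 0, end = n_starts, weight = 1))
  }
  ir <- IRanges::reduce(IRanges::IRanges(z$start + 1, z$end))
  es <- IRanges::start(ir) - 1
  ee <- IRanges::end(ir)
  pieces <- list()
  cursor <- 0
  for (i in seq_along(es)) {
    if (es[i] > cursor) {
      pieces[[length(pieces) + 1]] <- data.frame(start = cursor, end = es[i],
                                                 weight = 1)
    }
    pieces[[length(pieces) + 1]] <- data.frame(start = es[i], end = ee[i],
                                               weight = enrich)
    cursor <- ee[i]
  }
  if (cursor < n_starts) {
    pieces[[length(pieces) + 1]] <- data.frame(start = cursor, end = n_starts,
                                               weight = 1)
  }
  do.call(rbind, pieces)
}

sample_starts <- function(piece_table, n) {
  # piece_table: chrom, start, end, weight (start positions, genotype coords)
  w_len <- (piece_table$end - piece_table$start) * piece_table$weight
  cw <- cumsum(w_len)
  total <- cw[length(cw)]
  u <- stats::runif(n, 0, total)
  idx <- findInterval(u, c(0, cw), rightmost.closed = TRUE)
  idx[idx > nrow(piece_table)] <- nrow(piece_table)
  off <- (u - c(0, cw)[idx]) / piece_table$weight[idx]
  pos <- piece_table$start[idx] + floor(off)
  pos <- pmin(pos, piece_table$end[idx] - 1)
  data.frame(chrom = piece_table$chrom[idx], pos = pos,
             stringsAsFactors = FALSE)
}

# mismatch cumsum per segment: element k is c(0, cumsum(mismatch)) of the
# haplotype segment vs its mapping-reference home, or NULL if unmapped
segment_mismatch_cs <- function(segs, hap_seq, map_seqs) {
  lapply(seq_len(nrow(segs)), function(k) {
    if (is.na(segs$m_chrom[k])) return(NULL)
    len <- segs$g_end[k] - segs$g_start[k]
    a <- substr(hap_seq, segs$g_start[k] + 1, segs$g_end[k])
    b <- substr(map_seqs[[segs$m_chrom[k]]], segs$m_start[k] + 1,
                segs$m_start[k] + len)
    if (a == b) return(numeric(len + 1))
    c(0, cumsum(strsplit(a, NULL)[[1]] != strsplit(b, NULL)[[1]]))
  })
}

# best-hit-random placement between near-identical reference locus pairs:
# a read wholly inside one locus of a pair moves to the partner with p=0.5
relocate_duplicates <- function(m_chrom, m_start, rl, duplicate_loci) {
  if (is.null(duplicate_loci) || length(m_chrom) == 0) {
    return(list(chrom = m_chrom, start = m_start))
  }
  moved <- logical(length(m_chrom))
  for (r in seq_len(nrow(duplicate_loci))) {
    d <- duplicate_loci[r, ]
    len <- d$end1 - d$start1
    homes <- list(list(chrom = d$chrom1, start = d$start1,
                       to_chrom = d$chrom2, to_start = d$start2),
                  list(chrom = d$chrom2, start = d$start2,
                       to_chrom = d$chrom1, to_start = d$start1))
    for (h in homes) {
      idx <- which(!moved & m_chrom == h$chrom & m_start >= h$start &
                     m_start + rl <= h$start + len)
      if (length(idx) == 0) next
      flip <- idx[stats::runif(length(idx)) < 0.5]
      m_chrom[flip] <- h$to_chrom
      m_start[flip] <- h$to_start + (m_start[flip] - h$start)
      moved[idx] <- TRUE
    }
  }
  list(chrom = m_chrom, start = m_start)
}

# ---- the simulator ----------------------------------------------------------

#' Simulate capture-enriched depth for a synthetic genotype
#'
#' Reads are abstracted as placed 100%-identity intervals: start positions
#' are sampled with capture enrichment over target spans, split evenly
#' between the two haplotypes, and each read is then placed on the mapping
#' reference through the genotype's event map. A read crossing a deletion
#' breakpoint is discarded under `strict` mapping; under `gapped` mapping it
#' is placed (split around the gap) if the InDel is at most
#' `max_short_indel` bases. Reads crossing duplication or exchange junctions
#' are discarded in both modes; reads from an exchanged span are placed on
#' the homoeologous location when the mapping reference contains it. Deleted
#' reference bases therefore receive no support from a homozygous carrier,
#' and homozygous duplications double the expected depth over the gene span.
#'
#' @param genotype a `sim_genotype` from [inject_variants()].
#' @param mode `"strict"` (no alignment gaps) or `"gapped"`.
#' @param config the [sim_config()].
#' @param seed integer seed.
#' @param mapping_ref `reference_set` to place reads on (default: the
#'   genotype's own base reference).
#' @param targets capture-target intervals on base-reference coordinates
#'   (default: the genotype's gene spans).
#' @param max_short_indel largest InDel a gapped read may span.
#' @param duplicate_loci optional table of near-identical reference locus
#'   pairs (`chrom1`, `start1`, `end1`, `chrom2`, `start2`): a read landing
#'   wholly inside one locus is assigned to the partner with probability
#'   0.5, emulating random best-hit placement between indistinguishable
#'   copies (e.g. a homoeologous exchange and its donor locus).
#' @param max_mismatch mismatch budget override (default: the config's
#'   per-mode budget).
#' @return A [depth_track()]; `junction_reads` counts mapped reads spanning
#'   each injected InDel.
#' @export
simulate_depth <- function(genotype, mode, config, seed = 1,
                           mapping_ref = NULL, targets = NULL,
                           max_short_indel = 18, duplicate_loci = NULL,
                           max_mismatch = NULL) {
  stopifnot(inherits(genotype, "sim_genotype"), inherits(config, "sim_config"))
  if (!mode %in% c("strict", "gapped")) stop("unknown mapping mode: ", mode)
  mapping_ref <- mapping_ref %||% genotype$ref
  targets <- targets %||% gene_spans(genotype$genes)
  rl <- config$read_length
  n_reads <- config$n_reads
  max_mismatch <- max_mismatch %||%
    (if (mode == "strict") config$max_mismatch_strict
     else config$max_mismatch_gapped)

  map_lens <- chrom_lengths(mapping_ref)
  delta <- lapply(map_lens, function(L) numeric(L + 1))
  total_mapped <- 0
  junction <- stats::setNames(numeric(nrow(genotype$truth)), genotype$truth$id)

  with_seed(seed, {
    n_hap1 <- stats::rbinom(1, n_reads, 0.5)
    for (hap in c("hap1", "hap2")) {
      n_hap <- if (hap == "hap1") n_hap1 else n_reads - n_hap1
      if (n_hap == 0) next
      segmaps <- haplotype_segments(genotype, hap, mapping_ref)
      pieces <- list()
      for (ch in names(segmaps)) {
        p <- start_pieces(segmaps[[ch]], targets, rl,
                          config$on_target_enrichment)
        if (!is.null(p)) {
          p$chrom <- ch
          pieces[[length(pieces) + 1]] <- p
        }
      }
      pieces <- do.call(rbind, pieces)
      reads <- sample_starts(pieces, n_hap)

      for (ch in unique(reads$chrom)) {
        sm <- segmaps[[ch]]
        segs <- sm$segments
        mmcs <- segment_mismatch_cs(segs, genotype$haplotypes[[hap]][[ch]],
                                    mapping_ref$sequences)
        starts <- reads$pos[reads$chrom == ch]
        si <- findInterval(starts, segs$g_start)
        ei <- findInterval(starts + rl - 1, segs$g_start)

        # bulk case: read inside one segment
        same <- si == ei
        idx <- which(same & !is.na(segs$m_chrom[si]))
        if (length(idx) > 0) {
          mm <- numeric(length(idx))
          for (k in unique(si[idx])) {
            sel <- si[idx] == k
            off <- starts[idx[sel]] - segs$g_start[k]
            mm[sel] <- mmcs[[k]][off + rl + 1] - mmcs[[k]][off + 1]
          }
          idx <- idx[mm <= max_mismatch]
        }
        if (length(idx) > 0) {
          m_chrom <- segs$m_chrom[si[idx]]
          m_start <- segs$m_start[si[idx]] + (starts[idx] - segs$g_start[si[idx]])
          rel <- relocate_duplicates(m_chrom, m_start, rl, duplicate_loci)
          for (mch in unique(rel$chrom)) {
            ms <- rel$start[rel$chrom == mch]
            L <- map_lens[[mch]]
            delta[[mch]] <- delta[[mch]] +
              tabulate(ms + 1, nbins = L + 1) -
              tabulate(ms + rl + 1, nbins = L + 1)
          }
          total_mapped <- total_mapped + length(idx)
        }

        # junction-crossing reads: handled one by one (rare)
        if (mode == "gapped") {
          piece_mm <- function(k, off, len) {
            mmcs[[k]][off + len + 1] - mmcs[[k]][off + 1]
          }
          for (r in which(!same)) {
            i <- si[r]; j <- ei[r]
            s <- starts[r]
            if (j == i + 1) {
              b <- boundary_between(sm$boundaries, i)
              if (b$type == "del" && b$gap <= max_short_indel &&
                  !is.na(segs$m_chrom[i]) && !is.na(segs$m_chrom[j])) {
                left_len <- segs$g_end[i] - s
                right_len <- rl - left_len
                off_l <- s - segs$g_start[i]
                if (piece_mm(i, off_l, left_len) +
                      piece_mm(j, 0, right_len) <= max_mismatch) {
                  a <- segs$m_start[i] + off_l
                  mch <- segs$m_chrom[i]
                  delta[[mch]][a + 1] <- delta[[mch]][a + 1] + 1
                  delta[[mch]][a + left_len + 1] <-
                    delta[[mch]][a + left_len + 1] - 1
                  a <- segs$m_start[j]
                  mch <- segs$m_chrom[j]
                  delta[[mch]][a + 1] <- delta[[mch]][a + 1] + 1
                  delta[[mch]][a + right_len + 1] <-
                    delta[[mch]][a + right_len + 1] - 1
                  total_mapped <- total_mapped + 1
                  junction[b$event] <- junction[b$event] + 1
                }
              }
            } else if (j == i + 2 && is.na(segs$m_chrom[i + 1])) {
              b <- boundary_between(sm$boundaries, i)
              if (b$type == "ins" && b$gap <= max_short_indel &&
                  !is.na(segs$m_chrom[i]) && !is.na(segs$m_chrom[j])) {
                left_len <- segs$g_end[i] - s
                right_len <- rl - left_len - b$gap
                off_l <- s - segs$g_start[i]
                if (right_len > 0 &&
                    piece_mm(i, off_l, left_len) +
                      piece_mm(j, 0, right_len) <= max_mismatch) {
                  a <- segs$m_start[i] + off_l
                  mch <- segs$m_chrom[i]
                  delta[[mch]][a + 1] <- delta[[mch]][a + 1] + 1
                  delta[[mch]][a + left_len + 1] <-
                    delta[[mch]][a + left_len + 1] - 1
                  a <- segs$m_start[j]
                  mch <- segs$m_chrom[j]
                  delta[[mch]][a + 1] <- delta[[mch]][a + 1] + 1
                  delta[[mch]][a + right_len + 1] <-
                    delta[[mch]][a + right_len + 1] - 1
                  total_mapped <- total_mapped + 1
                  junction[b$event] <- junction[b$event] + 1
                }
              }
            }
          }
        }
      }
    }
  })

  depth <- lapply(names(delta), function(mch) {
    d <- cumsum(delta[[mch]])[seq_len(map_lens[[mch]])]
    as.integer(round(d))
  })
  names(depth) <- names(delta)
  depth_track(depth, reference = mapping_ref$name, mode = mode,
              genotype = genotype$genotype_id,
              total_mapped_reads = total_mapped, read_length = rl,
              junction_reads = junction)
}

#' Simulate a tetraploid population coverage baseline
#'
#' Samples `n_genotypes` CNV-free tetraploid genotypes, computes each
#' gene's normalized coverage on the tetraploid reference, and returns the
#' per-gene mean — the population reference used as tiebreak by the CNV
#' caller. The same table keyed by the homoeolog map serves the diploid
#' analyses, since a diploid genotype's normalized coverage on its own
#' reference matches the tetraploid scale (half the reads on half the
#' genome).
#'
#' @param refpair output of [simulate_reference_pair()].
#' @param n_genotypes population size (desk-scale default 20).
#' @param seed integer seed.
#' @param config optional override of `refpair$config`.
#' @return Data frame `gene_id`, `chrom`, `start`, `end`, `mean_nc` with
#'   attribute `n_genotypes`.
#' @export
simulate_population_reference <- function(refpair, n_genotypes = 20, seed = 1,
                                          config = NULL) {
  stopifnot(n_genotypes >= 1)
  config <- config %||% refpair$config
  base <- inject_variants(refpair$tetraploid, refpair$genes_tetraploid,
                          variant_spec("snp")[0, ], seed = seed,
                          genotype_id = "pop")
  tab <- gene_table(refpair$genes_tetraploid)
  ncs <- matrix(NA_real_, nrow = nrow(tab), ncol = n_genotypes)
  for (g in seq_len(n_genotypes)) {
    track <- simulate_depth(base, "strict", config, seed = seed + g)
    cov <- coverage_table(track, refpair$genes_tetraploid,
                          genome_size(refpair$tetraploid))
    ncs[, g] <- cov$nc[match(tab$gene_id, cov$gene_id)]
  }
  out <- data.frame(gene_id = tab$gene_id, chrom = tab$chrom,
                    start = tab$start, end = tab$end,
                    mean_nc = rowMeans(ncs), stringsAsFactors = FALSE)
  attr(out, "n_genotypes") <- n_genotypes
  out
}
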