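#' Functional transcript categories
#'
#' The ten categories assigned by [classify_units()], in rule order.
#' @export
TRANSCRIPT_CATEGORIES <- c("PROTEIN_CODING", "NONCODING_RNA", "LNCRNA",
                           "ENHANCER", "DIVERGENT", "ANTISENSE", "REPEAT",
                           "OTHER_GENIC_SENSE", "OTHER_GENIC_ANTISENSE",
                           "INTERGENIC")

# per-unit maximal overlap fraction (of the unit's length) with any target,
# plus the index of the maximising target; strand = "same"/"opposite"/"any"
.max_overlap_frac <- function(units, targets, strand_rule = "same") {
  frac <- numeric(length(units))
  best <- rep(NA_integer_, length(units))
  tfrac <- numeric(length(units))   # overlap fraction of the target's length
  if (is.null(targets) || length(targets) == 0L) {
    return(list(frac = frac, idx = best, target_frac = tfrac))
  }
  q <- units
  if (strand_rule == "opposite") q <- GenomicRanges::invertStrand(units)
  hits <- GenomicRanges::findOverlaps(q, targets,
                                      ignore.strand = strand_rule == "any")
  if (length(hits)) {
    ov <- width(GenomicRanges::pintersect(granges(units)[queryHits(hits)],
                                          granges(targets)[subjectHits(hits)],
                                          ignore.strand = TRUE))
    f <- ov / width(units)[queryHits(hits)]
    for (i in unique(queryHits(hits))) {
      sel <- which(queryHits(hits) == i)
      j <- sel[which.max(f[sel])]
      frac[i] <- f[j]
      best[i] <- subjectHits(hits)[j]
      tfrac[i] <- ov[j] / width(targets)[subjectHits(hits)[j]]
    }
  }
  list(frac = frac, idx = best, target_frac = tfrac)
}

# total fraction of each unit covered by the union of targets (strand-blind)
.union_overlap_frac <- function(units, targets) {
  if (is.null(targets) || length(targets) == 0L) {
    return(numeric(length(units)))
  }
  red <- GenomicRanges::reduce(granges(targets), ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(units, red, ignore.strand = TRUE)
  tot <- numeric(length(units))
  if (length(hits)) {
    ov <- width(GenomicRanges::pintersect(granges(units)[queryHits(hits)],
                                          red[subjectHits(hits)],
                                          ignore.strand = TRUE))
    agg <- tapply(ov, queryHits(hits), sum)
    tot[as.integer(names(agg))] <- as.numeric(agg)
  }
  tot / width(units)
}

#' Assign called transcription units to ten functional classes
#'
#' Applies the category rules in a fixed order, first match wins, so every
#' unit receives exactly one label:
#'
#' 1. `PROTEIN_CODING` — more than 20 of the unit's sequence overlaps a
#'    protein-coding gene on the same strand.
#' 2. `NONCODING_RNA` — any same-strand overlap with an annotated short
#'    non-coding RNA gene (no size or overlap-quality restriction).
#' 3. `LNCRNA` — more than 20% overlaps an annotated lncRNA (same strand).
#' 4. `ENHANCER` — member of a bidirectional enhancer transcript pair
#'    (from [detect_enhancer_pairs()], decided before rule 5).
#' 5. `DIVERGENT` — more than 10% of the unit overlaps the proximal
#'    promoter (±500 bp around the TSS) of a primary transcript longer
#'    than 1 kb on the opposite strand, and the unit is shorter than 50%
#'    of that primary transcript.
#' 6. `ANTISENSE` — more than 20% of the unit overlaps more than 20% of a
#'    protein-coding or lncRNA gene on the opposite strand.
#' 7. `REPEAT` — more than 50% of the unit overlaps annotated repeat
#'    intervals.
#' 8./9. `OTHER_GENIC_SENSE` / `OTHER_GENIC_ANTISENSE` — overlaps some gene
#'    annotation but below the 20% sense (or antisense) threshold.
#' 10. `INTERGENIC` — none of the above.
#'
#' @param units A `GRanges` of (polished) called units.
#' @param coding Protein-coding gene annotations (`GRanges`), or `NULL`.
#' @param ncrna Short non-coding RNA gene annotations, or `NULL`.
#' @param lncrna lncRNA annotations, or `NULL`.
#' @param repeats Repeat intervals (strand ignored), or `NULL`.
#' @param enhancer_pairs Result of [detect_enhancer_pairs()] on these
#'   units, or `NULL` to compute it here from `coding`/`lncrna`.
#' @param promoter_halfwidth Promoter half-width for the divergent rule
#'   (bp, default 500).
#' @return `units` with metadata columns `category` (factor over
#'   [TRANSCRIPT_CATEGORIES]), `evidence` (index of the matched annotation
#'   in its resource, `NA` if none) and `overlap_fraction`.
#' @export
classify_units <- function(units, coding = NULL, ncrna = NULL,
                           lncrna = NULL, repeats = NULL,
                           enhancer_pairs = NULL,
                           promoter_halfwidth = 500) {
  stopifnot(is(units, "GRanges"))
  n <- length(units)
  cat_out <- rep(NA_character_, n)
  evidence <- rep(NA_integer_, n)
  ovfrac <- rep(NA_real_, n)
  if (n == 0L) {
    units$category <- factor(character(), levels = TRANSCRIPT_CATEGORIES)
    units$evidence <- integer(); units$overlap_fraction <- numeric()
    return(units)
  }
  primary <- c(if (!is.null(coding)) granges(coding),
               if (!is.null(lncrna)) granges(lncrna))
  all_genes <- c(if (!is.null(coding)) granges(coding),
                 if (!is.null(ncrna)) granges(ncrna),
                 if (!is.null(lncrna)) granges(lncrna))

  if (is.null(enhancer_pairs)) {
    enhancer_pairs <- detect_enhancer_pairs(units, all_genes)
  }
  enh_members <- unique(c(enhancer_pairs$plus_idx, enhancer_pairs$minus_idx))

  co <- .max_overlap_frac(units, coding, "same")
  nc <- .max_overlap_frac(units, ncrna, "same")
  ln <- .max_overlap_frac(units, lncrna, "same")
  as_co <- .max_overlap_frac(units, primary, "opposite")
  rp <- .union_overlap_frac(units, repeats)
  sense_any <- .max_overlap_frac(units, all_genes, "same")
  anti_any <- .max_overlap_frac(units, all_genes, "opposite")

  # divergent rule: promoter windows of long primaries, opposite strand
  div_frac <- numeric(n); div_idx <- rep(NA_integer_, n)
  if (!is.null(primary) && length(primary)) {
    long_primary <- primary[width(primary) > 1000]
    if (length(long_primary)) {
      tss <- ifelse(as.character(strand(long_primary)) == "+",
                    start(long_primary), end(long_primary))
      prom <- GenomicRanges::GRanges(
        seqnames(long_primary),
        IRanges::IRanges(pmax(1, tss - promoter_halfwidth),
                         tss + promoter_halfwidth),
        strand = strand(long_primary))
      pv <- .max_overlap_frac(units, prom, "opposite")
      size_ok <- !is.na(pv$idx) &
        width(units) < 0.5 * width(long_primary)[ifelse(is.na(pv$idx), 1L,
                                                        pv$idx)]
      div_frac <- ifelse(size_ok, pv$frac, 0)
      div_idx <- ifelse(size_ok, pv$idx, NA_integer_)
    }
  }

  for (i in seq_len(n)) {
    if (co$frac[i] > 0.2) {
      cat_out[i] <- "PROTEIN_CODING"; evidence[i] <- co$idx[i]
      ovfrac[i] <- co$frac[i]
    } else if (nc$frac[i] > 0) {
      cat_out[i] <- "NONCODING_RNA"; evidence[i] <- nc$idx[i]
      ovfrac[i] <- nc$frac[i]
    } else if (ln$frac[i] > 0.2) {
      cat_out[i] <- "LNCRNA"; evidence[i] <- ln$idx[i]
      ovfrac[i] <- ln$frac[i]
    } else if (i %in% enh_members) {
      cat_out[i] <- "ENHANCER"
    } else if (div_frac[i] > 0.1) {
      cat_out[i] <- "DIVERGENT"; evidence[i] <- div_idx[i]
      ovfrac[i] <- div_frac[i]
    } else if (as_co$frac[i] > 0.2 && as_co$target_frac[i] > 0.2) {
      cat_out[i] <- "ANTISENSE"; evidence[i] <- as_co$idx[i]
      ovfrac[i] <- as_co$frac[i]
    } else if (rp[i] > 0.5) {
      cat_out[i] <- "REPEAT"; ovfrac[i] <- rp[i]
    } else if (sense_any$frac[i] > 0) {
      cat_out[i] <- "OTHER_GENIC_SENSE"; evidence[i] <- sense_any$idx[i]
      ovfrac[i] <- sense_any$frac[i]
    } else if (anti_any$frac[i] > 0) {
      cat_out[i] <- "OTHER_GENIC_ANTISENSE"; evidence[i] <- anti_any$idx[i]
      ovfrac[i] <- anti_any$frac[i]
    } else {
      cat_out[i] <- "INTERGENIC"
    }
  }
  units$category <- factor(cat_out, levels = TRANSCRIPT_CATEGORIES)
  units$evidence <- evidence
  units$overlap_fraction <- ovfrac
  units
}

#' Detect bidirectional enhancer transcript pairs
#'
#' An enhancer transcript pair is a pair of short (`< max_len`) called
#' units on opposite strands whose intervals partially overlap (at least
#' 1 bp) and whose TSSs both lie more than `min_distance` from every
#' annotated gene TSS and TTS.  Each unit joins at most one pair: pairs
#' are chosen greedily by decreasing overlap, ties towards the leftmost
#' pair.
#'
#' @param units A `GRanges` of called units.
#' @param annotations Gene annotations used for the distance filter
#'   (`GRanges`; may be empty).
#' @param max_len Maximum unit length in bp (default 10,000).
#' @param min_distance Minimum TSS distance from annotated TSS/TTS in bp
#'   (default 10,000).
#' @return A data.frame with one row per pair: `chrom`, `plus_idx`,
#'   `minus_idx` (indices into `units`), `plus_start`, `plus_end`,
#'   `minus_start`, `minus_end`, `overlap`, `center` (midpoint of the
#'   overlap of the two intervals, bp).
#' @export
detect_enhancer_pairs <- function(units, annotations = NULL,
                                  max_len = 10000, min_distance = 10000) {
  stopifnot(is(units, "GRanges"))
  empty <- data.frame(chrom = character(), plus_idx = integer(),
                      minus_idx = integer(), plus_start = integer(),
                      plus_end = integer(), minus_start = integer(),
                      minus_end = integer(), overlap = integer(),
                      center = numeric())
  if (length(units) == 0L) return(empty)
  short <- width(units) < max_len
  far <- rep(TRUE, length(units))
  if (!is.null(annotations) && length(annotations)) {
    u_tss <- ifelse(as.character(strand(units)) == "+", start(units),
                    end(units))
    a_str <- as.character(strand(annotations))
    a_tss <- ifelse(a_str == "+", start(annotations), end(annotations))
    a_tts <- ifelse(a_str == "+", end(annotations), start(annotations))
    for (i in seq_along(units)) {
      on_chrom <- as.character(seqnames(annotations)) ==
        as.character(seqnames(units))[i]
      if (!any(on_chrom)) next
      d <- min(abs(u_tss[i] - a_tss[on_chrom]),
               abs(u_tss[i] - a_tts[on_chrom]))
      far[i] <- d > min_distance
    }
  }
  cand <- which(short & far)
  plus <- cand[as.character(strand(units))[cand] == "+"]
  minus <- cand[as.character(strand(units))[cand] == "-"]
  if (!length(plus) || !length(minus)) return(empty)
  hits <- GenomicRanges::findOverlaps(granges(units)[plus],
                                      granges(units)[minus],
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  p <- plus[queryHits(hits)]
  m <- minus[subjectHits(hits)]
  ov_lo <- pmax(start(units)[p], start(units)[m])
  ov_hi <- pmin(end(units)[p], end(units)[m])
  ov <- ov_hi - ov_lo + 1L
  o <- order(-ov, pmin(start(units)[p], start(units)[m]))
  used <- logical(length(units))
  rows <- list()
  for (r in o) {
    if (used[p[r]] || used[m[r]]) next
    used[p[r]] <- used[m[r]] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = as.character(seqnames(units))[p[r]],
      plus_idx = p[r], minus_idx = m[r],
      plus_start = start(units)[p[r]], plus_end = end(units)[p[r]],
      minus_start = start(units)[m[r]], minus_end = end(units)[m[r]],
      overlap = ov[r], center = (ov_lo[r] + ov_hi[r]) / 2)
  }
  do.call(rbind, rows)
}

#' Cell-type specificity of enhancer transcript pairs
#'
#' A pair in one cell type is *shared* when its merged pair interval
#' overlaps a pair from another cell type by at least 20% of its own
#' length; otherwise it is cell-type-specific.  Pairs connected through
#' chains of such overlaps form one cross-cell enhancer (connected
#' component), and each pair is annotated with the set of cell types its
#' component is active in.
#'
#' @param pairs_by_cell Named list (>= 2 cell types) of pair data.frames
#'   from [detect_enhancer_pairs()].
#' @param min_share Minimum reciprocal overlap fraction (default 0.2).
#' @return A data.frame with columns `cell`, `pair` (row in that cell's
#'   table), `chrom`, `start`, `end` (merged interval), `specific`,
#'   `component` and `cells_active` (comma-separated).
#' @export
cell_type_specificity <- function(pairs_by_cell, min_share = 0.2) {
  if (length(pairs_by_cell) < 2L) stop("need pairs from >= 2 cell types")
  if (is.null(names(pairs_by_cell))) stop("pairs_by_cell must be named")
  tab <- do.call(rbind, lapply(names(pairs_by_cell), function(cell) {
    p <- pairs_by_cell[[cell]]
    if (is.null(p) || nrow(p) == 0L) return(NULL)
    data.frame(cell = cell, pair = seq_len(nrow(p)), chrom = p$chrom,
               start = pmin(p$plus_start, p$minus_start),
               end = pmax(p$plus_end, p$minus_end),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab) || nrow(tab) == 0L) {
    return(data.frame(cell = character(), pair = integer(),
                      chrom = character(), start = integer(),
                      end = integer(), specific = logical(),
                      component = integer(), cells_active = character()))
  }
  n <- nrow(tab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  shared <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || tab$cell[i] == tab$cell[j]) next
      if (tab$chrom[i] != tab$chrom[j]) next
      ov <- .overlap_bp(tab$start[i], tab$end[i], tab$start[j], tab$end[j])
      if (ov >= min_share * (tab$end[i] - tab$start[i] + 1)) {
        shared[i] <- TRUE
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comp <- as.integer(factor(comp))
  cells_active <- vapply(comp, function(cmp) {
    paste(sort(unique(tab$cell[comp == cmp])), collapse = ",")
  }, character(1))
  data.frame(tab, specific = !shared, component = comp,
             cells_active = cells_active, stringsAsFactors = FALSE)
}

#' Metagene profile around genomic anchors
#'
#' Bins strand-specific read 5' positions in a fixed window around each
#' anchor (e.g. enhancer-pair centers) and averages over anchors.  Anchors
#' too close to a chromosome edge are skipped with a warning.
#'
#' @param reads A `GRanges` of stranded reads.
#' @param centers Numeric anchor positions (bp) with a parallel `chrom`
#'   character vector, or a `GRanges` whose midpoints are used.
#' @param chrom For numeric `centers`, the chromosome of each anchor.
#' @param half_window Half-width of the profile window in bp (default
#'   4000); must be a multiple of `bin`.
#' @param bin Bin width in bp (default 100).
#' @param chrom_lengths Optional named lengths for edge checking.
#' @return A list with `offset` (bin start offsets relative to the anchor),
#'   `profile_plus`, `profile_minus` (mean counts per bin), and
#'   `matrix_plus`, `matrix_minus` (per-anchor rows, for heatmaps).
#' @export
metagene <- function(reads, centers, chrom = NULL, half_window = 4000,
                     bin = 100, chrom_lengths = NULL) {
  if (half_window %% bin != 0) stop("half_window must be a multiple of bin")
  if (is(centers, "GRanges")) {
    chrom <- as.character(seqnames(centers))
    centers <- (start(centers) + end(centers)) / 2
  }
  if (length(centers) == 0L) stop("no anchor centers supplied")
  if (is.null(chrom) || length(chrom) != length(centers)) {
    stop("chrom must parallel centers")
  }
  keep <- centers - half_window >= 1
  if (!is.null(chrom_lengths)) {
    keep <- keep & centers + half_window <= chrom_lengths[chrom]
  }
  if (any(!keep)) {
    warning(sum(!keep), " anchor(s) too close to a chromosome edge; skipped")
  }
  centers <- centers[keep]; chrom <- chrom[keep]
  if (length(centers) == 0L) stop("all anchors skipped")
  n_bins <- 2L * half_window / bin
  pos5 <- .read_5prime(reads)
  rchrom <- as.character(seqnames(reads))
  rstrand <- as.character(strand(reads))
  mp <- mm <- matrix(0, nrow = length(centers), ncol = n_bins)
  for (i in seq_along(centers)) {
    lo <- centers[i] - half_window
    on <- rchrom == chrom[i] & pos5 >= lo & pos5 < centers[i] + half_window
    if (!any(on)) next
    idx <- floor((pos5[on] - lo) / bin) + 1L
    for (s in c("+", "-")) {
      tb <- tabulate(idx[rstrand[on] == s], nbins = n_bins)
      if (s == "+") mp[i, ] <- tb else mm[i, ] <- tb
    }
  }
  list(offset = seq(-half_window, half_window - bin, by = bin),
       profile_plus = colMeans(mp), profile_minus = colMeans(mm),
       matrix_plus = mp, matrix_minus = mm)
}
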