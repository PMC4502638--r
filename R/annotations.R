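#' Build non-overlapping consensus annotations from multi-source gene models
#'
#' Collapses isoform-level gene models into one representative interval per
#' gene symbol, then resolves residual overlaps between different symbols on
#' the same strand so that the output is pairwise non-overlapping per strand
#' and every transcription start site (TSS) is preserved:
#'
#' 1. Within a symbol with two or more isoforms, the consensus is the region
#'    covered by at least two isoforms of that symbol (merged); if that
#'    region is fragmented the longest fragment is kept, and if it is empty
#'    (disjoint isoforms) the longest isoform is kept.  A single-isoform
#'    symbol passes through unchanged.
#' 2. Across symbols on one strand, overlapping intervals are trimmed at
#'    their 3' ends: genes are processed in TSS order and each gene's 3' end
#'    is cut back to the next gene's TSS, so no TSS is ever lost.
#'
#' Symbols whose isoforms disagree on strand or chromosome are dropped with
#' a warning.
#'
#' @param models A `GRanges` of gene models with a `symbol` metadata column
#'   (e.g. from [read_annotations()]).
#' @return A `GRanges` of consensus annotations, non-overlapping per strand,
#'   with metadata columns `symbol`, `tss` and `tts` (bp, 1-based).
#' @examples
#' iso <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(11, 21), c(100, 120)), strand = "+",
#'   symbol = c("A", "A"))
#' build_consensus(iso)  # shared interval [21, 100]
#' @export
build_consensus <- function(models) {
  stopifnot(is(models, "GRanges"), !is.null(models$symbol))
  per_sym <- split(seq_along(models), models$symbol)
  rows <- list()
  for (sym in names(per_sym)) {
    iso <- models[per_sym[[sym]]]
    if (length(unique(as.character(strand(iso)))) > 1L ||
        length(unique(as.character(seqnames(iso)))) > 1L) {
      warning("symbol '", sym, "' has isoforms on conflicting strands or ",
              "chromosomes; dropped")
      next
    }
    if (length(iso) == 1L) {
      rows[[sym]] <- iso
      next
    }
    cov <- IRanges::coverage(IRanges::ranges(iso))
    deep <- IRanges::reduce(as(IRanges::slice(cov, lower = 2), "IRanges"))
    rng <- if (length(deep) == 0L) {
      IRanges::ranges(iso)[which.max(width(iso))]
    } else {
      deep[which.max(IRanges::width(deep))]
    }
    rows[[sym]] <- GenomicRanges::GRanges(
      seqnames(iso)[1], rng, strand = as.character(strand(iso))[1],
      symbol = sym)
  }
  if (length(rows) == 0L) {
    return(GenomicRanges::GRanges(symbol = character()))
  }
  cons <- do.call(c, unname(lapply(rows, granges)))
  cons$symbol <- names(rows)
  names(cons) <- NULL
  cons <- .trim_overlaps_3prime(cons)
  cons$tss <- ifelse(as.character(strand(cons)) == "+", start(cons), end(cons))
  cons$tts <- ifelse(as.character(strand(cons)) == "+", end(cons), start(cons))
  GenomicRanges::sort(cons, ignore.strand = TRUE)
}

# resolve cross-symbol overlaps on one strand by truncating the 3' end of the
# gene whose TSS is upstream at the downstream gene's TSS
.trim_overlaps_3prime <- function(cons) {
  keep <- rep(TRUE, length(cons))
  for (chrom in unique(as.character(seqnames(cons)))) {
    for (s in c("+", "-")) {
      idx <- which(as.character(seqnames(cons)) == chrom &
                     as.character(strand(cons)) == s)
      if (length(idx) < 2L) next
      if (s == "+") {
        idx <- idx[order(start(cons)[idx], end(cons)[idx])]
        for (i in seq_len(length(idx) - 1L)) {
          a <- idx[i]; b <- idx[i + 1L]
          if (end(cons)[a] >= start(cons)[b]) {
            new_end <- start(cons)[b] - 1L
            if (new_end < start(cons)[a]) {
              warning("symbol '", cons$symbol[a],
                      "' emptied by 3'-trimming (shared TSS); dropped")
              keep[a] <- FALSE
            } else {
              end(cons)[a] <- new_end
            }
          }
        }
      } else {
        idx <- idx[order(-end(cons)[idx], -start(cons)[idx])]
        for (i in seq_len(length(idx) - 1L)) {
          a <- idx[i]; b <- idx[i + 1L]   # a has the upstream (larger) TSS
          if (start(cons)[a] <= end(cons)[b]) {
            new_start <- end(cons)[b] + 1L
            if (new_start > end(cons)[a]) {
              warning("symbol '", cons$symbol[a],
                      "' emptied by 3'-trimming (shared TSS); dropped")
              keep[a] <- FALSE
            } else {
              start(cons)[a] <- new_start
            }
          }
        }
      }
    }
  }
  cons[keep]
}

# 5'-most genomic positions of stranded reads (1-based)
.read_5prime <- function(reads) {
  ifelse(as.character(strand(reads)) == "+", start(reads), end(reads))
}

#' Evenly-divided-regions (EDR) expression test
#'
#' Splits each annotation's gene body into `n` equal-length segments (the
#' last segment absorbs the remainder) and reports whether every segment
#' contains at least one same-strand read 5' position.  EDR measures the
#' robustness and smoothness of expression along the whole gene body.
#'
#' @param annotations A `GRanges` of (consensus) annotations.
#' @param reads A `GRanges` of stranded aligned reads.
#' @param n Number of segments (>= 1); must not exceed any gene's length.
#' @return A data.frame with columns `symbol`, `n_segments`, `satisfied`.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000),
#'                             strand = "+", symbol = "A")
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(51, 601), width = 30),
#'                             strand = "+")
#' edr(g, r, n = 2)
#' @export
edr <- function(annotations, reads, n) {
  stopifnot(is(annotations, "GRanges"), n >= 1)
  if (any(n > width(annotations))) {
    stop("n exceeds the length (bp) of at least one annotation")
  }
  pos5 <- .read_5prime(reads)
  rchrom <- as.character(seqnames(reads))
  rstrand <- as.character(strand(reads))
  sat <- logical(length(annotations))
  for (i in seq_along(annotations)) {
    a <- annotations[i]
    sel <- rchrom == as.character(seqnames(a)) &
      rstrand == as.character(strand(a)) &
      pos5 >= start(a) & pos5 <= end(a)
    if (!any(sel)) { sat[i] <- FALSE; next }
    w <- width(a)
    seg <- floor(w / n)
    # segment k covers offsets [(k-1)*seg, k*seg), last absorbs remainder
    offs <- pos5[sel] - start(a)
    bin <- pmin(floor(offs / seg) + 1L, n)
    sat[i] <- length(unique(bin)) == n
  }
  data.frame(symbol = if (!is.null(annotations$symbol)) annotations$symbol
                      else as.character(seq_along(annotations)),
             n_segments = n, satisfied = sat,
             stringsAsFactors = FALSE)
}

#' Filter annotations to the well-expressed subset
#'
#' Keeps annotations satisfying the EDR criterion at `n` segments (order
#' preserved).  `n = 10` reproduces the "well-expressed" filter used for
#' error evaluation; `n = 1` keeps every gene with at least one read.
#'
#' @inheritParams edr
#' @return The subset of `annotations` passing [edr()].
#' @export
expressed_subset <- function(annotations, reads, n = 10) {
  res <- edr(annotations, reads, n)
  annotations[res$satisfied]
}
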