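#' Break called units that merge multiple annotations
#'
#' Annotation-guided boundary repair, first half: a called unit overlapping
#' two or more same-strand annotations is split at the midpoint between
#' each adjacent annotation pair (midpoint of the gap between the upstream
#' gene's 3' end and the downstream gene's 5' start, in genomic
#' coordinates).  Pieces shorter than one window are dropped.
#'
#' @param units A `GRanges` of called units.
#' @param annotations Non-overlapping (per strand) annotations.
#' @param window_size Minimum piece length in bp (default 50).
#' @return A `GRanges` of repaired units with fresh ids.
#' @export
break_on_annotations <- function(units, annotations, window_size = 50) {
  stopifnot(is(units, "GRanges"), is(annotations, "GRanges"))
  .check_nonoverlapping(annotations, "annotations")
  hits <- GenomicRanges::findOverlaps(units, annotations)
  out <- list()
  for (i in seq_along(units)) {
    anns <- subjectHits(hits)[queryHits(hits) == i]
    u <- units[i]
    if (length(anns) < 2L) {
      out[[length(out) + 1L]] <- granges(u)
      next
    }
    a <- annotations[anns]
    a <- a[order(start(a))]
    # split points: midpoints of the inter-gene gaps
    cuts <- floor((end(a)[-length(a)] + start(a)[-1]) / 2)
    bounds <- c(start(u), cuts + 1L)
    ends <- c(cuts, end(u))
    keep <- (ends - bounds + 1L) >= window_size
    if (!any(keep)) next
    out[[length(out) + 1L]] <- GenomicRanges::GRanges(
      seqnames(u), IRanges::IRanges(bounds[keep], ends[keep]),
      strand = strand(u))
  }
  pieces <- if (length(out)) do.call(c, out) else
    GenomicRanges::GRanges()
  pieces <- GenomicRanges::sort(pieces, ignore.strand = TRUE)
  if (length(pieces)) pieces$id <- sprintf("tu_%05d", seq_along(pieces))
  pieces
}

#' Combine called units that fragment one annotation
#'
#' Boundary repair, second half: all units whose best match
#' ([match_units()]) is the same annotation and that lie within its span
#' (plus a one-window tolerance for window quantisation of calls) are
#' replaced by a single unit from the minimum start to the maximum end.
#' Units matched to no annotation pass through untouched.
#'
#' @inheritParams break_on_annotations
#' @param window_size Tolerance in bp around the annotation span.
#' @return A `GRanges` of repaired units with fresh ids.
#' @export
combine_on_annotations <- function(units, annotations, window_size = 50) {
  stopifnot(is(units, "GRanges"), is(annotations, "GRanges"))
  .check_nonoverlapping(annotations, "annotations")
  if (length(units) == 0L) return(units)
  # best annotation per unit (maximal overlap); the unit joins that
  # annotation's combine group only if it lies within the span +/- one window
  hits <- GenomicRanges::findOverlaps(units, annotations)
  group <- rep(NA_integer_, length(units))
  if (length(hits)) {
    ov <- width(GenomicRanges::pintersect(units[queryHits(hits)],
                                          annotations[subjectHits(hits)]))
    for (i in unique(queryHits(hits))) {
      sel <- which(queryHits(hits) == i)
      a <- subjectHits(hits)[sel[which.max(ov[sel])]]
      if (start(units)[i] >= start(annotations)[a] - window_size &&
          end(units)[i] <= end(annotations)[a] + window_size) {
        group[i] <- a
      }
    }
  }
  out <- list()
  for (a in unique(group[!is.na(group)])) {
    idx <- which(group == a)
    u <- units[idx]
    out[[length(out) + 1L]] <- GenomicRanges::GRanges(
      seqnames(u)[1], IRanges::IRanges(min(start(u)), max(end(u))),
      strand = as.character(strand(u))[1])
  }
  untouched <- granges(units[is.na(group)])
  combined <- if (length(out)) do.call(c, out) else GenomicRanges::GRanges()
  res <- GenomicRanges::sort(c(untouched, combined), ignore.strand = TRUE)
  if (length(res)) res$id <- sprintf("tu_%05d", seq_along(res))
  res
}

#' Annotation-guided boundary repair (break then combine)
#'
#' @inheritParams break_on_annotations
#' @param do_break,do_combine Toggle the two repair halves.
#' @return Repaired `GRanges` of units.
#' @export
polish_units <- function(units, annotations, window_size = 50,
                         do_break = TRUE, do_combine = TRUE) {
  if (do_break) units <- break_on_annotations(units, annotations, window_size)
  if (do_combine) units <- combine_on_annotations(units, annotations,
                                                  window_size)
  units
}
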