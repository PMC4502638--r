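#' Map called transcription units to annotations one-to-one
#'
#' Each annotation is associated with its best overlapping called unit on
#' the same strand ("best" = maximal overlap in bp; ties broken towards the
#' 5'-most unit).  A unit may serve several annotations — that is precisely
#' the merged-annotation case counted by [annotation_errors()].
#'
#' @param units A `GRanges` of called units.
#' @param annotations A `GRanges` of annotations.
#' @return A list with `pairs` (data.frame: `annotation`, `unit` — integer
#'   indices — and `overlap` bp), `unmatched_annotations` and
#'   `unmatched_units` (integer indices).
#' @export
match_units <- function(units, annotations) {
  stopifnot(is(units, "GRanges"), is(annotations, "GRanges"))
  hits <- GenomicRanges::findOverlaps(annotations, units)
  if (length(hits) == 0L) {
    return(list(pairs = data.frame(annotation = integer(), unit = integer(),
                                   overlap = integer()),
                unmatched_annotations = seq_along(annotations),
                unmatched_units = seq_along(units)))
  }
  qh <- queryHits(hits); sh <- subjectHits(hits)
  ov <- width(GenomicRanges::pintersect(annotations[qh], units[sh]))
  best <- integer(0); best_ann <- integer(0); best_ov <- integer(0)
  for (a in unique(qh)) {
    sel <- which(qh == a)
    mx <- max(ov[sel])
    cand <- sel[ov[sel] == mx]
    if (length(cand) > 1L) {
      # tie: 5'-most unit on the annotation's strand
      u <- units[sh[cand]]
      cand <- if (as.character(strand(annotations[a])) == "-") {
        cand[order(-end(u), start(u))][1L]
      } else {
        cand[order(start(u), end(u))][1L]
      }
    }
    best_ann <- c(best_ann, a)
    best <- c(best, sh[cand[1L]])
    best_ov <- c(best_ov, mx)
  }
  list(pairs = data.frame(annotation = best_ann, unit = best,
                          overlap = best_ov),
       unmatched_annotations = setdiff(seq_along(annotations), best_ann),
       unmatched_units = setdiff(seq_along(units), unique(sh)))
}

.check_nonoverlapping <- function(annotations, what = "annotations") {
  self <- GenomicRanges::findOverlaps(annotations, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(self)) {
    stop(what, " must be non-overlapping per strand (found overlapping ",
         "pair at indices ", queryHits(self)[1L], ", ",
         subjectHits(self)[1L], ")")
  }
  invisible(TRUE)
}

#' Merged / dissociated annotation errors of a call set
#'
#' Two natural boundary errors against a non-overlapping annotation set:
#' a *merged annotation error* is a called unit spanning two or more
#' expressed annotations on its strand; a *dissociated annotation error* is
#' an expressed annotation broken across two or more called units.  The
#' overall rate is their sum over the number of annotations evaluated.
#'
#' @param units A `GRanges` of called units.
#' @param expressed_annotations A `GRanges` of expressed annotations,
#'   non-overlapping per strand (see [expressed_subset()]).
#' @return An object of class `error_report`: `n_merged`, `n_dissociated`,
#'   `n_eval`, `rate`, `n_units`, `median_unit_length`.
#' @export
annotation_errors <- function(units, expressed_annotations) {
  stopifnot(is(units, "GRanges"), is(expressed_annotations, "GRanges"))
  .check_nonoverlapping(expressed_annotations, "expressed annotations")
  hits <- GenomicRanges::findOverlaps(expressed_annotations, units)
  ann_per_unit <- table(subjectHits(hits))
  units_per_ann <- table(queryHits(hits))
  n_merged <- sum(ann_per_unit >= 2L)
  n_dissociated <- sum(units_per_ann >= 2L)
  n_eval <- length(expressed_annotations)
  structure(list(n_merged = as.integer(n_merged),
                 n_dissociated = as.integer(n_dissociated),
                 n_eval = n_eval,
                 rate = if (n_eval > 0) (n_merged + n_dissociated) / n_eval
                        else NA_real_,
                 n_units = length(units),
                 median_unit_length = if (length(units))
                   as.numeric(median(width(units))) else NA_real_),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("Annotation-error report\n")
  cat(sprintf("  called units        : %d (median length %s bp)\n",
              x$n_units, format(x$median_unit_length)))
  cat(sprintf("  annotations checked : %d\n", x$n_eval))
  cat(sprintf("  merged errors       : %d\n", x$n_merged))
  cat(sprintf("  dissociated errors  : %d\n", x$n_dissociated))
  cat(sprintf("  overall error rate  : %.4f\n", x$rate))
  invisible(x)
}

# per-annotation scaled evaluation regions (upstream / body / downstream,
# in the 5'->3' sense), as 1-based closed intervals
.eval_regions <- function(ann, upstream_fraction) {
  w <- width(ann)
  L <- pmax(1L, as.integer(round(upstream_fraction * w)))
  plus <- as.character(strand(ann)) == "+"
  up_s <- ifelse(plus, start(ann) - L, end(ann) + 1L)
  up_e <- ifelse(plus, start(ann) - 1L, end(ann) + L)
  dn_s <- ifelse(plus, end(ann) + 1L, start(ann) - L)
  dn_e <- ifelse(plus, end(ann) + L, start(ann) - 1L)
  list(up_s = up_s, up_e = up_e, dn_s = dn_s, dn_e = dn_e, L = L)
}

.overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

#' Transcription-unit accuracy components from aggregate areas
#'
#' Applies the defining constraint `fp5_hat + tn5_hat = tp_hat` (capping
#' `fp5_hat` at `tp_hat`) and evaluates the accuracy score
#' `(tp_hat + tn5_hat) / (tp_hat + fn_hat + fp5_hat + tn5_hat)`, which
#' simplifies to `(2*tp_hat - fp5_hat) / (1 + tp_hat)` because
#' `fn_hat = 1 - tp_hat`.
#'
#' @param tp_hat Aggregate gene-body coverage proportion, in `[0, 1]`.
#' @param fp5_hat Aggregate upstream-region coverage proportion, in `[0, 1]`.
#' @return A list with `tp_hat`, `fp5_hat` (after capping), `tn5_hat`,
#'   `fn_hat` and `tua`.
#' @export
tua_score <- function(tp_hat, fp5_hat) {
  stopifnot(tp_hat >= 0, tp_hat <= 1, fp5_hat >= 0, fp5_hat <= 1)
  fp5_hat <- min(fp5_hat, tp_hat)
  tn5_hat <- tp_hat - fp5_hat
  fn_hat <- 1 - tp_hat
  tua <- if (tp_hat == 0) 0 else (2 * tp_hat - fp5_hat) / (1 + tp_hat)
  list(tp_hat = tp_hat, fp5_hat = fp5_hat, tn5_hat = tn5_hat,
       fn_hat = fn_hat, tua = tua)
}

#' Transcription-unit accuracy (TUA) of a call set
#'
#' Scales every annotation to a uniform length, associates it with its best
#' matched called unit ([match_units()]), and measures coverage proportions
#' in three regions: upstream of the TSS, the gene body, and downstream of
#' the TTS.  Aggregating over annotations gives the areas `tp_hat` (body),
#' `fp5_hat` (upstream) and `post_tts_hat` (downstream; reported but
#' excluded from the score, since polymerase continues past the
#' polyadenylation site).  The scalar accuracy is computed by [tua_score()].
#'
#' @param units A `GRanges` of called units.
#' @param expressed_annotations A `GRanges` of expressed annotations,
#'   non-overlapping per strand.
#' @param upstream_fraction Length of the upstream (and downstream)
#'   evaluation region as a fraction of each gene's length (default 1).
#' @return An object of class `tua_result` with fields `tp_hat`, `fp5_hat`,
#'   `tn5_hat`, `fn_hat`, `post_tts_hat`, `tua`, `n_eval`.
#' @export
tua <- function(units, expressed_annotations, upstream_fraction = 1) {
  if (upstream_fraction <= 0) stop("upstream_fraction must be positive")
  stopifnot(is(units, "GRanges"), is(expressed_annotations, "GRanges"))
  ann <- expressed_annotations
  n <- length(ann)
  if (n == 0L) stop("no annotations to evaluate")
  mm <- match_units(units, ann)
  tp_i <- fp_i <- dn_i <- numeric(n)
  if (nrow(mm$pairs)) {
    reg <- .eval_regions(ann, upstream_fraction)
    a <- mm$pairs$annotation
    u <- units[mm$pairs$unit]
    tp_i[a] <- mm$pairs$overlap / width(ann)[a]
    fp_i[a] <- .overlap_bp(start(u), end(u), reg$up_s[a], reg$up_e[a]) /
      reg$L[a]
    dn_i[a] <- .overlap_bp(start(u), end(u), reg$dn_s[a], reg$dn_e[a]) /
      reg$L[a]
  }
  sc <- tua_score(mean(tp_i), min(mean(fp_i), 1))
  structure(c(sc, list(post_tts_hat = mean(dn_i), n_eval = n)),
            class = "tua_result")
}

#' @export
print.tua_result <- function(x, ...) {
  cat("Transcription-unit accuracy\n")
  cat(sprintf("  TP = %.4f  5'FP = %.4f  5'TN = %.4f  FN = %.4f  PostTTS = %.4f\n",
              x$tp_hat, x$fp5_hat, x$tn5_hat, x$fn_hat, x$post_tts_hat))
  cat(sprintf("  TUA = %.4f  (over %d annotations)\n", x$tua, x$n_eval))
  invisible(x)
}

#' Scaled transcript-density profile around annotations
#'
#' For each annotation, the matched called unit's footprint is mapped onto
#' scaled coordinates spanning the upstream region, gene body and downstream
#' region (each divided into `n_bins` bins, ordered 5' to 3').  The density
#' of a bin is the fraction of annotations whose matched unit overlaps it.
#'
#' @inheritParams tua
#' @param n_bins Bins per region (>= 1; total bins = 3 * n_bins).
#' @return A data.frame with columns `region` (upstream/body/downstream),
#'   `bin` (1..n_bins within region) and `density` in `[0, 1]`.
#' @export
transcript_density <- function(units, expressed_annotations, n_bins = 10,
                               upstream_fraction = 1) {
  stopifnot(n_bins >= 1)
  ann <- expressed_annotations
  n <- length(ann)
  if (n == 0L) stop("no annotations")
  mm <- match_units(units, ann)
  cover <- matrix(0, nrow = n, ncol = 3L * n_bins)
  if (nrow(mm$pairs)) {
    for (r in seq_len(nrow(mm$pairs))) {
      a <- mm$pairs$annotation[r]
      u <- units[mm$pairs$unit[r]]
      g <- ann[a]
      w <- width(g)
      L <- max(1, round(upstream_fraction * w))
      # scaled axis: 0-based offset from the TSS along the 5'->3' direction;
      # bins tile [-L, w + L) with n_bins bins per region
      edges <- c(seq(-L, 0, length.out = n_bins + 1),
                 seq(0, w, length.out = n_bins + 1)[-1],
                 seq(w, w + L, length.out = n_bins + 1)[-1])
      o_lo <- head(edges, -1)
      o_hi <- tail(edges, -1)
      if (as.character(strand(g)) == "+") {
        b_lo <- start(g) + o_lo
        b_hi <- start(g) + o_hi - 1
      } else {
        b_lo <- end(g) - o_hi + 1
        b_hi <- end(g) - o_lo
      }
      cover[a, ] <- as.numeric(
        .overlap_bp(start(u), end(u), b_lo, b_hi) > 0)
    }
  }
  data.frame(region = rep(c("upstream", "body", "downstream"),
                          each = n_bins),
             bin = rep(seq_len(n_bins), 3L),
             density = colMeans(cover),
             stringsAsFactors = FALSE)
}

#' Genic and intergenic genome coverage of called units
#'
#' Tiles every chromosome (per strand) into non-overlapping windows.  A
#' window is *genic* if it intersects a same-strand expressed annotation,
#' else *intergenic*; it is *covered* if it intersects a same-strand called
#' unit.  Returns the covered fraction per class.
#'
#' @inheritParams tua
#' @param window Window size in bp (default 100).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @return A list with `genic_fraction`, `intergenic_fraction` and window
#'   counts.
#' @export
genome_coverage <- function(units, expressed_annotations, window = 100,
                            chrom_lengths) {
  stopifnot(!is.null(names(chrom_lengths)))
  genic_cov <- genic_tot <- inter_cov <- inter_tot <- 0
  for (chrom in names(chrom_lengths)) {
    n_win <- ceiling(chrom_lengths[[chrom]] / window)
    win <- IRanges::IRanges(start = (seq_len(n_win) - 1) * window + 1,
                            width = window)
    for (s in c("+", "-")) {
      sel_a <- as.character(seqnames(expressed_annotations)) == chrom &
        as.character(strand(expressed_annotations)) == s
      sel_u <- as.character(seqnames(units)) == chrom &
        as.character(strand(units)) == s
      genic <- IRanges::overlapsAny(
        win, IRanges::ranges(expressed_annotations[sel_a]))
      covered <- IRanges::overlapsAny(win, IRanges::ranges(units[sel_u]))
      genic_tot <- genic_tot + sum(genic)
      genic_cov <- genic_cov + sum(genic & covered)
      inter_tot <- inter_tot + sum(!genic)
      inter_cov <- inter_cov + sum(!genic & covered)
    }
  }
  list(genic_fraction = if (genic_tot > 0) genic_cov / genic_tot else 0,
       intergenic_fraction = if (inter_tot > 0) inter_cov / inter_tot else 0,
       genic_windows = genic_tot, intergenic_windows = inter_tot)
}
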