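#' Specify a synthetic genome and sequencing regime
#'
#' Builds the parameter set consumed by [simulate_genome()] and
#' [simulate_reads()].  Presets fix the gene density at the average for the
#' organism class — human 11, fly 76, worm 200 genes per Mb — with
#' gene-length distributions (log-normal) chosen so the genes fit their
#' genome's packing: human median 23 kb (the median annotated gene length),
#' fly 3 kb, worm 1.5 kb.  Transcribed windows emit reads at a
#' gamma-Poisson rate with mean `k_T * theta_T * read_scale` reads per
#' window; background windows are Poisson with mean `background_rate`.
#'
#' @param preset `"human"`, `"fly"` or `"worm"`.
#' @param chrom_lengths Named chromosome lengths (default one 10-Mb
#'   chromosome).
#' @param gene_density Genes per Mb (default: preset value).
#' @param gene_length_median,gene_length_sdlog Log-normal gene-length
#'   parameters (bp; defaults per preset).
#' @param n_enhancer_pairs Planted bidirectional enhancer pairs (default 4
#'   for the human preset, else 0 — gene-dense genomes rarely leave the
#'   required 10-kb clearance).
#' @param k_T,theta_T Transcribed-state gamma (default shape 2, scale 5:
#'   mean 10 reads per window).
#' @param background_rate Mean background reads per window (default 0.05).
#' @param read_scale Depth multiplier on the transcribed rate (default 1).
#' @param window_size Simulation window in bp (default 50).
#' @param read_length Read length in bp (default 30).
#' @param seed Integer seed; all randomness derives from it
#'   ([simulate_genome()] seeds with `seed`, [simulate_reads()] with
#'   `seed + 1`).
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(preset = c("human", "fly", "worm"),
                        chrom_lengths = c(chrSim = 1e7),
                        gene_density = NULL,
                        gene_length_median = NULL,
                        gene_length_sdlog = NULL,
                        n_enhancer_pairs = NULL,
                        k_T = 2, theta_T = 5,
                        background_rate = 0.05, read_scale = 1,
                        window_size = 50, read_length = 30, seed = 1) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    human = list(density = 11, med = 23000, sdlog = 0.8, enh = 4L),
    fly   = list(density = 76, med = 3000,  sdlog = 0.6, enh = 0L),
    worm  = list(density = 200, med = 1500, sdlog = 0.5, enh = 0L))
  spec <- list(preset = preset, chrom_lengths = chrom_lengths,
               gene_density = gene_density %||% defaults$density,
               gene_length_median = gene_length_median %||% defaults$med,
               gene_length_sdlog = gene_length_sdlog %||% defaults$sdlog,
               n_enhancer_pairs = n_enhancer_pairs %||% defaults$enh,
               k_T = k_T, theta_T = theta_T,
               background_rate = background_rate, read_scale = read_scale,
               window_size = window_size, read_length = read_length,
               seed = seed)
  stopifnot(spec$gene_density > 0, all(chrom_lengths > 0))
  class(spec) <- "genome_spec"
  spec
}

#' Simulate a ground-truth genome layout
#'
#' Places genes (non-overlapping per strand) by Poisson-sampled counts and
#' log-normal lengths, and plants bidirectional enhancer transcript pairs
#' in intergenic space more than 10 kb from every gene.  Fully reproducible
#' from the spec seed.
#'
#' @param spec A [genome_spec()].
#' @return A list of class `genome_truth`: `genes` (`GRanges` with
#'   `symbol`), `units` (`GRanges` of all true transcription units — genes
#'   plus enhancer transcripts — with `id` and `type`), `enhancer_pairs`
#'   (data.frame as in [detect_enhancer_pairs()]) and the `spec`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  genes <- GenomicRanges::GRanges()
  for (chrom in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[chrom]]
    n_genes <- rpois(1, spec$gene_density * len / 1e6)
    if (n_genes == 0) next
    widths <- pmax(spec$window_size * 4,
                   round(rlnorm(n_genes, meanlog = log(spec$gene_length_median),
                                sdlog = spec$gene_length_sdlog)))
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    placed_s <- list(`+` = integer(0), `-` = integer(0))
    placed_e <- list(`+` = integer(0), `-` = integer(0))
    for (g in seq_len(n_genes)) {
      w <- widths[g]; s <- strands[g]
      ok <- FALSE
      for (try in 1:300) {
        st <- floor(runif(1, 1, len - w))
        en <- st + w - 1
        if (!any(st <= placed_e[[s]] & en >= placed_s[[s]])) {
          placed_s[[s]] <- c(placed_s[[s]], st)
          placed_e[[s]] <- c(placed_e[[s]], en)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place gene ", g, " on ", chrom,
             ": gene density too high for this chromosome; lower ",
             "gene_density or gene lengths")
      }
    }
    gr <- GenomicRanges::GRanges(
      chrom,
      IRanges::IRanges(unlist(placed_s), unlist(placed_e)),
      strand = rep(c("+", "-"), times = lengths(placed_s)))
    genes <- c(genes, gr)
  }
  genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)
  if (length(genes)) {
    genes$symbol <- sprintf("SYNGENE%04d", seq_along(genes))
  } else {
    genes$symbol <- character(0)
  }

  pairs <- .plant_enhancers(genes, spec)
  enh_units <- GenomicRanges::GRanges()
  if (nrow(pairs)) {
    enh_units <- c(
      GenomicRanges::GRanges(pairs$chrom,
                             IRanges::IRanges(pairs$plus_start,
                                              pairs$plus_end),
                             strand = "+"),
      GenomicRanges::GRanges(pairs$chrom,
                             IRanges::IRanges(pairs$minus_start,
                                              pairs$minus_end),
                             strand = "-"))
  }
  units <- c(granges(genes), enh_units)
  units$type <- c(rep("gene", length(genes)),
                  rep("enhancer", length(enh_units)))
  units <- GenomicRanges::sort(units, ignore.strand = TRUE)
  units$id <- sprintf("true_%04d", seq_along(units))
  structure(list(genes = genes, units = units, enhancer_pairs = pairs,
                 spec = spec),
            class = "genome_truth")
}

# place bidirectional pairs in gaps > 10 kb clear of all genes
.plant_enhancers <- function(genes, spec) {
  empty <- data.frame(chrom = character(), plus_idx = integer(),
                      minus_idx = integer(), plus_start = integer(),
                      plus_end = integer(), minus_start = integer(),
                      minus_end = integer(), overlap = integer(),
                      center = numeric())
  n_want <- spec$n_enhancer_pairs
  if (n_want == 0) return(empty)
  clearance <- 10000 + 5000   # 10-kb rule plus room for the pair itself
  rows <- list()
  for (chrom in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[chrom]]
    on <- genes[as.character(seqnames(genes)) == chrom]
    occ <- GenomicRanges::reduce(granges(on), ignore.strand = TRUE)
    gap_lo <- c(1, end(occ) + 1)
    gap_hi <- c(start(occ) - 1, len)
    wide <- which(gap_hi - gap_lo + 1 > 2 * clearance)
    for (g in wide) {
      if (length(rows) >= n_want) break
      center <- round((gap_lo[g] + gap_hi[g]) / 2)
      lp <- round(runif(1, 800, 2500))
      lm <- round(runif(1, 800, 2500))
      o <- round(runif(1, 200, min(lp, lm) / 2))
      # plus unit extends 5'-ward (left) of the overlap, minus 3'-ward
      ps <- center - round(o / 2) - (lp - o)
      pe <- ps + lp - 1
      ms <- center - round(o / 2)
      me <- ms + lm - 1
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, plus_idx = NA_integer_, minus_idx = NA_integer_,
        plus_start = ps, plus_end = pe, minus_start = ms, minus_end = me,
        overlap = pe - ms + 1L, center = (ms + pe) / 2)
    }
  }
  if (length(rows) < n_want) {
    warning("only ", length(rows), " of ", n_want,
            " enhancer pairs could be placed >10 kb from genes")
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Simulate strand-specific nascent-transcription reads
#'
#' For every simulation window inside a true transcription unit, a rate is
#' drawn from the transcribed gamma `Gamma(k_T, theta_T)` and the window's
#' read count from `Poisson(rate * read_scale)` — the gamma-Poisson regime
#' the HMM's pseudocounted gamma emissions approximate.  Background windows
#' draw counts from `Poisson(background_rate)` on each strand.  Reads are
#' placed uniformly within their window, on the unit's strand, and given
#' the spec's read length.
#'
#' @param truth A `genome_truth` from [simulate_genome()].
#' @param spec Optional [genome_spec()] override (defaults to
#'   `truth$spec`).
#' @return A `GRanges` of aligned reads with `name` and `score` columns,
#'   ready for [bin_reads()] or [write_transcripts_bed()]-style export.
#' @export
simulate_reads <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "genome_truth"))
  set.seed(spec$seed + 1)
  w <- spec$window_size
  rl <- spec$read_length
  chroms <- character(0); starts <- integer(0); strands <- character(0)
  for (chrom in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[chrom]]
    n_win <- ceiling(len / w)
    for (s in c("+", "-")) {
      on <- truth$units[as.character(seqnames(truth$units)) == chrom &
                          as.character(strand(truth$units)) == s]
      transcribed <- rep(FALSE, n_win)
      for (i in seq_along(on)) {
        lo <- floor((start(on)[i] - 1) / w) + 1L
        hi <- floor((end(on)[i] - 1) / w) + 1L
        transcribed[lo:hi] <- TRUE
      }
      n_tr <- sum(transcribed)
      counts <- integer(n_win)
      if (n_tr > 0 && spec$read_scale > 0) {
        rates <- rgamma(n_tr, shape = spec$k_T, scale = spec$theta_T)
        counts[transcribed] <- rpois(n_tr, rates * spec$read_scale)
      }
      if (spec$background_rate > 0) {
        counts[!transcribed] <- rpois(n_win - n_tr, spec$background_rate)
      }
      nz <- which(counts > 0)
      if (!length(nz)) next
      win_of_read <- rep(nz, counts[nz])
      # uniform 5' position within the window, kept clear of the ends so
      # the whole read stays on the chromosome
      pos5 <- (win_of_read - 1L) * w +
        floor(runif(length(win_of_read), 0, w)) + 1L
      pos5 <- pmin(pmax(pos5, rl), len - rl)
      chroms <- c(chroms, rep(chrom, length(pos5)))
      strands <- c(strands, rep(s, length(pos5)))
      starts <- c(starts, if (s == "+") pos5 else pos5 - rl + 1L)
    }
  }
  if (!length(starts)) {
    return(GenomicRanges::GRanges(name = character(), score = numeric()))
  }
  gr <- GenomicRanges::GRanges(chroms,
                               IRanges::IRanges(starts, width = rl),
                               strand = strands)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  gr$name <- sprintf("read_%07d", seq_along(gr))
  gr$score <- 0
  gr
}
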