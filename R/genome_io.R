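#' Read strand-specific aligned reads from a BED6 file
#'
#' Parses a six-column BED file of aligned reads into a `GRanges`.  GRO-seq
#' analysis is inherently strand-specific, so the strand column is mandatory
#' and must be `+` or `-`; a `.` strand is rejected.  BED coordinates
#' (0-based, half-open) are converted to the 1-based closed convention used
#' by `GRanges`.
#'
#' @param path Path to a tab-delimited BED6 file with no header.
#' @return A `GRanges` with metadata columns `name` and `score`.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t36\tr1\t0\t+", tf)
#' read_bed(tf)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges(name = character(), score = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("BED6 parse error at line ", which(nf < 6L)[1L],
         ": fewer than 6 fields")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  name <- vapply(fields, `[[`, character(1), 4L)
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5L)))
  strnd <- vapply(fields, `[[`, character(1), 6L)

  bad <- which(is.na(start0) | is.na(end0) | start0 != floor(start0) |
                 end0 != floor(end0))
  if (length(bad)) {
    stop("BED6 parse error at line ", bad[1L], ": non-integer coordinate")
  }
  bad <- which(start0 >= end0)
  if (length(bad)) {
    stop("BED6 parse error at line ", bad[1L], ": start >= end")
  }
  bad <- which(!strnd %in% c("+", "-"))
  if (length(bad)) {
    stop("BED6 parse error at line ", bad[1L],
         ": strand must be '+' or '-' (strand is required for nascent ",
         "transcription data)")
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         strand = strnd, name = name,
                         score = ifelse(is.na(score), 0, score))
}

#' Write transcription units as BED6
#'
#' Units are written sorted by (chromosome, start), score 0, with a stable
#' unit id in the name column.  Writing then reading with [read_bed()]
#' recovers identical intervals and strands.
#'
#' @param units A `GRanges` of called transcription units (optionally with an
#'   `id` metadata column; ids are generated otherwise).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_transcripts_bed <- function(units, path) {
  stopifnot(is(units, "GRanges"))
  if (length(units) == 0L) {
    con <- file(path, "w"); close(con)
    return(invisible(path))
  }
  o <- order(as.character(seqnames(units)), start(units))
  units <- units[o]
  ids <- if (!is.null(units$id)) as.character(units$id) else
    sprintf("tu_%05d", seq_along(units))
  lines <- paste(as.character(seqnames(units)), start(units) - 1L,
                 end(units), ids, 0L, as.character(strand(units)),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromosome-length table
#'
#' Two whitespace-delimited columns: chromosome name and length in bp
#' (the UCSC "chrom.sizes" format).
#'
#' @param path Path to the table.
#' @return A named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("chromosome-size table needs two columns")
  setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
}

#' Read gene annotations from GTF/GFF3 or BED
#'
#' A thin wrapper over `rtracklayer::import()` for GTF/GFF3/BED12, and over
#' [read_bed()] for strict BED6.  Returns one interval per gene model with a
#' `symbol` metadata column.  For GTF/GFF3 input, rows of the feature types in
#' `feature` are kept and the symbol is taken from `symbol_attr`.
#'
#' @param path Annotation file.
#' @param format One of `"auto"`, `"gtf"`, `"gff3"`, `"bed"`, `"bed6"`.
#' @param symbol_attr Attribute holding the gene symbol (GTF/GFF3 only).
#' @param feature GTF/GFF3 feature types to keep (first type present wins).
#' @return A `GRanges` with a `symbol` column.
#' @export
read_annotations <- function(path, format = "auto",
                             symbol_attr = "gene_id",
                             feature = c("gene", "transcript")) {
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gtf = "gtf", gff = "gff3", gff3 = "gff3",
                     bed = "bed", bed6 = "bed6",
                     stop("cannot guess annotation format from extension '",
                          ext, "'"))
  }
  if (format == "bed6") {
    gr <- read_bed(path)
    gr$symbol <- gr$name
    return(gr)
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "bed" else format)
  if (format %in% c("gtf", "gff3")) {
    if (!is.null(gr$type)) {
      for (ft in feature) {
        if (any(gr$type == ft)) { gr <- gr[gr$type == ft]; break }
      }
    }
    sym <- mcols(gr)[[symbol_attr]]
    if (is.null(sym)) stop("attribute '", symbol_attr, "' absent from ", path)
    gr$symbol <- as.character(sym)
  } else {
    gr$symbol <- if (!is.null(gr$name)) as.character(gr$name) else
      sprintf("gene_%05d", seq_along(gr))
  }
  mcols(gr) <- mcols(gr)[, "symbol", drop = FALSE]
  gr
}

#' Bin reads into strand-specific fixed-width windows
#'
#' Each read increments exactly one window, chosen by its 5'-most genomic
#' position (the start for `+` reads, the end for `-` reads): nascent-
#' transcription reads mark the polymerase position, so no overlap-fraction
#' spanning rule is applied.  Windows are `[i*w, (i+1)*w)` in 0-based
#' coordinates; the two strands are binned separately and never mixed.
#'
#' @param reads A `GRanges` of aligned reads (strand `+`/`-` only).
#' @param window_size Window width in bp (default 50).
#' @param chrom_lengths Named numeric vector of chromosome lengths; every
#'   read's chromosome must be present and no read may extend past the end.
#' @return A `windowed_counts` object: one integer count vector per
#'   (chromosome, strand) track.
#' @examples
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 36), strand = "+")
#' wc <- bin_reads(r, 50, c(chr1 = 1000))
#' wc$tracks[["chr1:+"]]$counts[1:3]
#' @export
bin_reads <- function(reads, window_size = 50, chrom_lengths) {
  stopifnot(is(reads, "GRanges"), window_size >= 1)
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  chroms <- unique(as.character(seqnames(reads)))
  missing_chrom <- setdiff(chroms, names(chrom_lengths))
  if (length(missing_chrom)) {
    stop("chromosome(s) absent from chrom_lengths: ",
         paste(missing_chrom, collapse = ", "))
  }
  past <- which(end(reads) > chrom_lengths[as.character(seqnames(reads))])
  if (length(past)) {
    r <- reads[past[1L]]
    stop("read past chromosome end: ", as.character(seqnames(r)), ":",
         start(r) - 1L, "-", end(r))
  }
  str_chr <- as.character(strand(reads))
  if (any(str_chr == "*")) stop("reads must be stranded (+/-)")

  tracks <- list()
  for (chrom in names(chrom_lengths)) {
    n_win <- as.integer(ceiling(chrom_lengths[[chrom]] / window_size))
    on_chrom <- as.character(seqnames(reads)) == chrom
    for (s in c("+", "-")) {
      sel <- on_chrom & str_chr == s
      # 5' position, 0-based
      pos0 <- if (s == "+") start(reads)[sel] - 1L else end(reads)[sel] - 1L
      idx <- floor(pos0 / window_size) + 1L
      counts <- tabulate(idx, nbins = n_win)
      tracks[[paste0(chrom, ":", s)]] <-
        list(chrom = chrom, strand = s, counts = as.integer(counts))
    }
  }
  windowed_counts(tracks, window_size, chrom_lengths)
}

#' Construct a windowed-counts container
#'
#' @param tracks Named list of tracks, each `list(chrom, strand, counts)`.
#' @param window_size Window width in bp.
#' @param chrom_lengths Named chromosome lengths.
#' @return A `windowed_counts` object.
#' @export
windowed_counts <- function(tracks, window_size, chrom_lengths) {
  stopifnot(all(vapply(tracks, function(t)
    all(c("chrom", "strand", "counts") %in% names(t)), logical(1))))
  structure(list(tracks = tracks, window_size = window_size,
                 chrom_lengths = chrom_lengths),
            class = "windowed_counts")
}

#' @export
print.windowed_counts <- function(x, ...) {
  cat("Windowed read counts:", length(x$tracks), "track(s),",
      x$window_size, "bp windows\n")
  for (nm in names(x$tracks)) {
    tr <- x$tracks[[nm]]
    cat(sprintf("  %-12s %8d windows, %10d reads\n", nm,
                length(tr$counts), sum(tr$counts)))
  }
  invisible(x)
}

# coerce a bare numeric vector into a one-track windowed_counts (tests and
# single-locus use); strand "+" on a pseudo-chromosome
.as_windowed_counts <- function(x, window_size = 50) {
  if (inherits(x, "windowed_counts")) return(x)
  stopifnot(is.numeric(x))
  windowed_counts(list(`seq:+` = list(chrom = "seq", strand = "+",
                                      counts = x)),
                  window_size, c(seq = length(x) * window_size))
}
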