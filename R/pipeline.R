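.PIPELINE_STAGES <- c("simulate", "bin", "tune", "call", "polish",
                      "evaluate", "classify", "enhancers", "metagene")

.PIPELINE_KEYS <- c("stages", "seed", "preset", "chrom_lengths",
                    "window_size", "read_scale", "background_rate",
                    "uts", "lt_prob_b", "lt_values", "uts_values",
                    "max_iter", "tol", "edr_n", "reads_bed",
                    "annotations", "metagene_half_window", "metagene_bin")

#' Run the transcription-unit calling pipeline
#'
#' Wires the package's stages — simulate, bin, tune, call, polish,
#' evaluate, classify, enhancers, metagene — in dependency order from a
#' flat key-value configuration (a named list, or a path to a YAML file
#' with the same keys).  Every run writes its resolved configuration,
#' package version and seed to `manifest.yaml` in the output directory, so
#' a run is reproducible from its manifest alone.
#'
#' Recognised keys: `stages` (subset of the stage names; default all),
#' `seed`, `preset`, `chrom_lengths`, `window_size`, `read_scale`,
#' `background_rate`, `uts`, `lt_prob_b` (fixed-parameter call when `tune`
#' is not among the stages), `lt_values`/`uts_values` (tuning grids),
#' `max_iter`, `tol`, `edr_n`, `reads_bed`/`annotations` (external inputs
#' instead of simulation), `metagene_half_window`, `metagene_bin`.
#'
#' @param config Named list or YAML file path.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the principal in-memory artifacts
#'   (`truth`, `reads`, `counts`, `model`, `units`, `polished`, `report`,
#'   `tua`, `classified`, `enhancer_pairs`, `metagene`).
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("tu_run_")) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  bad <- setdiff(names(config), .PIPELINE_KEYS)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys are: ", paste(.PIPELINE_KEYS, collapse = ", "))
  }
  cfg <- utils::modifyList(list(
    stages = .PIPELINE_STAGES, seed = 1, preset = "human",
    chrom_lengths = c(chrSim = 1e7), window_size = 50, read_scale = 1,
    background_rate = 0.05, uts = 30, lt_prob_b = 350,
    lt_values = NULL, uts_values = NULL, max_iter = 50, tol = 1e-4,
    edr_n = 10, reads_bed = NULL, annotations = NULL,
    metagene_half_window = 4000, metagene_bin = 100), config)
  unknown_stage <- setdiff(cfg$stages, .PIPELINE_STAGES)
  if (length(unknown_stage)) {
    stop("unknown stage(s): ", paste(unknown_stage, collapse = ", "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  chrom_lengths <- unlist(cfg$chrom_lengths)

  art <- list()
  stage <- function(s) s %in% cfg$stages

  if (stage("simulate")) {
    spec <- genome_spec(preset = cfg$preset, chrom_lengths = chrom_lengths,
                        read_scale = cfg$read_scale,
                        background_rate = cfg$background_rate,
                        window_size = cfg$window_size, seed = cfg$seed)
    art$truth <- simulate_genome(spec)
    art$reads <- simulate_reads(art$truth)
    write_transcripts_bed(art$reads, file.path(outdir, "reads.bed"))
    g <- art$truth$genes; g$id <- g$symbol
    write_transcripts_bed(g, file.path(outdir, "truth_genes.bed"))
    write_transcripts_bed(art$truth$units, file.path(outdir,
                                                     "truth_units.bed"))
    art$annotations <- art$truth$genes
  } else {
    if (!is.null(cfg$reads_bed)) art$reads <- read_bed(cfg$reads_bed)
    if (!is.null(cfg$annotations)) {
      art$annotations <- read_annotations(cfg$annotations)
    }
  }

  if (stage("bin")) {
    if (is.null(art$reads)) {
      stop("stage 'bin' needs reads; run 'simulate' first or set reads_bed")
    }
    art$counts <- bin_reads(art$reads, cfg$window_size, chrom_lengths)
  }

  needs_ann <- function(s) {
    if (is.null(art$annotations)) {
      stop("stage '", s, "' needs annotations; run 'simulate' first or ",
           "set the annotations key")
    }
  }

  if (stage("tune")) {
    if (is.null(art$counts)) stop("stage 'tune' needs counts; run 'bin' first")
    needs_ann("tune")
    expressed <- expressed_subset(art$annotations, art$reads, cfg$edr_n)
    grid <- grid_search(art$counts,
                        lt_values = cfg$lt_values %||% tuning_grid()$lt,
                        uts_values = cfg$uts_values %||% tuning_grid()$uts,
                        expressed_annotations = expressed,
                        max_iter = cfg$max_iter, tol = cfg$tol)
    utils::write.table(as.data.frame(grid),
                       file.path(outdir, "grid.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sel <- select_optimal(grid, n_consensus = length(art$annotations))
    art$model <- sel$model
    art$units <- sel$units
  }

  if (stage("call") && is.null(art$model)) {
    if (is.null(art$counts)) stop("stage 'call' needs counts; run 'bin' first")
    art$model <- tu_hmm(art$counts, uts = cfg$uts,
                        lt_prob_b = cfg$lt_prob_b,
                        max_iter = cfg$max_iter, tol = cfg$tol)
  }
  if (stage("call") && is.null(art$units)) {
    art$units <- predict(art$model, art$counts)
  }
  if (!is.null(art$units)) {
    write_transcripts_bed(art$units, file.path(outdir, "calls.bed"))
    if (!is.null(art$model)) {
      writeLines(paste(names(coef(art$model)), coef(art$model), sep = "\t"),
                 file.path(outdir, "model_params.tsv"))
    }
  }

  if (stage("polish")) {
    if (is.null(art$units)) stop("stage 'polish' needs calls; run 'call' first")
    needs_ann("polish")
    art$polished <- polish_units(art$units, art$annotations,
                                 cfg$window_size)
    write_transcripts_bed(art$polished, file.path(outdir, "polished.bed"))
  }

  if (stage("evaluate")) {
    u <- art$polished %||% art$units
    if (is.null(u)) stop("stage 'evaluate' needs calls; run 'call' first")
    needs_ann("evaluate")
    expressed <- expressed_subset(art$annotations, art$reads, cfg$edr_n)
    art$report <- annotation_errors(u, expressed)
    art$tua <- tua(u, expressed)
    rep_df <- data.frame(
      n_units = art$report$n_units,
      median_unit_length = art$report$median_unit_length,
      n_merged = art$report$n_merged,
      n_dissociated = art$report$n_dissociated,
      n_eval = art$report$n_eval, rate = art$report$rate,
      tp_hat = art$tua$tp_hat, fp5_hat = art$tua$fp5_hat,
      tn5_hat = art$tua$tn5_hat, fn_hat = art$tua$fn_hat,
      post_tts_hat = art$tua$post_tts_hat, tua = art$tua$tua)
    utils::write.table(rep_df, file.path(outdir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (stage("enhancers") || stage("classify")) {
    u <- art$polished %||% art$units
    if (is.null(u)) stop("stage 'classify' needs calls; run 'call' first")
    art$enhancer_pairs <- detect_enhancer_pairs(u, art$annotations)
    utils::write.table(art$enhancer_pairs,
                       file.path(outdir, "enhancers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (stage("classify")) {
    u <- art$polished %||% art$units
    art$classified <- classify_units(u, coding = art$annotations,
                                     enhancer_pairs = art$enhancer_pairs)
    cls <- data.frame(chrom = as.character(seqnames(art$classified)),
                      start = start(art$classified) - 1L,
                      end = end(art$classified),
                      strand = as.character(strand(art$classified)),
                      category = as.character(art$classified$category))
    utils::write.table(cls, file.path(outdir, "classified.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (stage("metagene") && !is.null(art$enhancer_pairs) &&
      nrow(art$enhancer_pairs) > 0 && !is.null(art$reads)) {
    art$metagene <- metagene(art$reads, art$enhancer_pairs$center,
                             chrom = art$enhancer_pairs$chrom,
                             half_window = cfg$metagene_half_window,
                             bin = cfg$metagene_bin,
                             chrom_lengths = chrom_lengths)
    mg <- data.frame(offset = art$metagene$offset,
                     plus = art$metagene$profile_plus,
                     minus = art$metagene$profile_minus)
    utils::write.table(mg, file.path(outdir, "metagene.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- cfg
  manifest$chrom_lengths <- as.list(chrom_lengths)
  manifest$package_version <- as.character(packageVersion("nascentHMM"))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  art$outdir <- outdir
  invisible(art)
}
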