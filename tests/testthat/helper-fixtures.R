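suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# terse GRanges constructor for fixtures
gr <- function(chrom, start, end, strand = "+", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand, ...)
}

# Brute-force HMM oracle: enumerates every state path (0 = N, 1 = T).
# Independent of the package's recursions; only shares the emission
# density definition, which is checked against closed forms separately.
oracle_enumerate <- function(x, model) {
  L <- length(x)
  stopifnot(L <= 14)
  le <- cbind(dgamma(x, shape = model$uts, scale = 1 / model$uts,
                     log = TRUE),
              dgamma(x, shape = model$k_T, scale = model$theta_T,
                     log = TRUE))
  le[le < -1e12] <- -1e12
  # lt[from + 1, to + 1]
  lt <- matrix(c(log1p(-model$n_trans), -model$lt_prob_b,
                 log(model$n_trans), log1p(-exp(-model$lt_prob_b))),
               nrow = 2)
  li <- c(0, -1e12)  # starts in N
  paths <- as.matrix(expand.grid(rep(list(0:1), L)))
  n <- nrow(paths)
  em <- matrix(le[cbind(rep(seq_len(L), each = n), as.vector(paths) + 1)],
               n, L)
  lp <- li[paths[, 1] + 1] + rowSums(em)
  if (L > 1) {
    from <- paths[, -L, drop = FALSE]
    to <- paths[, -1, drop = FALSE]
    tr <- matrix(lt[cbind(as.vector(from) + 1, as.vector(to) + 1)],
                 n, L - 1)
    lp <- lp + rowSums(tr)
  }
  m <- max(lp)
  list(loglik = m + log(sum(exp(lp - m))),
       best_path = paths[which.max(lp), ],
       best_logp = m)
}

# a small fixed model with mild parameters for oracle comparisons
oracle_model <- function(uts = 2, k_T = 3, theta_T = 4, lt_prob_b = 3,
                         n_trans = 0.05) {
  tu_hmm_model(k_T = k_T, theta_T = theta_T, uts = uts,
               lt_prob_b = lt_prob_b, n_trans = n_trans, pseudocount = 0)
}

# random positive emission values (continuous, so Viterbi ties have
# probability zero)
random_emissions <- function(n, seed) {
  set.seed(seed)
  rgamma(n, shape = 1.5, scale = 3)
}

# one archetype unit per functional class, spaced far apart on one chromosome
archetype_fixture <- function() {
  coding <- c(gr("chr1", 100001, 120000, "+", symbol = "mRNA1"),
              gr("chr1", 300001, 330000, "-", symbol = "mRNA2"),
              gr("chr1", 500001, 530000, "+", symbol = "mRNA3"))
  ncrna <- gr("chr1", 700001, 700100, "+", symbol = "miR1")
  lncrna <- gr("chr1", 900001, 920000, "+", symbol = "linc1")
  repeats <- gr("chr1", 1100001, 1110000, "+", symbol = "LINE1")
  units <- c(
    gr("chr1", 100001, 125000, "+"),   # 80% coding overlap -> PROTEIN_CODING
    gr("chr1", 699001, 700050, "+"),   # touches the miRNA -> NONCODING_RNA
    gr("chr1", 900001, 915000, "+"),   # > 20% lncRNA      -> LNCRNA
    gr("chr1", 1300001, 1302000, "+"), # eRNA pair, plus    -> ENHANCER
    gr("chr1", 1301501, 1303500, "-"), # eRNA pair, minus   -> ENHANCER
    gr("chr1", 329601, 331000, "+"),   # promoter of mRNA2  -> DIVERGENT
    gr("chr1", 505001, 525000, "-"),   # antisense to mRNA3 -> ANTISENSE
    gr("chr1", 1100001, 1108000, "+"), # 100% repeat        -> REPEAT
    gr("chr1", 118001, 150000, "+"),   # 6% sense coding    -> OTHER_GENIC_SENSE
    gr("chr1", 118001, 150000, "-"),   # same, antisense    -> OTHER_GENIC_ANTISENSE
    gr("chr1", 1600001, 1605000, "+")  # nothing            -> INTERGENIC
  )
  list(units = units, coding = coding, ncrna = ncrna, lncrna = lncrna,
       repeats = repeats,
       expected = c("PROTEIN_CODING", "NONCODING_RNA", "LNCRNA", "ENHANCER",
                    "ENHANCER", "DIVERGENT", "ANTISENSE", "REPEAT",
                    "OTHER_GENIC_SENSE", "OTHER_GENIC_ANTISENSE",
                    "INTERGENIC"))
}

# tiny synthetic run shared by several tests
small_sim <- function(seed = 7, len = 2e6, preset = "human") {
  spec <- genome_spec(preset, chrom_lengths = c(chrSim = len), seed = seed)
  # small fixture genomes may not fit every default enhancer pair
  truth <- suppressWarnings(simulate_genome(spec))
  reads <- simulate_reads(truth)
  list(spec = spec, truth = truth, reads = reads,
       counts = bin_reads(reads, spec$window_size, spec$chrom_lengths))
}
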