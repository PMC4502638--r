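test_that("match_units picks the maximal-overlap unit per annotation", {
  genes <- gr("chr1", 1001, 2000, "+", symbol = "A")
  units <- c(gr("chr1", 1001, 1600, "+"),   # 60% overlap
             gr("chr1", 1701, 2000, "+"))   # 30% overlap
  mm <- match_units(units, genes)
  expect_equal(nrow(mm$pairs), 1)
  expect_equal(mm$pairs$unit, 1)
  expect_equal(mm$pairs$overlap, 600)
})

test_that("match_units respects strand and reports unmatched sets", {
  genes <- gr("chr1", 1001, 2000, "-", symbol = "A")
  units <- gr("chr1", 1001, 2000, "+")
  mm <- match_units(units, genes)
  expect_equal(nrow(mm$pairs), 0)
  expect_equal(mm$unmatched_annotations, 1L)
  expect_equal(mm$unmatched_units, 1L)
})

test_that("merged and dissociated errors are counted per definition", {
  genes <- c(gr("chr1", 1001, 2000, "+", symbol = "A"),
             gr("chr1", 3001, 4000, "+", symbol = "B"),
             gr("chr1", 6001, 7000, "+", symbol = "C"))
  # one unit spans A and B (merged); two units fragment C (dissociated)
  units <- c(gr("chr1", 901, 4100, "+"),
             gr("chr1", 6001, 6400, "+"), gr("chr1", 6601, 7000, "+"))
  er <- annotation_errors(units, genes)
  expect_equal(er$n_merged, 1L)
  expect_equal(er$n_dissociated, 1L)
  expect_equal(er$n_eval, 3L)
  expect_equal(er$rate, 2 / 3)
})

test_that("perfect one-to-one calls give zero error rate", {
  genes <- gr("chr1", seq(1, 90001, by = 10000), seq(5000, 95000, by = 10000),
              "+", symbol = LETTERS[1:10])
  er <- annotation_errors(granges(genes), genes)
  expect_equal(er$rate, 0)
})

test_that("overlapping annotations are rejected", {
  bad <- c(gr("chr1", 1, 100, "+", symbol = "A"),
           gr("chr1", 50, 150, "+", symbol = "B"))
  expect_error(annotation_errors(GRanges(), bad), "non-overlapping")
})

test_that("TUA closed form matches its defining ratio under the constraint", {
  set.seed(99)
  for (i in 1:200) {
    tp <- runif(1)
    fp <- runif(1)
    sc <- tua_score(tp, fp)
    # direct evaluation of (TP + 5'TN) / (TP + FN + 5'FP + 5'TN)
    direct <- (sc$tp_hat + sc$tn5_hat) /
      (sc$tp_hat + sc$fn_hat + sc$fp5_hat + sc$tn5_hat)
    if (sc$tp_hat > 0) expect_equal(sc$tua, direct, tolerance = 1e-12)
    expect_true(sc$tua >= 0 && sc$tua <= 1)
    expect_equal(sc$fn_hat, 1 - sc$tp_hat)
    expect_equal(sc$fp5_hat + sc$tn5_hat, sc$tp_hat)
  }
})

test_that("TUA is 1 for exact calls, 0 for none, 0.5 for gene+upstream", {
  genes <- gr("chr1", 5001, 10000, "+", symbol = "A")
  expect_equal(tua(granges(genes), genes)$tua, 1)
  expect_equal(tua(GRanges(), genes)$tua, 0)
  # unit covering the gene plus the entire scaled upstream region
  big <- gr("chr1", 1, 10000, "+")
  expect_equal(tua(big, genes)$tua, 0.5)
})

test_that("TUA is monotone in tp and fp5", {
  expect_true(tua_score(0.9, 0.2)$tua > tua_score(0.7, 0.2)$tua)
  expect_true(tua_score(0.9, 0.1)$tua > tua_score(0.9, 0.3)$tua)
})

test_that("transcript density is 1 on the body and 0 upstream for exact calls", {
  genes <- c(gr("chr1", 50001, 70000, "+", symbol = "A"),
             gr("chr1", 150001, 190000, "-", symbol = "B"))
  dens <- transcript_density(granges(genes), genes, n_bins = 5)
  expect_equal(dens$density[dens$region == "body"], rep(1, 5))
  expect_equal(dens$density[dens$region == "upstream"], rep(0, 5))
  # no calls -> all zero
  dens0 <- transcript_density(GRanges(), genes, n_bins = 5)
  expect_equal(dens0$density, rep(0, 15))
  # one of two genes called -> body density 0.5
  dens1 <- transcript_density(granges(genes[1]), genes, n_bins = 5)
  expect_equal(dens1$density[dens1$region == "body"], rep(0.5, 5))
})

test_that("genome coverage separates genic from intergenic windows", {
  sizes <- c(chr1 = 10000)
  genes <- gr("chr1", 1001, 2000, "+", symbol = "A")
  cov_exact <- genome_coverage(granges(genes), genes, 100, sizes)
  expect_equal(cov_exact$genic_fraction, 1)
  expect_equal(cov_exact$intergenic_fraction, 0)
  cov_none <- genome_coverage(GRanges(), genes, 100, sizes)
  expect_equal(cov_none$genic_fraction, 0)
  expect_equal(cov_none$intergenic_fraction, 0)
  # a 100-bp unit inside a 10-window gene covers exactly one genic window
  u <- gr("chr1", 1101, 1200, "+")
  cov1 <- genome_coverage(u, genes, 100, sizes)
  expect_equal(cov1$genic_fraction, 1 / 10)
})

test_that("error counting is invariant under unit reordering", {
  set.seed(17)
  genes <- gr("chr1", seq(1, 40001, 10000), seq(4000, 44000, 10000), "+",
              symbol = LETTERS[1:5])
  starts <- sample(seq(1, 43000, 500), 20)
  units <- gr("chr1", starts, starts + 799, "+")
  e1 <- annotation_errors(units, genes)
  e2 <- annotation_errors(units[sample(20)], genes)
  expect_equal(e1$n_merged, e2$n_merged)
  expect_equal(e1$n_dissociated, e2$n_dissociated)
})
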