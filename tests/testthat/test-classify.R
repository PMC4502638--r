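test_that("each archetype receives its class and the ten classes appear", {
  fx <- archetype_fixture()
  cls <- classify_units(fx$units, coding = fx$coding, ncrna = fx$ncrna,
                        lncrna = fx$lncrna, repeats = fx$repeats)
  expect_equal(as.character(cls$category), fx$expected)
  expect_setequal(as.character(unique(cls$category)),
                  TRANSCRIPT_CATEGORIES)
})

test_that("classification is a partition and order-independent", {
  fx <- archetype_fixture()
  for (rep in 1:5) {
    perm <- sample(length(fx$units))
    cls <- classify_units(fx$units[perm], coding = fx$coding,
                          ncrna = fx$ncrna, lncrna = fx$lncrna,
                          repeats = fx$repeats)
    expect_equal(sum(table(cls$category)), length(fx$units))
    expect_false(any(is.na(cls$category)))
  }
})

test_that("category counts sum to the unit count on random fixtures", {
  set.seed(404)
  fx <- archetype_fixture()
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    starts <- sample(seq(1, 1.6e6, 100), n)
    units <- gr("chr1", starts, starts + sample(200:20000, n, TRUE),
                sample(c("+", "-"), n, TRUE))
    cls <- classify_units(units, coding = fx$coding, ncrna = fx$ncrna,
                          lncrna = fx$lncrna, repeats = fx$repeats)
    expect_equal(sum(table(cls$category)), n)
  }
})

test_that("the 20% coding threshold is sharp", {
  coding <- gr("chr1", 100001, 200000, "+", symbol = "g")
  at25 <- gr("chr1", 97501, 102500, "+")     # 2500/5000 = 50% overlap
  cls <- classify_units(c(at25), coding = coding)
  expect_equal(as.character(cls$category), "PROTEIN_CODING")
  u <- gr("chr1", 90001, 101999, "+")        # 1999/12000 ~ 17% -> other genic
  cls2 <- classify_units(u, coding = coding)
  expect_equal(as.character(cls2$category), "OTHER_GENIC_SENSE")
})

test_that("divergent rule needs promoter overlap, opposite strand and size", {
  # 10-kb primary on minus strand, TSS at its end (110000)
  primary <- gr("chr1", 100001, 110000, "-", symbol = "g")
  # 2-kb plus-strand unit: 300 bp inside promoter [109500, 110500] -> 15%
  div <- gr("chr1", 110201, 112200, "+")
  cls <- classify_units(div, coding = primary)
  expect_equal(as.character(cls$category), "DIVERGENT")
  # same geometry but a unit longer than half the primary is not divergent
  big <- gr("chr1", 110201, 116300, "+")
  cls2 <- classify_units(big, coding = primary)
  expect_false(as.character(cls2$category) == "DIVERGENT")
})

test_that("enhancer pairs require overlap, shortness and 10-kb clearance", {
  genes <- gr("chr1", 500001, 540000, "+", symbol = "g")
  # overlapping short pair 100 kb from the gene
  p <- c(gr("chr1", 100001, 102000, "+"), gr("chr1", 101501, 103500, "-"))
  pairs <- detect_enhancer_pairs(p, genes)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$center, (101501 + 102000) / 2)
  # non-overlapping opposite-strand units pair with nothing
  apart <- c(gr("chr1", 100001, 102000, "+"), gr("chr1", 107001, 109000, "-"))
  expect_equal(nrow(detect_enhancer_pairs(apart, genes)), 0)
  # a pair 3 kb from the gene TSS fails the distance filter
  near <- c(gr("chr1", 495001, 497000, "+"), gr("chr1", 496501, 498500, "-"))
  expect_equal(nrow(detect_enhancer_pairs(near, genes)), 0)
  # units over the length cap are excluded
  long <- c(gr("chr1", 100001, 115000, "+"), gr("chr1", 114001, 116000, "-"))
  expect_equal(nrow(detect_enhancer_pairs(long, genes)), 0)
})

test_that("each unit joins at most one enhancer pair (greedy by overlap)", {
  units <- c(gr("chr1", 100001, 102000, "+"),
             gr("chr1", 101001, 103000, "-"),   # 1000 bp overlap with u1
             gr("chr1", 101801, 103800, "-"))   # 200 bp overlap with u1
  pairs <- detect_enhancer_pairs(units, GRanges())
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$minus_idx, 2)
})

test_that("swapping strand labels swaps pair members only", {
  units <- c(gr("chr1", 100001, 102000, "+"), gr("chr1", 101501, 103500, "-"))
  swapped <- GenomicRanges::invertStrand(units)
  p1 <- detect_enhancer_pairs(units, GRanges())
  p2 <- detect_enhancer_pairs(swapped, GRanges())
  expect_equal(p1$center, p2$center)
  expect_equal(p1$plus_start, p2$minus_start)
  expect_equal(p1$minus_end, p2$plus_end)
})

test_that("planted enhancer pairs are recovered on the synthetic genome", {
  sim <- small_sim(seed = 7, len = 2e6)
  fit <- tu_hmm(sim$counts, uts = 30, lt_prob_b = 350, max_iter = 20)
  units <- predict(fit, sim$counts)
  pairs <- detect_enhancer_pairs(units, sim$truth$genes)
  expect_equal(nrow(pairs), nrow(sim$truth$enhancer_pairs))
  expect_true(all(abs(sort(pairs$center) -
                        sort(sim$truth$enhancer_pairs$center)) < 200))
})

test_that("cell-type specificity uses the 20% reciprocal-overlap rule", {
  pair_at <- function(s) data.frame(
    chrom = "chr1", plus_idx = 1L, minus_idx = 2L,
    plus_start = s, plus_end = s + 1999,
    minus_start = s + 1500, minus_end = s + 3499,
    overlap = 500L, center = s + 1750)
  # identical pair in two cells -> both shared
  res <- cell_type_specificity(list(A = pair_at(1000), B = pair_at(1000)))
  expect_true(all(!res$specific))
  expect_equal(unique(res$cells_active), "A,B")
  # ~10% overlap -> both specific
  res2 <- cell_type_specificity(list(A = pair_at(1000), B = pair_at(4150)))
  expect_true(all(res2$specific))
  # pair present in one cell only -> specific
  res3 <- cell_type_specificity(list(A = pair_at(1000), B = pair_at(1e6)))
  expect_true(all(res3$specific))
  expect_error(cell_type_specificity(list(A = pair_at(1000))), ">= 2 cell")
})

test_that("metagene averages per-anchor profiles and skips edge anchors", {
  reads <- gr("chr1", c(5001, 5003, 5050), c(5030, 5032, 5079), "+")
  mg <- metagene(reads, centers = 5000, chrom = "chr1",
                 half_window = 400, bin = 100)
  expect_length(mg$profile_plus, 8)
  expect_equal(sum(mg$profile_plus), 3)    # all three reads in the window
  expect_equal(mg$profile_plus[5], 3)      # offsets [0,100)
  # identical local layouts at two anchors equal the single-anchor profile
  reads2 <- c(reads, GenomicRanges::shift(reads, 20000))
  mg2 <- metagene(reads2, centers = c(5000, 25000),
                  chrom = c("chr1", "chr1"), half_window = 400, bin = 100)
  expect_equal(mg2$profile_plus, mg$profile_plus)
  expect_warning(
    metagene(reads, centers = c(100, 5000), chrom = c("chr1", "chr1"),
             half_window = 400, bin = 100),
    "edge")
  expect_error(metagene(reads, centers = numeric(0), chrom = character(0)),
               "no anchor")
})
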