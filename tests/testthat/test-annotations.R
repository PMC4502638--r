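test_that("consensus of overlapping isoforms is the shared interval", {
  # 0-based [10,100) and [20,120) share [20,100) -> 1-based [21,100]
  iso <- gr("chr1", c(11, 21), c(100, 120), "+", symbol = c("A", "A"))
  cons <- build_consensus(iso)
  expect_length(cons, 1)
  expect_equal(start(cons), 21)
  expect_equal(end(cons), 100)
  expect_equal(cons$tss, 21)
})

test_that("single-isoform symbols pass through unchanged", {
  iso <- gr("chr1", 1, 50, "+", symbol = "B")
  cons <- build_consensus(iso)
  expect_equal(start(cons), 1)
  expect_equal(end(cons), 50)
})

test_that("cross-symbol overlap is trimmed 3' preserving both TSSs", {
  # A [0,100)+ TSS 0; B [80,200)+ TSS 80 -> A trimmed to [0,80)
  iso <- gr("chr1", c(1, 81), c(100, 200), "+", symbol = c("A", "B"))
  cons <- build_consensus(iso)
  a <- cons[cons$symbol == "A"]
  b <- cons[cons$symbol == "B"]
  expect_equal(end(a), 80)
  expect_equal(start(a), 1)
  expect_equal(c(start(b), end(b)), c(81, 200))
})

test_that("minus-strand trimming cuts the 3' (left) end of the upstream gene", {
  # A [100,200]- TSS 200; B [50,150]- TSS 150 -> A trimmed to [151,200]
  iso <- gr("chr1", c(100, 50), c(200, 150), "-", symbol = c("A", "B"))
  cons <- build_consensus(iso)
  a <- cons[cons$symbol == "A"]
  expect_equal(start(a), 151)
  expect_equal(a$tss, 200)
  b <- cons[cons$symbol == "B"]
  expect_equal(c(start(b), end(b)), c(50, 150))
})

test_that("strand-conflicting symbols are dropped with a warning", {
  iso <- gr("chr1", c(1, 1), c(50, 50), c("+", "-"), symbol = c("X", "X"))
  expect_warning(cons <- build_consensus(iso), "conflicting strands")
  expect_length(cons, 0)
})

test_that("consensus invariants hold on random isoform sets", {
  set.seed(2024)
  for (rep in 1:25) {
    n_sym <- sample(3:8, 1)
    isos <- list()
    for (s in seq_len(n_sym)) {
      k <- sample(1:4, 1)
      st <- sample(1:5000, 1)
      starts <- st + sample(0:300, k, replace = TRUE)
      widths <- sample(200:2000, k, replace = TRUE)
      isos[[s]] <- gr("chr1", starts, starts + widths,
                      sample(c("+", "-"), 1),
                      symbol = rep(sprintf("S%02d", s), k))
    }
    models <- suppressWarnings(do.call(c, isos))
    cons <- suppressWarnings(build_consensus(models))
    # non-overlapping per strand
    expect_length(GenomicRanges::findOverlaps(cons, drop.self = TRUE,
                                              drop.redundant = TRUE), 0)
    # every consensus TSS is the TSS of some input isoform of that symbol
    for (i in seq_along(cons)) {
      iso_i <- models[models$symbol == cons$symbol[i]]
      tss_in <- ifelse(as.character(strand(iso_i)) == "+", start(iso_i),
                       end(iso_i))
      expect_true(cons$tss[i] %in% tss_in)
    }
  }
})

test_that("EDR splits the body evenly and checks every segment", {
  g <- gr("chr1", 1, 1000, "+", symbol = "A")
  reads <- gr("chr1", c(51, 601), c(80, 630), "+")
  expect_true(edr(g, reads, 2)$satisfied)     # one read per half
  expect_false(edr(g, reads, 10)$satisfied)   # 8 empty segments
  expect_false(edr(g, GRanges(), 1)$satisfied)
  expect_error(edr(g, reads, 2000), "exceeds the length")
})

test_that("EDR respects the strand and uses 5' read positions", {
  g <- gr("chr1", 1, 1000, "-", symbol = "A")
  # minus read with 5' end (= end coordinate) at 400
  r_minus <- gr("chr1", 371, 400, "-")
  r_plus <- gr("chr1", 601, 630, "+")
  expect_true(edr(g, c(r_minus), 1)$satisfied)
  expect_false(edr(g, c(r_plus), 1)$satisfied)   # wrong strand
})

test_that("EDR is monotone over divisor segment counts", {
  set.seed(31)
  g <- gr("chr1", 1, 1200, "+", symbol = "A")
  pos <- sample(1:1170, 40)
  reads <- gr("chr1", pos, pos + 29, "+")
  for (n in c(12, 6, 4, 3, 2, 1)) {
    if (edr(g, reads, 12)$satisfied) {
      expect_true(edr(g, reads, n)$satisfied)
    }
  }
})

test_that("expressed_subset filters by EDR and preserves order", {
  anns <- c(gr("chr1", 1, 1000, "+", symbol = "A"),
            gr("chr1", 2001, 3000, "+", symbol = "B"))
  reads <- gr("chr1", 101, 130, "+")
  kept <- expressed_subset(anns, reads, n = 1)
  expect_equal(kept$symbol, "A")
  expect_true(all(kept$symbol %in% anns$symbol))
})
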