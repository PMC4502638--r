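test_that("emission log-densities match closed-form gamma pdfs", {
  # uts = 1 makes the background Exp(1): log f(1) = -1
  m <- tu_hmm_model(k_T = 1, theta_T = 2, uts = 1, lt_prob_b = 10,
                    n_trans = 0.1)
  expect_equal(emission_logdensity(1, "N", m), -1)
  # Gamma(1, 2) at x = 2: 0.5 * exp(-1)
  expect_equal(emission_logdensity(2, "T", m), -1 - log(2))
  expect_error(emission_logdensity(0, "N", m), "positive")
})

test_that("emission densities integrate to one", {
  m <- oracle_model()
  for (st in c("N", "T")) {
    z <- integrate(function(x) exp(emission_logdensity(x, st, m)),
                   0, Inf)$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
})

test_that("forward log-likelihood equals the brute-force path sum", {
  m <- oracle_model()
  for (seed in 1:5) {
    x <- random_emissions(10, seed)
    fb <- forward_backward(x, m)
    oracle <- oracle_enumerate(x, m)
    expect_equal(fb$log_likelihood, oracle$loglik, tolerance = 1e-10)
    post <- fb$posterior[[1]]
    expect_true(all(post >= 0 & post <= 1))
  }
})

test_that("posteriors are near zero for background-only data", {
  # all-zero counts -> emission value = pseudocount = 1, the background mean
  m <- tu_hmm_model(k_T = 5, theta_T = 4, uts = 10, lt_prob_b = 10,
                    n_trans = 0.01, pseudocount = 1)
  fb <- forward_backward(rep(0, 50), m)
  expect_true(all(fb$posterior[[1]] < 0.5))
})

test_that("Viterbi matches exhaustive enumeration on short sequences", {
  m <- oracle_model()
  for (seed in 1:5) {
    x <- random_emissions(12, seed + 100)
    vit <- viterbi(x, m)[[1]]
    oracle <- oracle_enumerate(x, m)
    expect_equal(as.integer(vit$states == "T"),
                 unname(oracle$best_path))
    expect_equal(vit$log_joint, oracle$best_logp, tolerance = 1e-10)
  }
})

test_that("Viterbi calls an all-background path on zero counts", {
  m <- tu_hmm_model(k_T = 5, theta_T = 4, uts = 10, lt_prob_b = 10,
                    n_trans = 0.01, pseudocount = 1)
  vit <- viterbi(rep(0, 40), m)[[1]]
  expect_true(all(vit$states == "N"))
})

test_that("a high-count block flanked by zeros becomes one contiguous unit", {
  m <- tu_hmm_model(k_T = 2, theta_T = 5, uts = 10, lt_prob_b = 10,
                    n_trans = 0.01, pseudocount = 1)
  x <- c(rep(0, 20), rep(12, 15), rep(0, 20))
  vit <- viterbi(x, m)[[1]]
  r <- rle(vit$states)
  expect_equal(sum(r$values == "T"), 1)   # exactly one transcribed run
  expect_true(all(which(vit$states == "T") %in% 21:35))
})

test_that("path_to_units maps runs to window-quantised intervals", {
  u <- path_to_units(c("N", "N", "T", "T", "T", "N", "N"), "chr1", "+", 50)
  expect_length(u, 1)
  expect_equal(start(u), 101)   # 0-based [100, 250)
  expect_equal(end(u), 250)
  expect_length(path_to_units(rep("N", 5), "chr1", "+", 50), 0)
  u2 <- path_to_units(c("T", "N", "T"), "chr1", "-", 50)
  expect_length(u2, 2)
})

test_that("minus-strand decoding is mapped back to genomic orientation", {
  m <- tu_hmm_model(k_T = 2, theta_T = 5, uts = 10, lt_prob_b = 10,
                    n_trans = 0.01, pseudocount = 1)
  x <- c(rep(0, 10), rep(12, 5), rep(0, 25))
  wc <- windowed_counts(list(`c:-` = list(chrom = "c", strand = "-",
                                          counts = x)),
                        50, c(c = 2000))
  vit <- viterbi(wc, m)[[1]]
  expect_equal(which(vit$states == "T"), 11:15)
})

test_that("EM trains only k_T, theta_T and n_trans; LL is monotone", {
  set.seed(11)
  x <- c(rpois(400, 0.1), rpois(80, 8), rpois(300, 0.1), rpois(50, 8))
  fit <- tu_hmm(x, uts = 12, lt_prob_b = 30, max_iter = 50, tol = 0)
  expect_identical(fit$uts, 12)
  expect_identical(fit$lt_prob_b, 30)
  expect_true(all(diff(fit$ll_trace) >= -1e-6))
})

test_that("max_iter = 0 returns the initial model unchanged", {
  init <- tu_hmm_model(k_T = 3, theta_T = 2, uts = 10, lt_prob_b = 50,
                       n_trans = 0.005)
  fit <- tu_hmm(rpois(100, 1), uts = 10, lt_prob_b = 50, max_iter = 0,
                init = init)
  expect_equal(fit$k_T, 3)
  expect_equal(fit$theta_T, 2)
  expect_equal(fit$n_trans, 0.005)
  expect_length(fit$ll_trace, 0)
})

test_that("EM recovers parameters of the generating model", {
  gen <- tu_hmm_model(k_T = 2, theta_T = 5, uts = 20, lt_prob_b = 4,
                      n_trans = 0.01, pseudocount = 0)
  sim <- simulate(gen, nsim = 1, seed = 99, n_windows = 1e5)[[1]]
  fit <- tu_hmm(sim$values, uts = 20, lt_prob_b = 4, pseudocount = 0,
                max_iter = 60)
  expect_lt(abs(fit$k_T * fit$theta_T - 10) / 10, 0.10)
  expect_lt(abs(fit$n_trans - 0.01) / 0.01, 0.20)
})

test_that("stronger length penalty never shrinks any called unit", {
  sim <- small_sim(seed = 5, len = 5e5)
  fit <- tu_hmm(sim$counts, uts = 30, lt_prob_b = 200, max_iter = 20)
  calls <- lapply(c(50, 275, 500), function(v) {
    m <- tu_hmm_model(fit$k_T, fit$theta_T, fit$uts, v, fit$n_trans,
                      fit$pseudocount)
    vt <- viterbi(sim$counts, m)
    do.call(c, unname(lapply(vt, function(x)
      path_to_units(x$states, x$chrom, x$strand, 50))))
  })
  for (i in 1:2) {
    hits <- GenomicRanges::findOverlaps(calls[[i]], calls[[i + 1]],
                                        type = "within")
    expect_equal(length(unique(S4Vectors::queryHits(hits))),
                 length(calls[[i]]))
  }
})

test_that("strand processing order does not change the calls", {
  sim <- small_sim(seed = 13, len = 5e5)
  wc <- sim$counts
  wc_rev <- windowed_counts(rev(wc$tracks), wc$window_size,
                            wc$chrom_lengths)
  fit <- tu_hmm(wc, uts = 30, lt_prob_b = 350, max_iter = 10)
  u1 <- predict(fit, wc)
  u2 <- predict(fit, wc_rev)
  expect_equal(granges(u1), granges(u2))
})
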