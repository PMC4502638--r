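#' Construct a two-state transcription-unit HMM parameter set
#'
#' The model has a non-transcribed state N and a transcribed state T over
#' windowed read counts.  Emissions are gamma densities evaluated on
#' `count + pseudocount`:
#' * N emits from the constrained gamma `Gamma(shape = uts, scale = 1/uts)`,
#'   whose mean is exactly 1 — the background level of pseudocounted
#'   GRO-seq windows.  `uts` is the first held-out tuning parameter.
#' * T emits from `Gamma(shape = k_T, scale = theta_T)`, trained by EM.
#'
#' Transitions: `P(T -> N) = exp(-lt_prob_b)` (natural log scale;
#' `lt_prob_b` is the second held-out tuning parameter and acts as a length
#' penalty on called units), `P(N -> T) = n_trans` (trained).
#' Self-transitions are the complements.  Each track starts in N.
#'
#' @param k_T,theta_T Shape and scale of the transcribed-state gamma (> 0).
#' @param uts Shape of the constrained background gamma (> 0); its scale is
#'   `1/uts` so the background mean is pinned at 1.
#' @param lt_prob_b Positive number `v` with `log P(T -> N) = -v`.
#' @param n_trans Transition probability N -> T, in (0, 1).
#' @param pseudocount Added to every window count before emission
#'   evaluation (default 1).
#' @return An object of class `tuhmm_model`.
#' @export
tu_hmm_model <- function(k_T, theta_T, uts, lt_prob_b, n_trans,
                         pseudocount = 1) {
  stopifnot(k_T > 0, theta_T > 0, uts > 0, lt_prob_b > 0,
            n_trans > 0, n_trans < 1, pseudocount >= 0)
  structure(list(k_T = k_T, theta_T = theta_T, uts = uts,
                 lt_prob_b = lt_prob_b, n_trans = n_trans,
                 pseudocount = pseudocount),
            class = "tuhmm_model")
}

#' Gamma emission log-density of one HMM state
#'
#' @param x Emission value(s), strictly positive (window count plus
#'   pseudocount).
#' @param state `"N"`/`"nontranscribed"` or `"T"`/`"transcribed"`.
#' @param model A `tuhmm_model` (or fitted `tuhmm`).
#' @return Log-density values, floored at the package's numerical floor.
#' @export
emission_logdensity <- function(x, state, model) {
  if (any(x <= 0)) stop("emission values must be positive")
  state <- toupper(substr(state, 1, 1))
  ld <- switch(state,
    N = dgamma(x, shape = model$uts, scale = 1 / model$uts, log = TRUE),
    T = dgamma(x, shape = model$k_T, scale = model$theta_T, log = TRUE),
    stop("state must be 'N' or 'T'"))
  ld[!is.finite(ld) | ld < .LOG_FLOOR] <- .LOG_FLOOR
  ld
}

# log transition parameters of a model
.log_trans <- function(model) {
  v <- model$lt_prob_b
  list(lnn = log1p(-model$n_trans), lnt = log(model$n_trans),
       ltn = -v, ltt = log1p(-exp(-v)),
       li0 = 0, li1 = .LOG_FLOOR)
}

# emission matrix for one track; minus-strand tracks are reversed so every
# sequence is scanned 5' -> 3' (the asymmetric T->N penalty is orientation-
# dependent); results must be mapped back by the caller.
.track_values <- function(track, model) {
  x <- track$counts + model$pseudocount
  if (track$strand == "-") x <- rev(x)
  x
}

.track_emissions <- function(x, model) {
  list(le0 = emission_logdensity(x, "N", model),
       le1 = emission_logdensity(x, "T", model))
}

#' Forward-backward pass of the transcription HMM
#'
#' Computes, in log space, the total log-likelihood of the windowed counts
#' under the model and the per-window posterior probability of the
#' transcribed state.
#'
#' @param counts A `windowed_counts` object (or a bare numeric vector,
#'   treated as a single plus-strand track).
#' @param model A `tuhmm_model` or fitted `tuhmm`.
#' @return List with `log_likelihood` (sum over tracks) and `posterior`
#'   (named list of per-window P(transcribed) vectors, in genomic
#'   orientation).
#' @export
forward_backward <- function(counts, model) {
  counts <- .as_windowed_counts(counts)
  if (length(counts$tracks) == 0L) stop("no count tracks")
  post <- list()
  ll <- 0
  lt <- .log_trans(model)
  for (nm in names(counts$tracks)) {
    tr <- counts$tracks[[nm]]
    if (length(tr$counts) == 0L) stop("empty counts in track ", nm)
    x <- .track_values(tr, model)
    em <- .track_emissions(x, model)
    fb <- .fb2_cpp(em$le0, em$le1, lt$lnn, lt$lnt, lt$ltn, lt$ltt,
                   lt$li0, lt$li1)
    p <- fb$post1
    if (tr$strand == "-") p <- rev(p)
    post[[nm]] <- p
    ll <- ll + fb$loglik
  }
  list(log_likelihood = ll, posterior = post)
}

#' Viterbi decoding to a maximum-probability state path
#'
#' @inheritParams forward_backward
#' @return Named list of per-track results, each with `states` (character
#'   vector of `"N"`/`"T"` in genomic orientation) and `log_joint` (log
#'   probability of the path jointly with the observations).  Ties are
#'   broken towards the non-transcribed state.
#' @export
viterbi <- function(counts, model) {
  counts <- .as_windowed_counts(counts)
  lt <- .log_trans(model)
  out <- list()
  for (nm in names(counts$tracks)) {
    tr <- counts$tracks[[nm]]
    if (length(tr$counts) == 0L) stop("empty counts in track ", nm)
    x <- .track_values(tr, model)
    em <- .track_emissions(x, model)
    vt <- .viterbi2_cpp(em$le0, em$le1, lt$lnn, lt$lnt, lt$ltn, lt$ltt,
                        lt$li0, lt$li1)
    st <- c("N", "T")[vt$path + 1L]
    if (tr$strand == "-") st <- rev(st)
    out[[nm]] <- list(states = st, log_joint = vt$log_joint,
                      chrom = tr$chrom, strand = tr$strand)
  }
  out
}

#' Convert a decoded state path to transcription units
#'
#' Each maximal run of transcribed windows becomes one stranded unit whose
#' coordinates are the run boundaries times the window size (the last unit
#' is clipped to the chromosome length).
#'
#' @param states Character vector of `"N"`/`"T"` in genomic orientation.
#' @param chrom,strand Chromosome and strand of the track.
#' @param window_size Window width in bp.
#' @param chrom_length Optional chromosome length for end clipping.
#' @return A `GRanges` of disjoint units.
#' @export
path_to_units <- function(states, chrom, strand, window_size,
                          chrom_length = NULL) {
  r <- rle(states == "T")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) {
    return(GenomicRanges::GRanges(seqnames = character(),
                                  ranges = IRanges::IRanges(),
                                  strand = character()))
  }
  w0 <- (starts[keep] - 1L) * window_size     # 0-based unit starts
  w1 <- ends[keep] * window_size              # 0-based exclusive ends
  if (!is.null(chrom_length)) w1 <- pmin(w1, chrom_length)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(w0 + 1, w1), strand = strand)
}

# ---- fitting -------------------------------------------------------------

# weighted gamma MLE: maximise sum w_i log dgamma(x_i; k, k*theta = mean).
# Newton iteration on the shape via digamma/trigamma; exact M-step, so the
# EM ascent guarantee holds.
.gamma_wmle <- function(sw, swx, swlx, k_prev) {
  m1 <- swx / sw
  s <- log(m1) - swlx / sw
  if (!is.finite(s) || s < 1e-10) {
    warning("degenerate emission data in M-step (near-constant values); ",
            "keeping previous shape")
    return(list(k = k_prev, theta = m1 / k_prev))
  }
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    step <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    k_new <- k - step
    if (!is.finite(k_new) || k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * k) { k <- k_new; break }
    k <- k_new
  }
  list(k = k, theta = m1 / k)
}

# moment-based initialisation from high-count windows
.init_model <- function(x_all, uts, lt_prob_b, pseudocount) {
  thr <- quantile(x_all, 0.75)
  xs <- x_all[x_all > thr]
  if (length(xs) < 10) xs <- tail(sort(x_all), 10)
  m <- mean(xs)
  v <- var(xs)
  if (!is.finite(v) || v <= 0) v <- m^2
  k_T <- max(m^2 / v, 1e-3)
  theta_T <- m / k_T
  tu_hmm_model(k_T, theta_T, uts, lt_prob_b, n_trans = 1e-3,
               pseudocount = pseudocount)
}

#' Fit the two-state transcription-unit HMM
#'
#' Trains the transcribed-state gamma `(k_T, theta_T)` and the
#' N-to-T transition probability by Baum-Welch EM, holding the two tuning
#' parameters — `uts` (background gamma shape) and `lt_prob_b` (length
#' penalty) — fixed throughout.  The M-step uses the exact
#' posterior-weighted gamma maximum-likelihood update (Newton on the shape),
#' so the log-likelihood is non-decreasing across iterations.
#'
#' @param counts A `windowed_counts` object from [bin_reads()], or a bare
#'   numeric count vector.
#' @param uts Background tuning parameter \eqn{\sigma^2}: shape of the
#'   constrained non-transcribed gamma `Gamma(uts, 1/uts)` (mean fixed
#'   at 1).  Default 30, the optimum reported for human GRO-seq data.
#' @param lt_prob_b Length-penalty tuning parameter: `log P(T -> N) =
#'   -lt_prob_b` (natural log).  Default 350, the reported human optimum.
#' @param pseudocount Added to every window count before emission
#'   evaluation; default 1, which pins the background mean at about 1.
#' @param max_iter Maximum EM iterations; `0` returns the initial model
#'   unchanged (no training).
#' @param tol Stop when the log-likelihood improvement falls below `tol`.
#' @param init Optional `tuhmm_model` to start from; otherwise moments of
#'   the upper-quartile windows initialise the transcribed gamma.
#' @param verbose Print per-iteration log-likelihood.
#' @return An object of class `tuhmm` with components `k_T`, `theta_T`,
#'   `uts`, `lt_prob_b`, `n_trans`, `pseudocount`, `log_likelihood`,
#'   `ll_trace`, `n_iter`, `converged`, `window_size` and the call.
#' @seealso [predict.tuhmm()] to decode transcription units,
#'   [simulate.tuhmm()] to draw data from the fitted model.
#' @examples
#' set.seed(1)
#' x <- c(rpois(200, 0.2), rpois(60, 12), rpois(200, 0.2))
#' fit <- tu_hmm(x, uts = 10, lt_prob_b = 20, max_iter = 20)
#' fit
#' predict(fit, x)
#' @export
tu_hmm <- function(counts, uts = 30, lt_prob_b = 350, pseudocount = 1,
                   max_iter = 100, tol = 1e-4, init = NULL,
                   verbose = FALSE) {
  wc <- .as_windowed_counts(counts)
  if (length(wc$tracks) == 0L) stop("no count tracks")
  stopifnot(uts > 0, lt_prob_b > 0, max_iter >= 0, tol >= 0)

  x_by_track <- lapply(wc$tracks, .track_values,
                       model = list(pseudocount = pseudocount))
  x_all <- unlist(x_by_track, use.names = FALSE)
  if (any(x_all <= 0)) {
    stop("all emission values (count + pseudocount) must be positive; ",
         "use pseudocount >= 1 with raw counts")
  }

  model <- if (is.null(init)) {
    .init_model(x_all, uts, lt_prob_b, pseudocount)
  } else {
    tu_hmm_model(init$k_T, init$theta_T, uts, lt_prob_b, init$n_trans,
                 pseudocount)
  }

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  if (max_iter > 0) {
    lt <- .log_trans(model)
    repeat {
      iter <- iter + 1L
      sw <- swx <- swlx <- 0
      exp_nt <- exp_n <- 0
      ll <- 0
      for (x in x_by_track) {
        em <- .track_emissions(x, model)
        fb <- .fb2_cpp(em$le0, em$le1, lt$lnn, lt$lnt, lt$ltn, lt$ltt,
                       lt$li0, lt$li1)
        w <- fb$post1
        sw <- sw + sum(w)
        swx <- swx + sum(w * x)
        swlx <- swlx + sum(w * log(x))
        exp_nt <- exp_nt + fb$exp_nt
        exp_n <- exp_n + fb$exp_n
        ll <- ll + fb$loglik
      }
      ll_trace <- c(ll_trace, ll)
      if (verbose) message(sprintf("EM iter %3d  logLik %.4f", iter, ll))
      if (iter > 1 && !is.finite(ll)) {
        stop("non-finite log-likelihood at EM iteration ", iter)
      }
      if (iter > 1 && abs(ll - ll_trace[iter - 1L]) < tol) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      # M-step (exact): transcribed gamma by weighted MLE, N->T by expected
      # transition frequency; uts and lt_prob_b stay fixed.
      if (sw <= 0) stop("NaN/zero posterior mass in M-step at iteration ", iter)
      g <- .gamma_wmle(sw, swx, swlx, model$k_T)
      n_new <- exp_nt / max(exp_n, .Machine$double.eps)
      n_new <- min(max(n_new, 1e-12), 1 - 1e-12)
      if (!is.finite(g$k) || !is.finite(g$theta) || !is.finite(n_new)) {
        stop("NaN in M-step at iteration ", iter)
      }
      model <- tu_hmm_model(g$k, g$theta, uts, lt_prob_b, n_new, pseudocount)
      lt <- .log_trans(model)
    }
  }

  structure(list(k_T = model$k_T, theta_T = model$theta_T, uts = uts,
                 lt_prob_b = lt_prob_b, n_trans = model$n_trans,
                 pseudocount = pseudocount,
                 log_likelihood = if (length(ll_trace)) tail(ll_trace, 1)
                                  else NA_real_,
                 ll_trace = ll_trace, n_iter = iter, converged = converged,
                 window_size = wc$window_size, call = match.call()),
            class = c("tuhmm", "tuhmm_model"))
}
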