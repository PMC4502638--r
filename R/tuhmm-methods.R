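#' @export
print.tuhmm <- function(x, digits = 4, ...) {
  cat("Two-state transcription-unit HMM\n")
  cat(sprintf("  transcribed emission : Gamma(shape = %.*g, scale = %.*g)  mean %.*g\n",
              digits, x$k_T, digits, x$theta_T, digits, x$k_T * x$theta_T))
  cat(sprintf("  background emission  : Gamma(shape = %.*g, scale = 1/%.*g)  mean 1\n",
              digits, x$uts, digits, x$uts))
  cat(sprintf("  P(N -> T) = %.*g ;  log P(T -> N) = -%g\n",
              digits, x$n_trans, x$lt_prob_b))
  if (length(x$ll_trace)) {
    cat(sprintf("  EM: %d iteration(s), logLik %.4f, %s\n", x$n_iter,
                x$log_likelihood,
                if (x$converged) "converged" else "not converged"))
  } else {
    cat("  untrained (max_iter = 0)\n")
  }
  invisible(x)
}

#' @export
print.tuhmm_model <- function(x, digits = 4, ...) {
  if (inherits(x, "tuhmm")) return(NextMethod())
  cat("Transcription-unit HMM parameters\n")
  cat(sprintf("  k_T = %.*g, theta_T = %.*g, uts = %.*g, lt_prob_b = %g, n_trans = %.*g\n",
              digits, x$k_T, digits, x$theta_T, digits, x$uts,
              x$lt_prob_b, digits, x$n_trans))
  invisible(x)
}

#' @export
summary.tuhmm <- function(object, ...) {
  out <- list(coefficients = coef(object),
              log_likelihood = object$log_likelihood,
              n_iter = object$n_iter, converged = object$converged,
              transcribed_mean = object$k_T * object$theta_T,
              ll_trace = object$ll_trace)
  class(out) <- "summary.tuhmm"
  out
}

#' @export
print.summary.tuhmm <- function(x, ...) {
  cat("Fitted transcription-unit HMM\n\nCoefficients:\n")
  print(x$coefficients)
  cat(sprintf("\nTranscribed-state mean emission: %.4g\n", x$transcribed_mean))
  cat(sprintf("Log-likelihood %.4f after %d EM iteration(s) (%s)\n",
              x$log_likelihood, x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @export
coef.tuhmm <- function(object, ...) {
  c(k_T = object$k_T, theta_T = object$theta_T, n_trans = object$n_trans,
    uts = object$uts, lt_prob_b = object$lt_prob_b)
}

#' @export
logLik.tuhmm <- function(object, ...) {
  structure(object$log_likelihood, df = 3, class = "logLik")
}

#' Decode transcription units (or states) from a fitted HMM
#'
#' Runs Viterbi decoding of `counts` under the fitted model and, for
#' `type = "units"`, converts maximal transcribed runs into stranded
#' `GRanges` intervals with stable ids.
#'
#' @param object A fitted `tuhmm`.
#' @param counts A `windowed_counts` object or numeric vector.
#' @param type `"units"` (default), `"states"` (per-track N/T vectors) or
#'   `"posterior"` (per-track P(transcribed)).
#' @param ... Unused.
#' @return A `GRanges` of disjoint units per strand, or a named list.
#' @export
predict.tuhmm <- function(object, counts,
                          type = c("units", "states", "posterior"), ...) {
  type <- match.arg(type)
  wc <- .as_windowed_counts(counts, window_size = object$window_size %||% 50)
  if (type == "posterior") {
    return(forward_backward(wc, object)$posterior)
  }
  vit <- viterbi(wc, object)
  if (type == "states") {
    return(lapply(vit, `[[`, "states"))
  }
  grl <- lapply(names(vit), function(nm) {
    v <- vit[[nm]]
    path_to_units(v$states, v$chrom, v$strand, wc$window_size,
                  chrom_length = wc$chrom_lengths[[v$chrom]])
  })
  units <- do.call(c, grl)
  units <- GenomicRanges::sort(units, ignore.strand = TRUE)
  if (length(units)) units$id <- sprintf("tu_%05d", seq_along(units))
  units
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate state paths and emission values from the HMM
#'
#' Draws hidden state sequences from the model's Markov chain (starting in
#' the non-transcribed state) and emission values from the corresponding
#' gamma distributions.  The simulated values are emission-scale values
#' (i.e. already include the pseudocount offset); refit them with
#' `tu_hmm(values, pseudocount = 0, ...)`.
#'
#' @param object A `tuhmm` or `tuhmm_model`.
#' @param nsim Number of independent sequences.
#' @param seed Optional integer seed.
#' @param n_windows Length of each simulated sequence.
#' @param ... Unused.
#' @return A list of `nsim` elements, each with `states` ("N"/"T") and
#'   `values` (positive emission values).
#' @export
simulate.tuhmm_model <- function(object, nsim = 1, seed = NULL,
                                 n_windows = 1000, ...) {
  if (!is.null(seed)) set.seed(seed)
  p_tn <- exp(-object$lt_prob_b)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    st <- integer(n_windows)
    u <- runif(n_windows)
    st[1] <- 0L
    for (t in 2:n_windows) {
      st[t] <- if (st[t - 1] == 0L) as.integer(u[t] < object$n_trans)
               else as.integer(u[t] >= p_tn)
    }
    vals <- numeric(n_windows)
    nN <- sum(st == 0L)
    vals[st == 0L] <- rgamma(nN, shape = object$uts, scale = 1 / object$uts)
    vals[st == 1L] <- rgamma(n_windows - nN, shape = object$k_T,
                             scale = object$theta_T)
    out[[i]] <- list(states = c("N", "T")[st + 1L], values = vals)
  }
  out
}

#' @rdname simulate.tuhmm_model
#' @export
simulate.tuhmm <- simulate.tuhmm_model

#' Plot a fitted transcription-unit HMM
#'
#' Left panel: the two gamma emission densities (background vs transcribed).
#' Right panel: the EM log-likelihood trace, when the model was trained.
#'
#' @param x A fitted `tuhmm`.
#' @param xmax Upper emission value for the density panel (default: the
#'   transcribed mean plus four standard deviations).
#' @param ... Passed to `plot()`.
#' @return Invisibly, `x`.
#' @export
plot.tuhmm <- function(x, xmax = NULL, ...) {
  trained <- length(x$ll_trace) > 1
  if (trained) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (is.null(xmax)) {
    xmax <- x$k_T * x$theta_T + 4 * sqrt(x$k_T) * x$theta_T
  }
  xs <- seq(1e-3, xmax, length.out = 400)
  dN <- dgamma(xs, shape = x$uts, scale = 1 / x$uts)
  dT <- dgamma(xs, shape = x$k_T, scale = x$theta_T)
  graphics::plot(xs, dN, type = "l", col = "grey40", lwd = 2,
                 xlab = "emission value (count + pseudocount)",
                 ylab = "density", main = "Emission densities", ...)
  graphics::lines(xs, dT, col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = c("non-transcribed", "transcribed"),
                   col = c("grey40", "firebrick"), lwd = 2, bty = "n")
  if (trained) {
    graphics::plot(seq_along(x$ll_trace), x$ll_trace, type = "b", pch = 16,
                   xlab = "EM iteration", ylab = "log-likelihood",
                   main = "EM trace")
  }
  invisible(x)
}
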