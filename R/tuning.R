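#' Grid search over the two held-out tuning parameters
#'
#' For every combination of `lt_values` (length penalty, `-log P(T -> N)`)
#' and `uts_values` (background gamma shape), trains the HMM on `counts`,
#' decodes transcription units, and scores them against the expressed
#' annotations with [annotation_errors()].  Failures at individual grid
#' points are recorded, not fatal.
#'
#' @param counts A `windowed_counts` object.
#' @param lt_values Numeric vector of `lt_prob_b` values (default: ten
#'   evenly spaced values over 50..500, the mammalian range; use
#'   `tuning_grid("nonmammalian")` for gene-dense genomes, which need a
#'   larger length penalty).
#' @param uts_values Numeric vector of `uts` values (default: ten evenly
#'   spaced values over 5..50).
#' @param expressed_annotations Non-overlapping expressed annotations used
#'   for scoring.
#' @param ... Further arguments to [tu_hmm()] (e.g. `max_iter`, `tol`).
#' @return An object of class `tu_grid`: a data.frame with one row per grid
#'   point (`lt_prob_b`, `uts`, `n_units`, `median_unit_length`, `n_merged`,
#'   `n_dissociated`, `rate`, `ok`) and attributes `models` and `units`
#'   (lists parallel to the rows).
#' @export
grid_search <- function(counts, lt_values = tuning_grid()$lt,
                        uts_values = tuning_grid()$uts,
                        expressed_annotations, ...) {
  stopifnot(length(lt_values) > 0, length(uts_values) > 0)
  combos <- expand.grid(lt_prob_b = lt_values, uts = uts_values,
                        KEEP.OUT.ATTRS = FALSE)
  n <- nrow(combos)
  models <- vector("list", n)
  units_list <- vector("list", n)
  res <- data.frame(combos,
                    n_units = NA_integer_,
                    median_unit_length = NA_real_,
                    n_merged = NA_integer_, n_dissociated = NA_integer_,
                    rate = NA_real_, ok = FALSE)
  for (i in seq_len(n)) {
    out <- tryCatch({
      fit <- tu_hmm(counts, uts = combos$uts[i],
                    lt_prob_b = combos$lt_prob_b[i], ...)
      units <- predict(fit, counts)
      er <- annotation_errors(units, expressed_annotations)
      list(fit = fit, units = units, er = er)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      warning("grid point (lt_prob_b = ", combos$lt_prob_b[i], ", uts = ",
              combos$uts[i], ") failed: ", conditionMessage(out))
      next
    }
    models[[i]] <- out$fit
    units_list[[i]] <- out$units
    res$n_units[i] <- out$er$n_units
    res$median_unit_length[i] <- out$er$median_unit_length
    res$n_merged[i] <- out$er$n_merged
    res$n_dissociated[i] <- out$er$n_dissociated
    res$rate[i] <- out$er$rate
    res$ok[i] <- TRUE
  }
  structure(res, models = models, units = units_list,
            class = c("tu_grid", "data.frame"))
}

#' Default tuning-parameter grids
#'
#' The mammalian preset spans `lt_prob_b` 50..500 and `uts` 5..50 in ten
#' steps each (one hundred parametric models).  The non-mammalian preset
#' extends the length-penalty range upward: gene-dense genomes need a
#' stronger penalty against leaving the transcribed state.
#'
#' @param preset `"mammalian"` or `"nonmammalian"`.
#' @param n_steps Values per parameter (default 10).
#' @return List with numeric vectors `lt` and `uts`.
#' @export
tuning_grid <- function(preset = c("mammalian", "nonmammalian"),
                        n_steps = 10) {
  preset <- match.arg(preset)
  lt_range <- if (preset == "mammalian") c(50, 500) else c(50, 2000)
  list(lt = seq(lt_range[1], lt_range[2], length.out = n_steps),
       uts = seq(5, 50, length.out = n_steps))
}

#' Select the optimal model from a tuning grid
#'
#' Model selection in three steps: (1) keep models whose median unit length
#' lies within the interquartile range of median lengths across the grid;
#' (2) keep models whose unit count is strictly between `1.25 *
#' n_consensus` and `1.5 * n_consensus`; (3) among survivors, return the
#' model with the lowest overall error rate (ties: smaller `lt_prob_b`,
#' then smaller `uts`).  A filter that would empty the pool is skipped with
#' a warning — small genomes can fail the count band.
#'
#' @param results A `tu_grid` from [grid_search()].
#' @param n_consensus Number of consensus annotations (for the count band).
#' @param apply_filters Set `FALSE` to go straight to the argmin of rate.
#' @return A list with `lt_prob_b`, `uts`, `rate`, `index` (row of
#'   `results`), `model` (the trained `tuhmm`) and `units` (its calls).
#' @export
select_optimal <- function(results, n_consensus, apply_filters = TRUE) {
  stopifnot(inherits(results, "tu_grid"))
  pool <- which(results$ok)
  if (length(pool) == 0L) stop("no successful grid points")
  if (apply_filters && length(pool) > 1L) {
    med <- results$median_unit_length[pool]
    qs <- quantile(med, c(0.25, 0.75), na.rm = TRUE)
    keep <- pool[med >= qs[1] & med <= qs[2]]
    if (length(keep) == 0L) {
      warning("median-length IQR filter would empty the pool; skipped")
    } else {
      pool <- keep
    }
    keep <- pool[results$n_units[pool] > 1.25 * n_consensus &
                   results$n_units[pool] < 1.5 * n_consensus]
    if (length(keep) == 0L) {
      warning("transcript-count band filter would empty the pool; skipped")
    } else {
      pool <- keep
    }
  }
  o <- pool[order(results$rate[pool], results$lt_prob_b[pool],
                  results$uts[pool])]
  i <- o[1L]
  list(lt_prob_b = results$lt_prob_b[i], uts = results$uts[i],
       rate = results$rate[i], index = i,
       model = attr(results, "models")[[i]],
       units = attr(results, "units")[[i]])
}
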