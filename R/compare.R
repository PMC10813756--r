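#' Percent error between predicted and experimental values
#'
#' `100 * |predicted - experimental| / |experimental|`, vectorised over
#' specimens.
#'
#' @param predicted,experimental numeric vectors of equal length;
#'   `experimental` must be nonzero.
#' @return percent errors.
#' @export
percent_error <- function(predicted, experimental) {
  if (length(predicted) != length(experimental))
    stop("'predicted' and 'experimental' must have equal length")
  if (any(experimental == 0)) stop("experimental value of 0: undefined error")
  100 * abs(predicted - experimental) / abs(experimental)
}

#' Coefficient of determination between model and experiment
#'
#' Realized as the squared Pearson correlation of the paired values (for a
#' simple linear fit this equals the regression R-squared).
#'
#' @param predicted,experimental numeric vectors, >= 3 pairs;
#'   `experimental` must not be constant.
#' @return R-squared in \[0, 1\].
#' @export
coefficient_of_determination <- function(predicted, experimental) {
  if (length(predicted) != length(experimental))
    stop("'predicted' and 'experimental' must have equal length")
  if (length(predicted) < 3L) stop("need at least 3 pairs")
  if (stats::var(experimental) == 0)
    stop("experimental values are constant: R-squared undefined")
  stats::cor(predicted, experimental)^2
}

#' Model-versus-experiment summary statistics
#'
#' @param predicted_stiffness,experimental_stiffness kN/mm.
#' @param predicted_strength,experimental_strength kN.
#' @return An object of class `comparison_stats`: per-specimen percent
#'   errors, their means, and R-squared for stiffness and strength.
#' @export
comparison_stats <- function(predicted_stiffness, experimental_stiffness,
                             predicted_strength, experimental_strength) {
  es <- percent_error(predicted_stiffness, experimental_stiffness)
  ef <- percent_error(predicted_strength, experimental_strength)
  structure(list(
    n_specimens = length(es),
    stiffness_percent_error = es,
    strength_percent_error = ef,
    mean_stiffness_error = mean(es),
    mean_strength_error = mean(ef),
    r2_stiffness = coefficient_of_determination(predicted_stiffness,
                                                experimental_stiffness),
    r2_strength = coefficient_of_determination(predicted_strength,
                                               experimental_strength)),
    class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf(
    paste0("comparison_stats (n = %d):\n",
           "  stiffness: mean error %.1f%%, R2 = %.3f\n",
           "  strength:  mean error %.1f%%, R2 = %.3f\n"),
    x$n_specimens, x$mean_stiffness_error, x$r2_stiffness,
    x$mean_strength_error, x$r2_strength))
  invisible(x)
}

#' Calibrate the yield-strain scaling factor against experiment
#'
#' Finds the multiplicative scale on the yield strain that minimises the
#' mean absolute strength percent error over a specimen set (strength is
#' the calibrated metric; stiffness is reported but not optimised).
#' Because the plastic limit load is (near-)linear in the scale, the
#' search is warm-started at `mean(experimental / predicted-at-scale-1)`
#' and then refined by bounded 1-D minimisation around the warm start.
#'
#' @param predict_strength function taking a scalar `scale` and returning
#'   the predicted strengths (kN) of all specimens at that yield-strain
#'   scale.  Evaluations are memoised.
#' @param experimental_strength positive experimental strengths, kN.
#' @param bounds length-2 admissible scale range.
#' @param tol relative convergence tolerance on the scale.
#' @param bracket_halfwidth half-width (relative to the warm start) of the
#'   refinement bracket.
#' @return list with `scale`, `objective` (mean strength percent error at
#'   `scale`), `objective_at_1`, `warm_start`, `n_evaluations`, and
#'   `evaluations` (data.frame of all probed scales).
#' @export
calibrate_yield_scale <- function(predict_strength, experimental_strength,
                                  bounds = c(0.2, 10), tol = 1e-3,
                                  bracket_halfwidth = 0.3) {
  if (length(experimental_strength) < 1L || any(experimental_strength <= 0))
    stop("need at least one positive experimental strength")
  if (bounds[1] <= 0 || bounds[2] <= bounds[1]) stop("invalid 'bounds'")
  cache <- new.env(parent = emptyenv())
  evals <- list()
  objective <- function(scale) {
    key <- sprintf("%.15g", scale)
    if (!is.null(cache[[key]])) return(cache[[key]])
    pred <- predict_strength(scale)
    obj <- mean(percent_error(pred, experimental_strength))
    cache[[key]] <- obj
    evals[[length(evals) + 1L]] <<- data.frame(scale = scale,
                                               objective = obj)
    obj
  }

  pred1 <- predict_strength(1)
  obj1 <- mean(percent_error(pred1, experimental_strength))
  cache[["1"]] <- obj1
  evals[[1L]] <- data.frame(scale = 1, objective = obj1)
  if (any(pred1 <= 0)) stop("scale-1 predictions must be positive")
  s0 <- mean(experimental_strength / pred1)
  s0 <- min(max(s0, bounds[1]), bounds[2])

  lo <- max(bounds[1], s0 * (1 - bracket_halfwidth))
  hi <- min(bounds[2], s0 * (1 + bracket_halfwidth))
  opt <- stats::optimize(objective, lower = lo, upper = hi,
                         tol = max(tol * s0, 1e-8))
  best <- list(scale = opt$minimum, objective = opt$objective)
  # calibration must never hurt the calibrated metric
  ev <- do.call(rbind, evals)
  imin <- which.min(ev$objective)
  if (ev$objective[imin] < best$objective)
    best <- list(scale = ev$scale[imin], objective = ev$objective[imin])
  list(scale = best$scale, objective = best$objective,
       objective_at_1 = obj1, warm_start = s0,
       n_evaluations = nrow(ev), evaluations = ev)
}
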