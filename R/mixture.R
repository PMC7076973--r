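#' Linear opinion pool (finite mixture) of distributions
#'
#' Pools expert distributions on the distribution (density) scale: the
#' pooled density at any point is the weighted average of the component
#' densities.  By default every component — i.e. every expert — carries
#' equal weight, which is the pooling rule used to synthesise elicited
#' opinion.  Components may be univariate (`split_normal`, `point_mass`,
#' nested mixtures) or bivariate two-arm distributions; they must all
#' share the same dimension.
#'
#' @param components A list of distribution objects (at least one).
#' @param weights Optional nonnegative weights, one per component;
#'   renormalised to sum to 1.  Defaults to equal weights.
#' @return An object of class `c("mixture_dist", "dist")` (and
#'   `"dist2d"` when the components are bivariate) with fields
#'   `components` and `weights`.
#' @examples
#' pool <- mixture_pool(list(split_normal(0, 1, 1), split_normal(4, 1, 1)))
#' ddist(pool, 2)  # average of the two normal densities at 2
#' @export
mixture_pool <- function(components, weights = NULL) {
  if (!is.list(components) || length(components) == 0L) {
    abort_mnar("`components` must be a non-empty list of distributions",
               "mnarsens_invalid_argument")
  }
  if (!all(vapply(components, inherits, logical(1), what = "dist"))) {
    abort_mnar("every component must be a distribution object",
               "mnarsens_invalid_argument")
  }
  bi <- vapply(components, inherits, logical(1), what = "dist2d")
  if (any(bi) && !all(bi)) {
    abort_mnar("cannot mix univariate and bivariate components",
               "mnarsens_invalid_argument")
  }
  k <- length(components)
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) != k || any(!is.finite(weights)) || any(weights < 0) ||
      sum(weights) <= 0) {
    abort_mnar("`weights` must be nonnegative, finite, one per component",
               "mnarsens_invalid_argument")
  }
  structure(
    list(components = components, weights = weights / sum(weights)),
    class = c("mixture_dist", "dist", if (all(bi)) "dist2d")
  )
}

#' @export
ddist.mixture_dist <- function(d, x, ...) {
  dens <- lapply(d$components, ddist, x = x, ...)
  Reduce(`+`, Map(`*`, d$weights, dens))
}

#' @export
pdist.mixture_dist <- function(d, q, ...) {
  ps <- lapply(d$components, pdist, q = q, ...)
  Reduce(`+`, Map(`*`, d$weights, ps))
}

#' @export
qdist.mixture_dist <- function(d, p, ...) {
  # numeric inversion of the mixture CDF on its joint support
  if (inherits(d, "dist2d")) {
    abort_mnar("quantiles are not defined for bivariate mixtures",
               "mnarsens_invalid_argument")
  }
  vapply(p, function(pp) {
    if (pp <= 0 || pp >= 1) {
      qs <- vapply(d$components, qdist, numeric(1), p = pp)
      return(if (pp <= 0) min(qs) else max(qs))
    }
    qs <- vapply(d$components, qdist, numeric(1), p = pp)
    lo <- min(qs) - 1; hi <- max(qs) + 1
    stats::uniroot(function(x) pdist(d, x) - pp, c(lo, hi),
                   extendInt = "upX", tol = 1e-10)$root
  }, numeric(1))
}

## component-then-value sampling: scales to many-expert pools without
## evaluating the pooled density
#' @export
rdist.mixture_dist <- function(d, n, seed = NULL, ...) {
  k <- length(d$components)
  idx <- sample.int(k, n, replace = TRUE, prob = d$weights)
  if (inherits(d, "dist2d")) {
    out <- matrix(NA_real_, n, 2)
    for (j in seq_len(k)) {
      take <- idx == j
      if (any(take)) out[take, ] <- rdist(d$components[[j]], sum(take))
    }
    colnames(out) <- c("usual_care", "intervention")
  } else {
    out <- numeric(n)
    for (j in seq_len(k)) {
      take <- idx == j
      if (any(take)) out[take] <- rdist(d$components[[j]], sum(take))
    }
  }
  out
}

#' @export
dist_mean.mixture_dist <- function(d) {
  means <- lapply(d$components, dist_mean)
  Reduce(`+`, Map(`*`, d$weights, means))
}

#' @export
print.mixture_dist <- function(x, ...) {
  cat(sprintf("mixture of %d component%s (%s)\n", length(x$components),
              if (length(x$components) == 1L) "" else "s",
              if (inherits(x, "dist2d")) "bivariate" else "univariate"))
  invisible(x)
}
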