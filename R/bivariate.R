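#' Bivariate (two-arm) split-normal distribution
#'
#' Couples the elicited control-arm and intervention-arm distributions
#' into a joint prior.  The marginals are preserved exactly and the
#' between-arm relationship is expressed through a Gaussian copula with a
#' single dependence parameter in (-1, 1): 0 gives independent arms,
#' values near 1 make an expert who believes in a high control-arm mean
#' also believe in a high intervention-arm mean.
#'
#' @param marginal_control,marginal_intervention Univariate distribution
#'   objects (usually [split_normal()]) for the usual-care and
#'   intervention arms.
#' @param dependence Copula correlation in (-1, 1); default 0.5.
#' @return An object of class `c("bivariate_split_normal", "dist2d", "dist")`.
#' @examples
#' b <- bivariate_split_normal(split_normal(15, 3, 5, 0, 51),
#'                             split_normal(12, 3, 5, 0, 51), 0.5)
#' head(rdist(b, 4, seed = 1))
#' @export
bivariate_split_normal <- function(marginal_control, marginal_intervention,
                                   dependence = 0.5) {
  if (!inherits(marginal_control, "dist") ||
      !inherits(marginal_intervention, "dist") ||
      inherits(marginal_control, "dist2d") ||
      inherits(marginal_intervention, "dist2d")) {
    abort_mnar("marginals must be univariate distribution objects",
               "mnarsens_invalid_parameter")
  }
  check_number(dependence, "dependence")
  if (abs(dependence) >= 1) {
    abort_mnar("`dependence` must lie strictly inside (-1, 1)",
               "mnarsens_invalid_parameter")
  }
  structure(
    list(marginal_control = marginal_control,
         marginal_intervention = marginal_intervention,
         dependence = dependence),
    class = c("bivariate_split_normal", "dist2d", "dist")
  )
}

#' @export
rdist.bivariate_split_normal <- function(d, n, seed = NULL, ...) {
  rho <- d$dependence
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  out <- cbind(
    usual_care = qdist(d$marginal_control, stats::pnorm(z1)),
    intervention = qdist(d$marginal_intervention, stats::pnorm(z2))
  )
  out
}

## joint density via the Gaussian copula: c(F1(x1), F2(x2)) f1(x1) f2(x2)
#' @export
ddist.bivariate_split_normal <- function(d, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  rho <- d$dependence
  f1 <- ddist(d$marginal_control, x[, 1])
  f2 <- ddist(d$marginal_intervention, x[, 2])
  u1 <- pdist(d$marginal_control, x[, 1])
  u2 <- pdist(d$marginal_intervention, x[, 2])
  z1 <- stats::qnorm(pmin(pmax(u1, 1e-15), 1 - 1e-15))
  z2 <- stats::qnorm(pmin(pmax(u2, 1e-15), 1 - 1e-15))
  copdens <- exp(-((rho^2) * (z1^2 + z2^2) - 2 * rho * z1 * z2) /
                   (2 * (1 - rho^2))) / sqrt(1 - rho^2)
  out <- copdens * f1 * f2
  out[f1 == 0 | f2 == 0] <- 0
  out
}

#' @export
dist_mean.bivariate_split_normal <- function(d) {
  c(usual_care = dist_mean(d$marginal_control),
    intervention = dist_mean(d$marginal_intervention))
}

#' @export
print.bivariate_split_normal <- function(x, ...) {
  cat(sprintf("bivariate split normal (dependence %g)\n", x$dependence))
  cat("  usual_care:   "); print(x$marginal_control)
  cat("  intervention: "); print(x$marginal_intervention)
  invisible(x)
}
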