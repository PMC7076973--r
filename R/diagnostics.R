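#' MCMC convergence diagnostics
#'
#' `split_rhat()` computes the split-chain potential scale reduction
#' factor: each chain is split in half and the usual between/within
#' variance ratio is taken over the resulting 2M half-chains.
#' `ess_basic()` estimates the effective sample size from the
#' chain-averaged autocorrelation function, truncated by Geyer's initial
#' positive sequence rule.
#'
#' @param chains A matrix with one column per chain (draws in rows), or
#'   a list of equal-length numeric vectors.
#' @return A single number.
#' @export
split_rhat <- function(chains) {
  chains <- as_chain_matrix(chains)
  n <- nrow(chains)
  half <- floor(n / 2)
  splits <- cbind(chains[seq_len(half), , drop = FALSE],
                  chains[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits); nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  w <- mean(vars)
  b <- nn * stats::var(means)
  if (w == 0) return(1)  # degenerate chains
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

#' @rdname split_rhat
#' @export
ess_basic <- function(chains) {
  chains <- as_chain_matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (stats::var(as.vector(chains)) == 0) return(n * m)
  max_lag <- min(n - 1, 500)
  acfs <- apply(chains, 2, function(x) {
    stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  rho <- rowMeans(acfs)[-1]  # drop lag 0
  # Geyer initial positive sequence: sum consecutive pairs while positive
  npair <- floor(length(rho) / 2)
  tau <- 1
  for (k in seq_len(npair)) {
    pair <- rho[2 * k - 1] + rho[2 * k]
    if (pair < 0) break
    tau <- tau + 2 * pair
  }
  min(n * m, n * m / tau)
}

as_chain_matrix <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  if (is.null(dim(chains))) chains <- matrix(chains, ncol = 1)
  chains
}
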