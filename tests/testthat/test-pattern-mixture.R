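test_that("fit configuration and trial data are validated", {
  expect_error(fit_config(chains = 1), class = "mnarsens_invalid_parameter")
  expect_error(fit_config(iter = 100, burnin = 100),
               class = "mnarsens_invalid_parameter")
  g <- small_trial(seed = 1)
  bad <- g$data
  bad$outcome[bad$arm == "intervention"] <- NA
  bad$response_indicator <- !is.na(bad$outcome)
  expect_error(fit_pattern_mixture(bad, quick_config()),
               class = "mnarsens_inestimable_model")
  bad2 <- g$data
  bad2$response_indicator[1] <- !bad2$response_indicator[1]
  expect_error(fit_pattern_mixture(bad2, quick_config()),
               class = "mnarsens_schema_violation")
})

test_that("identical seeds give bit-identical draws", {
  g <- small_trial(seed = 2, n_clusters = 10, patients_per_cluster = 12)
  cfg <- fit_config(chains = 2, iter = 600, burnin = 200, seed = 99,
                    delta = c(0, 5))
  f1 <- fit_pattern_mixture(g$data, cfg)
  f2 <- fit_pattern_mixture(g$data, cfg)
  expect_identical(f1$chains, f2$chains)
})

test_that("the sampler recovers generating parameters on a clean dataset", {
  g <- small_trial(seed = 5, delta_true = c(usual_care = 0, intervention = 0),
                   n_clusters = 20, patients_per_cluster = 40)
  fit <- fit_pattern_mixture(g$data, quick_config(seed = 3, iter = 2500,
                                                  burnin = 1000))
  s <- summarize_fit(fit, "lower_is_better")
  truth <- g$truth$params$beta_treat
  expect_true(s$cri[1] < truth && truth < s$cri[2])
  # residual and cluster sds in sensible ranges around the generating values
  sig <- mean(unlist(lapply(fit$chains, function(m) m[, "sigma"])))
  expect_lt(abs(sig - g$truth$params$sigma), 1.5)
  expect_lt(s$rhat, 1.05)
})

test_that("a point-mass zero offset reproduces the MAR analysis", {
  g <- small_trial(seed = 7)
  mar <- fit_pattern_mixture(g$data, quick_config(seed = 11, delta = "mar"))
  pm0 <- fit_pattern_mixture(g$data, quick_config(seed = 12,
                                                  delta = c(0, 0)))
  e_mar <- lapply(mar$chains, function(m) m[, "effect"])
  e_pm <- lapply(pm0$chains, function(m) m[, "effect"])
  se <- sqrt(mc_se(e_mar)^2 + mc_se(e_pm)^2)
  expect_lt(abs(mean(unlist(e_mar)) - mean(unlist(e_pm))), 3 * se)
})

test_that("with no missing outcomes the offset prior does not move the posterior", {
  g <- small_trial(seed = 8, n_clusters = 12, patients_per_cluster = 20)
  complete <- g$data
  complete$outcome <- g$truth$latent_outcome
  complete$response_indicator <- TRUE
  cfg_a <- fit_config(chains = 2, iter = 1200, burnin = 400, seed = 21,
                      delta = c(0, 10))
  cfg_b <- fit_config(chains = 2, iter = 1200, burnin = 400, seed = 21,
                      delta = "mar")
  fa <- fit_pattern_mixture(complete, cfg_a)
  fb <- fit_pattern_mixture(complete, cfg_b)
  # p_miss is 0 everywhere, so the offset cancels from the effect draws
  expect_equal(unlist(lapply(fa$chains, function(m) m[, "effect"])),
               unlist(lapply(fb$chains, function(m) m[, "effect"])),
               tolerance = 1e-12)
})

test_that("marginal arm means follow the pattern-weighted identity", {
  g <- small_trial(seed = 9)
  cfg0 <- fit_config(chains = 2, iter = 1200, burnin = 400, seed = 31,
                     delta = c(0, 0))
  cfg4 <- fit_config(chains = 2, iter = 1200, burnin = 400, seed = 31,
                     delta = c(0, 4))
  f0 <- fit_pattern_mixture(g$data, cfg0)
  f4 <- fit_pattern_mixture(g$data, cfg4)
  p_int <- f0$p_miss$p_miss[f0$p_miss$arm == "intervention" &
                              f0$p_miss$period == "intervention_period"]
  # same seed: identical observed-model draws, so the shift is exact
  shift <- marginal_arm_mean(f4, "intervention") -
    marginal_arm_mean(f0, "intervention")
  expect_equal(shift, rep(p_int * 4, length(shift)), tolerance = 1e-10)
  expect_equal(marginal_arm_mean(f4, "usual_care"),
               marginal_arm_mean(f0, "usual_care"), tolerance = 1e-12)
})

test_that("marginal arm mean matches a brute-force imputation average", {
  g <- small_trial(seed = 13)
  cfg <- fit_config(chains = 2, iter = 1500, burnin = 500, seed = 41,
                    delta = c(0, 6))
  fit <- fit_pattern_mixture(g$data, cfg)
  mm <- mean(marginal_arm_mean(fit, "intervention"))
  # oracle: average posterior-imputed outcomes of the cell's patients,
  # using posterior mean coefficients and the imputation model mean
  beta <- colMeans(do.call(rbind, fit$chains))
  cell <- g$data[g$data$arm == "intervention" &
                   g$data$period == "intervention_period", ]
  linpred <- beta[["(Intercept)"]] + beta[[".period_ind"]] +
    beta[[".treat_ind"]] +
    beta[["gendermale"]] * (cell$gender == "male") +
    beta[["age_groupyounger"]] * (cell$age_group == "younger") +
    beta[["anxietynot_anxious"]] * (cell$anxiety == "not_anxious") +
    beta[["ucell.intervention.intervention_period"]]
  imputed <- ifelse(is.na(cell$outcome), linpred + 6, linpred)
  expect_lt(abs(mm - mean(imputed)),
            3 * sd(marginal_arm_mean(fit, "intervention")) / sqrt(500) + 0.35)
})

test_that("posterior summaries handle degenerate and analytic cases", {
  const <- summarize_draws(rep(-2, 2000), "lower_is_better")
  expect_equal(const$mean, -2)
  expect_equal(const$cri, c(-2, -2))
  expect_equal(const$p_favours, 1)
  expect_equal(summarize_draws(rep(3, 2000), "lower_is_better")$p_favours, 0)

  set.seed(77)
  sym <- summarize_draws(rnorm(2e4), "lower_is_better")
  expect_lt(abs(sym$p_favours - 0.5), 0.02)
  z <- rnorm(1e4)
  s <- summarize_draws(z, "lower_is_better")
  expect_lt(abs(s$cri[1] - qnorm(0.025)), 0.05)
  expect_lt(abs(s$cri[2] - qnorm(0.975)), 0.05)
  expect_error(summarize_draws(rnorm(100), "lower_is_better"),
               class = "mnarsens_insufficient_sample")
})

test_that("credible intervals tighten as the offset prior's sds shrink", {
  g <- small_trial(seed = 15)
  widths <- sapply(c(8, 3, 0.5), function(sd) {
    prior <- bivariate_split_normal(split_normal(0, sd, sd),
                                    split_normal(8, sd, sd), 0)
    cfg <- fit_config(chains = 2, iter = 1500, burnin = 500, seed = 51,
                      delta = prior)
    s <- summarize_fit(fit_pattern_mixture(g$data, cfg), "lower_is_better")
    diff(s$cri)
  })
  expect_true(all(diff(widths) < 0))
})

test_that("scenario runs keep labels, reject duplicates, and agree MAR vs point-mass zero", {
  g <- small_trial(seed = 17, n_clusters = 12, patients_per_cluster = 15)
  prior <- bivariate_split_normal(split_normal(2, 2, 3, -10, 20),
                                  split_normal(0, 2, 3, -10, 20), 0.5)
  res <- run_scenarios(g$data,
                       list(complete_case = "complete_case", MAR = "mar",
                            zero = c(0, 0), expert = prior),
                       fit_config(chains = 2, iter = 1200, burnin = 400,
                                  seed = 61),
                       direction = "lower_is_better")
  expect_equal(res$table$scenario, c("complete_case", "MAR", "zero", "expert"))
  expect_equal(nrow(res$table), 4)
  # MAR and a point mass at zero are the same analysis
  expect_lt(abs(res$table$mean[2] - res$table$mean[3]), 1e-10)
  # complete case carries no offset provenance
  expect_identical(res$table$delta_provenance[1], "")
  dup <- list(MAR = "mar", MAR = "mar")
  expect_error(run_scenarios(g$data, dup),
               class = "mnarsens_invalid_argument")
})

test_that("split-Rhat and ESS behave on known chains", {
  set.seed(101)
  good <- matrix(rnorm(4000), ncol = 2)
  expect_lt(split_rhat(good), 1.02)
  expect_gt(ess_basic(good), 2000)
  shifted <- cbind(rnorm(2000), rnorm(2000, 5))
  expect_gt(split_rhat(shifted), 1.5)
  # strongly autocorrelated chains have a much smaller ESS
  ar <- replicate(2, as.numeric(arima.sim(list(ar = 0.95), 2000)))
  expect_lt(ess_basic(ar), 500)
})
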