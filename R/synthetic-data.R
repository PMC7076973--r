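#' Configuration for the synthetic trial generator
#'
#' Emulates a two-arm cluster-randomised trial with a baseline and an
#' intervention period, a bounded patient-reported outcome and a
#' controllable missing-not-at-random mechanism.  Defaults reflect the
#' motivating study design: 24 ICU clusters randomised 1:1, roughly 60
#' patients per cluster, a PSS-SR outcome (0-51), anticipated loss to
#' follow-up of 20%, and a missingness model that is logistic in the
#' covariates and (optionally) the latent outcome.
#'
#' @param n_clusters Number of clusters, randomised 1:1 to arms.
#' @param patients_per_cluster Mean cluster size per period.
#' @param cluster_size_dispersion 0 for fixed sizes, otherwise Poisson
#'   sizes with this much extra dispersion (negative-binomial `size`
#'   parameter = mean/dispersion).
#' @param params Generating parameters: `beta0` (usual-care baseline
#'   mean), `beta_period`, `beta_treat` (treatment-by-period
#'   interaction, the estimand), `beta_gender`, `beta_age`,
#'   `beta_anxiety`, `tau` (cluster sd), `sigma` (residual sd).
#' @param delta_true True sensitivity offsets `c(usual_care,
#'   intervention)`: the generating non-responder mean in each cell is
#'   the responder mean plus the offset of the treatment received.
#' @param scale The bounded [outcome_scale()]; out-of-bounds residual
#'   draws are resampled so generating means stay interpretable.
#' @param miss_coef Logistic missingness coefficients: `outcome` (per
#'   unit of the latent outcome), `gender`, `age`, `anxiety`.  The
#'   intercept is solved numerically so the marginal missingness hits
#'   `target_missingness` exactly in expectation.
#' @param target_missingness Marginal missingness probability.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `trial_sim_config`.
#' @export
trial_sim_config <- function(n_clusters = 24, patients_per_cluster = 60,
                             cluster_size_dispersion = 0,
                             params = list(beta0 = 18, beta_period = -1,
                                           beta_treat = -2, beta_gender = 2,
                                           beta_age = 1.5, beta_anxiety = 4,
                                           tau = 2, sigma = 8),
                             delta_true = c(usual_care = 0, intervention = 0),
                             scale = pss_scale(),
                             miss_coef = list(outcome = 0.03, gender = 0.2,
                                              age = 0.2, anxiety = 0.4),
                             target_missingness = 0.20, seed = 1) {
  check_number(n_clusters, "n_clusters", lower = 2)
  check_number(patients_per_cluster, "patients_per_cluster", lower = 2)
  check_number(target_missingness, "target_missingness",
               lower = 1e-6, upper = 1 - 1e-6)
  if (length(delta_true) != 2L) {
    abort_mnar("`delta_true` must have one offset per arm",
               "mnarsens_invalid_parameter")
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 patients_per_cluster = patients_per_cluster,
                 cluster_size_dispersion = cluster_size_dispersion,
                 params = params, delta_true = delta_true, scale = scale,
                 miss_coef = miss_coef,
                 target_missingness = target_missingness,
                 seed = as.integer(seed)),
            class = "trial_sim_config")
}

#' Generate a synthetic cluster-randomised trial with MNAR outcomes
#'
#' Outcomes are drawn from the observed-pattern linear model (cluster
#' random intercepts, period effect, treatment-by-period interaction,
#' covariates), resampling residuals that fall outside the scale
#' bounds.  Missingness is then assigned by the logistic rule with the
#' intercept calibrated to the target marginal rate, and finally the
#' missing records' latent outcomes are shifted within each
#' (treatment-received, period) cell so that the realized non-responder
#' mean equals the responder mean plus the cell's true offset — the
#' exact pattern-mixture semantics of the sensitivity parameter.
#'
#' @param cfg A [trial_sim_config()].
#' @return A list with `data` (the trial table; `outcome` is `NA` where
#'   missing, `response_indicator` marks completers) and `truth` (all
#'   generating parameters, the latent outcomes, realized missingness
#'   by cell, and `marginal_effect`, the pattern-weighted treatment
#'   effect implied by the generating parameters and realized
#'   missingness — the estimand the MNAR analysis targets).
#' @export
generate_trial <- function(cfg = trial_sim_config()) {
  set.seed(cfg$seed)
  pars <- cfg$params
  arms <- rep(c("usual_care", "intervention"), length.out = cfg$n_clusters)
  arms <- sample(arms)  # random allocation of clusters
  sizes <- if (cfg$cluster_size_dispersion > 0) {
    pmax(2L, stats::rnbinom(2 * cfg$n_clusters,
                            mu = cfg$patients_per_cluster,
                            size = cfg$patients_per_cluster /
                              cfg$cluster_size_dispersion))
  } else {
    rep(as.integer(round(cfg$patients_per_cluster)), 2 * cfg$n_clusters)
  }
  # one cohort per cluster per period
  cluster_id <- rep(rep(seq_len(cfg$n_clusters), 2), times = sizes)
  period <- rep(rep(c("baseline", "intervention_period"),
                    each = cfg$n_clusters), times = sizes)
  n <- length(cluster_id)
  arm <- arms[cluster_id]
  gender <- sample(c("female", "male"), n, replace = TRUE)
  age_group <- sample(c("younger", "older"), n, replace = TRUE)
  anxiety <- sample(c("not_anxious", "anxious"), n, replace = TRUE)
  u <- stats::rnorm(cfg$n_clusters, 0, pars$tau)
  treat_ind <- as.numeric(period == "intervention_period" & arm == "intervention")
  linpred <- pars$beta0 +
    pars$beta_period * (period == "intervention_period") +
    pars$beta_treat * treat_ind +
    pars$beta_gender * (gender == "male") +
    pars$beta_age * (age_group == "older") +
    pars$beta_anxiety * (anxiety == "anxious") +
    u[cluster_id]
  y <- linpred + stats::rnorm(n, 0, pars$sigma)
  # resample residuals outside the scale bounds (documented behaviour)
  for (tries in 1:100) {
    out <- y < cfg$scale$lower | y > cfg$scale$upper
    if (!any(out)) break
    y[out] <- linpred[out] + stats::rnorm(sum(out), 0, pars$sigma)
  }
  if (any(y < cfg$scale$lower | y > cfg$scale$upper)) {
    abort_mnar("could not keep outcomes within scale bounds; generating means too close to a bound",
               "mnarsens_calibration_failure")
  }

  # logistic missingness, intercept calibrated to the target rate
  score <- cfg$miss_coef$outcome * (y - mean(y)) +
    cfg$miss_coef$gender * (gender == "male") +
    cfg$miss_coef$age * (age_group == "older") +
    cfg$miss_coef$anxiety * (anxiety == "anxious")
  root <- tryCatch(
    stats::uniroot(function(a) mean(stats::plogis(a + score)) -
                     cfg$target_missingness,
                   c(-30, 30), tol = 1e-10),
    error = function(e) abort_mnar(
      "could not calibrate missingness intercept to the target rate",
      "mnarsens_calibration_failure"))
  p_miss <- stats::plogis(root$root + score)
  missing <- stats::runif(n) < p_miss

  # enforce the pattern-mixture semantics: within each
  # (treatment-received, period) cell, shift missing latent outcomes so
  # their mean is the responder mean plus the true offset
  received <- ifelse(treat_ind == 1, "intervention", "usual_care")
  delta_true <- cfg$delta_true
  if (is.null(names(delta_true))) {
    names(delta_true) <- c("usual_care", "intervention")
  }
  y_full <- y
  for (a in unique(received)) {
    for (pp in unique(period)) {
      sel <- received == a & period == pp
      if (!any(sel & missing) || !any(sel & !missing)) next
      target <- mean(y[sel & !missing]) + delta_true[[a]]
      y_full[sel & missing] <- y[sel & missing] +
        (target - mean(y[sel & missing]))
    }
  }

  data <- data.frame(
    patient_id = seq_len(n),
    cluster_id = cluster_id,
    period = period,
    arm = arm,
    gender = gender,
    age_group = age_group,
    anxiety = anxiety,
    outcome = ifelse(missing, NA_real_, y_full),
    response_indicator = !missing,
    stringsAsFactors = FALSE
  )

  pm <- miss_props(data)
  marginal_effect <- pars$beta_treat +
    cell_p(pm, "intervention", "intervention_period") * delta_true[["intervention"]] -
    cell_p(pm, "usual_care", "intervention_period") * delta_true[["usual_care"]] -
    (cell_p(pm, "intervention", "baseline") -
       cell_p(pm, "usual_care", "baseline")) * delta_true[["usual_care"]]

  truth <- list(params = pars, delta_true = as.list(delta_true),
                arms = stats::setNames(as.list(arms), seq_len(cfg$n_clusters)),
                cluster_effects = u,
                latent_outcome = y_full,
                realized_missingness = mean(missing),
                missingness_by_cell = pm,
                marginal_effect = unname(marginal_effect),
                seed = cfg$seed)
  list(data = data, truth = truth)
}

#' Configuration for the synthetic expert-panel generator
#'
#' Stands in for the study's elicitation panel: expert modes scatter
#' around the true non-responder means, slider sds are drawn from a
#' log-normal pair with configurable left/right asymmetry, and stated
#' fractions of the panel are produced as unusable (unmoved sliders) or
#' high-confidence (all reviewer flags true).  The default panel size
#' of 59 mirrors the number of usable questionnaires in the motivating
#' study.
#'
#' @param n_experts Panel size.
#' @param truth True non-responder means per arm, either a length-2
#'   vector `c(usual_care, intervention)` applied to all subgroups or a
#'   2 x 3 matrix (arms x subgroups A, B, C).
#' @param scatter_sd Between-expert sd of the elicited modes.
#' @param sd_meanlog,sd_sdlog Log-normal parameters of the slider sds.
#' @param asymmetry Multiplicative right/left sd asymmetry (1 =
#'   symmetric experts on average).
#' @param fraction_unusable,fraction_high_confidence Fractions of the
#'   panel generated as unusable and as high-confidence (the remainder
#'   are plain usable); must sum to at most 1.
#' @param dependence Between-arm relationship answer given by every
#'   expert.
#' @param seed Integer seed.
#' @return A list of class `expert_sim_config`.
#' @export
expert_sim_config <- function(n_experts = 59,
                              truth = c(usual_care = 22, intervention = 19),
                              scatter_sd = 3, sd_meanlog = log(4),
                              sd_sdlog = 0.3, asymmetry = 1.2,
                              fraction_unusable = 0.15,
                              fraction_high_confidence = 0.39,
                              dependence = 0.5, seed = 1) {
  check_number(n_experts, "n_experts", lower = 1)
  check_number(fraction_unusable, "fraction_unusable", lower = 0, upper = 1)
  check_number(fraction_high_confidence, "fraction_high_confidence",
               lower = 0, upper = 1)
  if (fraction_unusable + fraction_high_confidence > 1) {
    abort_mnar("unusable and high-confidence fractions must sum to at most 1",
               "mnarsens_invalid_argument")
  }
  structure(list(n_experts = as.integer(n_experts), truth = truth,
                 scatter_sd = scatter_sd, sd_meanlog = sd_meanlog,
                 sd_sdlog = sd_sdlog, asymmetry = asymmetry,
                 fraction_unusable = fraction_unusable,
                 fraction_high_confidence = fraction_high_confidence,
                 dependence = dependence, seed = as.integer(seed)),
            class = "expert_sim_config")
}

#' Generate a synthetic expert panel
#'
#' @param cfg An [expert_sim_config()].
#' @param anchors An [anchor_table()] for the outcome being elicited.
#' @param scale The [outcome_scale()] of the elicitation.
#' @param outcome Outcome label written into the response rows.
#' @return A list with `responses` (a [read_responses()]-valid table),
#'   `evaluations` (resolved reviewer records) and `truth` (generating
#'   parameters and the designated category of every expert).
#' @export
generate_experts <- function(cfg = expert_sim_config(),
                             anchors = anchor_table("symptom_severity", 15, 13),
                             scale = pss_scale(),
                             outcome = anchors$outcome[1]) {
  set.seed(cfg$seed)
  subgroups <- c("A", "B", "C")
  arms <- c("usual_care", "intervention")
  truth <- cfg$truth
  truth_mat <- if (is.matrix(truth)) truth else
    matrix(rep(truth, 3), nrow = 2, dimnames = list(arms, subgroups))
  if (is.null(rownames(truth_mat))) rownames(truth_mat) <- arms
  if (is.null(colnames(truth_mat))) colnames(truth_mat) <- subgroups

  n_unus <- round(cfg$n_experts * cfg$fraction_unusable)
  n_high <- round(cfg$n_experts * cfg$fraction_high_confidence)
  if (n_unus + n_high > cfg$n_experts) {
    abort_mnar("fractions inconsistent with the panel size",
               "mnarsens_invalid_argument")
  }
  ids <- sprintf("E%03d", seq_len(cfg$n_experts))
  category <- rep("usable", cfg$n_experts)
  if (n_unus > 0) category[seq_len(n_unus)] <- "unusable"
  if (n_high > 0) category[n_unus + seq_len(n_high)] <- "usable_high_confidence"
  category <- sample(category)  # categories spread over the panel
  names(category) <- ids

  rows <- list()
  for (i in seq_along(ids)) {
    for (a in arms) {
      for (s in subgroups) {
        if (category[i] == "unusable") {
          # an expert who misunderstood: sliders left at tool defaults
          mode <- anchor_for(anchors, a)
          sdl <- sdr <- 4
          moved <- FALSE
        } else {
          mode <- truth_mat[a, s] + stats::rnorm(1, 0, cfg$scatter_sd)
          mode <- min(max(mode, scale$lower), scale$upper)
          sdl <- stats::rlnorm(1, cfg$sd_meanlog, cfg$sd_sdlog)
          sdr <- stats::rlnorm(1, cfg$sd_meanlog, cfg$sd_sdlog) * cfg$asymmetry
          moved <- TRUE
        }
        rows[[length(rows) + 1L]] <- data.frame(
          expert_id = ids[i], outcome = outcome, arm = a, subgroup = s,
          mode = mode, sd_left = sdl, sd_right = sdr,
          moved_mode = moved, moved_left = moved, moved_right = moved,
          dependence = cfg$dependence,
          rationale = if (category[i] == "unusable") "" else
            "clinical experience with non-responders",
          stringsAsFactors = FALSE)
      }
    }
  }
  responses <- read_responses(do.call(rbind, rows))

  evaluations <- read_evaluations(data.frame(
    expert_id = ids,
    reviewer_id = "resolved",
    engagement_evidence = category != "unusable",
    quant_qual_consistency = category == "usable_high_confidence",
    cross_subgroup_consistency = category != "unusable",
    misunderstanding = category == "unusable",
    notes = "",
    stringsAsFactors = FALSE))

  truth_rec <- list(truth = truth_mat,
                    category = as.list(category),
                    n_unusable = n_unus, n_high_confidence = n_high,
                    dependence = cfg$dependence, seed = cfg$seed)
  list(responses = responses, evaluations = evaluations, truth = truth_rec)
}
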