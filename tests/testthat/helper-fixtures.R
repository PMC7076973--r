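# Fixtures are built in code at test time; nothing is stored on disk.

# one expert's six response rows (2 arms x 3 subgroups) on the PSS scale
make_expert_rows <- function(expert_id, mode_ctl = 20, mode_int = 17,
                             sd_left = 3, sd_right = 5, moved = TRUE,
                             dependence = 0.5) {
  grid <- expand.grid(arm = c("usual_care", "intervention"),
                      subgroup = c("A", "B", "C"),
                      stringsAsFactors = FALSE)
  data.frame(
    expert_id = expert_id, outcome = "symptom_severity",
    arm = grid$arm, subgroup = grid$subgroup,
    mode = ifelse(grid$arm == "usual_care", mode_ctl, mode_int),
    sd_left = sd_left, sd_right = sd_right,
    moved_mode = moved, moved_left = moved, moved_right = moved,
    dependence = dependence,
    stringsAsFactors = FALSE
  )
}

make_panel <- function(specs) {
  read_responses(do.call(rbind, specs))
}

resolved_eval <- function(expert_id, flags = c(TRUE, TRUE, TRUE),
                          misunderstanding = FALSE) {
  data.frame(expert_id = expert_id, reviewer_id = "resolved",
             engagement_evidence = flags[1],
             quant_qual_consistency = flags[2],
             cross_subgroup_consistency = flags[3],
             misunderstanding = misunderstanding,
             notes = "", stringsAsFactors = FALSE)
}

# small MNAR trial used across the model tests
small_trial <- function(seed = 42, delta_true = c(usual_care = 0,
                                                  intervention = 8),
                        n_clusters = 20, patients_per_cluster = 25) {
  generate_trial(trial_sim_config(
    n_clusters = n_clusters, patients_per_cluster = patients_per_cluster,
    delta_true = delta_true,
    miss_coef = list(outcome = 0, gender = 0.2, age = 0.2, anxiety = 0.4),
    target_missingness = 0.20, seed = seed))
}

quick_config <- function(seed = 1, delta = "mar", iter = 1500, burnin = 500) {
  fit_config(chains = 2, iter = iter, burnin = burnin, seed = seed,
             delta = delta)
}

# MC standard error of a posterior mean via the effective sample size
mc_se <- function(draws_by_chain) {
  x <- unlist(draws_by_chain)
  stats::sd(x) / sqrt(ess_basic(draws_by_chain))
}
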