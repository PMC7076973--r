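test_that("well-formed responses round-trip and invalid sliders are rejected with row diagnostics", {
  rows <- rbind(make_expert_rows("E1"), make_expert_rows("E2", 25, 22),
                make_expert_rows("E3", 12, 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE)
  resp <- read_responses(path)
  expect_equal(length(unique(resp$expert_id)), 3)
  expect_s3_class(resp, "elicitation_responses")

  bad <- rows; bad$mode[4] <- 60  # above the 0-51 PSS-SR scale
  expect_error(read_responses(bad), "row 4.*60.*51",
               class = "mnarsens_schema_violation")
  bad2 <- rows; bad2$sd_left[2] <- -1
  expect_error(read_responses(bad2), "row 2.*sd_left",
               class = "mnarsens_schema_violation")
  expect_error(read_responses(rows[, -5]), "mode",
               class = "mnarsens_schema_violation")
})

test_that("unmoved-slider screening uses a strict-below threshold", {
  all_moved <- make_expert_rows("E1", moved = TRUE)
  none_moved <- make_expert_rows("E2", moved = FALSE)
  sc <- screen_unusable(none_moved)
  expect_true(sc$unusable)
  expect_match(sc$reasons, "unmoved sliders")
  expect_false(screen_unusable(all_moved)$unusable)
  # exactly at the threshold: kept
  half <- all_moved
  half$moved_mode <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  half$moved_left <- half$moved_mode
  half$moved_right <- half$moved_mode
  expect_false(screen_unusable(half, min_moved_fraction = 0.5)$unusable)
  # reviewer-entered misunderstanding flag screens out on its own
  expect_true(screen_unusable(all_moved, misunderstanding = TRUE)$unusable)
})

test_that("categorisation: all three flags give high confidence, screening dominates", {
  ok <- list(unusable = FALSE, reasons = character(0))
  out <- list(unusable = TRUE, reasons = "unmoved sliders")
  expect_identical(categorize(ok, c(TRUE, TRUE, TRUE)), "usable_high_confidence")
  expect_identical(categorize(ok, c(TRUE, FALSE, TRUE)), "usable")
  expect_identical(categorize(out, c(TRUE, TRUE, TRUE)), "unusable")
})

test_that("dual review requires a resolved record when reviewers disagree", {
  resp <- make_panel(list(make_expert_rows("E1")))
  evals <- rbind(
    data.frame(expert_id = "E1", reviewer_id = "R1",
               engagement_evidence = TRUE, quant_qual_consistency = TRUE,
               cross_subgroup_consistency = TRUE, misunderstanding = FALSE,
               notes = ""),
    data.frame(expert_id = "E1", reviewer_id = "R2",
               engagement_evidence = TRUE, quant_qual_consistency = FALSE,
               cross_subgroup_consistency = TRUE, misunderstanding = FALSE,
               notes = ""))
  expect_error(evaluate_responses(resp, read_evaluations(evals)),
               class = "mnarsens_unresolved_review")
  resolved <- rbind(evals, resolved_eval("E1", c(TRUE, FALSE, TRUE)))
  cats <- evaluate_responses(resp, read_evaluations(resolved))
  expect_identical(cats$category, "usable")
})

test_that("category counts partition the panel", {
  pan <- generate_experts(expert_sim_config(n_experts = 30,
                                            fraction_unusable = 0.1,
                                            fraction_high_confidence = 0.4,
                                            seed = 3))
  cats <- evaluate_responses(pan$responses, pan$evaluations)
  tab <- table(cats$category)
  expect_equal(sum(tab), 30)
  expect_equal(unname(tab[["unusable"]]), 3)
  expect_equal(unname(tab[["usable_high_confidence"]]), 12)
})

test_that("delta translation shifts the elicited distribution and its bounds, preserving shape", {
  el <- split_normal(20, 3, 6, 0, 51)
  d <- delta_from_response(el, 15)
  expect_equal(d$mode, 5)
  expect_equal(c(d$lower, d$upper), c(-15, 36))
  x <- seq(-15, 36, length.out = 400)
  expect_equal(ddist(d, x), ddist(el, x + 15), tolerance = 1e-12)
  # anchor equal to the mode gives a zero-mode offset
  expect_equal(delta_from_response(split_normal(15, 2, 2, 0, 51), 15)$mode, 0)
  expect_error(delta_from_response(el, 60), class = "mnarsens_invalid_anchor")
})

test_that("per-expert joint prior honours subgroup weights and mixes linearly", {
  anch <- anchor_table("symptom_severity", 15, 13)
  rows <- make_expert_rows("E1")
  rows$mode <- rows$mode + rep(c(0, 3, 6), each = 2)  # distinct subgroup modes
  resp <- make_panel(list(rows))
  jA <- expert_joint_delta(resp, anch, subgroup_weights = c(A = 1, B = 0, C = 0))
  bA <- jA$components[[1]]
  rowA <- resp[resp$subgroup == "A" & resp$arm == "usual_care", ]
  expect_equal(bA$marginal_control$mode, rowA$mode - 15)
  expect_equal(jA$weights, c(1, 0, 0))
  # equal weights: the mixture mean per arm is the average of subgroup means
  j <- expert_joint_delta(resp, anch)
  per_sub <- sapply(j$components, dist_mean)
  expected <- rowMeans(per_sub)
  draws <- rdist(j, 2e5, seed = 4)
  se <- apply(draws, 2, sd) / sqrt(2e5)
  expect_lt(abs(mean(draws[, 1]) - expected[1]), 4 * se[1])
  expect_lt(abs(mean(draws[, 2]) - expected[2]), 4 * se[2])
  # missing arm triggers an incomplete-response signal
  expect_error(expert_joint_delta(resp[resp$arm == "usual_care", ], anch),
               class = "mnarsens_incomplete_response")
})

test_that("pooling is idempotent for a single expert and order-invariant", {
  anch <- anchor_table("symptom_severity", 15, 13)
  resp <- make_panel(list(make_expert_rows("E1", 22, 18),
                          make_expert_rows("E2", 12, 16, 2, 2),
                          make_expert_rows("E3", 30, 25, 4, 6)))
  cats <- data.frame(expert_id = c("E1", "E2", "E3"),
                     category = c("usable", "usable_high_confidence", "usable"))
  single <- pool_experts(resp[resp$expert_id == "E2", ], anch,
                         cats[cats$expert_id == "E2", ])
  own <- expert_joint_delta(resp[resp$expert_id == "E2", ], anch)
  pts <- cbind(runif(40, -15, 30), runif(40, -13, 30))
  expect_equal(ddist(single$joint, pts), ddist(own, pts), tolerance = 1e-12)

  pool_fwd <- pool_experts(resp, anch, cats)
  perm <- resp[order(rev(seq_len(nrow(resp)))), ]
  pool_rev <- pool_experts(perm, anch, cats)
  expect_equal(ddist(pool_fwd$joint, pts), ddist(pool_rev$joint, pts),
               tolerance = 1e-12)
  expect_identical(pool_fwd$provenance, "pooled-usable")
  expect_error(pool_experts(resp, anch,
                            data.frame(expert_id = "E1",
                                       category = "unusable"),
                            include = "usable_high_confidence"),
               class = "mnarsens_empty_pool")
})

test_that("pooling two disjoint-support experts gives a half-weight bimodal prior", {
  anch <- anchor_table("symptom_severity", 15, 15)
  lo <- split_normal(-10, 1, 1, -14, -6)
  hi <- split_normal(10, 1, 1, 6, 14)
  pool <- mixture_pool(list(lo, hi))
  expect_equal(pdist(pool, 0), 0.5, tolerance = 1e-10)
  expect_equal(ddist(pool, -10), 0.5 * ddist(lo, -10), tolerance = 1e-12)
})

test_that("a 23-expert high-confidence pool carries 23 equal weights", {
  pan <- generate_experts(expert_sim_config(n_experts = 59,
                                            fraction_unusable = 0.15,
                                            fraction_high_confidence = 23 / 59,
                                            seed = 10))
  cats <- evaluate_responses(pan$responses, pan$evaluations)
  anch <- anchor_table("symptom_severity", 15, 13)
  pool <- pool_experts(pan$responses, anch, cats,
                       include = "usable_high_confidence")
  expect_equal(length(pool$weights), 23)
  expect_equal(pool$weights, rep(1 / 23, 23))
})

test_that("probability the intervention is better: degenerate and symmetric cases", {
  anch_eq <- anchor_table("symptom_severity", 15, 15)
  ex <- bivariate_split_normal(split_normal(2, 2, 2, -15, 36),
                               split_normal(2, 2, 2, -15, 36), 0)
  p <- prob_intervention_better(ex, anch_eq, "lower_is_better", n = 1e5, seed = 1)
  expect_lt(abs(p - 0.5), 4 * sqrt(0.25 / 1e5))
  # point masses: intervention mean 5 vs control mean 10
  anch0 <- anchor_table("symptom_severity", 0, 0)
  pm <- bivariate_split_normal(point_mass(10), point_mass(5), 0)
  expect_equal(prob_intervention_better(pm, anch0, "lower_is_better"), 1)
  expect_equal(prob_intervention_better(pm, anch0, "higher_is_better"), 0)
  eq <- bivariate_split_normal(point_mass(7), point_mass(7), 0)
  expect_equal(prob_intervention_better(eq, anch0, "lower_is_better"), 0.5)
})

test_that("the favourable-direction probability is invariant to a common affine rescaling", {
  anch <- anchor_table("symptom_severity", 15, 13)
  b <- bivariate_split_normal(split_normal(4, 2, 3, -15, 36),
                              split_normal(1, 2, 4, -13, 38), 0.5)
  p1 <- prob_intervention_better(b, anch, "lower_is_better", n = 5e4, seed = 2)
  # multiply the whole presentation scale by 100
  scale100 <- function(d) split_normal(100 * d$mode, 100 * d$sd_left,
                                       100 * d$sd_right, 100 * d$lower,
                                       100 * d$upper)
  b100 <- bivariate_split_normal(scale100(b$marginal_control),
                                 scale100(b$marginal_intervention), 0.5)
  anch100 <- anchor_table("hrqol", 1500, 1300,
                          outcome_scale("big", 0, 5100))
  p2 <- prob_intervention_better(b100, anch100, "lower_is_better",
                                 n = 5e4, seed = 2)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("extreme-expert selection matches an independent quadrature ranking", {
  anch <- anchor_table("symptom_severity", 15, 13)
  specs <- list(
    make_expert_rows("E1", 20, 22, 2, 2),  # believes intervention worse
    make_expert_rows("E2", 20, 17, 2, 2),  # mildly favourable
    make_expert_rows("E3", 22, 12, 2, 2))  # strongly favourable
  resp <- make_panel(specs)
  resp$dependence <- 0
  cats <- data.frame(expert_id = c("E1", "E2", "E3"),
                     category = "usable_high_confidence")
  # oracle: with independent arms, P(13 + Di < 15 + Dc) by 1-D quadrature
  oracle <- sapply(c("E1", "E2", "E3"), function(id) {
    rows <- resp[resp$expert_id == id & resp$subgroup == "A", ]
    dc <- delta_from_response(split_normal(rows$mode[rows$arm == "usual_care"],
                                           2, 2, 0, 51), 15)
    di <- delta_from_response(split_normal(rows$mode[rows$arm == "intervention"],
                                           2, 2, 0, 51), 13)
    integrate(function(y) ddist(di, y) * (1 - pdist(dc, y - 2)),
              di$lower, di$upper, rel.tol = 1e-10)$value
  })
  sel <- select_extremes(resp, anch, cats, "lower_is_better",
                         n = 2e4, seed = 1)
  expect_identical(sel$sceptical, names(which.min(oracle)))
  expect_identical(sel$enthusiastic, names(which.max(oracle)))
  expect_lt(max(abs(sel$probabilities - oracle)),
            3 * sqrt(0.25 / 2e4) + 1e-3)
  # ties broken lexicographically by expert id
  same <- make_panel(list(make_expert_rows("B2"), make_expert_rows("A1"),
                          make_expert_rows("C3")))
  cats2 <- data.frame(expert_id = c("A1", "B2", "C3"),
                      category = "usable_high_confidence")
  tie <- select_extremes(same, anch, cats2, "lower_is_better",
                         n = 1e4, seed = 1)
  expect_identical(tie$sceptical, "A1")
  expect_identical(tie$enthusiastic, "A1")
  expect_error(select_extremes(resp, anch, cats[1, , drop = FALSE]),
               class = "mnarsens_insufficient_experts")
})
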