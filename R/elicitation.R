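#' Read and validate elicitation responses
#'
#' Responses are stored long, one row per expert x outcome x arm x
#' subgroup, with the three slider values of the elicited (truncated)
#' split normal and a moved/unmoved flag per slider.  Mandatory columns:
#' `expert_id, outcome, arm, subgroup, mode, sd_left, sd_right,
#' moved_mode, moved_left, moved_right`.  Optional columns carried
#' through if present: `dependence` (the expert's answer about the
#' relationship between the two arms), `rationale` (free text), `job`,
#' `years_in_role`, `trial_site`.
#'
#' Validation is row-level: slider modes must lie within the outcome's
#' presentation-scale bounds and sds must be positive; violations are
#' reported naming the row and field.
#'
#' @param path CSV file path (or a data frame already in memory).
#' @param scales Named list of [outcome_scale()] objects keyed by the
#'   values of the `outcome` column; default the two study scales.
#' @param arms,subgroups Allowed factor levels.
#' @return A validated data frame of class `elicitation_responses`.
#' @export
read_responses <- function(path,
                           scales = list(symptom_severity = pss_scale(),
                                         hrqol = hrqol_scale()),
                           arms = c("usual_care", "intervention"),
                           subgroups = c("A", "B", "C")) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("expert_id", "outcome", "arm", "subgroup",
                 "mode", "sd_left", "sd_right",
                 "moved_mode", "moved_left", "moved_right")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    abort_mnar(paste("response table missing mandatory columns:",
                     paste(missing_cols, collapse = ", ")),
               "mnarsens_schema_violation")
  }
  problems <- character(0)
  note <- function(row, field, msg) {
    problems <<- c(problems, sprintf("row %d, %s: %s", row, field, msg))
  }
  for (i in seq_len(nrow(df))) {
    out <- df$outcome[i]
    if (!out %in% names(scales)) {
      note(i, "outcome", sprintf("unknown outcome '%s'", out)); next
    }
    sc <- scales[[out]]
    if (!df$arm[i] %in% arms) note(i, "arm", sprintf("unknown arm '%s'", df$arm[i]))
    if (!df$subgroup[i] %in% subgroups) {
      note(i, "subgroup", sprintf("unknown subgroup '%s'", df$subgroup[i]))
    }
    if (!is.finite(df$mode[i]) || df$mode[i] < sc$lower || df$mode[i] > sc$upper) {
      note(i, "mode", sprintf("value %s outside [%g, %g]",
                              format(df$mode[i]), sc$lower, sc$upper))
    }
    for (f in c("sd_left", "sd_right")) {
      if (!is.finite(df[[f]][i]) || df[[f]][i] <= 0) {
        note(i, f, sprintf("value %s is not a positive sd", format(df[[f]][i])))
      }
    }
  }
  if (length(problems)) {
    abort_mnar(paste0("invalid elicitation responses:\n  ",
                      paste(problems, collapse = "\n  ")),
               "mnarsens_schema_violation")
  }
  for (f in c("moved_mode", "moved_left", "moved_right")) {
    df[[f]] <- as.logical(df[[f]])
  }
  class(df) <- c("elicitation_responses", class(df))
  df
}

#' Read reviewer evaluation records
#'
#' One row per expert x reviewer with the three confidence flags
#' (`engagement_evidence`, `quant_qual_consistency`,
#' `cross_subgroup_consistency`), a `misunderstanding` flag from the
#' free-text review, and `notes`.  Dual review is represented by two
#' reviewer rows per expert plus, where the reviewers disagreed, a row
#' with `reviewer_id == "resolved"` recording the discussed resolution.
#'
#' @param path CSV file path (or data frame).
#' @return A validated data frame of class `evaluation_records`.
#' @export
read_evaluations <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("expert_id", "reviewer_id", "engagement_evidence",
                 "quant_qual_consistency", "cross_subgroup_consistency")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    abort_mnar(paste("evaluation table missing mandatory columns:",
                     paste(missing_cols, collapse = ", ")),
               "mnarsens_schema_violation")
  }
  for (f in c("engagement_evidence", "quant_qual_consistency",
              "cross_subgroup_consistency")) {
    df[[f]] <- as.logical(df[[f]])
  }
  if (!"misunderstanding" %in% names(df)) df$misunderstanding <- FALSE
  df$misunderstanding <- as.logical(df$misunderstanding)
  class(df) <- c("evaluation_records", class(df))
  df
}

#' Screen a response for evidence the task was misunderstood
#'
#' A response is screened out as unusable when the fraction of sliders
#' the expert actually moved falls strictly below `min_moved_fraction`
#' (default 0.5), or when a reviewer has flagged free-text evidence of
#' misunderstanding.  A response exactly at the threshold is kept.
#'
#' @param response_rows Rows of an [read_responses()] table for one
#'   expert (and one outcome).
#' @param min_moved_fraction Threshold on the moved-slider fraction.
#' @param misunderstanding Reviewer-entered flag from the free-text
#'   answers.
#' @return A list with elements `unusable` (logical) and `reasons`
#'   (character vector, possibly empty).
#' @export
screen_unusable <- function(response_rows, min_moved_fraction = 0.5,
                            misunderstanding = FALSE) {
  moved <- c(response_rows$moved_mode, response_rows$moved_left,
             response_rows$moved_right)
  frac <- mean(moved)
  reasons <- character(0)
  if (frac < min_moved_fraction) {
    reasons <- c(reasons, sprintf(
      "unmoved sliders: only %.0f%% of sliders moved (threshold %.0f%%)",
      100 * frac, 100 * min_moved_fraction))
  }
  if (isTRUE(misunderstanding)) {
    reasons <- c(reasons, "free-text answers indicate misunderstanding")
  }
  list(unusable = length(reasons) > 0, reasons = reasons)
}

#' Categorise a screened response
#'
#' Implements the evaluation workflow: a screened-out response is
#' `unusable` regardless of reviewer flags; otherwise the response is
#' `usable_high_confidence` iff all three reviewer flags (engagement
#' evidence, quantitative/qualitative consistency, cross-subgroup
#' consistency) are true, and plain `usable` otherwise.
#'
#' @param screen Result of [screen_unusable()].
#' @param flags Logical vector (length 3) or one resolved row of an
#'   [read_evaluations()] table.
#' @return One of `"unusable"`, `"usable"`, `"usable_high_confidence"`.
#' @export
categorize <- function(screen, flags) {
  if (isTRUE(screen$unusable)) return("unusable")
  if (is.data.frame(flags)) {
    flags <- c(flags$engagement_evidence[1], flags$quant_qual_consistency[1],
               flags$cross_subgroup_consistency[1])
  }
  if (length(flags) != 3L || any(is.na(flags))) {
    abort_mnar("three reviewer flags are required", "mnarsens_invalid_argument")
  }
  if (all(flags)) "usable_high_confidence" else "usable"
}

#' Evaluate all experts: screening plus dual-review reconciliation
#'
#' For each expert the screening rule is applied to their response rows
#' and the reviewer flags are taken from the resolved evaluation record.
#' When two reviewers' categorisations of an expert disagree and no
#' `reviewer_id == "resolved"` row is present, an unresolved-review
#' error is signalled.
#'
#' @param responses An [read_responses()] table.
#' @param evaluations An [read_evaluations()] table.
#' @inheritParams screen_unusable
#' @return Data frame with columns `expert_id`, `category`, `reasons`.
#' @export
evaluate_responses <- function(responses, evaluations,
                               min_moved_fraction = 0.5) {
  ids <- unique(responses$expert_id)
  rows <- lapply(ids, function(id) {
    rr <- responses[responses$expert_id == id, , drop = FALSE]
    ee <- evaluations[evaluations$expert_id == id, , drop = FALSE]
    if (nrow(ee) == 0L) {
      abort_mnar(sprintf("expert '%s' has no evaluation record", id),
                 "mnarsens_schema_violation")
    }
    resolved <- ee[ee$reviewer_id == "resolved", , drop = FALSE]
    if (nrow(resolved) == 0L) {
      cats <- apply(ee[, c("engagement_evidence", "quant_qual_consistency",
                           "cross_subgroup_consistency", "misunderstanding")],
                    1, paste, collapse = "|")
      if (length(unique(cats)) > 1L) {
        abort_mnar(sprintf(
          "expert '%s': reviewers disagree and no resolved record is present", id),
          "mnarsens_unresolved_review")
      }
      resolved <- ee[1, , drop = FALSE]
    }
    sc <- screen_unusable(rr, min_moved_fraction,
                          misunderstanding = isTRUE(resolved$misunderstanding[1]))
    data.frame(expert_id = id,
               category = categorize(sc, resolved),
               reasons = paste(sc$reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Responder-mean anchors
#'
#' The anchor is the mean observed outcome among questionnaire
#' completers for an arm, shown to experts as the vertical arrow on the
#' elicitation scale.  `anchor_table()` builds the table explicitly;
#' `compute_anchors()` derives it from a trial table as a convenience.
#'
#' @param outcome Outcome name (e.g. `"symptom_severity"`).
#' @param usual_care,intervention Responder means per arm on the
#'   presentation scale.
#' @param scale The [outcome_scale()]; anchors must lie within it.
#' @return Data frame with columns `outcome`, `arm`, `responder_mean`.
#' @export
anchor_table <- function(outcome, usual_care, intervention,
                         scale = pss_scale()) {
  for (v in c(usual_care, intervention)) {
    if (v < scale$lower || v > scale$upper) {
      abort_mnar(sprintf("anchor %g outside scale bounds [%g, %g]",
                         v, scale$lower, scale$upper),
                 "mnarsens_invalid_anchor")
    }
  }
  data.frame(outcome = outcome,
             arm = c("usual_care", "intervention"),
             responder_mean = c(usual_care, intervention),
             stringsAsFactors = FALSE)
}

#' @rdname anchor_table
#' @param trial_data A trial data frame with `arm` and `outcome` columns
#'   (missing outcomes `NA`).
#' @export
compute_anchors <- function(trial_data, outcome = "symptom_severity",
                            scale = pss_scale()) {
  means <- tapply(trial_data$outcome, trial_data$arm, mean, na.rm = TRUE)
  anchor_table(outcome, means[["usual_care"]], means[["intervention"]], scale)
}

anchor_for <- function(anchors, arm) {
  v <- anchors$responder_mean[anchors$arm == arm]
  if (length(v) != 1L) {
    abort_mnar(sprintf("anchors must contain exactly one row for arm '%s'", arm),
               "mnarsens_invalid_anchor")
  }
  v
}

#' Translate an elicited distribution to the sensitivity-offset scale
#'
#' The sensitivity parameter Delta is the difference between the mean
#' outcome of non-responders and the responder-mean anchor, so the
#' elicited distribution is shifted by minus the anchor, and its
#' truncation bounds shift with it: outcome bounds \[0, 51\] with anchor
#' 15 give Delta support \[-15, 36\].  The shape is preserved exactly.
#'
#' @param elicited A [split_normal()] on the outcome presentation scale.
#' @param anchor The arm's responder mean (scalar) or an
#'   [anchor_table()] row set together with `arm`.
#' @param arm Arm label when `anchor` is a table.
#' @return A [split_normal()] over Delta.
#' @examples
#' delta_from_response(split_normal(20, 3, 6, 0, 51), 15)  # mode 5
#' @export
delta_from_response <- function(elicited, anchor, arm = NULL) {
  if (is.data.frame(anchor)) anchor <- anchor_for(anchor, arm)
  check_number(anchor, "anchor")
  if (anchor < elicited$lower || anchor > elicited$upper) {
    abort_mnar("anchor lies outside the elicited distribution's bounds",
               "mnarsens_invalid_anchor")
  }
  split_normal(elicited$mode - anchor, elicited$sd_left, elicited$sd_right,
               elicited$lower - anchor, elicited$upper - anchor)
}

response_dist <- function(row, scale) {
  split_normal(row$mode, row$sd_left, row$sd_right, scale$lower, scale$upper)
}

#' Per-expert joint Delta prior
#'
#' Builds one expert's joint prior over (Delta_control,
#' Delta_intervention): per subgroup, the two arms' elicited
#' distributions are translated to the Delta scale and coupled through
#' the expert's between-arm dependence; the three subgroups are then
#' combined as a mixture with configurable weights (equal by default).
#'
#' @param response_rows Rows of a [read_responses()] table for one
#'   expert and one outcome (both arms present for each subgroup).
#' @param anchors An [anchor_table()] for the outcome.
#' @param scale The [outcome_scale()].
#' @param subgroup_weights Named or ordered weights over subgroups
#'   (default equal).
#' @param dependence Between-arm coupling used when the response has no
#'   `dependence` column; default 0.5.
#' @return A [mixture_pool()] of [bivariate_split_normal()] components
#'   (a single bivariate when only one subgroup has weight).
#' @export
expert_joint_delta <- function(response_rows, anchors, scale = pss_scale(),
                               subgroup_weights = NULL, dependence = 0.5) {
  sg <- sort(unique(response_rows$subgroup))
  if (!is.null(response_rows$dependence) &&
      any(is.finite(response_rows$dependence))) {
    dependence <- response_rows$dependence[is.finite(response_rows$dependence)][1]
  }
  comps <- lapply(sg, function(s) {
    rows <- response_rows[response_rows$subgroup == s, , drop = FALSE]
    per_arm <- lapply(c("usual_care", "intervention"), function(a) {
      r <- rows[rows$arm == a, , drop = FALSE]
      if (nrow(r) != 1L) {
        abort_mnar(sprintf(
          "expert '%s', subgroup %s: expected one row for arm '%s'",
          rows$expert_id[1], s, a), "mnarsens_incomplete_response")
      }
      delta_from_response(response_dist(r, scale), anchors, a)
    })
    bivariate_split_normal(per_arm[[1]], per_arm[[2]], dependence)
  })
  if (is.null(subgroup_weights)) subgroup_weights <- rep(1, length(sg))
  if (!is.null(names(subgroup_weights))) subgroup_weights <- subgroup_weights[sg]
  mixture_pool(comps, unname(subgroup_weights))
}

#' Pool experts' joint Delta priors by equal-weight linear pooling
#'
#' The pooled prior is the equal-weight mixture of the per-expert joint
#' Delta priors of every expert in the selected category filter —
#' linear pooling on the distribution scale with each expert weighted
#' equally.  Provenance (which pool, which experts) is recorded.
#'
#' @param responses An [read_responses()] table.
#' @param anchors An [anchor_table()].
#' @param categories An [evaluate_responses()] table (or a data frame
#'   with `expert_id` and `category`).
#' @param include Categories to pool over: `"usable"` pools usable plus
#'   high-confidence experts (the paper's "usable" pool);
#'   `"usable_high_confidence"` restricts to the high-confidence group.
#' @inheritParams expert_joint_delta
#' @return An object of class `delta_prior`: list with `joint` (mixture
#'   over experts), `experts`, `weights`, `provenance`.
#' @export
pool_experts <- function(responses, anchors, categories,
                         include = c("usable", "usable_high_confidence"),
                         scale = pss_scale(), subgroup_weights = NULL,
                         dependence = 0.5) {
  include <- match.arg(include)
  keep <- if (include == "usable") {
    categories$category %in% c("usable", "usable_high_confidence")
  } else {
    categories$category == "usable_high_confidence"
  }
  ids <- sort(categories$expert_id[keep])
  if (length(ids) == 0L) {
    abort_mnar("no experts in the requested pool", "mnarsens_empty_pool")
  }
  joints <- lapply(ids, function(id) {
    expert_joint_delta(responses[responses$expert_id == id, , drop = FALSE],
                       anchors, scale, subgroup_weights, dependence)
  })
  pooled <- mixture_pool(joints)
  structure(list(joint = pooled, experts = ids, weights = pooled$weights,
                 provenance = if (include == "usable") "pooled-usable"
                              else "pooled-high-confidence"),
            class = "delta_prior")
}

#' Single-expert Delta prior
#'
#' @param expert_id The expert whose joint prior is wanted.
#' @inheritParams pool_experts
#' @return A `delta_prior` with single-expert provenance.
#' @export
single_expert_prior <- function(responses, anchors, expert_id,
                                scale = pss_scale(), subgroup_weights = NULL,
                                dependence = 0.5) {
  rows <- responses[responses$expert_id == expert_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    abort_mnar(sprintf("no responses for expert '%s'", expert_id),
               "mnarsens_empty_pool")
  }
  joint <- expert_joint_delta(rows, anchors, scale, subgroup_weights, dependence)
  structure(list(joint = joint, experts = expert_id, weights = 1,
                 provenance = paste0("single-expert:", expert_id)),
            class = "delta_prior")
}

#' @export
print.delta_prior <- function(x, ...) {
  cat(sprintf("delta prior [%s] over %d expert%s\n", x$provenance,
              length(x$experts), if (length(x$experts) == 1L) "" else "s"))
  invisible(x)
}

#' Probability that the intervention's non-responder mean is better
#'
#' Under a joint prior over (Delta_control, Delta_intervention) combined
#' with the arm anchors, the non-responder mean for an arm is
#' anchor + Delta.  This returns the Monte-Carlo probability that the
#' intervention arm's non-responder mean is on the favourable side
#' (lower for symptom severity, higher for quality of life).  Exact
#' ties (point-mass priors with equal means) contribute probability
#' one half.
#'
#' @param joint A bivariate distribution or mixture over
#'   (Delta_control, Delta_intervention), or a `delta_prior`.
#' @param anchors An [anchor_table()].
#' @param direction `"lower_is_better"` or `"higher_is_better"`.
#' @param n Monte-Carlo sample size.
#' @param seed Seed for reproducibility.
#' @return Probability in \[0, 1\].
#' @export
prob_intervention_better <- function(joint, anchors,
                                     direction = c("lower_is_better",
                                                   "higher_is_better"),
                                     n = 1e5, seed = 1) {
  direction <- match.arg(direction)
  if (inherits(joint, "delta_prior")) joint <- joint$joint
  if (!inherits(joint, "dist2d")) {
    abort_mnar("`joint` must be a bivariate distribution over the two arms",
               "mnarsens_invalid_argument")
  }
  draws <- rdist(joint, n, seed = seed)
  m_ctl <- anchor_for(anchors, "usual_care") + draws[, 1]
  m_int <- anchor_for(anchors, "intervention") + draws[, 2]
  if (direction == "lower_is_better") {
    mean(m_int < m_ctl) + 0.5 * mean(m_int == m_ctl)
  } else {
    mean(m_int > m_ctl) + 0.5 * mean(m_int == m_ctl)
  }
}

#' Select the most sceptical and most enthusiastic experts
#'
#' Among the high-confidence experts, the most sceptical (lowest) and
#' most enthusiastic (highest) probability that the mean outcome is
#' better under the intervention.  Ties are broken deterministically by
#' lexicographic expert id.
#'
#' @inheritParams pool_experts
#' @inheritParams prob_intervention_better
#' @return List with `sceptical`, `enthusiastic` (expert ids) and
#'   `probabilities` (named vector over eligible experts).
#' @export
select_extremes <- function(responses, anchors, categories,
                            direction = c("lower_is_better",
                                          "higher_is_better"),
                            scale = pss_scale(), subgroup_weights = NULL,
                            dependence = 0.5, n = 1e5, seed = 1) {
  direction <- match.arg(direction)
  ids <- sort(categories$expert_id[categories$category == "usable_high_confidence"])
  if (length(ids) < 2L) {
    abort_mnar("at least two high-confidence experts are required",
               "mnarsens_insufficient_experts")
  }
  probs <- vapply(ids, function(id) {
    joint <- expert_joint_delta(responses[responses$expert_id == id, ,
                                          drop = FALSE],
                                anchors, scale, subgroup_weights, dependence)
    prob_intervention_better(joint, anchors, direction, n = n, seed = seed)
  }, numeric(1))
  names(probs) <- ids
  # ids are sorted, so which.min/which.max break ties by lexicographic id
  list(sceptical = ids[which.min(probs)],
       enthusiastic = ids[which.max(probs)],
       probabilities = probs)
}
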