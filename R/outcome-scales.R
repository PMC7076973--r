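#' Outcome scales presented to experts
#'
#' An outcome scale records the bounds of the presentation scale used in
#' the elicitation, the multiplier from the analysis scale to the
#' presentation scale, and (optionally) labelled severity bands drawn
#' under the slider axis.  Two scales are built in:
#'
#' * [pss_scale()] — PTSD Symptom Scale, Self Report total (PSS-SR),
#'   range 0 to 51, higher is worse, with the published severity bands
#'   none (0), mild (1-10), moderate (11-20), moderate to severe (21-35)
#'   and severe (36-51).
#' * [hrqol_scale()] — EQ-5D-5L utility index, anchored at -0.28 and 1
#'   on the analysis scale and multiplied by 100 for presentation
#'   (so -28 to 100), higher is better.
#'
#' @param name Scale name.
#' @param lower,upper Bounds on the presentation scale.
#' @param presentation_multiplier Factor from analysis to presentation
#'   scale (1 for PSS-SR, 100 for the utility index).
#' @param severity_bands Optional data frame with columns `label`,
#'   `lower`, `upper` describing contiguous, non-overlapping intervals
#'   `(lower, upper]` that cover `(scale lower, scale upper]`.
#' @param direction `"lower_is_better"` or `"higher_is_better"`.
#' @return An object of class `"outcome_scale"`.
#' @export
outcome_scale <- function(name, lower, upper, presentation_multiplier = 1,
                          severity_bands = NULL,
                          direction = c("lower_is_better", "higher_is_better")) {
  check_number(lower, "lower"); check_number(upper, "upper")
  if (lower >= upper) {
    abort_mnar("scale lower bound must be below upper bound",
               "mnarsens_invalid_parameter")
  }
  direction <- match.arg(direction)
  if (!is.null(severity_bands)) {
    b <- severity_bands[order(severity_bands$lower), ]
    contiguous <- all(abs(b$upper[-nrow(b)] - b$lower[-1]) < 1e-9) &&
      abs(b$lower[1] - lower) < 1e-9 && abs(b$upper[nrow(b)] - upper) < 1e-9
    if (!contiguous) {
      abort_mnar("severity bands must be contiguous and cover the scale",
                 "mnarsens_invalid_parameter")
    }
    severity_bands <- b
  }
  structure(list(name = name, lower = lower, upper = upper,
                 presentation_multiplier = presentation_multiplier,
                 severity_bands = severity_bands, direction = direction),
            class = "outcome_scale")
}

#' @rdname outcome_scale
#' @export
pss_scale <- function() {
  outcome_scale(
    "symptom_severity", 0, 51, 1,
    severity_bands = data.frame(
      label = c("mild", "moderate", "moderate to severe", "severe"),
      lower = c(0, 10, 20, 35),
      upper = c(10, 20, 35, 51)
    ),
    direction = "lower_is_better"
  )
}

#' @rdname outcome_scale
#' @export
hrqol_scale <- function() {
  outcome_scale("hrqol", -28, 100, 100, direction = "higher_is_better")
}

#' Severity band containing a PSS-SR score
#'
#' Returns the label of the published severity category: 0 is "none",
#' then mild (1-10), moderate (11-20), moderate to severe (21-35) and
#' severe (36-51).  Integer edge scores belong to the printed integer
#' ranges; non-integer scores are assigned by the covering half-open
#' interval `(lower, upper]`.
#'
#' @param score Numeric vector of scores in \[0, 51\].
#' @param scale An [outcome_scale()] with severity bands;
#'   default [pss_scale()].
#' @return Character vector of band labels.
#' @examples
#' severity_band(c(0, 15, 40))
#' @export
severity_band <- function(score, scale = pss_scale()) {
  if (is.null(scale$severity_bands)) {
    abort_mnar("scale has no severity bands", "mnarsens_invalid_argument")
  }
  if (any(!is.finite(score)) || any(score < scale$lower | score > scale$upper)) {
    abort_mnar(sprintf("scores must lie within [%g, %g]",
                       scale$lower, scale$upper),
               "mnarsens_invalid_score")
  }
  b <- scale$severity_bands
  vapply(score, function(s) {
    if (s == scale$lower) return("none")
    b$label[which(s > b$lower & s <= b$upper)[1]]
  }, character(1))
}

#' EQ-5D-5L health state and utility index
#'
#' `health_state()` records a five-dimension, five-level EQ-5D-5L
#' descriptive-system state (mobility, self-care, usual activities,
#' pain/discomfort, anxiety/depression; level 1 = no problems, level 5 =
#' extreme problems).  `eq5d_index()` scores it with a population value
#' set: utility = intercept minus the per-dimension level decrements,
#' presented on the x100 scale used in the elicitation (so full health
#' scores 100 and the all-moderate state 3,3,3,3,3 displays 62 with the
#' packaged value set).
#'
#' The packaged default value set
#' (`eq5d_value_set("uk_synthetic")`) is a synthetic UK-style table:
#' the exact published tariff is not redistributable, so the table is
#' constructed to be monotone within each dimension and calibrated to
#' the documented anchors (full health 1, worst state -0.28, all-moderate
#' 0.615).  Any value-set CSV with columns `dimension, level, decrement`
#' plus an `intercept` row can be supplied instead.
#'
#' @param mobility,self_care,usual_activities,pain_discomfort,anxiety_depression
#'   Integer levels in 1..5.
#' @param state A `health_state` object (or integer vector of 5 levels).
#' @param value_set A value-set table from [eq5d_value_set()].
#' @param display If `TRUE` (default) round to the nearest integer on the
#'   presentation scale, as shown by the elicitation tool; if `FALSE`
#'   return full precision.
#' @return `eq5d_index()`: the utility score on the x100 presentation
#'   scale.
#' @examples
#' eq5d_index(health_state(3, 3, 3, 3, 3))          # 62
#' eq5d_index(health_state(1, 1, 1, 1, 1))          # 100
#' @export
health_state <- function(mobility, self_care, usual_activities,
                         pain_discomfort, anxiety_depression) {
  lv <- c(mobility = mobility, self_care = self_care,
          usual_activities = usual_activities,
          pain_discomfort = pain_discomfort,
          anxiety_depression = anxiety_depression)
  if (any(lv != round(lv)) || any(lv < 1 | lv > 5)) {
    abort_mnar("every dimension level must be an integer in 1..5",
               "mnarsens_invalid_parameter")
  }
  structure(as.integer(lv), names = names(lv), class = "health_state")
}

eq5d_dimensions <- c("mobility", "self_care", "usual_activities",
                     "pain_discomfort", "anxiety_depression")

#' @rdname health_state
#' @param name Name of a packaged value set (`"uk_synthetic"`) or a path
#'   to a value-set CSV.
#' @export
eq5d_value_set <- function(name = "uk_synthetic") {
  path <- if (file.exists(name)) {
    name
  } else if (name == "uk_synthetic") {
    system.file("extdata", "eq5d5l_value_set_uk_synthetic.csv",
                package = "mnarsens", mustWork = TRUE)
  } else {
    abort_mnar(sprintf("unknown value set '%s' (not packaged, not a file)",
                       name), "mnarsens_configuration")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dimension", "level", "decrement")
  if (!all(need %in% names(tab))) {
    abort_mnar("value-set CSV needs columns dimension, level, decrement",
               "mnarsens_schema_violation")
  }
  if (!"intercept" %in% tab$dimension) {
    abort_mnar("value-set CSV needs an intercept row", "mnarsens_schema_violation")
  }
  missing_dims <- setdiff(eq5d_dimensions, tab$dimension)
  if (length(missing_dims)) {
    abort_mnar(paste("value set missing dimensions:",
                     paste(missing_dims, collapse = ", ")),
               "mnarsens_schema_violation")
  }
  attr(tab, "value_set_name") <- if (name == "uk_synthetic") name else basename(path)
  tab
}

#' @rdname health_state
#' @export
eq5d_index <- function(state, value_set = eq5d_value_set(), display = TRUE) {
  if (!inherits(state, "health_state")) {
    state <- do.call(health_state, unname(as.list(state)))
  }
  intercept <- value_set$decrement[value_set$dimension == "intercept"][1]
  dec <- vapply(eq5d_dimensions, function(dim) {
    row <- value_set$dimension == dim & value_set$level == state[[dim]]
    if (!any(row)) {
      abort_mnar(sprintf("value set has no entry for %s level %d",
                         dim, state[[dim]]), "mnarsens_configuration")
    }
    value_set$decrement[row][1]
  }, numeric(1))
  utility <- (intercept - sum(dec)) * 100  # x100 presentation scale
  if (display) round(utility) else utility
}
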