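#' Serialise distributions to and from plain JSON records
#'
#' Distribution parameter sets are exchanged as plain lists/JSON with
#' keys `mode`, `sd_left`, `sd_right`, `lower`, `upper` (split normal),
#' `value` (point mass), `dependence` plus the two marginals (bivariate)
#' and `{weights, components}` (mixtures).  Infinite bounds are encoded
#' as the strings `"-Inf"`/`"Inf"` so the JSON stays portable.
#'
#' @param d A distribution object.
#' @param record A list as produced by `dist_to_record()` (e.g. parsed
#'   from JSON).
#' @return `dist_to_record()` a plain list; `dist_from_record()` the
#'   distribution object.
#' @examples
#' rec <- dist_to_record(split_normal(10, 2, 5, 0, 51))
#' identical_pdf <- ddist(dist_from_record(rec), 10)
#' @export
dist_to_record <- function(d) {
  if (inherits(d, "split_normal")) {
    list(type = "split_normal", mode = d$mode,
         sd_left = d$sd_left, sd_right = d$sd_right,
         lower = encode_bound(d$lower), upper = encode_bound(d$upper))
  } else if (inherits(d, "point_mass")) {
    list(type = "point_mass", value = d$value)
  } else if (inherits(d, "bivariate_split_normal")) {
    list(type = "bivariate_split_normal",
         dependence = d$dependence,
         marginal_control = dist_to_record(d$marginal_control),
         marginal_intervention = dist_to_record(d$marginal_intervention))
  } else if (inherits(d, "mixture_dist")) {
    list(type = "mixture", weights = d$weights,
         components = lapply(d$components, dist_to_record))
  } else {
    abort_mnar("unknown distribution class", "mnarsens_invalid_argument")
  }
}

#' @rdname dist_to_record
#' @export
dist_from_record <- function(record) {
  if (is.null(record$type)) {
    abort_mnar("record has no `type` field", "mnarsens_schema_violation")
  }
  switch(record$type,
    split_normal = split_normal(record$mode, record$sd_left, record$sd_right,
                                decode_bound(record$lower, -Inf),
                                decode_bound(record$upper, Inf)),
    point_mass = point_mass(record$value),
    bivariate_split_normal = bivariate_split_normal(
      dist_from_record(record$marginal_control),
      dist_from_record(record$marginal_intervention),
      record$dependence),
    mixture = mixture_pool(lapply(record$components, dist_from_record),
                           unlist(record$weights)),
    abort_mnar(sprintf("unknown distribution type '%s'", record$type),
               "mnarsens_schema_violation")
  )
}

encode_bound <- function(x) if (is.finite(x)) x else as.character(x)

decode_bound <- function(x, default) {
  if (is.null(x)) return(default)
  if (is.character(x)) return(as.numeric(x))
  x
}
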