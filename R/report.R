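#' Run configuration
#'
#' A run configuration collects file paths, outcome/direction, the
#' scenario list and fit settings for the command-style entry points
#' [cmd_simulate()] and [cmd_analyse()].  It can be read from JSON;
#' unspecified fields fall back to documented defaults and every
#' default actually applied is recorded in the run log.
#'
#' @param path Path to a JSON run configuration.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort_mnar(sprintf("run configuration '%s' not found", path),
               "mnarsens_io")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

## 32-bit polynomial rolling hash of the canonical JSON of a config;
## embedded in outputs so a re-run of the same configuration is
## recognisable (provenance tag, not cryptographic)
config_hash <- function(config) {
  config$outdir <- NULL  # the same analysis in another directory is the same run
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

apply_defaults <- function(config, defaults, log) {
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
      log(sprintf("default applied: %s = %s", nm,
                  paste(format(unlist(defaults[[nm]])), collapse = ", ")))
    }
  }
  config
}

make_logger <- function(outdir) {
  logfile <- file.path(outdir, "run.log")
  function(msg) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
        file = logfile, append = TRUE)
  }
}

#' Simulate a trial and expert panel to files
#'
#' Writes `trial.csv`, `responses.csv`, `evaluations.csv` and the two
#' truth sidecars (`trial_truth.json`, `experts_truth.json`) to the
#' output directory, in exactly the schemas consumed by
#' [cmd_analyse()].  Re-running with the same configuration reproduces
#' every file byte-for-byte.
#'
#' @param config A named list (or path to a JSON file) with optional
#'   fields `seed`, `outdir`, `trial` (overrides for
#'   [trial_sim_config()]) and `experts` (overrides for
#'   [expert_sim_config()]).
#' @return Invisibly, the vector of files written.
#' @export
cmd_simulate <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$outdir %||% "."
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    abort_mnar(sprintf("cannot create output directory '%s'", outdir),
               "mnarsens_io")
  }
  log <- make_logger(outdir)
  config <- apply_defaults(config, list(seed = 1), log)
  log(sprintf("simulate: config hash %s, seed %d",
              config_hash(config), config$seed))

  trial_cfg <- do.call(trial_sim_config,
                       c(config$trial, list(seed = config$seed)))
  trial <- generate_trial(trial_cfg)
  anchors <- compute_anchors(trial$data, scale = trial_cfg$scale)
  expert_args <- config$experts
  if (is.null(expert_args$truth)) {
    # default synthetic truth: non-responders somewhat worse than responders
    expert_args$truth <- c(usual_care = anchors$responder_mean[1] + 5,
                           intervention = anchors$responder_mean[2] + 3)
    log("default applied: experts$truth = responder means + (5, 3)")
  }
  expert_cfg <- do.call(expert_sim_config,
                        c(expert_args, list(seed = config$seed + 1L)))
  panel <- generate_experts(expert_cfg, anchors, trial_cfg$scale)

  files <- file.path(outdir, c("trial.csv", "responses.csv",
                               "evaluations.csv", "anchors.csv",
                               "trial_truth.json", "experts_truth.json"))
  utils::write.csv(trial$data, files[1], row.names = FALSE)
  utils::write.csv(as.data.frame(panel$responses), files[2], row.names = FALSE)
  utils::write.csv(as.data.frame(panel$evaluations), files[3], row.names = FALSE)
  utils::write.csv(anchors, files[4], row.names = FALSE)
  trial$truth$config_hash <- config_hash(config)
  panel$truth$config_hash <- config_hash(config)
  jsonlite::write_json(trial$truth, files[5], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  jsonlite::write_json(panel$truth, files[6], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  log(sprintf("simulate: wrote %d files to %s", length(files), outdir))
  invisible(files)
}

#' Run the full sensitivity analysis from files
#'
#' Reads the trial table, responses, evaluations and anchors; screens
#' and categorises the experts; builds the pooled (usable and
#' high-confidence) and extreme-expert priors; runs the scenario set
#' against the complete-case and missing-at-random references; and
#' writes `scenarios.csv`, `summary.json` and one density-strip figure
#' per scenario.
#'
#' @param config A named list (or JSON path): `trial`, `responses`,
#'   `evaluations`, `anchors` file paths, plus optional `outdir`,
#'   `seed`, `outcome`, `direction`, `dependence`, `fit` (overrides for
#'   [fit_config()]) and `scenarios` (subset of the six standard
#'   labels).
#' @return Invisibly, the [run_scenarios()] result.
#' @export
cmd_analyse <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  for (f in c("trial", "responses", "evaluations", "anchors")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      abort_mnar(sprintf("input file for '%s' is missing", f), "mnarsens_io")
    }
  }
  outdir <- config$outdir %||% "."
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log <- make_logger(outdir)
  config <- apply_defaults(config, list(
    seed = 1, outcome = "symptom_severity", direction = "lower_is_better",
    dependence = 0.5,
    scenarios = c("complete_case", "MAR", "pooled_usable",
                  "pooled_high_confidence", "most_sceptical",
                  "most_enthusiastic")), log)
  log(sprintf("analyse: config hash %s, seed %d",
              config_hash(config), config$seed))

  scale <- if (config$outcome == "hrqol") hrqol_scale() else pss_scale()
  trial <- utils::read.csv(config$trial, stringsAsFactors = FALSE)
  validate_trial_data(trial)
  responses <- read_responses(config$responses)
  evaluations <- read_evaluations(config$evaluations)
  anchors <- utils::read.csv(config$anchors, stringsAsFactors = FALSE)
  categories <- evaluate_responses(responses, evaluations)
  log(sprintf("categories: %s",
              paste(names(table(categories$category)),
                    table(categories$category), collapse = ", ", sep = "=")))

  scen <- list()
  for (lab in config$scenarios) {
    scen[[lab]] <- switch(lab,
      complete_case = "complete_case",
      MAR = "mar",
      pooled_usable = pool_experts(responses, anchors, categories,
                                   include = "usable", scale = scale,
                                   dependence = config$dependence),
      pooled_high_confidence = pool_experts(responses, anchors, categories,
                                            include = "usable_high_confidence",
                                            scale = scale,
                                            dependence = config$dependence),
      most_sceptical = ,
      most_enthusiastic = {
        ext <- select_extremes(responses, anchors, categories,
                               direction = config$direction, scale = scale,
                               dependence = config$dependence,
                               seed = config$seed)
        id <- if (lab == "most_sceptical") ext$sceptical else ext$enthusiastic
        single_expert_prior(responses, anchors, id, scale = scale,
                            dependence = config$dependence)
      },
      abort_mnar(sprintf("unknown scenario label '%s'", lab),
                 "mnarsens_invalid_argument"))
  }

  fit_cfg <- do.call(fit_config, c(config$fit, list(seed = config$seed)))
  res <- run_scenarios(trial, scen, fit_cfg, direction = config$direction)

  utils::write.csv(res$table, file.path(outdir, "scenarios.csv"),
                   row.names = FALSE)
  summary_out <- lapply(res$summaries, function(s) {
    out <- list(mean = s$mean, cri = s$cri, p_favours_intervention = s$p_favours,
                rhat = s$rhat, ess = s$ess,
                delta_provenance = s$delta_provenance, seed = config$seed,
                config_hash = config_hash(config))
    out[!vapply(out, is.null, logical(1))]
  })
  jsonlite::write_json(summary_out, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (lab in names(res$summaries)) {
    render_density_strip(res$summaries[[lab]],
                         file = file.path(outdir, paste0("strip_", lab, ".pdf")),
                         caption = sprintf("prior: %s; seed %d",
                                           res$summaries[[lab]]$delta_provenance %||%
                                             "none (complete case)",
                                           config$seed))
  }
  log(sprintf("analyse: wrote scenario table and %d strips to %s",
              length(res$summaries), outdir))
  invisible(res)
}

#' Density-strip display of a posterior distribution
#'
#' Draws the one-dimensional shaded strip used to display the full
#' treatment-effect posterior: the darkness at a point is proportional
#' to the posterior density, darkest at the maximum and fading into the
#' background at the minimum, with the posterior mean and the 95%
#' credible interval marked as ticks.
#'
#' @param summary A `posterior_summary` from [summarize_fit()] (any
#'   object with a `density` grid, `mean` and `cri`).
#' @param file Optional output file (vector formats recommended); when
#'   `NULL` the ggplot object is returned without writing.
#' @param caption Optional caption recording prior provenance and seed.
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly when written to file.
#' @export
render_density_strip <- function(summary, file = NULL, caption = NULL,
                                 width = 6, height = 1.6) {
  grid <- summary$density
  if (is.null(grid) || nrow(grid) == 0) {
    abort_mnar("summary has an empty density grid", "mnarsens_invalid_argument")
  }
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = x, y = 1)) +
    ggplot2::geom_tile(ggplot2::aes(alpha = darkness), fill = "black",
                       height = 0.6) +
    ggplot2::scale_alpha_identity() +
    ggplot2::annotate("point", x = summary$mean, y = 0.55, shape = 17) +
    ggplot2::annotate("segment", x = summary$cri[1], xend = summary$cri[1],
                      y = 0.7, yend = 1.3) +
    ggplot2::annotate("segment", x = summary$cri[2], xend = summary$cri[2],
                      y = 0.7, yend = 1.3) +
    ggplot2::labs(x = "treatment effect", y = NULL, title = summary$label,
                  caption = caption) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
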