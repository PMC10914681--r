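#' Summarize classification counts as percentages
#'
#' Converts per-category neuron counts into percentages of the total, with
#' nearest-integer rounding by default and a one-decimal truncation mode
#' matching one-decimal display conventions (e.g. 34 of 60 -> 56.6).
#'
#' @param counts named numeric vector of per-category counts.
#' @param total total neuron count (counts must not exceed it).
#' @param mode \code{"round"} (nearest integer) or \code{"trunc1"}
#'   (truncate to one decimal).
#' @return Data frame: category, count, total, percent.
#' @examples
#' summarize_classification(c(object_value = 48), 233)$percent  # 21
#' summarize_classification(c(view_choice = 34), 60, "trunc1")$percent  # 56.6
#' @export
summarize_classification <- function(counts, total,
                                     mode = c("round", "trunc1")) {
  mode <- match.arg(mode)
  if (total <= 0) stopf("total must be positive")
  if (any(counts > total)) stopf("counts cannot exceed the total")
  pct <- 100 * counts / total
  pct <- if (mode == "round") round(pct) else trunc(pct * 10) / 10
  data.frame(category = names(counts) %||% seq_along(counts),
             count = as.numeric(counts), total = total, percent = unname(pct),
             row.names = NULL)
}

#' Default experiment configuration
#'
#' The bundled reference configuration: a 150-trial main-task
#' session, a 233-neuron population at the default type prevalences,
#' parametric spike counts, value-cell classification, view-choice
#' decoding, and the value RSA.
#'
#' @param seed global seed; stage seeds are derived deterministically.
#' @return Nested list validating against \code{\link{run_experiment}}.
#' @export
default_experiment_config <- function(seed = 1L) {
  list(
    seed = seed,
    schedule = list(task_variant = "main", n_trials = 150),
    agent = list(variant = "reversal", alpha = 0.3, beta = 3, w_mag = 2),
    population = list(n_neurons = 233),
    spikes = list(rate_source = "parametric", bin_ms = 20),
    analyses = list(classify = TRUE, decode = TRUE, rsa = TRUE),
    decode = list(epoch = "cue2", method = "svm", n_matchings = 5,
                  n_shuffles = 20, min_trials = 5),
    rsa = list(n_perm = 500))
}

#' Read an experiment configuration from a YAML file
#' @param path YAML file with the structure of
#'   \code{\link{default_experiment_config}}.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  required <- c("seed", "schedule", "agent", "population", "spikes")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stopf("configuration is missing stage(s): %s",
          paste(missing, collapse = ", "))
  if (is.null(cfg$schedule$n_trials))
    stopf("configuration is missing schedule$n_trials")
  if (is.null(cfg$population$n_neurons))
    stopf("configuration is missing population$n_neurons")
  invisible(TRUE)
}

#' Run an end-to-end synthetic experiment
#'
#' Executes the pipeline stages in dependency order: schedule -> agent ->
#' session values -> population -> spike counts -> analyses (value-cell
#' classification with category percentages, view-choice decoding, value
#' RSA). All stage seeds derive deterministically from the global seed, so
#' identical configurations reproduce identical reports.
#'
#' @param config nested list (see \code{\link{default_experiment_config}})
#'   or a YAML path.
#' @param outdir optional directory for CSV/JSON stage outputs.
#' @return An object of class \code{experiment_report} with per-stage
#'   results and provenance (stage seeds).
#' @export
run_experiment <- function(config = default_experiment_config(),
                           outdir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  validate_config(config)
  seed <- config$seed
  report <- list(config = config,
                 seeds = list(schedule = child_seed(seed, 1),
                              agent = child_seed(seed, 2),
                              population = child_seed(seed, 3),
                              spikes = child_seed(seed, 4),
                              analyses = child_seed(seed, 5)))

  sch <- generate_schedule(config$schedule$task_variant %||% "main",
                           config$schedule$n_trials,
                           seed = report$seeds$schedule)
  params <- do.call(rl_params, config$agent)
  beh <- attach_values(simulate_agent(sch, params, seed = report$seeds$agent))
  pop <- generate_population(config$population$n_neurons,
                             seed = report$seeds$population)
  rec <- generate_spike_counts(pop, beh,
                               rate_source = config$spikes$rate_source %||% "parametric",
                               bin_ms = config$spikes$bin_ms %||% 20,
                               seed = report$seeds$spikes)
  report$behavior_summary <- list(
    n_trials = nrow(beh$trials),
    frac_first_chosen = mean(beh$trials$view_choice == "first"),
    frac_rewarded = mean(beh$trials$rewarded))

  an <- config$analyses %||% list()
  if (isTRUE(an$classify)) {
    types <- classify_functional_type(rec)
    counts <- table(factor(types, levels = NEURON_TYPES))
    grouped <- c(
      object_value = sum(counts[c("object_value_A", "object_value_B")]),
      view_value = sum(counts[c("view_value_pos", "view_value_neg")]),
      view_choice = sum(counts[c("view_choice_current", "view_choice_last")]),
      other = sum(counts[c("object_choice", "object_sequence", "combination")]),
      untuned = sum(counts["untuned"]))
    report$classification <- list(
      types = types,
      table = summarize_classification(grouped, length(types)))
  }
  if (isTRUE(an$decode)) {
    dc <- config$decode %||% list()
    ps <- pseudo_from_recording(rec, beh$trials$view_choice,
                                epoch = dc$epoch %||% "cue2",
                                min_trials = dc$min_trials %||% 5)
    report$decoding <- decode_population(
      ps, dc$method %||% "svm", n_matchings = dc$n_matchings %||% 5,
      n_shuffles = dc$n_shuffles %||% 20,
      seed = child_seed(report$seeds$analyses, 1))
  }
  if (isTRUE(an$rsa)) {
    spec <- value_conditions()
    cm <- condition_rsa(rec, spec, assign_value_conditions(beh), epoch = "cue1")
    tpl <- build_templates(spec, c("identity", "object", "view_value",
                                   "object_value"))
    report$rsa <- rsa_regression(cm, tpl,
                                 n_perm = (config$rsa %||% list())$n_perm %||% 500,
                                 seed = child_seed(report$seeds$analyses, 2))
  }
  report$recording <- rec

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    export_recording_csv(rec, outdir)
    if (!is.null(report$classification))
      utils::write.csv(report$classification$table,
                       file.path(outdir, "classification.csv"),
                       row.names = FALSE)
    summary_json <- list(
      behavior = report$behavior_summary,
      decoding = if (!is.null(report$decoding))
        list(mean_accuracy = report$decoding$mean_accuracy,
             p = report$decoding$p),
      seeds = report$seeds)
    jsonlite::write_json(summary_json, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report\n")
  cat(sprintf("  behavior: %d trials, %.0f%% rewarded\n",
              x$behavior_summary$n_trials,
              100 * x$behavior_summary$frac_rewarded))
  if (!is.null(x$classification)) {
    cat("  classification:\n")
    print(x$classification$table, row.names = FALSE)
  }
  if (!is.null(x$decoding))
    cat(sprintf("  view-choice decoding: %.1f%% (p = %.3g)\n",
                x$decoding$mean_accuracy, x$decoding$p))
  if (!is.null(x$rsa)) {
    sig <- x$rsa$coefficients$template[x$rsa$coefficients$significant]
    cat("  RSA significant templates:",
        if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}
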