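NEURON_TYPES <- c("object_value_A", "object_value_B",
                  "view_value_pos", "view_value_neg",
                  "view_choice_current", "view_choice_last",
                  "object_choice", "object_sequence", "combination",
                  "untuned")

AMYGDALA_NUCLEI <- c("dLA", "vLA", "BL", "BM", "CE")

#' Default functional-type proportions of a synthetic population
#'
#' Mirrors the prevalences reported for the recorded sample: roughly 21%
#' object-value, 30% view-based value, 26% view-based choice neurons, with
#' the remainder split among object-choice, object-sequence, combination
#' and untuned cells.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_type_proportions <- function() {
  c(object_value_A = 0.105, object_value_B = 0.105,
    view_value_pos = 0.15, view_value_neg = 0.15,
    view_choice_current = 0.13, view_choice_last = 0.13,
    object_choice = 0.06, object_sequence = 0.05, combination = 0.05,
    untuned = 0.07)
}

#' Generate a synthetic neuron population
#'
#' Draws functional types from the given proportions (multinomial), baseline
#' rates from a log-normal across neurons, response gains and latencies, and
#' assigns amygdala nucleus labels. Object-value cells are placed
#' preferentially in dLA, combination cells in BL, mirroring the anatomical
#' gradients described for the recorded sample.
#'
#' @param n_neurons number of neurons.
#' @param proportions named numeric vector over the functional types (must
#'   be non-negative and sum to 1); see \code{\link{default_type_proportions}}.
#' @param seed integer seed; the population is deterministic given
#'   \code{(proportions, n_neurons, seed)}.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline rate (impulses/s).
#' @param gain_mean,gain_sd normal parameters of the response gain
#'   (impulses/s per value unit or choice contrast); gains may be negative.
#' @return Data frame of class \code{neuron_population}: \code{neuron},
#'   \code{type}, \code{baseline}, \code{gain}, \code{latency} (ms),
#'   \code{nucleus}.
#' @examples
#' pop <- generate_population(50, seed = 1)
#' table(pop$type)
#' @export
generate_population <- function(n_neurons,
                                proportions = default_type_proportions(),
                                seed = NULL,
                                baseline_meanlog = log(8), baseline_sdlog = 0.5,
                                gain_mean = 10, gain_sd = 3) {
  if (any(proportions < 0)) stopf("type proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-8) stopf("type proportions must sum to 1")
  if (!all(names(proportions) %in% NEURON_TYPES))
    stopf("unknown neuron type(s): %s",
          paste(setdiff(names(proportions), NEURON_TYPES), collapse = ", "))
  with_seed(seed, {
    type <- sample(names(proportions), n_neurons, replace = TRUE,
                   prob = proportions)
    baseline <- rlnorm(n_neurons, baseline_meanlog, baseline_sdlog)
    gain <- rnorm(n_neurons, gain_mean, gain_sd)
    latency <- runif(n_neurons, 40, 120)
    nucleus <- vapply(type, function(tp) {
      w <- c(dLA = 1, vLA = 1, BL = 1, BM = 0.4, CE = 0.6)
      if (tp %in% c("object_value_A", "object_value_B")) w["dLA"] <- 3
      if (tp == "combination") w["BL"] <- 3
      sample(AMYGDALA_NUCLEI, 1, prob = w / sum(w))
    }, character(1))
  })
  out <- data.frame(neuron = seq_len(n_neurons), type = type,
                    baseline = baseline, gain = gain, latency = latency,
                    nucleus = nucleus, stringsAsFactors = FALSE)
  class(out) <- c("neuron_population", "data.frame")
  out
}

#' @export
print.neuron_population <- function(x, ...) {
  cat(sprintf("Synthetic population: %d neurons\n", nrow(x)))
  print(table(x$type))
  invisible(x)
}
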