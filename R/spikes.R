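EPOCH_NAMES <- c("fixation", "cue1", "delay1", "cue2", "delay2", "targets")

# Epoch windows in ms relative to first-cue onset; half-open [on, on+500).
epoch_windows <- function(with_targets = TRUE) {
  on <- c(fixation = -500, cue1 = 0, delay1 = 500, cue2 = 1000,
          delay2 = 1500, targets = 2000)
  if (!with_targets) on <- on[names(on) != "targets"]
  data.frame(epoch = names(on), start = unname(on), end = unname(on) + 500,
             stringsAsFactors = FALSE)
}

#' Generate binned spike counts for a synthetic population
#'
#' Emits Poisson spike counts per 20-ms bin for every neuron and trial.
#' With \code{rate_source = "parametric"} each neuron's rate follows its
#' functional type's tuning: object-value cells are affine in their
#' preferred object's value while that object is on screen; view-based
#' value cells follow the currently viewed value (positively or, for the
#' negative pool, its complement); view-based choice cells separate by
#' view-based choice from the second cue onward irrespective of object
#' identity; object-choice, object-sequence and combination cells carry
#' their respective contrasts; untuned cells fire at baseline. With
#' \code{rate_source = "circuit"} the per-trial rates are read from a
#' \code{\link{simulate_circuit_session}} trace: each neuron follows its
#' type's circuit population (V1/V2, C1/C2, sequence, combination, object
#' winner-take-all, or the value-scaled object drive), scaled by its gain
#' on top of its baseline.
#'
#' Rates are clipped at zero before Poisson emission; the number of clipped
#' neuron-bins is recorded in the \code{n_clipped} field.
#'
#' @param population a \code{\link{generate_population}} data frame.
#' @param behavior a \code{session_behavior} (values are attached if absent).
#' @param rate_source \code{"parametric"} or \code{"circuit"}.
#' @param seed integer seed.
#' @param bin_ms bin width (default 20 ms).
#' @param circuit optional \code{circuit_session} (required for
#'   \code{rate_source = "circuit"}).
#' @param with_targets include the choice-target epoch (parametric source
#'   only; circuit trials end at the post-second-cue delay).
#' @return An object of class \code{recording_set}: \code{counts} (neuron x
#'   trial x bin integer array), \code{bins} (start/end/center, ms relative
#'   to first-cue onset), \code{epochs}, \code{epoch_counts} (neuron x trial
#'   x epoch), the population, the behavior, and bookkeeping fields.
#' @examples
#' beh <- attach_values(simulate_agent(generate_schedule("main", 60, seed = 1),
#'                                     rl_params(w_mag = 2), seed = 2))
#' pop <- generate_population(5, seed = 3)
#' rec <- generate_spike_counts(pop, beh, seed = 4)
#' dim(rec$counts)
#' @export
generate_spike_counts <- function(population, behavior,
                                  rate_source = c("parametric", "circuit"),
                                  seed = NULL, bin_ms = 20, circuit = NULL,
                                  with_targets = TRUE) {
  rate_source <- match.arg(rate_source)
  stopifnot(inherits(population, "neuron_population"),
            inherits(behavior, "session_behavior"))
  if (nrow(population) == 0L || nrow(behavior$trials) == 0L)
    stopf("population and behavior must be nonempty")
  if (is.null(behavior$trials$value.A)) behavior <- attach_values(behavior)
  if (rate_source == "circuit" && is.null(circuit))
    stopf("rate_source='circuit' needs a circuit_session")

  tr <- behavior$trials
  n_tr <- nrow(tr)
  t_end <- if (with_targets) 2500 else 2000
  starts <- seq(-500, t_end - bin_ms, by = bin_ms)
  bins <- data.frame(start = starts, end = starts + bin_ms,
                     center = starts + bin_ms / 2)
  n_bins <- nrow(bins)
  n_nrn <- nrow(population)
  counts <- array(0L, c(n_nrn, n_tr, n_bins))
  n_clipped <- 0L

  with_seed(seed, {
    subtype <- vapply(population$type, function(tp) switch(tp,
      object_sequence = sample(c("A1", "A2", "B1", "B2"), 1),
      combination = sample(c("CA1", "CA2", "CB1", "CB2"), 1),
      object_choice = sample(c("CA", "CB"), 1),
      ""), character(1))
    for (i in seq_len(n_nrn)) {
      rate <- rate_matrix(population[i, ], subtype[i], tr, bins, rate_source,
                          circuit)
      n_clipped <- n_clipped + sum(rate < 0)
      lam <- pmax(rate, 0) * bin_ms / 1000
      counts[i, , ] <- matrix(rpois(length(lam), lam), n_tr, n_bins)
    }
  })

  ep <- epoch_windows(with_targets)
  epoch_counts <- array(0L, c(n_nrn, n_tr, nrow(ep)),
                        dimnames = list(NULL, NULL, ep$epoch))
  for (k in seq_len(nrow(ep))) {
    sel <- bins$start >= ep$start[k] & bins$end <= ep$end[k]
    epoch_counts[, , k] <- apply(counts[, , sel, drop = FALSE], c(1, 2), sum)
  }

  structure(list(counts = counts, bins = bins, epochs = ep,
                 epoch_counts = epoch_counts, population = population,
                 behavior = behavior, bin_ms = bin_ms,
                 rate_source = rate_source, subtype = subtype,
                 n_clipped = n_clipped, seed = seed),
            class = "recording_set")
}

# Rate (impulses/s) as trials x bins matrix for one neuron.
rate_matrix <- function(nrn, subtype, tr, bins, rate_source, circuit) {
  n_tr <- nrow(tr); n_bins <- nrow(bins)
  base <- matrix(nrn$baseline, n_tr, n_bins)
  g <- nrn$gain
  if (nrn$type == "untuned") return(base)

  if (rate_source == "circuit") {
    pop_nm <- switch(nrn$type,
      object_value_A = "rA", object_value_B = "rB",
      view_value_pos = "V2", view_value_neg = "V1",
      view_choice_current = "C2", view_choice_last = "C1",
      object_choice = subtype, object_sequence = subtype,
      combination = subtype)
    trace <- circuit$traces[[pop_nm]]           # time x trial
    # circuit time 0 = fixation onset; recording time 0 = first-cue onset
    tt <- circuit$times - 500
    drive <- t(vapply(seq_len(n_bins), function(b) {
      sel <- tt >= bins$start[b] & tt < bins$end[b]
      if (!any(sel)) return(numeric(n_tr))
      colMeans(trace[sel, , drop = FALSE])
    }, numeric(n_tr)))                          # bins x trials
    drive <- t(drive)                           # trials x bins
    if (nrn$type == "object_value_A") drive <- drive * tr$value.A
    if (nrn$type == "object_value_B") drive <- drive * tr$value.B
    return(base + g * drive)
  }

  lat <- nrn$latency
  win <- function(from, to) {
    m <- outer(rep(1, n_tr), as.numeric(bins$center >= from + lat &
                                        bins$center < to + lat))
    m
  }
  # value tunings are centered on the mid value: responses move below
  # baseline for below-average values (gain modulation around the
  # operating point), which carries the product-code similarity structure
  tuned <- switch(nrn$type,
    object_value_A = {
      cue1 <- win(0, 500) * (tr$obj_first == "A") * (tr$value.A - 0.5)
      cue2 <- win(1000, 1500) * (tr$obj_second == "A") * (tr$value.A - 0.5)
      cue1 + cue2
    },
    object_value_B = {
      cue1 <- win(0, 500) * (tr$obj_first == "B") * (tr$value.B - 0.5)
      cue2 <- win(1000, 1500) * (tr$obj_second == "B") * (tr$value.B - 0.5)
      cue1 + cue2
    },
    view_value_pos = win(0, 500) * (tr$value_first - 0.5) +
                     win(1000, 1500) * (tr$value_second - 0.5),
    view_value_neg = win(0, 500) * (0.5 - tr$value_first) +
                     win(1000, 1500) * (0.5 - tr$value_second),
    view_choice_current = win(1000, 2000) * (tr$view_choice == "second"),
    view_choice_last = win(1000, 2000) * (tr$view_choice == "first"),
    object_choice = {
      pref <- if (subtype == "CB") "B" else "A"
      win(2000, 2500) * (tr$chosen_obj == pref)
    },
    object_sequence = {
      # e.g. A1: responds at the second cue when its object was shown first
      obj <- substr(subtype, 1, 1)
      ord <- substr(subtype, 2, 2)
      on <- if (ord == "1") tr$obj_first == obj else tr$obj_second == obj
      win(1000, 1500) * on
    },
    combination = {
      obj <- substr(subtype, 2, 2)
      ord <- substr(subtype, 3, 3)
      seq_on <- if (ord == "1") tr$obj_first == obj else tr$obj_second == obj
      vc_on <- if (ord == "1") tr$view_choice == "first" else
                               tr$view_choice == "second"
      win(1000, 2000) * (seq_on & vc_on)
    })
  base + g * tuned
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("Recording set (%s rates): %d neurons x %d trials x %d bins (%d ms)\n",
              x$rate_source, dim(x$counts)[1], dim(x$counts)[2],
              dim(x$counts)[3], x$bin_ms))
  if (x$n_clipped > 0)
    cat(sprintf("  %d neuron-bins had negative tuned rates clipped to 0\n",
                x$n_clipped))
  invisible(x)
}

#' Export a recording set and trial log to CSV
#'
#' Writes the trial log (one row per trial) and the epoch spike-count table
#' (one row per neuron x trial) as plain CSV files.
#'
#' @param recording a \code{recording_set}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_recording_csv <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trial_path <- file.path(dir, "trials.csv")
  utils::write.csv(recording$behavior$trials, trial_path, row.names = FALSE)
  ec <- recording$epoch_counts
  long <- do.call(rbind, lapply(seq_len(dim(ec)[1]), function(i) {
    data.frame(neuron = i, trial = seq_len(dim(ec)[2]),
               as.data.frame(ec[i, , , drop = TRUE]))
  }))
  counts_path <- file.path(dir, "epoch_counts.csv")
  utils::write.csv(long, counts_path, row.names = FALSE)
  invisible(c(trial_path, counts_path))
}
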