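#' Parameters of the three-stage firing-rate circuit
#'
#' Defaults follow the reference parameter set of the view-based decision
#' circuit model: an integral-feedback value-comparison stage (populations
#' \eqn{V_i}, \eqn{M_i}), a winner-take-all view-based decision stage
#' (\eqn{C_1}, \eqn{C_2}) gated by a bistable excitatory-inhibitory switch
#' (\eqn{r_E}, \eqn{r_I}) with facilitating stimulus input (\eqn{w_F}), and
#' an expansion-recoding stage (object-sequence units with depressing
#' synapses, combination units, and an object winner-take-all \eqn{C_X}).
#'
#' Three quantities the reference set leaves implicit are exposed as
#' parameters: the memory self-coupling is the effective value
#' \code{wMM} * [M]+ (perfect integration at the default 1); \code{b_gain}
#' scales the object-selective drive onto the switch (the firing-rate scale
#' of those input populations); and \code{I_bg} is the constant resting
#' background of both winner-take-all stages (default: the I1 of the
#' object winner-take-all stage).
#' Facilitation is driven by the presynaptic object drive
#' (\code{k2 * (rA+rB) * wF}).
#'
#' @param ... named overrides of any default listed below.
#' @return A list of class \code{circuit_params}.
#' @examples
#' p <- circuit_params(eta = 0)
#' p$w_plus
#' @export
circuit_params <- function(...) {
  p <- list(
    tau = 10, tauF = 500, taus = 1000,      # ms
    wMM = 1, wMV = 0.6, wVM = 0.6,
    w_plus = 2.5, w_minus = 2, w = 0.1,
    wEE = 16, wEI = 9, wIE = 10, wII = 7,
    wb = 0.2, wc = 0.5,
    IE = -3, II = -1, I1 = -1.6,
    k1 = 0.015, k2 = 1.1, k3 = 0.22,
    kM = 0.2,                                # slope of fM(u) = kM [u]+
    f_theta = 1.35,                          # threshold of f(u) = [u - theta]+
    alphaE = 1, alphaI = 3, alpha1 = 1, alpha2 = 1,
    eta = 0.025,
    dt = 0.5,                                # ms
    b_gain = 1.5,                            # object-drive amplitude on switch
    v_gain = 6,                              # V-population output amplitude on C
    s_gain = 4,                              # combination-drive amplitude on object WTA
    I_bg = -1.6,                             # resting background of C stages
    I0_const = 0,                            # replaces rE in the no-switch variant
    wMC = 0.8,                               # memory feedback, positive-tuned variant
    blowup = 1e3)
  override <- list(...)
  unknown <- setdiff(names(override), names(p))
  if (length(unknown)) stopf("unknown circuit parameter(s): %s",
                             paste(unknown, collapse = ", "))
  p[names(override)] <- override
  if (p$tau <= 0 || p$tauF <= 0 || p$taus <= 0) stopf("time constants must be > 0")
  if (p$dt > p$tau / 10) stopf("dt must be <= tau/10 for stable integration")
  structure(p, class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Circuit parameters:\n")
  nm <- setdiff(names(x), "blowup")
  cat(" ", paste(sprintf("%s=%g", nm, unlist(x[nm])), collapse = ", "), "\n")
  invisible(x)
}

#' Stimulus protocol for a circuit trial
#'
#' Defines the event schedule of one trial: a fixation period, then the two
#' choice objects presented sequentially, each followed by a delay. During a
#' stimulus the value-comparison stage receives the complementary value
#' inputs \eqn{I_{V,1} = 1 - V_X} and \eqn{I_{V,2} = V_X} of the object on
#' screen, and the object-selective drive of that object is 1.
#'
#' @param values named numeric vector of object values in [0, 1]; names are
#'   the object ids (at least the two presented).
#' @param sequence character vector of length 2: first and second presented
#'   object ids.
#' @param cue_ms,delay_ms,fix_ms epoch durations (ms); the control tasks use
#'   350-ms cues and delays.
#' @return A list of class \code{stimulus_protocol} with the event table and
#'   total duration.
#' @export
stimulus_protocol <- function(values, sequence = names(values)[1:2],
                              cue_ms = 500, delay_ms = 500, fix_ms = 500) {
  if (is.null(names(values))) names(values) <- LETTERS[seq_along(values)]
  if (length(sequence) != 2L) stopf("sequence must name exactly two objects")
  if (!all(sequence %in% names(values)))
    stopf("sequence ids must be in names(values)")
  if (any(values < 0 | values > 1)) stopf("object values must lie in [0, 1]")
  events <- data.frame(
    epoch = c("fixation", "cue1", "delay1", "cue2", "delay2"),
    onset = cumsum(c(0, fix_ms, cue_ms, delay_ms, cue_ms)),
    duration = c(fix_ms, cue_ms, delay_ms, cue_ms, delay_ms),
    stringsAsFactors = FALSE)
  structure(list(values = values, sequence = sequence, events = events,
                 total_ms = sum(events$duration)),
            class = "stimulus_protocol")
}
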