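CIRCUIT_VARIANTS <- c("full", "classical_simultaneous", "no_switch",
                      "object_specific_view", "positive_tuned_wMC08")

# Vectorized Euler-Maruyama integration of the circuit over a batch of
# trials sharing one timing grid. `values` is a trials x objects matrix of
# object values in [0,1]; `seq1`/`seq2` give each trial's first/second
# presented object id. Every rate variable is a length-T vector advanced in
# lock-step; synaptic variables are noise-free. Returns recorded traces
# (steps x trials per population) and per-trial decision readouts.
circuit_run <- function(p, values, seq1, seq2, variant = "full",
                        cue_ms = 500, delay_ms = 500, fix_ms = 500,
                        post_ms = 500, record_every = 10L) {
  objs <- colnames(values)
  nT <- nrow(values)
  dt <- p$dt; tau <- p$tau
  on1 <- fix_ms; off1 <- on1 + cue_ms
  on2 <- off1 + delay_ms; off2 <- on2 + cue_ms
  total_ms <- off2 + delay_ms + post_ms
  simultaneous <- variant == "classical_simultaneous"
  object_channels <- variant %in% c("object_specific_view",
                                    "positive_tuned_wMC08",
                                    "classical_simultaneous")
  n_steps <- ceiling(total_ms / dt)

  sigC <- function(u) 1 / (1 + exp(-u / p$alpha1))
  sigE <- function(u) 1 / (1 + exp(-u / p$alphaE))
  sigI <- function(u) 1 / (1 + exp(-u / p$alphaI))

  v1st <- values[cbind(seq_len(nT), match(seq1, objs))]
  v2nd <- values[cbind(seq_len(nT), match(seq2, objs))]
  # object-channel variants compare the pair's two objects on fixed channels
  vch1 <- v1st; vch2 <- v2nd   # channel 1 = first-presented, 2 = second

  zeros <- numeric(nT)
  V1 <- zeros; V2 <- zeros; M1 <- zeros; M2 <- zeros
  rE <- rep(0.0044, nT); rI <- rep(0.27, nT); wF <- rep(1, nT)
  C1 <- zeros; C2 <- zeros
  rX <- X1 <- X2 <- wX1 <- wX2 <- CX1 <- CX2 <- CX <- list()
  for (o in objs) {
    rX[[o]] <- zeros; X1[[o]] <- zeros; X2[[o]] <- zeros
    wX1[[o]] <- rep(1, nT); wX2[[o]] <- rep(1, nT)
    CX1[[o]] <- zeros; CX2[[o]] <- zeros; CX[[o]] <- zeros
  }
  pres1 <- lapply(objs, function(o) as.numeric(seq1 == o))  # on during cue1
  pres2 <- lapply(objs, function(o) as.numeric(seq2 == o))
  names(pres1) <- names(pres2) <- objs
  if (simultaneous) for (o in objs) {
    pres1[[o]] <- pmax(pres1[[o]], pres2[[o]]); pres2[[o]] <- pres1[[o]] * 0
  }
  kin <- tau / cue_ms   # memory load gain of the positively tuned variant

  rec_steps <- seq(record_every, n_steps, by = record_every)
  pops <- c("V1", "V2", "M1", "M2", "rE", "rI", "wF", "C1", "C2",
            paste0("r", objs), paste0(objs, "1"), paste0(objs, "2"),
            paste0("w", objs, "1"), paste0("w", objs, "2"),
            paste0("C", objs, "1"), paste0("C", objs, "2"), paste0("C", objs))
  traces <- lapply(setNames(pops, pops),
                   function(nm) matrix(NA_real_, length(rec_steps), nT))
  noise_sd <- p$eta * sqrt(dt)

  ri <- 1L
  for (s in seq_len(n_steps)) {
    t <- s * dt
    in1 <- t > on1 && t <= off1    # first-stimulus window
    in2 <- t > on2 && t <= off2
    nz <- function() if (p$eta > 0) rnorm(nT, 0, noise_sd) else 0

    # stimulus drives
    if (object_channels) {
      IV1 <- if (in1) vch1 else zeros
      IV2 <- if (in2 || (simultaneous && in1)) vch2 else zeros
      if (simultaneous && in1) IV1 <- vch1
    } else {
      vx <- if (in1) v1st else if (in2) v2nd else zeros
      IV1 <- if (in1 || in2) 1 - vx else zeros
      IV2 <- if (in1 || in2) vx else zeros
    }

    if (variant == "positive_tuned_wMC08" || simultaneous) {
      dV1 <- (-V1 + p$wMC * pmax(pmax(M1, 0), IV1)) / tau
      dV2 <- (-V2 + p$wMC * pmax(pmax(M2, 0), IV2)) / tau
      dM1 <- (-M1 + pmax(M1, 0) + kin * IV1) / tau
      dM2 <- (-M2 + pmax(M2, 0) + kin * IV2) / tau
    } else {
      dV1 <- (-V1 - p$wVM * pmax(M1, 0) + IV1) / tau
      dV2 <- (-V2 - p$wVM * pmax(M2, 0) + IV2) / tau
      dM1 <- (-M1 + p$wMV * p$kM * pmax(V1, 0) + p$wMM * pmax(M1, 0)) / tau
      dM2 <- (-M2 + p$wMV * p$kM * pmax(V2, 0) + p$wMM * pmax(M2, 0)) / tau
    }

    r_sum <- Reduce(`+`, rX)
    b <- p$wb * p$b_gain * r_sum
    drE <- (-rE + sigE(p$wEE * rE - p$wEI * rI + p$IE + wF * b)) / tau
    drI <- (-rI + sigI(p$wIE * rE - p$wII * rI + p$II)) / tau
    dwF <- (p$k1 * (1 - wF) + p$k2 * r_sum * wF) / p$tauF

    I0 <- if (variant == "no_switch") p$I0_const else
          if (simultaneous) as.numeric(in1) else rE
    dC1 <- (-C1 + sigC(p$w_plus * C1 - p$w_minus * C2 + p$w * p$v_gain * V1 + I0 + p$I_bg)) / tau
    dC2 <- (-C2 + sigC(p$w_plus * C2 - p$w_minus * C1 + p$w * p$v_gain * V2 + I0 + p$I_bg)) / tau

    drX <- dX1 <- dX2 <- dwX1 <- dwX2 <- dCX1 <- dCX2 <- dCX <- list()
    sX <- list()
    for (o in objs) {
      IX <- if (in1) pres1[[o]] else if (in2) pres2[[o]] else zeros
      drX[[o]] <- (-rX[[o]] + IX) / tau
      r_oth <- r_sum - rX[[o]]
      dX1[[o]] <- (-X1[[o]] + wX1[[o]] * rX[[o]] + r_oth) / tau
      dX2[[o]] <- (-X2[[o]] + rX[[o]] + wX2[[o]] * r_oth) / tau
      dwX1[[o]] <- (p$k1 * (1 - wX1[[o]]) - p$k3 * X1[[o]] * wX1[[o]]) / p$taus
      dwX2[[o]] <- (p$k1 * (1 - wX2[[o]]) - p$k3 * X2[[o]] * wX2[[o]]) / p$taus
      dCX1[[o]] <- (-CX1[[o]] + pmax(X1[[o]] + C1 - p$f_theta, 0)) / tau
      dCX2[[o]] <- (-CX2[[o]] + pmax(X2[[o]] + C2 - p$f_theta, 0)) / tau
      sX[[o]] <- CX1[[o]] + CX2[[o]]
    }
    CX_sum <- Reduce(`+`, CX)
    for (o in objs) {
      dCX[[o]] <- (-CX[[o]] + sigC(p$w_plus * CX[[o]] -
                                   p$w_minus * (CX_sum - CX[[o]]) +
                                   p$wc * p$s_gain * sX[[o]] + p$I1)) / tau
    }

    V1 <- V1 + dt * dV1 + nz(); V2 <- V2 + dt * dV2 + nz()
    M1 <- M1 + dt * dM1 + nz(); M2 <- M2 + dt * dM2 + nz()
    rE <- rE + dt * drE + nz(); rI <- rI + dt * drI + nz()
    wF <- wF + dt * dwF
    C1 <- C1 + dt * dC1 + nz(); C2 <- C2 + dt * dC2 + nz()
    for (o in objs) {
      rX[[o]] <- rX[[o]] + dt * drX[[o]] + nz()
      X1[[o]] <- X1[[o]] + dt * dX1[[o]] + nz()
      X2[[o]] <- X2[[o]] + dt * dX2[[o]] + nz()
      wX1[[o]] <- wX1[[o]] + dt * dwX1[[o]]
      wX2[[o]] <- wX2[[o]] + dt * dwX2[[o]]
      CX1[[o]] <- CX1[[o]] + dt * dCX1[[o]] + nz()
      CX2[[o]] <- CX2[[o]] + dt * dCX2[[o]] + nz()
      CX[[o]] <- CX[[o]] + dt * dCX[[o]] + nz()
    }

    if (ri <= length(rec_steps) && s == rec_steps[ri]) {
      snap <- c(list(V1 = V1, V2 = V2, M1 = M1, M2 = M2, rE = rE, rI = rI,
                     wF = wF, C1 = C1, C2 = C2),
                setNames(rX, paste0("r", objs)),
                setNames(X1, paste0(objs, "1")),
                setNames(X2, paste0(objs, "2")),
                setNames(wX1, paste0("w", objs, "1")),
                setNames(wX2, paste0("w", objs, "2")),
                setNames(CX1, paste0("C", objs, "1")),
                setNames(CX2, paste0("C", objs, "2")),
                setNames(CX, paste0("C", objs)))
      bad <- !is.finite(snap$V1) | abs(snap$V1) > p$blowup |
             !is.finite(snap$C1) | abs(snap$C1) > p$blowup
      if (any(bad)) stopf("circuit integration blew up at t = %.1f ms", t)
      for (nm in pops) traces[[nm]][ri, ] <- snap[[nm]]
      ri <- ri + 1L
    }
  }

  times <- rec_steps * dt
  # ---- decision readouts ----
  view_end <- if (simultaneous) off1 else off2   # choice signal is transient
  iv <- which.min(abs(times - view_end))
  c1e <- traces$C1[iv, ]; c2e <- traces$C2[iv, ]
  margin_view <- abs(c1e - c2e)
  decided <- pmax(c1e, c2e) > 0.5 & margin_view > 0.2
  view_choice <- ifelse(margin_view <= 1e-9, NA_character_,
                        ifelse(c2e > c1e, "second", "first"))
  if (object_channels) {
    # channels index the pair's objects directly
    object_choice <- ifelse(margin_view <= 1e-9, NA_character_,
                            ifelse(c1e > c2e, seq1, seq2))
    view_choice <- ifelse(is.na(object_choice), NA_character_,
                          ifelse(object_choice == seq1, "first", "second"))
    margin_obj <- margin_view
  } else {
    # object choice from the object winner-take-all, read in a trailing
    # window of the second cue while the combination drive is present
    sel <- times > off2 - 100 & times <= off2
    cxm <- sapply(objs, function(o) colMeans(traces[[paste0("C", o)]][sel, , drop = FALSE]))
    if (is.null(dim(cxm))) cxm <- matrix(cxm, nrow = 1)
    i1 <- cbind(seq_len(nT), match(seq1, objs))
    i2 <- cbind(seq_len(nT), match(seq2, objs))
    margin_obj <- abs(cxm[i1] - cxm[i2])
    object_choice <- ifelse(margin_obj <= 1e-9, NA_character_,
                            ifelse(cxm[i1] > cxm[i2], seq1, seq2))
  }

  list(times = times, traces = traces, objects = objs,
       timing = c(fix_ms = fix_ms, cue_ms = cue_ms, delay_ms = delay_ms),
       readout = data.frame(
         trial = seq_len(nT), seq1 = seq1, seq2 = seq2,
         v_first = v1st, v_second = v2nd,
         view_choice = view_choice, object_choice = object_choice,
         margin_view = margin_view, margin_object = margin_obj,
         decided = decided, stringsAsFactors = FALSE))
}

#' Simulate one trial of the view-based decision circuit
#'
#' Euler-Maruyama integration of the coupled population equations: value
#' comparison with integral feedback (V/M), the bistable switch (rE/rI with
#' facilitating stimulus input wF), view-based winner-take-all decision
#' (C1/C2), object-sequence units with short-term depression, combination
#' units, and the object winner-take-all (CX). Additive Gaussian noise of
#' amplitude \code{eta} (scaled by \eqn{\sqrt{dt}}) enters every rate
#' equation; synaptic variables are noise-free. At \code{eta = 0} the
#' integration is deterministic.
#'
#' The view-based decision is read out as the larger of C1/C2 at the end of
#' the post-second-cue delay (a trial is "decided" when the winner exceeds
#' 0.5 with a margin above 0.2); the object choice is read from the object
#' winner-take-all populations in the closing 100 ms of the second cue,
#' while the combination-stage drive is present. Exact ties are labeled
#' undecided rather than arbitrarily resolved.
#'
#' @param params a \code{\link{circuit_params}} object.
#' @param protocol a \code{\link{stimulus_protocol}}.
#' @param seed integer seed for the noise stream.
#' @param variant circuit architecture: \code{"full"} (default) or one of
#'   the ablations (see \code{\link{run_ablation}}).
#' @param record_every store every k-th integration step (default 4, i.e.
#'   2-ms resolution at dt = 0.5 ms).
#' @return An object of class \code{circuit_trace}: \code{time} (ms),
#'   \code{states} (time x population matrix), the protocol, and the
#'   decision readouts \code{view_choice} (\code{"first"},
#'   \code{"second"} or NA), \code{object_choice}, and margins.
#' @examples
#' pr <- stimulus_protocol(c(A = 0.2, B = 0.8), c("A", "B"))
#' tr <- simulate_circuit_trial(circuit_params(eta = 0), pr)
#' tr$view_choice
#' @export
simulate_circuit_trial <- function(params = circuit_params(), protocol,
                                   seed = NULL, variant = "full",
                                   record_every = 4L) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(protocol, "stimulus_protocol"))
  if (!variant %in% CIRCUIT_VARIANTS) stopf("unknown circuit variant '%s'", variant)
  ev <- protocol$events
  run <- with_seed(seed, circuit_run(
    params,
    values = matrix(protocol$values, 1,
                    dimnames = list(NULL, names(protocol$values))),
    seq1 = protocol$sequence[1], seq2 = protocol$sequence[2],
    variant = variant,
    cue_ms = ev$duration[ev$epoch == "cue1"],
    delay_ms = ev$duration[ev$epoch == "delay1"],
    fix_ms = ev$duration[ev$epoch == "fixation"],
    record_every = record_every))
  states <- sapply(run$traces, function(m) m[, 1])
  ro <- run$readout
  structure(list(time = run$times, states = states, protocol = protocol,
                 params = params, variant = variant,
                 view_choice = ro$view_choice, object_choice = ro$object_choice,
                 margin_view = ro$margin_view, margin_object = ro$margin_object,
                 decided = ro$decided),
            class = "circuit_trace")
}

#' @export
print.circuit_trace <- function(x, ...) {
  cat(sprintf("Circuit trace (%s): %s -> %s, values %.2f / %.2f\n", x$variant,
              x$protocol$sequence[1], x$protocol$sequence[2],
              x$protocol$values[x$protocol$sequence[1]],
              x$protocol$values[x$protocol$sequence[2]]))
  cat(sprintf("  view choice: %s (margin %.2f); object choice: %s (margin %.2f)\n",
              x$view_choice, x$margin_view, x$object_choice, x$margin_object))
  invisible(x)
}

#' @export
plot.circuit_trace <- function(x, populations = c("V1", "V2", "C1", "C2", "rE"),
                               ...) {
  matplot(x$time, x$states[, populations, drop = FALSE], type = "l", lty = 1,
          xlab = "time (ms)", ylab = "rate", ...)
  legend("topleft", legend = populations, col = seq_along(populations),
         lty = 1, bty = "n")
  for (on in x$protocol$events$onset[-1]) abline(v = on, col = "grey80")
  invisible(x)
}

# Mean of a population trace within [from, to) ms.
trace_window_mean <- function(trace, population, from, to) {
  sel <- trace$time >= from & trace$time < to
  mean(trace$states[sel, population])
}

#' Simulate the circuit for every trial of a session
#'
#' Runs the full circuit over all trials of a (value-augmented) behavioral
#' session: each trial's first/second object values (session values rescaled
#' to [0, 1], see \code{\link{attach_values}}) and viewing order drive the
#' network. Used to generate circuit-constrained firing rates for synthetic
#' recordings and to compare network choices with agent choices.
#'
#' @param params a \code{\link{circuit_params}}.
#' @param behavior a \code{session_behavior} with attached values.
#' @param seed integer seed for the noise streams.
#' @param record_every recording stride in integration steps (default 10 =
#'   5-ms resolution).
#' @param cue_ms,delay_ms,fix_ms trial timing (ms).
#' @return A list of class \code{circuit_session}: recorded traces per
#'   population (time x trial matrices), bin \code{times}, and the per-trial
#'   \code{readout} data frame.
#' @export
simulate_circuit_session <- function(params = circuit_params(), behavior,
                                     seed = NULL, record_every = 10L,
                                     cue_ms = 500, delay_ms = 500, fix_ms = 500) {
  stopifnot(inherits(behavior, "session_behavior"))
  tr <- behavior$trials
  if (is.null(tr$value.A)) stopf("behavior needs attached values; see attach_values()")
  objs <- behavior$schedule$objects
  values <- as.matrix(tr[, paste0("value.", objs), drop = FALSE])
  colnames(values) <- objs
  values[is.na(values)] <- 0.5
  run <- with_seed(seed, circuit_run(
    params, values, seq1 = tr$obj_first, seq2 = tr$obj_second,
    variant = "full", cue_ms = cue_ms, delay_ms = delay_ms, fix_ms = fix_ms,
    record_every = record_every))
  structure(run, class = "circuit_session")
}

#' @export
print.circuit_session <- function(x, ...) {
  cat(sprintf("Circuit session: %d trials, %d recorded populations, %d time bins\n",
              nrow(x$readout), length(x$traces), length(x$times)))
  cat(sprintf("  decided: %.1f%%; view=second: %.1f%%\n",
              100 * mean(x$readout$decided),
              100 * mean(x$readout$view_choice == "second", na.rm = TRUE)))
  invisible(x)
}

#' Align behavioral choice labels with circuit decisions
#'
#' When spike counts are generated from circuit traces, the network is the
#' decision maker: this helper replaces the agent's per-trial view-based
#' choice (and the derived chosen-object, chosen-side and chosen-value
#' columns) with the circuit readout, keeping the agent's choice on
#' undecided trials. Reward outcomes are left untouched; they postdate the
#' within-trial codes under study.
#'
#' @param behavior a value-augmented \code{session_behavior}.
#' @param circuit a \code{circuit_session} simulated from the same behavior.
#' @return The behavior with circuit-consistent choice columns.
#' @export
align_behavior_to_circuit <- function(behavior, circuit) {
  stopifnot(inherits(behavior, "session_behavior"),
            inherits(circuit, "circuit_session"))
  tr <- behavior$trials
  ro <- circuit$readout
  if (nrow(tr) != nrow(ro)) stopf("behavior and circuit trial counts differ")
  vc <- ifelse(is.na(ro$view_choice), tr$view_choice, ro$view_choice)
  tr$view_choice <- vc
  tr$chosen_obj <- ifelse(vc == "first", tr$obj_first, tr$obj_second)
  tr$chosen_side <- ifelse(tr$chosen_obj == tr$left_obj, "left", "right")
  if (!is.null(tr$value_first)) {
    tr$value_chosen <- ifelse(vc == "first", tr$value_first, tr$value_second)
  }
  behavior$trials <- tr
  behavior
}
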