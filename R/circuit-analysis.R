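#' Bifurcation structure of the decision switch
#'
#' Solves the fixed points of the excitatory-inhibitory switch subsystem
#' (facilitation frozen) as a function of the stimulus input b added to the
#' E population, and labels their stability from the Jacobian eigenvalues.
#' The system is bistable over a finite b interval: low-activity and
#' high-activity branches coexist, separated by an unstable middle branch,
#' and the low branch is annihilated in a saddle-node at the upper edge.
#'
#' @param params a \code{\link{circuit_params}}.
#' @param b_range numeric grid of input values.
#' @return An object of class \code{bifurcation_diagram}: data frame with
#'   columns \code{b}, \code{rE}, \code{rI}, \code{stable}, plus a
#'   \code{converged} attribute flagging grid cells where root finding
#'   failed (they are reported, never fabricated).
#' @examples
#' bd <- switch_bifurcation(circuit_params(), seq(0, 2.5, 0.5))
#' table(bd$b, bd$stable)
#' @export
switch_bifurcation <- function(params = circuit_params(),
                               b_range = seq(0, 3, by = 0.05)) {
  if (!all(is.finite(b_range))) stopf("b_range must be a finite grid")
  p <- params
  sigE <- function(u) 1 / (1 + exp(-u / p$alphaE))
  sigI <- function(u) 1 / (1 + exp(-u / p$alphaI))
  rows <- list()
  failed <- numeric(0)
  for (b in b_range) {
    Ffun <- function(x) c(
      -x[1] + sigE(p$wEE * x[1] - p$wEI * x[2] + p$IE + b),
      -x[2] + sigI(p$wIE * x[1] - p$wII * x[2] + p$II))
    Jfun <- function(x) {
      sE <- sigE(p$wEE * x[1] - p$wEI * x[2] + p$IE + b)
      sI <- sigI(p$wIE * x[1] - p$wII * x[2] + p$II)
      dE <- sE * (1 - sE) / p$alphaE
      dI <- sI * (1 - sI) / p$alphaI
      rbind(c(-1 + p$wEE * dE, -p$wEI * dE),
            c(p$wIE * dI, -1 - p$wII * dI))
    }
    roots <- solve_fixed_points(Ffun, Jfun,
                                expand.grid(seq(0, 1, 0.05), seq(0, 1, 0.2)))
    if (!length(roots)) { failed <- c(failed, b); next }
    for (r in roots) {
      ev <- eigen(Jfun(r), only.values = TRUE)$values
      stable <- all(Re(ev) < -1e-8)
      rows[[length(rows) + 1]] <- data.frame(b = b, rE = r[1], rI = r[2],
                                             stable = stable)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "failed") <- failed
  class(out) <- c("bifurcation_diagram", "data.frame")
  out
}

# Damped-Newton root finding from a dense grid of initial guesses;
# returns the list of distinct roots found.
solve_fixed_points <- function(Ffun, Jfun, starts, tol = 1e-12,
                               maxit = 200L, damp = 0.7) {
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    x <- as.numeric(starts[i, ])
    ok <- FALSE
    for (it in seq_len(maxit)) {
      Fv <- Ffun(x)
      if (max(abs(Fv)) < tol) { ok <- TRUE; break }
      step <- tryCatch(solve(Jfun(x), -Fv), error = function(e) NULL)
      if (is.null(step)) break
      x <- x + damp * step
      if (any(!is.finite(x)) || max(abs(x)) > 10) break
    }
    if (ok && max(abs(Ffun(x))) < 1e-9) {
      dup <- any(vapply(roots, function(r) max(abs(r - x)) < 1e-6, logical(1)))
      if (!dup) roots[[length(roots) + 1]] <- x
    }
  }
  roots
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  nb <- length(unique(x$b))
  bist <- stats::aggregate(stable ~ b, data = x, FUN = sum)
  cat(sprintf("Bifurcation diagram: %d b values; bistable on [%.3g, %.3g]\n",
              nb, suppressWarnings(min(bist$b[bist$stable == 2])),
              suppressWarnings(max(bist$b[bist$stable == 2]))))
  invisible(x)
}

#' Decision-regime map of the view-based choice stage
#'
#' Classifies each background input I0 as non-competing (a single stable
#' fixed point with C1 = C2) or winner-take-all (two stable asymmetric
#' attractors) by solving the fixed points of the symmetric C1/C2 subsystem
#' (no value inputs). The background includes the resting term \code{I_bg},
#' so I0 plays the role of the switch output rE.
#'
#' @param params a \code{\link{circuit_params}}.
#' @param I0_range numeric grid of background inputs.
#' @return Data frame of class \code{regime_map}: \code{I0}, number of
#'   stable/unstable fixed points, and \code{regime}.
#' @examples
#' rm <- decision_regime(circuit_params(), c(0, 1))
#' rm$regime
#' @export
decision_regime <- function(params = circuit_params(),
                            I0_range = seq(0, 1.2, by = 0.05)) {
  p <- params
  sigC <- function(u) 1 / (1 + exp(-u / p$alpha1))
  rows <- lapply(I0_range, function(I0) {
    Ffun <- function(x) c(
      -x[1] + sigC(p$w_plus * x[1] - p$w_minus * x[2] + I0 + p$I_bg),
      -x[2] + sigC(p$w_plus * x[2] - p$w_minus * x[1] + I0 + p$I_bg))
    Jfun <- function(x) {
      s1 <- sigC(p$w_plus * x[1] - p$w_minus * x[2] + I0 + p$I_bg)
      s2 <- sigC(p$w_plus * x[2] - p$w_minus * x[1] + I0 + p$I_bg)
      d1 <- s1 * (1 - s1) / p$alpha1
      d2 <- s2 * (1 - s2) / p$alpha1
      rbind(c(-1 + p$w_plus * d1, -p$w_minus * d1),
            c(-p$w_minus * d2, -1 + p$w_plus * d2))
    }
    roots <- solve_fixed_points(Ffun, Jfun,
                                expand.grid(seq(0, 1, 0.1), seq(0, 1, 0.1)))
    stable <- vapply(roots, function(r)
      all(Re(eigen(Jfun(r), only.values = TRUE)$values) < -1e-8), logical(1))
    asym <- vapply(roots, function(r) abs(r[1] - r[2]) > 1e-6, logical(1))
    n_stable_asym <- sum(stable & asym)
    data.frame(I0 = I0, n_stable = sum(stable), n_unstable = sum(!stable),
               regime = if (n_stable_asym >= 2) "winner_take_all"
                        else "non_competing")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("regime_map", "data.frame")
  out
}

#' Run an ablation battery on a circuit variant
#'
#' Simulates a battery of trials (both viewing orders crossed with a grid of
#' value pairs) under an alternative architecture and summarizes the
#' qualitative outcome:
#' \describe{
#'   \item{classical_simultaneous}{classical attractor decision circuit with
#'     simultaneously applied object-specific value inputs; selects the
#'     higher value but needs one decision channel per object.}
#'   \item{no_switch}{no bistable switch; with low background the decision
#'     stage never separates into an attractor.}
#'   \item{object_specific_view}{cross-connections from object values to the
#'     view-based stage removed; the integral-feedback comparison is lost and
#'     the second-presented option always wins.}
#'   \item{positive_tuned_wMC08}{object-specific channels with positive
#'     memory feedback (weight 0.8); correct for two objects, but each added
#'     object needs new object-specific wiring.}
#' }
#'
#' @param variant one of the four ablation ids.
#' @param value_grid numeric values used to build ordered pairs.
#' @param params a \code{\link{circuit_params}}; battery runs use
#'   \code{eta = 0} unless overridden.
#' @param seed integer seed (used when \code{eta > 0}).
#' @return An object of class \code{ablation_report}: the per-trial outcome
#'   table and a verdict list derived only from the simulated outcomes plus
#'   the structural extensibility flag.
#' @examples
#' rep <- run_ablation("object_specific_view", value_grid = c(0.2, 0.8))
#' rep$verdict$second_always
#' @export
run_ablation <- function(variant = c("classical_simultaneous", "no_switch",
                                     "object_specific_view",
                                     "positive_tuned_wMC08"),
                         value_grid = seq(0.1, 0.9, by = 0.2),
                         params = circuit_params(eta = 0), seed = NULL) {
  variant <- match.arg(variant)
  pairs <- expand.grid(v1 = value_grid, v2 = value_grid)
  pairs <- pairs[abs(pairs$v1 - pairs$v2) >= 0.1, ]
  battery <- rbind(
    data.frame(pairs, s1 = "A", s2 = "B"),
    data.frame(pairs, s1 = "B", s2 = "A"))
  values <- matrix(NA_real_, nrow(battery), 2, dimnames = list(NULL, c("A", "B")))
  values[cbind(seq_len(nrow(battery)), match(battery$s1, c("A", "B")))] <- battery$v1
  values[cbind(seq_len(nrow(battery)), match(battery$s2, c("A", "B")))] <- battery$v2
  run <- with_seed(seed, circuit_run(params, values, battery$s1, battery$s2,
                                     variant = variant))
  ro <- run$readout
  higher <- ifelse(ro$v_second > ro$v_first, ro$seq2, ro$seq1)
  second <- ro$seq2
  verdict <- list(
    variant = variant,
    n_trials = nrow(ro),
    frac_decided = mean(ro$decided),
    frac_higher_value = mean(ro$object_choice == higher, na.rm = TRUE),
    frac_second_chosen = mean(ro$object_choice == second, na.rm = TRUE),
    second_always = all(ro$object_choice == second, na.rm = TRUE) &&
      !any(is.na(ro$object_choice)),
    never_decides = !any(ro$decided),
    many_objects_extensible = !(variant %in% c("classical_simultaneous",
                                               "object_specific_view",
                                               "positive_tuned_wMC08")))
  structure(list(variant = variant, outcomes = ro, verdict = verdict),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  v <- x$verdict
  cat(sprintf("Ablation '%s': %d trials\n", v$variant, v$n_trials))
  cat(sprintf("  decided %.0f%%; higher-value chosen %.0f%%; second chosen %.0f%%\n",
              100 * v$frac_decided, 100 * v$frac_higher_value,
              100 * v$frac_second_chosen))
  cat(sprintf("  extends to many objects without new wiring: %s\n",
              v$many_objects_extensible))
  invisible(x)
}

#' Choice among a pair drawn from a many-object set
#'
#' Extends the circuit to more than two objects: the view-based stage is
#' unchanged (it receives the value of whichever object is on screen), while
#' the object-sequence and combination stages carry one unit pair per
#' object and the object winner-take-all spans the whole set. Only the two
#' objects named in \code{pair} are presented.
#'
#' @param params a \code{\link{circuit_params}}.
#' @param object_values named numeric vector (>= 2 objects, values in [0,1]).
#' @param pair character vector of two object ids to present.
#' @param sequence optional explicit presentation order (defaults to
#'   \code{pair}).
#' @param seed integer seed.
#' @return List with \code{object_choice}, \code{view_choice}, margins and
#'   the trace bundle from the underlying run.
#' @examples
#' ov <- c(A = 0.1, B = 0.4, C = 0.6, D = 0.9)
#' simulate_many_objects(circuit_params(eta = 0), ov, c("B", "D"))$object_choice
#' @export
simulate_many_objects <- function(params = circuit_params(), object_values,
                                  pair, sequence = pair, seed = NULL) {
  if (length(object_values) < 2L) stopf("need at least two objects")
  if (is.null(names(object_values)))
    names(object_values) <- LETTERS[seq_along(object_values)]
  if (!all(pair %in% names(object_values)))
    stopf("pair ids must be members of the object set")
  if (length(pair) != 2L || pair[1] == pair[2])
    stopf("pair must name two distinct objects")
  values <- matrix(object_values, 1,
                   dimnames = list(NULL, names(object_values)))
  run <- with_seed(seed, circuit_run(params, values, sequence[1], sequence[2]))
  ro <- run$readout
  list(object_choice = ro$object_choice, view_choice = ro$view_choice,
       margin_object = ro$margin_object, margin_view = ro$margin_view,
       decided = ro$decided, run = run)
}
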