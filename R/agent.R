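RL_VARIANTS <- c("basic", "basic_2lr", "reversal", "reversal_2lr",
                 "pearce_hall", "ph_reversal", "ph_reversal_2lr")

#' Reinforcement-learning agent parameters
#'
#' Constructs and validates the parameter set of the RL model family.
#' The \code{reversal} variants update the unchosen object's value with the
#' sign-flipped reward (-R), capturing the anti-correlated value structure of
#' reversal learning; the Pearce-Hall variants replace the fixed learning
#' rate with a dynamic associability
#' \eqn{\alpha_t = \gamma |\delta_{t-1}| + (1-\gamma)\alpha_{t-1}}.
#'
#' @param variant one of \code{"basic"}, \code{"basic_2lr"}, \code{"reversal"},
#'   \code{"reversal_2lr"}, \code{"pearce_hall"}, \code{"ph_reversal"},
#'   \code{"ph_reversal_2lr"}.
#' @param alpha learning rate in [0, 1] (initial associability for
#'   Pearce-Hall variants).
#' @param beta softmax inverse temperature, >= 0.
#' @param alpha_minus second learning rate for unrewarded trials
#'   (\code{*_2lr} variants only).
#' @param gamma Pearce-Hall associability decay in [0, 1].
#' @param w_mag weight on the cued reward magnitude (mL) in the agent's
#'   decision utility \eqn{U_X = V_X + w_{mag} M_X}; 0 gives the pure
#'   probability-tracking agent assumed by the RL likelihood.
#' @return A list of class \code{rl_params}.
#' @examples
#' rl_params("reversal", alpha = 0.3, beta = 3)
#' @export
rl_params <- function(variant = "reversal", alpha = 0.3, beta = 3,
                      alpha_minus = NULL, gamma = NULL, w_mag = 0) {
  if (!variant %in% RL_VARIANTS) stopf("unknown RL variant '%s'", variant)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stopf("alpha must lie in [0, 1]")
  if (!is.numeric(beta) || beta < 0) stopf("beta must be >= 0")
  two_lr <- grepl("2lr$", variant)
  ph <- grepl("^ph|pearce", variant)
  if (two_lr) {
    alpha_minus <- alpha_minus %||% alpha
    if (alpha_minus < 0 || alpha_minus > 1) stopf("alpha_minus must lie in [0, 1]")
  }
  if (ph) {
    gamma <- gamma %||% 0.3
    if (gamma < 0 || gamma > 1) stopf("gamma must lie in [0, 1]")
  }
  structure(list(variant = variant, alpha = alpha, beta = beta,
                 alpha_minus = alpha_minus, gamma = gamma, w_mag = w_mag),
            class = "rl_params")
}

n_rl_params <- function(variant) {
  switch(variant,
         basic = 2L, reversal = 2L,
         basic_2lr = 3L, reversal_2lr = 3L,
         pearce_hall = 3L, ph_reversal = 3L,
         ph_reversal_2lr = 4L)
}

# One value update. `state` carries values (named by object) and the dynamic
# associabilities for Pearce-Hall variants.
rl_step <- function(state, chosen, unchosen, R, params) {
  v <- state$v
  ph <- grepl("^ph|pearce", params$variant)
  two_lr <- grepl("2lr$", params$variant)
  reversal <- grepl("reversal", params$variant) && params$variant != "basic_2lr"
  delta <- R - v[chosen]
  if (ph) {
    a_plus <- state$a_plus
    a_minus <- state$a_minus
    lr <- if (two_lr && R == 0) a_minus else a_plus
  } else {
    lr <- if (two_lr && R == 0) params$alpha_minus else params$alpha
  }
  v[chosen] <- v[chosen] + lr * delta
  if (reversal) v[unchosen] <- v[unchosen] + lr * (-R - v[unchosen])
  if (ph) {
    # Associability decays toward the unsigned prediction error.
    state$a_plus <- params$gamma * abs(delta) + (1 - params$gamma) * state$a_plus
    if (two_lr)
      state$a_minus <- params$gamma * abs(delta) + (1 - params$gamma) * state$a_minus
  }
  state$v <- v
  state$delta <- delta
  state
}

rl_init_state <- function(objects, params) {
  list(v = setNames(rep(0, length(objects)), objects),
       a_plus = params$alpha,
       a_minus = if (grepl("2lr$", params$variant)) params$alpha_minus else params$alpha,
       delta = NA_real_)
}

#' Simulate an RL agent on a session schedule
#'
#' Plays the schedule with a softmax reinforcement-learning agent: values of
#' the two presented objects are compared (optionally combined with the cued
#' magnitudes), a choice is sampled from the softmax of the utility
#' difference, and the reward outcome is drawn from the chosen object's block
#' probability. Values are then updated per the variant's learning rule.
#'
#' @param schedule a \code{session_schedule}.
#' @param params an \code{\link{rl_params}} object (or list coercible to one).
#' @param seed integer seed; the behavior is reproducible from
#'   \code{(schedule, params, seed)}.
#' @return An object of class \code{session_behavior}: the schedule plus a
#'   per-trial record with pre-choice values \code{v_first}/\code{v_second},
#'   the chosen object, the view-based choice (\code{"first"}/\code{"second"}),
#'   the chosen side, the binary reward outcome and the delivered volume (mL).
#' @examples
#' beh <- simulate_agent(generate_schedule("main", 100, seed = 1),
#'                       rl_params("reversal", 0.3, 3), seed = 2)
#' mean(beh$trials$rewarded)
#' @export
simulate_agent <- function(schedule, params = rl_params(), seed = NULL) {
  stopifnot(inherits(schedule, "session_schedule"))
  if (!inherits(params, "rl_params")) params <- do.call(rl_params, params)
  tr <- schedule$trials
  n <- nrow(tr)
  state <- rl_init_state(schedule$objects, params)
  two_juices <- schedule$task_variant == "two_juices"

  chosen <- character(n); rewarded <- integer(n); volume <- numeric(n)
  v_first <- numeric(n); v_second <- numeric(n)
  vmat <- matrix(NA_real_, n, length(schedule$objects),
                 dimnames = list(NULL, schedule$objects))
  delta <- numeric(n)

  with_seed(seed, {
    for (i in seq_len(n)) {
      o1 <- tr$obj_first[i]; o2 <- tr$obj_second[i]
      m1 <- tr[[paste0("mag.", o1)]][i]; m2 <- tr[[paste0("mag.", o2)]][i]
      u1 <- state$v[o1] + params$w_mag * m1
      u2 <- state$v[o2] + params$w_mag * m2
      v_first[i] <- u1; v_second[i] <- u2
      vmat[i, ] <- state$v
      p_first <- 1 / (1 + exp(-params$beta * (u1 - u2)))
      take_first <- runif(1) < p_first
      ch <- if (take_first) o1 else o2
      un <- if (take_first) o2 else o1
      p_rew <- tr[[paste0("prob.", ch)]][i]
      rew <- as.integer(runif(1) < p_rew)
      if (two_juices) {
        # Reward signal is the delivery of the preferred juice (J1).
        rew <- as.integer(tr[[paste0("juice.", ch)]][i] == "J1")
      }
      chosen[i] <- ch
      rewarded[i] <- rew
      volume[i] <- if (rew) tr[[paste0("mag.", ch)]][i] else SMALL_REWARD
      state <- rl_step(state, ch, un, rew, params)
      delta[i] <- state$delta
    }
  })

  rec <- data.frame(
    trial = tr$trial,
    chosen_obj = chosen,
    view_choice = ifelse(chosen == tr$obj_first, "first", "second"),
    chosen_side = ifelse(chosen == tr$left_obj, "left", "right"),
    v_first = v_first, v_second = v_second,
    rewarded = rewarded, volume = volume, pe = delta,
    stringsAsFactors = FALSE)
  colnames(vmat) <- paste0("v.", schedule$objects)
  rec <- cbind(rec, vmat)

  structure(list(schedule = schedule, params = params, seed = seed,
                 trials = cbind(tr, rec[, -1, drop = FALSE])),
            class = "session_behavior")
}

#' @export
print.session_behavior <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("Session behavior (%s task): %d trials\n",
              x$schedule$task_variant, nrow(tr)))
  if (nrow(tr)) {
    cat(sprintf("  first-viewed chosen: %.1f%%; rewarded: %.1f%%\n",
                100 * mean(tr$view_choice == "first"),
                100 * mean(tr$rewarded)))
  }
  invisible(x)
}
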