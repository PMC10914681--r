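#' Session-level logistic value model
#'
#' Fits, within one session, a logistic regression of the object-A choice on
#' the viewing order and on the magnitude and probability differences
#' between the objects,
#' \deqn{logit(P(A\ chosen)) = \beta_0 + \beta_1 AFirst +
#'   \beta_2 (RM_A - RM_B) + \beta_3 (Prob_A - Prob_B),}
#' and defines the session-specific object value as
#' \eqn{\beta_2 RM + \beta_3 Prob}. This captures the animal- and
#' session-specific weighting of magnitude against probability that all
#' neuronal value regressors inherit.
#'
#' Complete separation (or non-convergence) triggers a ridge-stabilized
#' refit, flagged in the result.
#'
#' @param behavior a \code{session_behavior} from the main task, with both
#'   choice outcomes present.
#' @param ridge L2 penalty used only for the stabilized refit.
#' @return An object of class \code{session_value_model} with the
#'   coefficients \code{b0..b3}, the value weights (\code{b2} for magnitude,
#'   \code{b3} for probability), and \code{separation} flag.
#' @examples
#' beh <- simulate_agent(generate_schedule("main", 200, seed = 1),
#'                       rl_params("reversal", 0.4, 4, w_mag = 2), seed = 2)
#' m <- session_value_model(beh)
#' coef(m)
#' @export
session_value_model <- function(behavior, ridge = 1e-2) {
  stopifnot(inherits(behavior, "session_behavior"))
  tr <- behavior$trials
  y <- as.integer(tr$chosen_obj == "A")
  if (length(unique(y)) < 2L)
    stopf("both outcome classes (A and B chosen) must be present")
  X <- data.frame(
    a_first = as.integer(tr$obj_first == "A"),
    d_mag = tr$mag.A - tr$mag.B,
    d_prob = tr$prob.A - tr$prob.B)
  fit <- suppressWarnings(glm(y ~ a_first + d_mag + d_prob,
                              data = cbind(X, y = y), family = binomial()))
  separated <- !fit$converged || max(abs(coef(fit))) > 15
  if (separated) {
    cf <- ridge_logistic(cbind(1, as.matrix(X)), y, lambda = ridge)
  } else {
    cf <- coef(fit)
  }
  names(cf) <- c("b0", "b1", "b2", "b3")
  structure(list(coefficients = cf, separation = separated,
                 glm = if (!separated) fit else NULL,
                 behavior = behavior),
            class = "session_value_model")
}

# Penalized IRLS (ridge on slopes, not the intercept); used when the
# session's choices are perfectly separable.
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 100L) {
  beta <- rep(0, ncol(X))
  P <- diag(c(0, rep(lambda, ncol(X) - 1L)))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- logistic(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X, X * w) + P, crossprod(X, w * z))
    if (max(abs(new - beta)) < 1e-10) { beta <- drop(new); break }
    beta <- drop(new)
  }
  beta
}

#' @export
coef.session_value_model <- function(object, ...) object$coefficients

#' @export
print.session_value_model <- function(x, ...) {
  cat("Session value model: logit(A chosen) ~ AFirst + dMag + dProb\n")
  print(round(x$coefficients, 4))
  if (x$separation) cat("  (ridge-stabilized: separation detected)\n")
  cat(sprintf("  value weights: magnitude %.3f, probability %.3f\n",
              x$coefficients["b2"], x$coefficients["b3"]))
  invisible(x)
}

#' Object value implied by a session value model
#'
#' \eqn{value = \beta_2 RM + \beta_3 Prob} with the session's fitted weights.
#'
#' @param model a \code{session_value_model}.
#' @param rm cued reward magnitude (mL).
#' @param prob reward probability.
#' @export
object_value <- function(model, rm, prob) {
  cf <- coef(model)
  unname(cf["b2"] * rm + cf["b3"] * prob)
}

#' Attach session object values to a behavior record
#'
#' Computes per-trial object values from a fitted
#' \code{\link{session_value_model}} and affinely rescales them to [0, 1]
#' using the session minimum/maximum, the scale required by the circuit
#' model and by the parametric tuning curves. Adds columns \code{value.A},
#' \code{value.B}, \code{value_first}, \code{value_second},
#' \code{value_chosen}, plus magnitude-only components \code{magval_first},
#' \code{magval_second} used by the tuning-reversal analyses.
#'
#' @param behavior a \code{session_behavior}.
#' @param model optional prefitted model; fitted from \code{behavior} if
#'   missing.
#' @return The behavior with augmented trial table; the model is attached as
#'   \code{$value_model}.
#' @export
attach_values <- function(behavior, model = NULL) {
  stopifnot(inherits(behavior, "session_behavior"))
  model <- model %||% session_value_model(behavior)
  tr <- behavior$trials
  vA <- object_value(model, tr$mag.A, tr$prob.A)
  vB <- object_value(model, tr$mag.B, tr$prob.B)
  rng <- range(c(vA, vB))
  scale01 <- function(v) if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0.5, length(v))
  tr$value.A <- scale01(vA)
  tr$value.B <- scale01(vB)
  tr$value_first <- ifelse(tr$obj_first == "A", tr$value.A, tr$value.B)
  tr$value_second <- ifelse(tr$obj_first == "A", tr$value.B, tr$value.A)
  tr$value_chosen <- ifelse(tr$chosen_obj == "A", tr$value.A, tr$value.B)
  mag_first <- ifelse(tr$obj_first == "A", tr$mag.A, tr$mag.B)
  mag_second <- ifelse(tr$obj_first == "A", tr$mag.B, tr$mag.A)
  cf <- coef(model)
  tr$magval_first <- cf["b2"] * mag_first
  tr$magval_second <- cf["b2"] * mag_second
  behavior$trials <- tr
  behavior$value_model <- model
  behavior
}
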