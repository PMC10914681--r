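#' Negative log-likelihood of an RL model on observed behavior
#'
#' Replays the trial-by-trial record under the given parameters: values are
#' updated exactly per the variant's rule (the reversal variants apply the
#' \eqn{-R_t} update to the unchosen object), and each realized choice
#' contributes \eqn{-\log} of its softmax probability. Choice probabilities
#' are floored at \code{1e-12} before taking logs; trials hitting the floor
#' are flagged.
#'
#' @param behavior a \code{session_behavior}.
#' @param params an \code{\link{rl_params}} object.
#' @return A list with \code{negll}, the per-trial choice probabilities
#'   \code{p_choice}, the pre-choice value series \code{values} (trials x
#'   objects), per-trial prediction errors \code{pe}, and \code{clamped}
#'   (TRUE if any probability hit the floor).
#' @examples
#' beh <- simulate_agent(generate_schedule("main", 60, seed = 1),
#'                       rl_params("reversal", 0.3, 3), seed = 2)
#' rl_loglikelihood(beh, rl_params("reversal", 0.3, 3))$negll
#' @export
rl_loglikelihood <- function(behavior, params) {
  stopifnot(inherits(behavior, "session_behavior"))
  if (!inherits(params, "rl_params")) params <- do.call(rl_params, params)
  tr <- behavior$trials
  n <- nrow(tr)
  if (n == 0L) stopf("behavior has no trials")
  objects <- behavior$schedule$objects
  values <- matrix(NA_real_, n, length(objects), dimnames = list(NULL, objects))
  p_choice <- numeric(n)
  pe <- numeric(n)
  floor_p <- 1e-12
  # inlined update loop (hot path for model fitting); rl_step is the
  # reference implementation used by the agent simulator
  v <- setNames(rep(0, length(objects)), objects)
  ph <- grepl("^ph|pearce", params$variant)
  two_lr <- grepl("2lr$", params$variant)
  reversal <- grepl("reversal", params$variant) && params$variant != "basic_2lr"
  a_plus <- params$alpha
  a_minus <- if (two_lr) params$alpha_minus else params$alpha
  beta <- params$beta
  gamma <- params$gamma
  ich <- match(tr$chosen_obj, objects)
  iun <- match(ifelse(tr$chosen_obj == tr$obj_first, tr$obj_second,
                      tr$obj_first), objects)
  R <- tr$rewarded
  for (i in seq_len(n)) {
    values[i, ] <- v
    ci <- ich[i]; ui <- iun[i]
    p_choice[i] <- 1 / (1 + exp(-beta * (v[ci] - v[ui])))
    delta <- R[i] - v[ci]
    lr <- if (ph) { if (two_lr && R[i] == 0) a_minus else a_plus } else {
      if (two_lr && R[i] == 0) params$alpha_minus else params$alpha
    }
    v[ci] <- v[ci] + lr * delta
    if (reversal) v[ui] <- v[ui] + lr * (-R[i] - v[ui])
    if (ph) {
      a_plus <- gamma * abs(delta) + (1 - gamma) * a_plus
      if (two_lr) a_minus <- gamma * abs(delta) + (1 - gamma) * a_minus
    }
    pe[i] <- delta
  }
  clamped <- any(p_choice < floor_p)
  negll <- -sum(log(pmax(p_choice, floor_p)))
  list(negll = negll, p_choice = p_choice, values = values, pe = pe,
       clamped = clamped)
}

# Parameter transforms keeping Nelder-Mead unconstrained: alpha/gamma via
# logistic, beta via exp.
rl_pack <- function(params) {
  variant <- params$variant
  th <- c(alpha = stats::qlogis(min(max(params$alpha, 1e-6), 1 - 1e-6)),
          beta = log(max(params$beta, 1e-6)))
  if (grepl("2lr$", variant))
    th <- c(th, alpha_minus = stats::qlogis(min(max(params$alpha_minus, 1e-6), 1 - 1e-6)))
  if (grepl("^ph|pearce", variant))
    th <- c(th, gamma = stats::qlogis(min(max(params$gamma, 1e-6), 1 - 1e-6)))
  th
}

rl_unpack <- function(theta, variant) {
  p <- list(variant = variant,
            alpha = stats::plogis(theta[["alpha"]]),
            beta = exp(theta[["beta"]]))
  if (grepl("2lr$", variant)) p$alpha_minus <- stats::plogis(theta[["alpha_minus"]])
  if (grepl("^ph|pearce", variant)) p$gamma <- stats::plogis(theta[["gamma"]])
  do.call(rl_params, p)
}

#' Fit an RL model to a session by maximum likelihood
#'
#' Minimizes the negative log-likelihood with Nelder-Mead from multiple
#' random starting points; parameters are constrained by smooth transforms
#' (learning rates and associability decay via the logistic, inverse
#' temperature via the exponential).
#'
#' @param behavior a \code{session_behavior} with at least 20 trials.
#' @param variant RL variant id (see \code{\link{rl_params}}).
#' @param n_restarts number of random Nelder-Mead starts.
#' @param seed integer seed for the random starts.
#' @param tol convergence tolerance on the negative log-likelihood.
#' @return An object of class \code{rl_fit} with components \code{params}
#'   (the \code{\link{rl_params}} estimate), \code{negll}, \code{aic},
#'   \code{bic}, \code{k}, \code{n}, \code{n_restarts}, \code{convergence}
#'   (per-restart codes) and \code{boundary} (TRUE when the inverse
#'   temperature is pinned near 0, signalling an uninformative likelihood).
#' @seealso \code{\link{compare_rl_models}}
#' @examples
#' beh <- simulate_agent(generate_schedule("main", 150, seed = 1),
#'                       rl_params("reversal", 0.3, 3), seed = 2)
#' fit <- rl_fit(beh, "reversal", n_restarts = 5, seed = 3)
#' coef(fit)
#' @export
rl_fit <- function(behavior, variant = "reversal", n_restarts = 20,
                   seed = NULL, tol = 1e-6) {
  stopifnot(inherits(behavior, "session_behavior"))
  if (!variant %in% RL_VARIANTS) stopf("unknown RL variant '%s'", variant)
  n <- nrow(behavior$trials)
  if (n < 20) stopf("need >= 20 trials to fit an RL model (got %d)", n)

  obj_fun <- function(theta_raw, template) {
    names(theta_raw) <- names(template)
    p <- rl_unpack(theta_raw, variant)
    rl_loglikelihood(behavior, p)$negll
  }

  template <- rl_pack(rl_params(variant, 0.5, 1,
                                alpha_minus = 0.5, gamma = 0.5))
  best <- NULL
  conv <- integer(0)
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      start <- template
      start[] <- rnorm(length(template), 0, 1.5)
      opt <- tryCatch(
        optim(start, obj_fun, template = template, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = tol)),
        error = function(e) NULL)
      if (is.null(opt)) next
      conv <- c(conv, opt$convergence)
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  })
  if (is.null(best)) stopf("all %d restarts failed to converge", n_restarts)

  theta <- best$par
  names(theta) <- names(template)
  params <- rl_unpack(theta, variant)
  k <- n_rl_params(variant)
  negll <- best$value
  structure(list(params = params, negll = negll,
                 aic = 2 * k + 2 * negll, bic = k * log(n) + 2 * negll,
                 k = k, n = n, n_restarts = n_restarts,
                 convergence = conv, boundary = params$beta < 0.05,
                 variant = variant, behavior = behavior, seed = seed),
            class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf("RL fit ('%s'): n = %d trials, k = %d\n", x$variant, x$n, x$k))
  cat("  ", paste(sprintf("%s = %.3f", names(coef(x)), coef(x)), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  -logL = %.2f, AIC = %.2f, BIC = %.2f\n", x$negll, x$aic, x$bic))
  if (x$boundary)
    cat("  note: inverse temperature pinned near zero (uninformative choices)\n")
  invisible(x)
}

#' @export
coef.rl_fit <- function(object, ...) {
  p <- object$params
  out <- c(alpha = p$alpha, beta = p$beta)
  if (!is.null(p$alpha_minus) && grepl("2lr$", p$variant))
    out <- c(out, alpha_minus = p$alpha_minus)
  if (!is.null(p$gamma) && grepl("^ph|pearce", p$variant))
    out <- c(out, gamma = p$gamma)
  out
}

#' @export
logLik.rl_fit <- function(object, ...) {
  structure(-object$negll, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
summary.rl_fit <- function(object, ...) {
  ll <- rl_loglikelihood(object$behavior, object$params)
  out <- list(fit = object, mean_p = mean(ll$p_choice), clamped = ll$clamped)
  class(out) <- "summary.rl_fit"
  out
}

#' @export
print.summary.rl_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  mean per-trial choice probability: %.3f\n", x$mean_p))
  invisible(x)
}

#' @export
simulate.rl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  lapply(seq_len(nsim), function(i)
    simulate_agent(object$behavior$schedule, object$params,
                   seed = child_seed(seed %||% 1L, i)))
}

#' Compare RL model variants across sessions
#'
#' Fits every variant to every session and tabulates summed AIC/BIC and the
#' per-session winner counts.
#'
#' @param behaviors a list of \code{session_behavior} objects.
#' @param variants character vector of variant ids.
#' @param n_restarts,seed passed to \code{\link{rl_fit}}.
#' @return A data frame of class \code{rl_model_comparison} with one row per
#'   variant: \code{k}, \code{sum_aic}, \code{sum_bic}, \code{aic_wins},
#'   \code{bic_wins}; the per-session fits are attached as attribute
#'   \code{"fits"}.
#' @export
compare_rl_models <- function(behaviors, variants = c("basic", "reversal"),
                              n_restarts = 10, seed = NULL) {
  if (inherits(behaviors, "session_behavior")) behaviors <- list(behaviors)
  fits <- lapply(seq_along(variants), function(j) {
    lapply(seq_along(behaviors), function(i)
      rl_fit(behaviors[[i]], variants[j], n_restarts = n_restarts,
             seed = child_seed(seed, i * 131 + j)))
  })
  names(fits) <- variants
  aic <- sapply(fits, function(fl) sapply(fl, `[[`, "aic"))
  bic <- sapply(fits, function(fl) sapply(fl, `[[`, "bic"))
  if (is.null(dim(aic))) { aic <- matrix(aic, 1); bic <- matrix(bic, 1) }
  out <- data.frame(
    variant = variants,
    k = sapply(variants, n_rl_params),
    sum_aic = colSums(aic), sum_bic = colSums(bic),
    aic_wins = tabulate(apply(aic, 1, which.min), length(variants)),
    bic_wins = tabulate(apply(bic, 1, which.min), length(variants)),
    row.names = NULL)
  attr(out, "fits") <- fits
  class(out) <- c("rl_model_comparison", "data.frame")
  out
}
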