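#' Z-normalize epoch activity against the pre-fixation control period
#'
#' Converts epoch spike counts to rates and normalizes each neuron by its
#' control-period statistics: (rate - baseline mean) / baseline SD, where
#' the baseline is the fixation epoch. Neurons with zero baseline SD are
#' excluded and listed.
#'
#' @param recording a \code{recording_set}.
#' @param baseline_epoch epoch used as control period.
#' @return List of class \code{zscored_epochs}: \code{z} (neuron x trial x
#'   epoch array for the retained neurons), \code{kept}, \code{excluded}
#'   (neuron indices with degenerate baseline).
#' @examples
#' beh <- attach_values(simulate_agent(generate_schedule("main", 50, seed = 1),
#'                                     seed = 2))
#' rec <- generate_spike_counts(generate_population(4, seed = 3), beh, seed = 4)
#' z <- zscore_epochs(rec)
#' round(mean(z$z[1, , "fixation"]), 8)
#' @export
zscore_epochs <- function(recording, baseline_epoch = "fixation") {
  stopifnot(inherits(recording, "recording_set"))
  ec <- recording$epoch_counts
  dur_s <- 0.5
  rates <- ec / dur_s
  base <- rates[, , baseline_epoch, drop = FALSE]
  mu <- apply(base, 1, mean)
  sdv <- apply(base, 1, sd)
  excluded <- which(sdv == 0 | !is.finite(sdv))
  kept <- setdiff(seq_len(dim(ec)[1]), excluded)
  z <- rates[kept, , , drop = FALSE]
  for (k in seq_along(kept)) {
    z[k, , ] <- (z[k, , ] - mu[kept[k]]) / sdv[kept[k]]
  }
  structure(list(z = z, kept = kept, excluded = excluded,
                 epochs = dimnames(ec)[[3]]),
            class = "zscored_epochs")
}

#' Multiple linear regression for single-neuron activity
#'
#' Least-squares fit of a neuronal response on a set of task regressors,
#' reporting raw and standardized coefficients (x_i s_i / s_y), two-sided t
#' tests, the overall F test, and the coefficient of partial determination
#' (partial R-squared) per regressor:
#' (SSE_reduced - SSE_full) / SSE_reduced.
#'
#' @param design data frame or matrix of regressors (no intercept column;
#'   one is added).
#' @param response numeric response vector.
#' @return An object of class \code{neuron_glm}: \code{coefficients} table
#'   (estimate, std_beta, t, p, partial_r2), \code{fstat}, \code{f_p},
#'   \code{r2}, \code{df_residual}, \code{n}.
#' @examples
#' d <- data.frame(a = rnorm(50), b = rnorm(50))
#' fit <- neuron_glm(d, 2 * d$a + rnorm(50))
#' fit$coefficients["a", "p"]
#' @export
neuron_glm <- function(design, response) {
  X0 <- as.matrix(design)
  if (is.null(colnames(X0))) colnames(X0) <- paste0("x", seq_len(ncol(X0)))
  n <- length(response)
  if (n != nrow(X0)) stopf("response length does not match design rows")
  if (n < ncol(X0) + 2L) stopf("need at least p + 2 observations")
  X <- cbind(`(Intercept)` = 1, X0)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(drop, collapse = ", "))
  }
  fit <- lm.fit(X, response)
  res <- fit$residuals
  p <- ncol(X)
  df <- n - p
  sse <- sum(res^2)
  s2 <- sse / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(XtXinv) * s2)
  est <- fit$coefficients
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df)
  sy <- sd(response)
  std <- vapply(seq_len(p), function(j)
    if (j == 1) NA_real_ else est[j] * sd(X[, j]) / sy, numeric(1))
  sst <- sum((response - mean(response))^2)
  r2 <- 1 - sse / sst
  fstat <- ((sst - sse) / (p - 1)) / s2
  f_p <- pf(fstat, p - 1, df, lower.tail = FALSE)
  # partial R2: refit without each regressor
  pr2 <- vapply(seq_len(p), function(j) {
    if (j == 1) return(NA_real_)
    rfit <- lm.fit(X[, -j, drop = FALSE], response)
    sse_red <- sum(rfit$residuals^2)
    (sse_red - sse) / sse_red
  }, numeric(1))
  coefs <- data.frame(estimate = est, std_beta = std, t = tval, p = pval,
                      partial_r2 = pr2, row.names = colnames(X))
  structure(list(coefficients = coefs, fstat = fstat, f_p = f_p, r2 = r2,
                 df_residual = df, n = n, sigma2 = s2),
            class = "neuron_glm")
}

#' @export
print.neuron_glm <- function(x, ...) {
  cat(sprintf("Neuron GLM: n = %d, R2 = %.3f, F p = %.3g\n", x$n, x$r2, x$f_p))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.neuron_glm <- function(object, ...) {
  setNames(object$coefficients$estimate, rownames(object$coefficients))
}

#' Task design matrices with the standard regressor codings
#'
#' Builds the regressor set of the fixed- and sliding-window neuron
#' regressions for the given task variant:
#' \describe{
#'   \item{glm2}{main task: ViewChoice (1 = first-viewed chosen),
#'     ObjectChoice (1 = A chosen), ObjectView (1 = A-then-B), FirstValue,
#'     SecondValue, ChosenValue, ObjectALeft, LeftChosen.}
#'   \item{glm3}{as glm2 but with the probability (model-derived) and
#'     magnitude components instead of integrated values.}
#'   \item{glm5}{four-objects task: ViewChoice, block-wise choice and
#'     viewing contrasts (A-B, C-D coded 1/-1/0), and the value terms;
#'     cue-position and left-choice regressors omitted.}
#'   \item{glm6}{two-juices task: ViewChoice, ObjectAChoice, JuiceAChoice,
#'     ObjectAView, JuiceAFirst, magnitude-defined values, and side terms.}
#' }
#'
#' @param behavior a \code{session_behavior} with attached values (main
#'   task) as produced by \code{\link{attach_values}}.
#' @param model which regressor set to build.
#' @return Data frame of regressors, one row per trial.
#' @export
build_design <- function(behavior, model = c("glm2", "glm3", "glm5", "glm6")) {
  model <- match.arg(model)
  tr <- behavior$trials
  vc <- as.integer(tr$view_choice == "first")
  if (model == "glm2") {
    data.frame(
      ViewChoice = vc,
      ObjectChoice = as.integer(tr$chosen_obj == "A"),
      ObjectView = as.integer(tr$obj_first == "A"),
      FirstValue = tr$value_first,
      SecondValue = tr$value_second,
      ChosenValue = tr$value_chosen,
      ObjectALeft = as.integer(tr$left_obj == "A"),
      LeftChosen = as.integer(tr$chosen_side == "left"))
  } else if (model == "glm3") {
    first_is_A <- tr$obj_first == "A"
    data.frame(
      ViewChoice = vc,
      ObjectChoice = as.integer(tr$chosen_obj == "A"),
      ObjectView = as.integer(first_is_A),
      FirstProb = ifelse(first_is_A, tr$v.A, tr$v.B),
      SecondProb = ifelse(first_is_A, tr$v.B, tr$v.A),
      FirstMag = ifelse(first_is_A, tr$mag.A, tr$mag.B),
      SecondMag = ifelse(first_is_A, tr$mag.B, tr$mag.A),
      ChosenProb = ifelse(tr$chosen_obj == "A", tr$v.A, tr$v.B),
      ChosenMag = ifelse(tr$chosen_obj == "A", tr$mag.A, tr$mag.B),
      ObjectALeft = as.integer(tr$left_obj == "A"),
      LeftChosen = as.integer(tr$chosen_side == "left"))
  } else if (model == "glm5") {
    ab_block <- tr$obj_first %in% c("A", "B")
    contrast <- function(pos, neg, active)
      ifelse(!active, 0, ifelse(pos, 1L, ifelse(neg, -1L, 0L)))
    # probability-only task: values are the model-derived estimates
    vsel <- function(obj) tr[cbind(seq_len(nrow(tr)),
                                   match(paste0("v.", obj), names(tr)))]
    v_first <- tr$value_first %||% vsel(tr$obj_first)
    v_second <- tr$value_second %||% vsel(tr$obj_second)
    v_chosen <- tr$value_chosen %||% vsel(tr$chosen_obj)
    data.frame(
      ViewChoice = vc,
      AminusB_choice = contrast(tr$chosen_obj == "A", tr$chosen_obj == "B", ab_block),
      CminusD_choice = contrast(tr$chosen_obj == "C", tr$chosen_obj == "D", !ab_block),
      AminusB_view = contrast(tr$obj_first == "A", tr$obj_first == "B", ab_block),
      CminusD_view = contrast(tr$obj_first == "C", tr$obj_first == "D", !ab_block),
      FirstValue = v_first,
      SecondValue = v_second,
      ChosenValue = v_chosen)
  } else {
    data.frame(
      ViewChoice = vc,
      ObjectAChoice = as.integer(tr$chosen_obj == "A"),
      JuiceAChoice = as.integer(ifelse(tr$chosen_obj == "A", tr$juice.A,
                                       tr$juice.B) == "J1"),
      ObjectAView = as.integer(tr$obj_first == "A"),
      JuiceAFirst = as.integer(ifelse(tr$obj_first == "A", tr$juice.A, tr$juice.B) == "J1"),
      FirstValue = ifelse(tr$obj_first == "A", tr$mag.A, tr$mag.B),
      SecondValue = ifelse(tr$obj_first == "A", tr$mag.B, tr$mag.A),
      ChosenValue = ifelse(tr$chosen_obj == "A", tr$mag.A, tr$mag.B),
      ObjectALeft = as.integer(tr$left_obj == "A"),
      LeftChosen = as.integer(tr$chosen_side == "left"))
  }
}

#' Wilcoxon task-relatedness gate
#'
#' Flags a neuron as task-related when its cue-period activity differs from
#' the pre-fixation control period (two-sided Wilcoxon signed-rank test at
#' the Bonferroni-corrected threshold).
#'
#' @param recording a \code{recording_set}.
#' @param alpha per-test threshold (default 0.005, Bonferroni-corrected).
#' @return Logical vector, one entry per neuron.
#' @export
task_related <- function(recording, alpha = 0.005) {
  ec <- recording$epoch_counts
  vapply(seq_len(dim(ec)[1]), function(i) {
    p1 <- suppressWarnings(wilcox.test(ec[i, , "cue1"], ec[i, , "fixation"],
                                       paired = TRUE)$p.value)
    p2 <- suppressWarnings(wilcox.test(ec[i, , "cue2"], ec[i, , "fixation"],
                                       paired = TRUE)$p.value)
    isTRUE(p1 < alpha) || isTRUE(p2 < alpha)
  }, logical(1))
}
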