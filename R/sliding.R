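#' Sliding-window regression for one neuron
#'
#' Fits the task regression in a 200-ms window moved in 20-ms steps across
#' the trial and records, per window and regressor, the coefficient, t, p,
#' and partial R-squared. Significance of a regressor over the trial is
#' assessed with the run-length criterion: a neuron is flagged significant
#' when more than \code{min_run} consecutive windows reach p < \code{alpha}
#' (the threshold calibrated so that fewer than 5\% of trial-shuffled
#' neurons pass; see \code{\link{shuffle_run_calibration}}).
#'
#' @param recording a \code{recording_set}.
#' @param neuron neuron index.
#' @param design regressor data frame (one row per trial), e.g. from
#'   \code{\link{build_design}}.
#' @param window_ms window width (ms), \code{step_ms} implied by the bin
#'   grid.
#' @param alpha per-window threshold.
#' @param min_run run-length criterion (strictly greater than).
#' @return An object of class \code{sliding_series}: \code{centers} (ms),
#'   per-regressor matrices \code{coef}, \code{t}, \code{p},
#'   \code{partial_r2} (window x regressor), and \code{significant} /
#'   \code{run_onset} per regressor.
#' @export
sliding_regression <- function(recording, neuron, design, window_ms = 200,
                               alpha = 0.05, min_run = 9) {
  stopifnot(inherits(recording, "recording_set"))
  y_bins <- recording$counts[neuron, , ]        # trials x bins
  sliding_fit(y_bins, design, recording$bins, recording$bin_ms, window_ms,
              alpha, min_run)
}

# Core sliding fit shared by the per-neuron interface and the shuffle
# calibration; y_bins is trials x bins.
sliding_fit <- function(y_bins, design, bins, bin_ms, window_ms = 200,
                        alpha = 0.05, min_run = 9, partial = TRUE) {
  X0 <- as.matrix(design)
  X <- cbind(`(Intercept)` = 1, X0)
  n <- nrow(X); p <- ncol(X)
  bpw <- window_ms / bin_ms                     # bins per window
  n_win <- ncol(y_bins) - bpw + 1L
  if (n_win < 1L) stopf("bin series shorter than one window")
  centers <- bins$start[seq_len(n_win)] + window_ms / 2
  # window responses: rate in impulses/s, windows as columns
  cs <- cbind(0, t(apply(y_bins, 1, cumsum)))
  Y <- (cs[, seq_len(n_win) + bpw] - cs[, seq_len(n_win)]) / (window_ms / 1000)

  qx <- qr(X)
  if (qx$rank < p) stopf("rank-deficient sliding design")
  coefs <- qr.coef(qx, Y)                       # p x n_win
  fitted <- X %*% coefs
  res <- Y - fitted
  df <- n - p
  sse <- colSums(res^2)
  s2 <- sse / df
  XtXinv_d <- diag(chol2inv(qr.R(qx)))
  tmat <- coefs / sqrt(outer(XtXinv_d, s2))
  pmat <- 2 * pt(-abs(tmat), df)
  # partial R2 per regressor: reduced multi-response fits
  pr2 <- matrix(NA_real_, p, n_win)
  if (partial) {
    for (j in seq(2, p)) {
      rres <- qr.resid(qr(X[, -j, drop = FALSE]), Y)
      sse_red <- colSums(rres^2)
      pr2[j, ] <- ifelse(sse_red > 0, (sse_red - sse) / sse_red, 0)
    }
  }
  rn <- colnames(X)
  sig <- logical(p); onset <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    r <- run_info(pmat[j, ] < alpha, min_run)
    sig[j] <- r$significant
    onset[j] <- if (r$significant) centers[r$onset] else NA_real_
  }
  structure(list(centers = centers,
                 coef = t(coefs), t = t(tmat), p = t(pmat),
                 partial_r2 = t(pr2),
                 regressors = rn, alpha = alpha, min_run = min_run,
                 significant = setNames(sig, rn),
                 run_onset = setNames(onset, rn)),
            class = "sliding_series")
}

# longest TRUE run and onset of the first run exceeding min_run
run_info <- function(flags, min_run) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths > min_run)
  list(significant = length(runs) > 0,
       onset = if (length(runs)) starts[runs[1]] else NA_integer_,
       max_run = if (any(r$values)) max(r$lengths[r$values]) else 0L)
}

#' @export
print.sliding_series <- function(x, ...) {
  cat(sprintf("Sliding regression: %d windows (%s to %s ms), %d regressors\n",
              length(x$centers), min(x$centers), max(x$centers),
              length(x$regressors) - 1))
  sig <- names(x$significant)[x$significant & names(x$significant) != "(Intercept)"]
  cat("  significant (run criterion):",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Calibrate the run-length criterion on trial-shuffled data
#'
#' Recomputes the sliding regression for every neuron after randomly
#' permuting trials (breaking the response-design pairing) and reports, per
#' shuffled neuron, the longest run of consecutive significant windows for
#' the regressor of interest. The empirical false-positive rate of the
#' "> min_run" criterion on this null should stay below 5\%.
#'
#' @param recording a \code{recording_set}.
#' @param design regressor data frame.
#' @param regressor regressor name to calibrate.
#' @param n_shuffles shuffles per neuron (1 gives one shuffled corpus pass).
#' @param alpha per-window threshold.
#' @param min_run candidate criterion.
#' @param seed integer seed.
#' @return List: \code{max_runs} (length neurons x n_shuffles),
#'   \code{fp_rate} for the criterion, and the smallest run threshold with
#'   a false-positive rate below 5\%.
#' @export
shuffle_run_calibration <- function(recording, design, regressor = NULL,
                                    n_shuffles = 1, alpha = 0.05,
                                    min_run = 9, seed = NULL) {
  stopifnot(inherits(recording, "recording_set"))
  n_nrn <- dim(recording$counts)[1]
  n_tr <- dim(recording$counts)[2]
  max_runs <- numeric(0)
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      for (i in seq_len(n_nrn)) {
        perm <- sample.int(n_tr)
        sl <- sliding_fit(recording$counts[i, perm, ], design,
                          recording$bins, recording$bin_ms,
                          alpha = alpha, min_run = min_run, partial = FALSE)
        js <- if (is.null(regressor)) setdiff(sl$regressors, "(Intercept)")
              else regressor
        mr <- max(vapply(js, function(j)
          run_info(sl$p[, match(j, sl$regressors)] < alpha, min_run)$max_run,
          numeric(1)))
        max_runs <- c(max_runs, mr)
      }
    }
  })
  fp <- mean(max_runs > min_run)
  thresholds <- sort(unique(max_runs))
  good <- thresholds[vapply(thresholds, function(th) mean(max_runs > th) < 0.05,
                            logical(1))]
  list(max_runs = max_runs, fp_rate = fp,
       calibrated_run = if (length(good)) min(good) else NA_integer_)
}

#' Value-to-choice transition verdict for one neuron
#'
#' A neuron shows a value-to-choice transition when its graded value signal
#' (run-length significant) begins before its binary view-choice signal,
#' with the choice run arising in or after the second-cue epoch. Onsets are
#' the first window of the qualifying run.
#'
#' @param series a \code{sliding_series} (from a design containing value and
#'   choice regressors).
#' @param value_regressor,choice_regressor regressor names.
#' @param cue2_window numeric window (ms) in which the choice run onset must
#'   fall.
#' @return List: \code{transition} (logical), \code{value_onset},
#'   \code{choice_onset}, \code{reason}.
#' @export
value_choice_transition <- function(series, value_regressor = "SecondValue",
                                    choice_regressor = "ViewChoice",
                                    cue2_window = c(1000, 2000)) {
  stopifnot(inherits(series, "sliding_series"))
  von <- series$run_onset[[value_regressor]]
  con <- series$run_onset[[choice_regressor]]
  if (is.na(von) && is.na(con))
    return(list(transition = FALSE, value_onset = NA, choice_onset = NA,
                reason = "neither signal significant"))
  if (is.na(von))
    return(list(transition = FALSE, value_onset = NA, choice_onset = con,
                reason = "no value signal"))
  if (is.na(con))
    return(list(transition = FALSE, value_onset = von, choice_onset = NA,
                reason = "no choice signal"))
  ok <- von < con && con >= cue2_window[1] && con <= cue2_window[2]
  list(transition = ok, value_onset = von, choice_onset = con,
       reason = if (ok) "value precedes choice" else "ordering not satisfied")
}
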