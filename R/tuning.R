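#' Tuning-reversal test across the neuron population
#'
#' Integral feedback predicts that a neuron's value tuning at the first cue
#' reverses sign later in the trial (delay / second cue): the memory
#' population feeds back inhibition proportional to the stored value. For
#' each neuron the first-cue and second-cue (or delay) value coefficients
#' are compared; a neuron is "consistent" when the signs flip. The
#' population-level test is a one-proportion z against 0.5 (normal
#' approximation, two-sided).
#'
#' @param coef_cue1,coef_late numeric vectors of per-neuron value
#'   coefficients (magnitude-only value component).
#' @return List of class \code{reversal_test}: \code{consistent} (logical
#'   per neuron), \code{k}, \code{n}, \code{z}, \code{p}.
#' @examples
#' # 48 of 60 consistent -> z = 4.65
#' r <- tuning_reversal_test(c(rep(1, 48), rep(1, 12)),
#'                           c(rep(-1, 48), rep(1, 12)))
#' round(r$z, 2)
#' @export
tuning_reversal_test <- function(coef_cue1, coef_late) {
  if (length(coef_cue1) != length(coef_late))
    stopf("coefficient vectors must have equal length")
  n <- length(coef_cue1)
  if (n == 0L) stopf("no neurons supplied")
  consistent <- coef_cue1 * coef_late < 0
  k <- sum(consistent)
  pz <- proportion_z(k, n, 0.5)
  structure(list(consistent = consistent, k = k, n = n,
                 z = pz$z, p = pz$p, phat = pz$phat),
            class = "reversal_test")
}

#' @export
print.reversal_test <- function(x, ...) {
  cat(sprintf("Tuning reversal: %d/%d consistent (%.1f%%), z = %.2f, p = %.2g\n",
              x$k, x$n, 100 * x$phat, x$z, x$p))
  invisible(x)
}

#' Across-neuron anti-correlation of value coefficients
#'
#' Correlates, across neurons, the first-option and second-option value
#' coefficients measured in the second-cue response (magnitude-only value
#' components, uncorrelated across options by design). Value-comparison
#' neurons respond to the second option's value relative to the first,
#' producing opposite-signed coefficient pairs and hence a negative
#' across-neuron correlation; shuffling object identity abolishes it.
#'
#' @param coef_first,coef_second per-neuron coefficient vectors.
#' @return List of class \code{value_anticorrelation}: \code{r}, \code{p}
#'   (two-sided), \code{n}.
#' @export
value_anticorrelation <- function(coef_first, coef_second) {
  if (length(coef_first) != length(coef_second))
    stopf("coefficient vectors must have equal length")
  n <- length(coef_first)
  if (n < 3L) stopf("need at least 3 neurons")
  ct <- cor.test(coef_first, coef_second, alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n),
            class = "value_anticorrelation")
}

#' @export
print.value_anticorrelation <- function(x, ...) {
  cat(sprintf("Value coefficient correlation: r = %.3f (n = %d), p = %.3g\n",
              x$r, x$n, x$p))
  invisible(x)
}

# Per-neuron magnitude-value coefficients at the two cues; returns a data
# frame used by the reversal and anti-correlation analyses.
value_coefficients <- function(recording, value_first, value_second) {
  ec <- recording$epoch_counts
  do.call(rbind, lapply(seq_len(dim(ec)[1]), function(i) {
    b1 <- coef(neuron_glm(data.frame(v = value_first), ec[i, , "cue1"]))[["v"]]
    f2a <- neuron_glm(data.frame(v = value_first), ec[i, , "cue2"])
    f2b <- neuron_glm(data.frame(v = value_second), ec[i, , "cue2"])
    data.frame(neuron = i, b_first_cue1 = b1,
               b_first_cue2 = coef(f2a)[["v"]],
               b_second_cue2 = coef(f2b)[["v"]])
  }))
}
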