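VALUE_CATEGORIES <- c("object_value_A", "object_value_B",
                      "view_value_positive", "view_value_negative",
                      "view_value_mixed", "unclassified")

#' Angle-based classification of a neuronal value response
#'
#' Regresses the first-cue response jointly on the two object values and
#' classifies the response by the polar angle of the two standardized
#' coefficients. The coefficient plane is divided into eight half-open 45
#' degree segments centered on 0, 45, ..., 315 degrees: segments pointing
#' toward 0/180 indicate coding of object-A value only, 90/270 object-B
#' value, and the diagonal segments indicate view-based value coding
#' (relationship to both values): 45 positive, 225 negative, and 135/315 a
#' mixed (opposite-sign) view-based pattern. Responses whose overall model
#' fit is not significant (F test, p >= gate) are unclassified. The
#' classification is axis-invariant: a common positive rescaling of both
#' coefficients leaves the angle unchanged. Exact boundary angles are
#' assigned to the counter-clockwise segment.
#'
#' @param cue_response numeric response vector (first-cue window).
#' @param valueA,valueB per-trial object values.
#' @param gate_p significance gate on the overall fit.
#' @return An object of class \code{value_cell_class}: \code{category},
#'   \code{angle} (degrees), standardized betas, and the gate p value.
#' @examples
#' v <- runif(200); w <- runif(200)
#' cl <- classify_value_neuron(5 + 3 * v + rnorm(200, 0, 0.5), v, w)
#' cl$category
#' @export
classify_value_neuron <- function(cue_response, valueA, valueB,
                                  gate_p = 0.05) {
  fit <- neuron_glm(data.frame(valueA = valueA, valueB = valueB),
                    cue_response)
  bA <- fit$coefficients["valueA", "std_beta"]
  bB <- fit$coefficients["valueB", "std_beta"]
  if (!is.finite(fit$f_p) || fit$f_p >= gate_p || (bA == 0 && bB == 0)) {
    return(structure(list(category = "unclassified", angle = NA_real_,
                          beta_A = bA, beta_B = bB, gate_p = fit$f_p,
                          fit = fit),
                     class = "value_cell_class"))
  }
  angle <- (atan2(bB, bA) * 180 / pi) %% 360
  category <- angle_category(angle)
  structure(list(category = category, angle = angle, beta_A = bA,
                 beta_B = bB, gate_p = fit$f_p, fit = fit),
            class = "value_cell_class")
}

# Segment lookup: half-open [center - 22.5, center + 22.5) so boundary
# angles fall in the counter-clockwise segment.
angle_category <- function(angle) {
  centers <- seq(0, 315, by = 45)
  labs <- c("object_value_A", "view_value_positive", "object_value_B",
            "view_value_mixed", "object_value_A", "view_value_negative",
            "object_value_B", "view_value_mixed")
  seg <- which(((angle - (centers - 22.5)) %% 360) < 45)[1]
  labs[seg]
}

#' @export
print.value_cell_class <- function(x, ...) {
  cat(sprintf("Value-cell class: %s (angle %.1f deg; betas %.2f / %.2f; gate p %.3g)\n",
              x$category, x$angle, x$beta_A, x$beta_B, x$gate_p))
  invisible(x)
}

#' Classify the functional type of a synthetic or recorded neuron
#'
#' Rule-based recovery of the functional cell types from fixed-window
#' statistics: value coding is assessed at the first cue with the
#' angle-based classifier; neurons not value-classified are tested in the
#' second-cue/delay window for the view-choice, viewing-order (sequence)
#' and conjunction (combination) contrasts, and at target onset for object
#' choice.
#'
#' @param recording a \code{recording_set}.
#' @param alpha significance threshold for the choice-family contrasts.
#' @return Character vector of inferred types (one per neuron), drawn from
#'   the same vocabulary as \code{\link{generate_population}}.
#' @export
classify_functional_type <- function(recording, alpha = 0.05) {
  stopifnot(inherits(recording, "recording_set"))
  beh <- recording$behavior
  tr <- beh$trials
  ec <- recording$epoch_counts
  has_targets <- "targets" %in% dimnames(ec)[[3]]
  d2 <- data.frame(
    ViewChoice = as.integer(tr$view_choice == "first"),
    ObjectView = as.integer(tr$obj_first == "A"),
    FirstValue = tr$value_first, SecondValue = tr$value_second)
  d2$Conjunction <- d2$ViewChoice * d2$ObjectView
  vapply(seq_len(dim(ec)[1]), function(i) {
    y1 <- ec[i, , "cue1"]
    vc <- tryCatch(classify_value_neuron(y1, tr$value.A, tr$value.B),
                   error = function(e) NULL)
    if (!is.null(vc) && vc$category != "unclassified") {
      return(switch(vc$category,
        object_value_A = "object_value_A", object_value_B = "object_value_B",
        view_value_positive = "view_value_pos",
        view_value_negative = "view_value_neg",
        view_value_mixed = "view_value_pos"))
    }
    y2 <- ec[i, , "cue2"] + ec[i, , "delay2"]
    fit <- tryCatch(neuron_glm(d2, y2), error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- fit$coefficients
      if (cf["Conjunction", "p"] < alpha / 5) return("combination")
      if (cf["ViewChoice", "p"] < alpha) {
        return(if (cf["ViewChoice", "estimate"] > 0) "view_choice_last"
               else "view_choice_current")
      }
      if (cf["ObjectView", "p"] < alpha) return("object_sequence")
    }
    if (has_targets) {
      yt <- ec[i, , "targets"]
      ft <- tryCatch(neuron_glm(
        data.frame(ObjectChoice = as.integer(tr$chosen_obj == "A")), yt),
        error = function(e) NULL)
      if (!is.null(ft) && ft$coefficients["ObjectChoice", "p"] < alpha)
        return("object_choice")
    }
    "untuned"
  }, character(1))
}

#' One-proportion z statistic
#'
#' Normal-approximation test of a proportion against a null value:
#' z = (phat - p0) / sqrt(p0 (1 - p0) / n), with a two-sided p value.
#'
#' @param k successes, @param n trials, @param p0 null proportion.
#' @return List with \code{z}, \code{p}, \code{phat}.
#' @examples
#' proportion_z(48, 60)$z   # 4.65
#' @export
proportion_z <- function(k, n, p0 = 0.5) {
  if (n <= 0) stopf("n must be positive")
  phat <- k / n
  z <- (phat - p0) / sqrt(p0 * (1 - p0) / n)
  list(z = z, p = 2 * pnorm(-abs(z)), phat = phat)
}
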