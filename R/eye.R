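#' Generate a synthetic eye-position trace for one trial
#'
#' Produces a uniformly sampled 2-D gaze trace: the animal fixates the
#' central spot through fixation and sequential cue viewing, then saccades
#' to the chosen target after target onset. Gaussian jitter models
#' fixational eye movements; saccades are brief high-velocity transitions.
#'
#' @param behavior a \code{session_behavior}.
#' @param trial trial index.
#' @param fs sampling rate (Hz).
#' @param jitter_sd fixational jitter (screen units); jitter below the
#'   tracker resolution is quantized away, as in real recordings.
#' @param resolution position quantization of the tracker (screen units).
#' @param rt saccade latency after target onset (ms).
#' @param seed integer seed.
#' @return An object of class \code{eye_trace}: \code{t} (ms, relative to
#'   first-cue onset, from -500 to 2500), \code{x}, \code{y}, and the
#'   stimulus onset times used for fixation exclusion.
#' @export
generate_eye_trace <- function(behavior, trial = 1L, fs = 250,
                               jitter_sd = 0.02, resolution = 0.1, rt = 250,
                               seed = NULL) {
  stopifnot(inherits(behavior, "session_behavior"))
  tr <- behavior$trials[trial, ]
  dt <- 1000 / fs
  t <- seq(-500, 2500, by = dt)
  target_x <- if (tr$chosen_side == "left") -5 else 5
  x <- ifelse(t < 2000 + rt, 0, target_x)
  y <- numeric(length(t))
  # 20-ms linear saccade ramp
  ramp <- t >= 2000 + rt & t < 2000 + rt + 20
  x[ramp] <- target_x * (t[ramp] - (2000 + rt)) / 20
  with_seed(seed, {
    x <- x + rnorm(length(t), 0, jitter_sd)
    y <- y + rnorm(length(t), 0, jitter_sd)
  })
  x <- round(x / resolution) * resolution
  y <- round(y / resolution) * resolution
  structure(list(t = t, x = x, y = y,
                 stim_onsets = c(cue1 = 0, cue2 = 1000, targets = 2000)),
            class = "eye_trace")
}

#' Detect fixations in an eye trace
#'
#' A fixation is a maximal run of samples whose eye speed stays below 25%
#' of the trace's speed standard deviation for more than 60 ms. Velocity is
#' estimated by central differences; the speed SD is estimated per trace.
#' Fixations beginning within 100 ms after a stimulus onset are flagged
#' \code{excluded} (anticipatory fixations).
#'
#' @param trace an \code{eye_trace} (uniformly sampled).
#' @param speed_frac threshold as a fraction of the speed SD.
#' @param min_ms minimum run duration (strictly greater than).
#' @param exclude_ms exclusion window after each stimulus onset.
#' @return Data frame of class \code{fixation_list}: \code{onset},
#'   \code{offset} (ms), \code{duration}, \code{x}, \code{y} (mean
#'   position), \code{excluded}. Traces shorter than \code{min_ms} give an
#'   empty list.
#' @examples
#' beh <- simulate_agent(generate_schedule("main", 5, seed = 1), seed = 2)
#' fx <- detect_fixations(generate_eye_trace(beh, 1, seed = 3))
#' nrow(fx)
#' @export
detect_fixations <- function(trace, speed_frac = 0.25, min_ms = 60,
                             exclude_ms = 100) {
  stopifnot(inherits(trace, "eye_trace"))
  n <- length(trace$t)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), x = numeric(0), y = numeric(0),
                      excluded = logical(0))
  class(empty) <- c("fixation_list", "data.frame")
  if (n < 3L || (trace$t[n] - trace$t[1]) < min_ms) return(empty)
  dt <- trace$t[2] - trace$t[1]
  vx <- c(NA, (trace$x[-(1:2)] - trace$x[1:(n - 2)]) / (2 * dt), NA)
  vy <- c(NA, (trace$y[-(1:2)] - trace$y[1:(n - 2)]) / (2 * dt), NA)
  speed <- sqrt(vx^2 + vy^2)
  sd_speed <- sd(speed, na.rm = TRUE)
  thr <- speed_frac * sd_speed
  # degenerate trace (no saccades, constant position): everything is slow
  slow <- if (sd_speed == 0) !is.na(speed) else !is.na(speed) & speed < thr
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths * dt > min_ms)
  if (!length(keep)) return(empty)
  out <- do.call(rbind, lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    data.frame(onset = trace$t[i0], offset = trace$t[i1],
               duration = trace$t[i1] - trace$t[i0],
               x = mean(trace$x[i0:i1]), y = mean(trace$y[i0:i1]))
  }))
  out$excluded <- vapply(out$onset, function(on)
    any(on >= trace$stim_onsets & on < trace$stim_onsets + exclude_ms),
    logical(1))
  class(out) <- c("fixation_list", "data.frame")
  out
}
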