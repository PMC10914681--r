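#' Optimality grid for the reversal-learning agent
#'
#' Simulates the reversal RL agent over a grid of learning rates and inverse
#' temperatures, replaying the block-wise reward probabilities of the given
#' schedules, and records the mean obtained reward volume (mL) per grid
#' cell. The default grid spans \eqn{\alpha \in [0,1]} in steps of 0.01 and
#' \eqn{\beta \in [0,5]} in steps of 0.05 (101 x 101 cells).
#'
#' All grid cells are advanced in lock-step through each session, so the
#' cost scales with trials, not with the grid size.
#'
#' @param schedules a \code{session_schedule} or list thereof (main task).
#' @param alpha_grid,beta_grid numeric grids.
#' @param n_reps simulation repetitions per schedule.
#' @param seed integer seed.
#' @param weighting \code{"equal"} combines the probability estimate with the
#'   cued magnitude (magnitude rescaled to [0, 1] by its largest level) with
#'   equal weight; \code{"probability_only"} ignores magnitudes when choosing.
#' @return An object of class \code{optimality_map}: list with
#'   \code{alpha_grid}, \code{beta_grid}, matrix \code{reward} (alpha x
#'   beta, mean obtained mL per trial) and \code{n_reps}.
#' @examples
#' sch <- generate_schedule("main", 100, seed = 1)
#' om <- optimality_grid(sch, alpha_grid = seq(0, 1, 0.1),
#'                       beta_grid = seq(0, 5, 0.5), n_reps = 2, seed = 1)
#' dim(om$reward)
#' @export
optimality_grid <- function(schedules,
                            alpha_grid = seq(0, 1, by = 0.01),
                            beta_grid = seq(0, 5, by = 0.05),
                            n_reps = 100, seed = NULL,
                            weighting = c("equal", "probability_only")) {
  weighting <- match.arg(weighting)
  if (inherits(schedules, "session_schedule")) schedules <- list(schedules)
  if (!length(schedules)) stopf("need at least one schedule")
  if (n_reps < 1) stopf("n_reps must be >= 1")

  cells <- expand.grid(alpha = alpha_grid, beta = beta_grid)
  ncell <- nrow(cells)
  alpha <- cells$alpha
  beta <- cells$beta
  w_mag <- if (weighting == "equal") 1 else 0
  total <- numeric(ncell)
  n_trials_total <- 0L

  with_seed(seed, {
    for (sch in schedules) {
      tr <- sch$trials
      n <- nrow(tr)
      if (n == 0L) next
      first_is_A <- tr$obj_first == "A"
      for (rep in seq_len(n_reps)) {
        vA <- numeric(ncell); vB <- numeric(ncell)
        for (i in seq_len(n)) {
          uA <- vA + w_mag * tr$mag.A[i] / max(MAG_SET)
          uB <- vB + w_mag * tr$mag.B[i] / max(MAG_SET)
          pA <- 1 / (1 + exp(-beta * (uA - uB)))
          chooseA <- runif(ncell) < pA
          p_rew <- ifelse(chooseA, tr$prob.A[i], tr$prob.B[i])
          rew <- runif(ncell) < p_rew
          mag_ch <- ifelse(chooseA, tr$mag.A[i], tr$mag.B[i])
          total <- total + ifelse(rew, mag_ch, SMALL_REWARD)
          r <- as.numeric(rew)
          # reversal update, vectorized over cells
          dA <- ifelse(chooseA, r - vA, -r - vA)
          dB <- ifelse(chooseA, -r - vB, r - vB)
          vA <- vA + alpha * dA
          vB <- vB + alpha * dB
        }
        n_trials_total <- n_trials_total + n
      }
    }
  })

  reward <- matrix(total / n_trials_total, nrow = length(alpha_grid),
                   ncol = length(beta_grid),
                   dimnames = list(alpha = alpha_grid, beta = beta_grid))
  structure(list(alpha_grid = alpha_grid, beta_grid = beta_grid,
                 reward = reward, n_reps = n_reps, weighting = weighting),
            class = "optimality_map")
}

#' @export
print.optimality_map <- function(x, ...) {
  cat(sprintf("Optimality map: %d x %d cells (%s weighting), %d reps\n",
              length(x$alpha_grid), length(x$beta_grid), x$weighting, x$n_reps))
  best <- arrayInd(which.max(x$reward), dim(x$reward))
  cat(sprintf("  best cell: alpha = %.2f, beta = %.2f (%.3f mL/trial)\n",
              x$alpha_grid[best[1]], x$beta_grid[best[2]], max(x$reward)))
  invisible(x)
}

#' Expected reward of a random chooser on a schedule
#'
#' Analytic baseline matching the \eqn{\beta = 0} row of the optimality
#' grid: each object is chosen with probability one half.
#' @param schedule a \code{session_schedule}.
#' @export
random_choice_baseline <- function(schedule) {
  tr <- schedule$trials
  ev <- function(p, m) p * m + (1 - p) * SMALL_REWARD
  mean(0.5 * ev(tr$prob.A, tr$mag.A) + 0.5 * ev(tr$prob.B, tr$mag.B))
}
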