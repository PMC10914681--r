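#' Reward probability and magnitude levels of the choice tasks
#'
#' The main task draws block-wise object-reward probabilities from an
#' 8-element set and trial-wise cued reward magnitudes from a 3-element set
#' (in mL). On non-rewarded trials a small consolation volume is delivered.
#'
#' @name task_levels
#' @keywords internal
NULL

PROB_SET <- c(0, 0.15, 0.35, 0.5, 0.65, 0.75, 0.85, 1.0)
MAG_SET <- c(0.25, 0.4, 0.65)
SMALL_REWARD <- 0.05

#' Generate a session schedule
#'
#' Builds the trial-by-trial task structure for one recording session:
#' block-wise reward probabilities, trial-wise cued reward magnitudes,
#' object viewing order and left/right target assignment.
#'
#' @param task_variant one of \code{"main"} (two objects, probability x
#'   magnitude), \code{"four_objects"} (two object pairs, probability only,
#'   0.85/0.15 reversing between objects) or \code{"two_juices"} (reward type
#'   x magnitude; the object-juice association switches twice per session).
#' @param n_trials number of trials (>= 0).
#' @param seed integer seed; schedules are bit-reproducible given
#'   \code{(task_variant, n_trials, seed)}.
#' @param block_range inclusive range of block lengths for the main task.
#'
#' @return An object of class \code{session_schedule}: a list with the
#'   variant, the object ids, and a per-trial data frame with columns
#'   \code{trial}, \code{block}, \code{obj_first}, \code{obj_second},
#'   \code{left_obj}, per-object reward probabilities \code{prob.<id>} and
#'   cued magnitudes \code{mag.<id>} (mL), and for the two-juices variant the
#'   per-object juice assignment \code{juice.<id>}.
#' @examples
#' sch <- generate_schedule("main", 150, seed = 1)
#' table(sch$trials$prob.A)
#' @export
generate_schedule <- function(task_variant = c("main", "four_objects", "two_juices"),
                              n_trials, seed = NULL,
                              block_range = c(15L, 40L)) {
  task_variant <- tryCatch(match.arg(task_variant),
                           error = function(e) stopf("unknown task variant"))
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 0)
    stopf("n_trials must be a single non-negative number")
  n_trials <- as.integer(n_trials)

  with_seed(seed, {
    trials <- switch(task_variant,
      main = schedule_main(n_trials, block_range),
      four_objects = schedule_four_objects(n_trials),
      two_juices = schedule_two_juices(n_trials))
  })

  objects <- switch(task_variant,
    main = c("A", "B"),
    four_objects = c("A", "B", "C", "D"),
    two_juices = c("A", "B"))

  structure(list(task_variant = task_variant, n_trials = n_trials,
                 objects = objects, prob_set = PROB_SET, mag_set = MAG_SET,
                 seed = seed, trials = trials),
            class = "session_schedule")
}

schedule_main <- function(n_trials, block_range) {
  if (n_trials == 0L) return(empty_trials(c("A", "B")))
  lens <- integer(0)
  while (sum(lens) < n_trials) {
    lens <- c(lens, sample(seq(block_range[1], block_range[2]), 1L))
  }
  block <- rep(seq_along(lens), lens)[seq_len(n_trials)]
  n_blocks <- max(block)
  pA <- sample(PROB_SET, n_blocks, replace = TRUE)
  pB <- sample(PROB_SET, n_blocks, replace = TRUE)
  first <- sample(c("A", "B"), n_trials, replace = TRUE)
  data.frame(
    trial = seq_len(n_trials),
    block = block,
    obj_first = first,
    obj_second = ifelse(first == "A", "B", "A"),
    left_obj = sample(c("A", "B"), n_trials, replace = TRUE),
    prob.A = pA[block],
    prob.B = pB[block],
    mag.A = sample(MAG_SET, n_trials, replace = TRUE),
    mag.B = sample(MAG_SET, n_trials, replace = TRUE),
    stringsAsFactors = FALSE)
}

schedule_four_objects <- function(n_trials) {
  if (n_trials == 0L) return(empty_trials(c("A", "B", "C", "D")))
  # Two object sets (A/B then C/D) switching half-way; within a set the
  # 0.85/0.15 probabilities reverse between objects across blocks of 25-35.
  lens <- integer(0)
  while (sum(lens) < n_trials) lens <- c(lens, sample(25:35, 1L))
  block <- rep(seq_along(lens), lens)[seq_len(n_trials)]
  half <- ceiling(n_trials / 2)
  set2 <- seq_len(n_trials) > half
  hi_first <- sample(c(TRUE, FALSE), max(block), replace = TRUE)
  hi_obj1 <- rep(NA, max(block))
  hi_obj1[1] <- hi_first[1]
  if (max(block) > 1) for (b in 2:max(block)) hi_obj1[b] <- !hi_obj1[b - 1]
  obj1 <- ifelse(set2, "C", "A")
  obj2 <- ifelse(set2, "D", "B")
  p1 <- ifelse(hi_obj1[block], 0.85, 0.15)
  p2 <- ifelse(hi_obj1[block], 0.15, 0.85)
  first_is_1 <- sample(c(TRUE, FALSE), n_trials, replace = TRUE)
  left_is_1 <- sample(c(TRUE, FALSE), n_trials, replace = TRUE)
  out <- data.frame(
    trial = seq_len(n_trials), block = block,
    obj_first = ifelse(first_is_1, obj1, obj2),
    obj_second = ifelse(first_is_1, obj2, obj1),
    left_obj = ifelse(left_is_1, obj1, obj2),
    prob.A = NA_real_, prob.B = NA_real_, prob.C = NA_real_, prob.D = NA_real_,
    mag.A = NA_real_, mag.B = NA_real_, mag.C = NA_real_, mag.D = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_len(n_trials)) {
    out[[paste0("prob.", obj1[i])]][i] <- p1[i]
    out[[paste0("prob.", obj2[i])]][i] <- p2[i]
    out[[paste0("mag.", obj1[i])]][i] <- 0.8
    out[[paste0("mag.", obj2[i])]][i] <- 0.8
  }
  out
}

schedule_two_juices <- function(n_trials) {
  if (n_trials == 0L) {
    out <- empty_trials(c("A", "B"))
    out$juice.A <- character(0); out$juice.B <- character(0)
    return(out)
  }
  # Object-juice association changes twice per session (thirds).
  first <- sample(c("A", "B"), n_trials, replace = TRUE)
  third <- pmin(((seq_len(n_trials) - 1) %/% ceiling(n_trials / 3)), 2)
  a_gets_j1 <- (third %% 2) == 0
  data.frame(
    trial = seq_len(n_trials), block = third + 1L,
    obj_first = first, obj_second = ifelse(first == "A", "B", "A"),
    left_obj = sample(c("A", "B"), n_trials, replace = TRUE),
    prob.A = 1, prob.B = 1,
    mag.A = sample(MAG_SET, n_trials, replace = TRUE),
    mag.B = sample(MAG_SET, n_trials, replace = TRUE),
    juice.A = ifelse(a_gets_j1, "J1", "J2"),
    juice.B = ifelse(a_gets_j1, "J2", "J1"),
    stringsAsFactors = FALSE)
}

empty_trials <- function(objects) {
  out <- data.frame(trial = integer(0), block = integer(0),
                    obj_first = character(0), obj_second = character(0),
                    left_obj = character(0), stringsAsFactors = FALSE)
  for (o in objects) out[[paste0("prob.", o)]] <- numeric(0)
  for (o in objects) out[[paste0("mag.", o)]] <- numeric(0)
  out
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("Session schedule (%s task): %d trials, %d block(s)\n",
              x$task_variant, x$n_trials,
              if (x$n_trials) max(x$trials$block) else 0L))
  invisible(x)
}
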