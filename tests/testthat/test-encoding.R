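# Minimal hand-built recording for deterministic constructions.
toy_recording <- function(counts, behavior, bin_ms = 20) {
  n_bins <- dim(counts)[3]
  starts <- seq(-500, by = bin_ms, length.out = n_bins)
  ep <- viewchoice:::epoch_windows(with_targets = max(starts) >= 2400)
  epoch_counts <- array(0L, c(dim(counts)[1], dim(counts)[2], nrow(ep)),
                        dimnames = list(NULL, NULL, ep$epoch))
  bins <- data.frame(start = starts, end = starts + bin_ms,
                     center = starts + bin_ms / 2)
  for (k in seq_len(nrow(ep))) {
    sel <- bins$start >= ep$start[k] & bins$end <= ep$end[k]
    epoch_counts[, , k] <- apply(counts[, , sel, drop = FALSE], c(1, 2), sum)
  }
  structure(list(counts = counts, bins = bins, epochs = ep,
                 epoch_counts = epoch_counts, behavior = behavior,
                 bin_ms = bin_ms, rate_source = "constructed",
                 n_clipped = 0L),
            class = "recording_set")
}

test_that("the regression matches the normal-equations closed form", {
  set.seed(51)
  X <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  y <- 1 + 2 * X$a - 0.5 * X$c + rnorm(60, 0, 0.3)
  fit <- neuron_glm(X, y)
  Xm <- cbind(1, as.matrix(X))
  beta <- solve(crossprod(Xm), crossprod(Xm, y))
  expect_equal(unname(fit$coefficients$estimate), unname(drop(beta)),
               tolerance = 1e-10)
  # noise-free planted coefficients recovered exactly
  y0 <- 3 - 1.5 * X$a + 0.25 * X$b
  fit0 <- neuron_glm(X, y0)
  expect_equal(fit0$coefficients[c("a", "b", "c"), "estimate"],
               c(-1.5, 0.25, 0), tolerance = 1e-10)
  # standardized coefficient of a response on itself is 1
  self <- neuron_glm(data.frame(y = y), y)
  expect_equal(self$coefficients["y", "std_beta"], 1, tolerance = 1e-12)
  expect_error(neuron_glm(data.frame(a = X$a, a2 = 2 * X$a), y), "a2")
})

test_that("partial R-squared matches its reduced-model definition and bounds", {
  set.seed(52)
  X <- data.frame(a = rnorm(80), b = rnorm(80))
  y <- 2 * X$a + rnorm(80)
  fit <- neuron_glm(X, y)
  sse_full <- sum((y - cbind(1, as.matrix(X)) %*%
                     fit$coefficients$estimate)^2)
  red <- lm(y ~ b, data = X)
  pr2_a <- (sum(red$residuals^2) - sse_full) / sum(red$residuals^2)
  expect_equal(fit$coefficients["a", "partial_r2"], pr2_a, tolerance = 1e-10)
  expect_true(all(fit$coefficients$partial_r2[-1] >= 0 &
                  fit$coefficients$partial_r2[-1] <= 1))
})

test_that("per-regressor type-I error is nominal on null responses", {
  set.seed(53)
  p <- replicate(400, {
    X <- data.frame(a = rnorm(30), b = rnorm(30))
    neuron_glm(X, rnorm(30))$coefficients["a", "p"]
  })
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("epoch z-scoring normalizes against the pre-fixation period", {
  rec <- parametric_recording()
  zs <- zscore_epochs(rec)
  for (i in seq_len(min(5, dim(zs$z)[1]))) {
    expect_equal(mean(zs$z[i, , "fixation"]), 0, tolerance = 1e-12)
    expect_equal(sd(zs$z[i, , "fixation"]), 1, tolerance = 1e-12)
  }
  # a silent neuron has zero baseline SD and is excluded
  beh <- main_behavior()
  pop <- generate_population(1, c(untuned = 1), seed = 54)
  silent <- generate_spike_counts(pop, beh, seed = 55)
  silent$counts[] <- 0L
  silent$epoch_counts[] <- 0L
  zs2 <- zscore_epochs(silent)
  expect_equal(zs2$excluded, 1L)
})

test_that("a planted two-SD response normalizes to two", {
  beh <- main_behavior()
  pop <- generate_population(1, c(untuned = 1), seed = 56,
                             baseline_meanlog = log(20), baseline_sdlog = 0)
  rec <- generate_spike_counts(pop, beh, seed = 57)
  base_rate <- rec$epoch_counts[1, , "fixation"] / 0.5
  bump <- 2 * sd(base_rate)
  rec$epoch_counts[1, , "cue1"] <-
    rec$epoch_counts[1, , "cue1"] + as.integer(round(bump * 0.5))
  zs <- zscore_epochs(rec)
  se <- 1 / sqrt(length(base_rate))   # SD ~1 after normalization
  expect_lt(abs(mean(zs$z[1, , "cue1"]) - 2), 4 * se + 0.15)
})

test_that("angle classification assigns the standard segments", {
  set.seed(58)
  vA <- runif(300); vB <- runif(300)
  clA <- classify_value_neuron(10 + 8 * vA + rnorm(300, 0, 0.5), vA, vB)
  expect_equal(clA$category, "object_value_A")
  expect_lt(abs(clA$angle %% 360), 22.5)
  clV <- classify_value_neuron(10 + 5 * vA + 5 * vB + rnorm(300, 0, 0.5),
                               vA, vB)
  expect_equal(clV$category, "view_value_positive")
  expect_lt(abs(clV$angle - 45), 22.5)
  clN <- classify_value_neuron(10 - 5 * vA - 5 * vB + rnorm(300, 0, 0.5),
                               vA, vB)
  expect_equal(clN$category, "view_value_negative")
  # noise gates to unclassified
  cl0 <- classify_value_neuron(rnorm(300), vA, vB, gate_p = 1e-6)
  expect_equal(cl0$category, "unclassified")
})

test_that("angle segments are half-open with counter-clockwise boundaries", {
  expect_equal(viewchoice:::angle_category(0), "object_value_A")
  expect_equal(viewchoice:::angle_category(22.4), "object_value_A")
  expect_equal(viewchoice:::angle_category(22.5), "view_value_positive")
  expect_equal(viewchoice:::angle_category(180), "object_value_A")
  expect_equal(viewchoice:::angle_category(90), "object_value_B")
  expect_equal(viewchoice:::angle_category(225), "view_value_negative")
  expect_equal(viewchoice:::angle_category(135), "view_value_mixed")
  expect_equal(viewchoice:::angle_category(337.5), "object_value_A")
})

test_that("classification is invariant to a common positive response rescaling", {
  set.seed(59)
  vA <- runif(250); vB <- runif(250)
  y <- 6 + 4 * vA + 4 * vB + rnorm(250, 0, 0.4)
  c1 <- classify_value_neuron(y, vA, vB)
  c2 <- classify_value_neuron(10 * y, vA, vB)
  expect_equal(c1$category, c2$category)
  expect_equal(c1$angle, c2$angle, tolerance = 1e-9)
})

test_that("planted object/view value populations are classified correctly", {
  set.seed(60)
  vA <- runif(300); vB <- runif(300)
  hits <- vapply(1:40, function(k) {
    if (k %% 2 == 0) {
      y <- 8 + 6 * vA + rnorm(300)
      classify_value_neuron(y, vA, vB)$category == "object_value_A"
    } else {
      y <- 8 + 4 * vA + 4 * vB + rnorm(300)
      classify_value_neuron(y, vA, vB)$category == "view_value_positive"
    }
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("sliding regression flags a planted signal where it lives", {
  beh <- main_behavior()
  n_tr <- nrow(beh$trials)
  vc <- as.integer(beh$trials$view_choice == "second")
  bins <- seq(-500, 2480, by = 20)
  set.seed(61)
  lam <- matrix(8 * 0.02, n_tr, length(bins))
  in_win <- bins >= 1000 & bins < 1500
  lam[, in_win] <- lam[, in_win] + outer(vc, rep(12 * 0.02, sum(in_win)))
  counts <- array(0L, c(1, n_tr, length(bins)))
  counts[1, , ] <- rpois(length(lam), lam)
  rec <- toy_recording(counts, beh)
  sl <- sliding_regression(rec, 1, build_design(beh, "glm2"))
  expect_true(sl$significant[["ViewChoice"]])
  on <- sl$run_onset[["ViewChoice"]]
  expect_gt(on, 700); expect_lt(on, 1300)
  # a constant-rate neuron has no significant run anywhere
  counts0 <- array(rpois(n_tr * length(bins), 8 * 0.02),
                   c(1, n_tr, length(bins)))
  sl0 <- sliding_regression(toy_recording(counts0, beh), 1,
                            build_design(beh, "glm2"))
  expect_false(any(sl0$significant[names(sl0$significant) != "(Intercept)"]))
})

test_that("the run criterion holds its false-positive rate on shuffled data", {
  rec <- parametric_recording()
  sub <- rec
  sub$counts <- rec$counts[1:30, , , drop = FALSE]
  cal <- shuffle_run_calibration(sub, build_design(main_behavior(), "glm2"),
                                 regressor = "ViewChoice", seed = 62)
  expect_lt(cal$fp_rate, 0.15)
})

test_that("transition verdicts follow the run ordering", {
  beh <- main_behavior()
  n_tr <- nrow(beh$trials)
  bins <- seq(-500, 2480, by = 20)
  set.seed(63)
  vc <- as.integer(beh$trials$view_choice == "second")
  v2 <- beh$trials$value_second
  # two-phase neuron: graded value at the second cue, then binary choice
  lam <- matrix(8 * 0.02, n_tr, length(bins))
  w_val <- bins >= 1000 & bins < 1400
  w_cho <- bins >= 1400 & bins < 2000
  lam[, w_val] <- lam[, w_val] + outer(25 * v2, rep(0.02, sum(w_val)))
  lam[, w_cho] <- lam[, w_cho] + outer(25 * vc, rep(0.02, sum(w_cho)))
  counts <- array(0L, c(1, n_tr, length(bins)))
  counts[1, , ] <- matrix(rpois(length(lam), lam), n_tr)
  rec <- toy_recording(counts, beh)
  sl <- sliding_regression(rec, 1, build_design(beh, "glm2"))
  tv <- value_choice_transition(sl)
  expect_true(tv$transition)
  expect_lt(tv$value_onset, tv$choice_onset)

  # pure choice neuron: no value run, verdict false
  lam2 <- matrix(8 * 0.02, n_tr, length(bins))
  lam2[, w_cho] <- lam2[, w_cho] + outer(25 * vc, rep(0.02, sum(w_cho)))
  cnt2 <- array(0L, c(1, n_tr, length(bins)))
  cnt2[1, , ] <- matrix(rpois(length(lam2), lam2), n_tr)
  rec2 <- toy_recording(cnt2, beh)
  tv2 <- value_choice_transition(sliding_regression(rec2, 1,
                                                    build_design(beh, "glm2")))
  expect_false(tv2$transition)

  # pure value neuron: no choice run, verdict false
  lam3 <- matrix(8 * 0.02, n_tr, length(bins))
  lam3[, w_val] <- lam3[, w_val] + outer(25 * v2, rep(0.02, sum(w_val)))
  cnt3 <- array(0L, c(1, n_tr, length(bins)))
  cnt3[1, , ] <- matrix(rpois(length(lam3), lam3), n_tr)
  rec3 <- toy_recording(cnt3, beh)
  tv3 <- value_choice_transition(sliding_regression(rec3, 1,
                                                    build_design(beh, "glm2")))
  expect_false(tv3$transition)
})

test_that("circuit corpora carry both value and choice signals", {
  cc <- circuit_corpus()
  des <- build_design(cc$behavior, "glm2")
  pop <- cc$population
  vv <- which(pop$type %in% c("view_value_pos", "view_value_neg"))
  vc <- which(pop$type %in% c("view_choice_current", "view_choice_last"))
  val_sig <- vapply(vv, function(i)
    sliding_regression(cc$recording, i, des)$significant[["SecondValue"]],
    logical(1))
  cho_sig <- vapply(vc, function(i)
    sliding_regression(cc$recording, i, des)$significant[["ViewChoice"]],
    logical(1))
  expect_gt(mean(val_sig), 0.5)
  expect_gt(mean(cho_sig), 0.5)
})

test_that("the worked-example proportion statistics are exact", {
  expect_equal(round(proportion_z(48, 60)$z, 2), 4.65)
  expect_equal(proportion_z(30, 60)$z, 0)
  expect_error(proportion_z(1, 0), "positive")
})

test_that("tuning reversal and value anti-correlation behave on the circuit corpus", {
  cc <- circuit_corpus()
  pop <- cc$population
  beh <- cc$behavior
  vv <- which(pop$type %in% c("view_value_pos", "view_value_neg"))
  vcf <- viewchoice:::value_coefficients(cc$recording,
                                         beh$trials$magval_first,
                                         beh$trials$magval_second)
  rv <- tuning_reversal_test(vcf$b_first_cue1[vv], vcf$b_first_cue2[vv])
  expect_gt(rv$phat, 0.5)
  ac <- value_anticorrelation(vcf$b_first_cue2[vv], vcf$b_second_cue2[vv])
  expect_lt(ac$r, 0)
  expect_lt(ac$p, 0.05)
  # shuffling the pairing abolishes the anti-correlation
  set.seed(64)
  worse <- replicate(20, {
    value_anticorrelation(vcf$b_first_cue2[vv],
                          sample(vcf$b_second_cue2[vv]))$r
  })
  expect_gt(mean(worse), ac$r)
})

test_that("independent coefficient pairs test at the nominal rate", {
  set.seed(65)
  p <- replicate(200, value_anticorrelation(rnorm(30), rnorm(30))$p)
  expect_lt(mean(p < 0.05), 0.12)
  expect_error(value_anticorrelation(1:2, 1:2), "3 neurons")
})

test_that("design matrices use the standard codings", {
  beh <- main_behavior()
  d <- build_design(beh, "glm2")
  tr <- beh$trials
  expect_setequal(unique(d$ViewChoice), c(0L, 1L))
  expect_equal(d$ViewChoice, as.integer(tr$view_choice == "first"))
  expect_equal(d$ObjectChoice, as.integer(tr$chosen_obj == "A"))
  expect_equal(d$ObjectView, as.integer(tr$obj_first == "A"))
  expect_equal(d$ChosenValue,
               ifelse(tr$chosen_obj == "A", tr$value.A, tr$value.B))
  d3 <- build_design(beh, "glm3")
  expect_true(all(c("FirstProb", "SecondProb", "FirstMag", "SecondMag",
                    "ChosenProb", "ChosenMag") %in% names(d3)))
  expect_true(all(d3$FirstMag %in% c(0.25, 0.4, 0.65)))

  b4 <- simulate_agent(generate_schedule("four_objects", 120, seed = 66),
                       seed = 67)
  d5 <- build_design(b4, "glm5")
  expect_setequal(unique(d5$AminusB_choice), c(-1L, 0L, 1L))
  expect_true(all(d5$AminusB_choice[d5$CminusD_choice != 0] == 0))

  b2 <- simulate_agent(generate_schedule("two_juices", 120, seed = 68),
                       seed = 69)
  d6 <- build_design(b2, "glm6")
  expect_setequal(unique(d6$JuiceAChoice), c(0L, 1L))
  expect_setequal(unique(d6$JuiceAFirst), c(0L, 1L))
})
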