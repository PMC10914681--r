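test_that("the trial filter excludes under-sampled neurons and matches group sizes", {
  responses <- list(rnorm(20), rnorm(14))
  groups <- list(rep(c("a", "b"), c(10, 10)), rep(c("a", "b"), c(4, 10)))
  ps <- build_pseudopopulation(responses, groups, min_trials = 5)
  expect_equal(ps$excluded, 2L)
  expect_equal(ps$kept, 1L)
  # group sizes equal the per-group minimum across included neurons
  ps2 <- build_pseudopopulation(list(rnorm(20), rnorm(17)),
                                list(rep(c("a", "b"), c(10, 10)),
                                     rep(c("a", "b"), c(7, 10))),
                                min_trials = 5)
  expect_equal(unname(ps2$n_per_group), c(7L, 10L))
  m <- viewchoice:::draw_matching(ps2)
  expect_equal(as.vector(table(m$y)), c(7L, 10L))
  expect_error(build_pseudopopulation(responses, groups, min_trials = 50),
               "filter")
})

test_that("decoding is deterministic under a fixed seed", {
  set.seed(71)
  X <- rbind(matrix(rnorm(200, 1), 20), matrix(rnorm(200, -1), 20))
  ps <- build_pseudopopulation(X, rep(c("a", "b"), each = 20))
  d1 <- decode_population(ps, "nn", n_matchings = 5, n_shuffles = 10, seed = 3)
  d2 <- decode_population(ps, "nn", n_matchings = 5, n_shuffles = 10, seed = 3)
  expect_identical(d1$accuracy, d2$accuracy)
})

test_that("separable groups decode perfectly; identical ones at chance", {
  set.seed(72)
  X <- rbind(matrix(rnorm(300, 5), 15), matrix(rnorm(300, -5), 15))
  ps <- build_pseudopopulation(X, rep(c("a", "b"), each = 15))
  for (m in c("svm", "nn")) {
    d <- decode_population(ps, m, n_matchings = 3, n_shuffles = 30, seed = 4)
    expect_equal(d$mean_accuracy, 100)
    expect_lt(d$p, 0.01)
  }
  # identical distributions: near chance and usually not significant
  ns <- vapply(1:8, function(s) {
    Xn <- matrix(rnorm(30 * 10), 30)
    psn <- build_pseudopopulation(Xn, rep(c("a", "b"), each = 15))
    d <- decode_population(psn, "nn", n_matchings = 10, n_shuffles = 50,
                           seed = s)
    c(d$mean_accuracy, d$p)
  }, numeric(2))
  expect_lt(abs(mean(ns[1, ]) - 50), 12)
  expect_gte(mean(ns[2, ] > 0.05), 0.7)
})

test_that("accuracy grows with the planted effect size", {
  set.seed(73)
  accs <- vapply(c(0.5, 1, 2), function(d) {
    X <- rbind(matrix(rnorm(200, d / 2), 20), matrix(rnorm(200, -d / 2), 20))
    ps <- build_pseudopopulation(X, rep(c("a", "b"), each = 20))
    decode_population(ps, "nn", n_matchings = 10, n_shuffles = 5,
                      seed = 5)$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
})

test_that("leave-one-out holds out the test trial", {
  # the trial index is uninformative out-of-sample: accuracy stays at chance
  set.seed(74)
  n <- 40
  X <- cbind(seq_len(n), seq_len(n))   # planted trial-index feature
  y <- sample(rep(c("a", "b"), each = n / 2))
  ps <- build_pseudopopulation(X, y, min_trials = 5)
  accs <- replicate(20, 100 * viewchoice:::loo_nn(
    viewchoice:::draw_matching(ps)$X, viewchoice:::draw_matching(ps)$y))
  expect_lt(mean(accs), 65)
  # leave-one-out covers each trial exactly once
  m <- viewchoice:::draw_matching(ps)
  D <- as.matrix(dist(m$X)); diag(D) <- Inf
  expect_equal(length(apply(D, 1, which.min)), nrow(m$X))
})

test_that("the nearest-neighbor decoder agrees with a brute-force scan", {
  set.seed(75)
  X <- matrix(rnorm(15 * 4), 15)
  y <- factor(rep(c("a", "b", "a"), c(5, 5, 5)))
  pred <- vapply(seq_len(nrow(X)), function(i) {
    d <- apply(X, 1, function(r) sqrt(sum((r - X[i, ])^2)))
    d[i] <- Inf
    as.character(y[which.min(d)])
  }, character(1))
  expect_equal(viewchoice:::loo_nn(X, y), mean(pred == y))
})

test_that("view-choice decoding generalizes across viewing sequences", {
  cc <- circuit_corpus()
  rec <- cc$recording
  tr <- cc$behavior$trials
  seqAB <- tr$obj_first == "A"
  mkps <- function(groups, sel)
    pseudo_from_recording(rec, ifelse(sel, groups, NA), epoch = "cue2",
                          min_trials = 5)
  ps_ab <- mkps(tr$view_choice, seqAB)
  ps_ba <- mkps(tr$view_choice, !seqAB)
  within <- decode_population(ps_ab, "svm", n_matchings = 4, n_shuffles = 10,
                              seed = 6)
  cross <- cross_condition_decode(ps_ab, ps_ba, "svm", "none",
                                  n_matchings = 8, n_shuffles = 10, seed = 7)
  expect_gt(cross$mean_accuracy, 60)
  expect_lt(abs(cross$mean_accuracy - within$mean_accuracy), 15)
})

test_that("object choice needs sequence recoding to cross viewing sequences", {
  cc <- circuit_corpus()
  rec <- cc$recording
  tr <- cc$behavior$trials
  seqAB <- tr$obj_first == "A"
  mkps <- function(sel)
    pseudo_from_recording(rec, ifelse(sel, tr$chosen_obj, NA), epoch = "cue2",
                          min_trials = 5)
  ps_ab <- mkps(seqAB); ps_ba <- mkps(!seqAB)
  plain <- cross_condition_decode(ps_ab, ps_ba, "svm", "none",
                                  n_matchings = 8, n_shuffles = 10, seed = 8)
  recoded <- cross_condition_decode(ps_ab, ps_ba, "svm", "invert_by_sequence",
                                    n_matchings = 8, n_shuffles = 10, seed = 9)
  expect_lt(plain$mean_accuracy, 40)      # systematically misclassified
  expect_gt(recoded$mean_accuracy, 60)    # recovered by label inversion
})

test_that("conjunction decoding separates all four sequence-choice classes", {
  cc <- circuit_corpus()
  tr <- cc$behavior$trials
  groups <- paste0(ifelse(tr$obj_first == "A", "AB", "BA"), "_",
                   tr$view_choice)
  # cap trials per class to keep leave-one-out light
  keep <- unlist(lapply(split(seq_along(groups), groups), head, 12))
  g <- rep(NA_character_, length(groups)); g[keep] <- groups[keep]
  ps <- pseudo_from_recording(cc$recording, g, epoch = "cue2", min_trials = 5)
  cj <- conjunction_decode(ps, n_matchings = 2, n_shuffles = 8, seed = 10)
  expect_true(all(cj$per_class > 25))
  expect_gt(cj$mean_accuracy, 40)
})

test_that("pure view-choice populations confuse sequence within a view choice", {
  cc <- circuit_corpus()
  tr <- cc$behavior$trials
  idx <- which(cc$population$type %in% c("view_choice_current",
                                         "view_choice_last"))
  groups <- paste0(ifelse(tr$obj_first == "A", "AB", "BA"), "_",
                   tr$view_choice)
  keep <- unlist(lapply(split(seq_along(groups), groups), head, 10))
  g <- rep(NA_character_, length(groups)); g[keep] <- groups[keep]
  ps <- pseudo_from_recording(cc$recording, g, epoch = "cue2",
                              min_trials = 5, neurons = idx)
  cj <- conjunction_decode(ps, n_matchings = 2, n_shuffles = 5, seed = 11)
  conf <- cj$confusion / rowSums(cj$confusion)
  # off-diagonal confusion concentrates on the sequence-differing,
  # view-matching class
  same_view_conf <- mean(c(conf["AB_first", "BA_first"],
                           conf["BA_first", "AB_first"],
                           conf["AB_second", "BA_second"],
                           conf["BA_second", "AB_second"]))
  diff_view_conf <- mean(c(conf["AB_first", "BA_second"],
                           conf["BA_second", "AB_first"],
                           conf["AB_second", "BA_first"],
                           conf["BA_first", "AB_second"]))
  expect_gt(same_view_conf, diff_view_conf)
})

test_that("decoding accuracy is ordered by decision difficulty on circuit data", {
  cc <- circuit_corpus()
  dd <- decode_by_difficulty(cc$recording, method = "svm", n_matchings = 4,
                             n_shuffles = 10, seed = 12)
  expect_gt(dd$easy$mean_accuracy, dd$hard$mean_accuracy)
  # tercile split is near-balanced (exact thirds are limited by the
  # discrete value levels, which tie at the quantile boundaries)
  tr <- cc$behavior$trials
  dv <- abs(tr$value_first - tr$value_second)
  qs <- quantile(dv, c(1 / 3, 2 / 3), type = 1)
  terc <- table(cut(dv, c(-Inf, qs, Inf)))
  expect_gte(min(terc), nrow(tr) / 6)
})

test_that("sample-size curves rise with a planted signal and stay flat without", {
  set.seed(76)
  Xs <- rbind(matrix(rnorm(50 * 30, 0.5), 25), matrix(rnorm(50 * 30, -0.5), 25))
  ps <- build_pseudopopulation(Xs, rep(c("a", "b"), each = 25))
  cv <- accuracy_vs_samplesize(ps, sizes = c(2, 30), reps = 20, seed = 13)
  expect_gt(cv$mean_accuracy[2], cv$mean_accuracy[1])
  Xn <- matrix(rnorm(50 * 30), 50)
  psn <- build_pseudopopulation(Xn, rep(c("a", "b"), each = 25))
  cvn <- accuracy_vs_samplesize(psn, sizes = c(2, 30), reps = 20, seed = 14)
  expect_true(all(abs(cvn$mean_accuracy - 50) < 12))
  expect_error(accuracy_vs_samplesize(ps, sizes = 0), "positive")
  expect_error(accuracy_vs_samplesize(ps, sizes = 100), "exceeds")
})

test_that("the nucleus-level readout finds the strongest value-coding nucleus", {
  beh <- main_behavior()
  # plant value coding exclusively in dLA
  pop <- generate_population(60, c(view_value_pos = 0.5, untuned = 0.5),
                             seed = 77, gain_mean = 15, gain_sd = 1)
  pop$nucleus <- rep(c("dLA", "BL"), 30)
  pop$nucleus[pop$type == "view_value_pos"] <- "dLA"
  pop$nucleus[pop$type == "untuned"] <- "BL"
  rec <- generate_spike_counts(pop, beh, seed = 78)
  nd <- nucleus_value_decode(rec, n_top = 15, n_matchings = 5, seed = 79)
  expect_gt(nd$accuracy[nd$nucleus == "dLA"],
            nd$accuracy[nd$nucleus == "BL"])
})
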