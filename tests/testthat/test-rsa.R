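test_that("RSA matrices are symmetric correlation matrices in condition order", {
  cc <- circuit_corpus()
  spec <- value_conditions()
  cm <- condition_rsa(cc$recording, spec, assign_value_conditions(cc$behavior),
                      epoch = "cue1")
  expect_equal(cm$R, t(cm$R))
  expect_equal(unname(diag(cm$R)), rep(1, nrow(spec)))
  expect_true(all(cm$R >= -1 - 1e-12 & cm$R <= 1 + 1e-12))
  expect_identical(rownames(cm$R), spec$condition)
  expect_error(condition_rsa(cc$recording, spec,
                             rep("A_q1", nrow(cc$behavior$trials))),
               "unrealized")
})

test_that("conditions with identical condition means correlate at exactly one", {
  beh <- main_behavior()
  n_tr <- nrow(beh$trials)
  counts <- array(0L, c(4, n_tr, 125))
  # deterministic pattern: parity preference alternates across neurons so
  # condition-mean vectors vary across neurons
  for (i in 1:4) {
    pref <- if (i %% 2 == 0) seq_len(n_tr) %% 2 else 1 - seq_len(n_tr) %% 2
    counts[i, , ] <- pref * 3 + 2
  }
  rec <- structure(list(counts = counts,
                        bins = data.frame(start = seq(-500, by = 20,
                                                      length.out = 125),
                                          end = seq(-480, by = 20,
                                                    length.out = 125)),
                        epochs = viewchoice:::epoch_windows(FALSE),
                        epoch_counts = array(counts[, , 1:5] + 1L,
                                             c(4, n_tr, 5),
                                             dimnames = list(NULL, NULL,
                                               viewchoice:::epoch_windows(FALSE)$epoch)),
                        behavior = beh, bin_ms = 20),
                   class = "recording_set")
  spec <- data.frame(condition = c("odd", "even", "odd2"))
  cond <- ifelse(seq_len(n_tr) %% 2 == 1,
                 ifelse(seq_len(n_tr) %% 4 == 1, "odd", "odd2"), "even")
  cm <- condition_rsa(rec, spec, cond, epoch = "cue1")
  # the two odd-trial conditions have identical means for every neuron
  expect_equal(cm$R["odd", "odd2"], 1, tolerance = 1e-10)
})

test_that("templates carry the standard level codes and products", {
  spec <- value_conditions()
  ts <- build_templates(spec, c("identity", "object", "view_value",
                                "object_value", "view_value_ordinal"))
  expect_equal(unname(diag(ts$identity)), rep(1, 8))
  expect_true(all(ts$identity[upper.tri(ts$identity)] == 0))
  # pairwise product of the extreme mean-centered levels
  i <- which(spec$value_level == -2.25 & spec$object == "A")
  j <- which(spec$value_level == 2.25 & spec$object == "A")
  expect_equal(ts$view_value[i, j], -5.0625)
  # object-value template vanishes across objects
  expect_true(all(ts$object_value[ts$object == 0] == 0))
  # ordinal variant: equal levels maximally similar, adjacency uniform
  lv <- match(spec$value_level, sort(unique(spec$value_level)))
  adj <- abs(outer(lv, lv, `-`)) == 1
  expect_equal(length(unique(ts$view_value_ordinal[adj])), 1L)
  expect_error(build_templates(data.frame(condition = "x"), "view_value"),
               "value_level")
})

test_that("template regression recovers planted population structure", {
  beh <- main_behavior()
  spec <- value_conditions()
  tpl <- build_templates(spec, c("identity", "object", "view_value",
                                 "object_value"))
  # mixed-sign view-value population: value similarity across objects
  popV <- generate_population(60, c(view_value_pos = 0.5, view_value_neg = 0.5),
                              seed = 80, gain_mean = 0, gain_sd = 15)
  recV <- generate_spike_counts(popV, beh, seed = 81)
  cmV <- condition_rsa(recV, spec,
                       assign_value_conditions(beh, both_periods = TRUE))
  rr <- rsa_regression(cmV, tpl, n_perm = 500, p_crit = 0.05, seed = 82)
  co <- rr$coefficients
  expect_true(co$significant[co$template == "view_value"])
  expect_false(co$significant[co$template == "object_value"])
  expect_gt(co$partial_r2[co$template == "view_value"],
            co$partial_r2[co$template == "object_value"])

  # mixed-sign object-value population: value structure within object only
  popO <- generate_population(60, c(object_value_A = 0.5, object_value_B = 0.5),
                              seed = 83, gain_mean = 0, gain_sd = 15)
  recO <- generate_spike_counts(popO, beh, seed = 84)
  cmO <- condition_rsa(recO, spec,
                       assign_value_conditions(beh, both_periods = TRUE))
  rrO <- rsa_regression(cmO, tpl, n_perm = 500, p_crit = 0.05, seed = 85)
  coO <- rrO$coefficients
  expect_true(coO$significant[coO$template == "object_value"])
  expect_gt(coO$estimate[coO$template == "object_value"], 0)
  expect_gt(coO$partial_r2[coO$template == "object_value"],
            coO$partial_r2[coO$template == "view_value"])
  expect_true(all(co$partial_r2 >= 0 & co$partial_r2 <= 1))
})

test_that("full-matrix and unique-cells regressions agree on planted structure", {
  beh <- main_behavior()
  popV <- generate_population(60, c(view_value_pos = 0.5, view_value_neg = 0.5),
                              seed = 80, gain_mean = 0, gain_sd = 15)
  recV <- generate_spike_counts(popV, beh, seed = 81)
  spec <- value_conditions()
  tpl <- build_templates(spec, c("object", "view_value", "object_value"))
  cm <- condition_rsa(recV, spec,
                      assign_value_conditions(beh, both_periods = TRUE))
  r_full <- rsa_regression(cm, tpl, n_perm = 300, p_crit = 0.05, seed = 85)
  r_uniq <- rsa_regression(cm, tpl, n_perm = 300, p_crit = 0.05,
                           unique_cells = TRUE, seed = 86)
  v <- function(r) r$coefficients[r$coefficients$template == "view_value", ]
  expect_equal(sign(v(r_full)$estimate), sign(v(r_uniq)$estimate))
  expect_equal(v(r_full)$significant, v(r_uniq)$significant)
})

test_that("permutation significance is near the nominal rate on null corpora", {
  set.seed(87)
  spec <- value_conditions()
  tpl <- build_templates(spec, c("object", "view_value"))
  hits <- replicate(40, {
    Mn <- matrix(rnorm(8 * 30), 8)
    R <- cor(t(Mn))
    rsa <- structure(list(conditions = spec, condition_means = Mn, R = R,
                          epoch = "null"), class = "rsa_matrix")
    rr <- rsa_regression(rsa, tpl, n_perm = 200, p_crit = 0.05)
    rr$coefficients$significant[rr$coefficients$template == "view_value"]
  })
  expect_lt(mean(hits), 0.2)
})

test_that("sliding RSA orders object, view-choice, then object-choice structure", {
  cc <- circuit_corpus()
  spec <- choice_conditions(with_side = TRUE)
  spec$first_obj <- ifelse(spec$sequence == "AB", "A", "B")
  cond <- assign_choice_conditions(cc$behavior, with_side = TRUE)
  tpl <- build_templates(spec, c("view_choice", "object_choice",
                                 "left_choice"))
  # sequence template: conditions sharing the first-viewed object
  seq_tpl <- outer(spec$first_obj, spec$first_obj, `==`) * 1
  dimnames(seq_tpl) <- list(spec$condition, spec$condition)
  tpl$sequence <- seq_tpl
  class(tpl) <- "template_set"
  sr <- sliding_rsa(cc$recording, spec, cond, tpl, span = c(-200, 2400))
  peak <- function(nm) sr$center[which.max(sr[[nm]])]
  # first-object structure during the first cue, view-based choice
  # structure around the decision, object-choice structure last
  expect_lt(peak("sequence"), 1000)
  expect_gt(peak("view_choice"), 1000)
  expect_lt(peak("sequence"), peak("view_choice"))
  expect_lte(peak("view_choice"), peak("object_choice"))
})
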