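test_that("parameter validation rejects unstable or unknown settings", {
  expect_error(circuit_params(dt = 2), "dt")
  expect_error(circuit_params(nonsense = 1), "unknown")
  expect_error(simulate_circuit_trial(circuit_params(),
                                      stimulus_protocol(c(A = 0.5, B = 0.5)),
                                      variant = "bogus"), "variant")
  expect_error(stimulus_protocol(c(A = 1.4, B = 0.5)), "\\[0, 1\\]")
})

test_that("the noise-free circuit chooses the higher-value option in both orders", {
  p0 <- circuit_params(eta = 0)
  vals <- c(0.15, 0.45, 0.85)
  grid <- expand.grid(v1 = vals, v2 = vals)
  grid <- grid[abs(grid$v1 - grid$v2) >= 0.1, ]
  for (ord in 1:2) {
    s1 <- if (ord == 1) "A" else "B"; s2 <- if (ord == 1) "B" else "A"
    vv <- cbind(A = if (ord == 1) grid$v1 else grid$v2,
                B = if (ord == 1) grid$v2 else grid$v1)
    ro <- viewchoice:::circuit_run(p0, vv, rep(s1, nrow(vv)),
                                   rep(s2, nrow(vv)))$readout
    corr_view <- ifelse(ro$v_second > ro$v_first, "second", "first")
    corr_obj <- ifelse(ro$v_second > ro$v_first, ro$seq2, ro$seq1)
    expect_true(all(ro$view_choice == corr_view))
    expect_true(all(ro$object_choice == corr_obj))
  }
})

test_that("equal values produce symmetric trajectories and no winner without noise", {
  tr <- simulate_circuit_trial(circuit_params(eta = 0),
                               stimulus_protocol(c(A = 0.5, B = 0.5)))
  expect_true(is.na(tr$view_choice))
  expect_false(tr$decided)
  expect_equal(max(abs(tr$states[, "C1"] - tr$states[, "C2"])), 0)
})

test_that("V2 shows value tuning at the first cue that reverses in the delay", {
  p0 <- circuit_params(eta = 0)
  vals <- c(0.2, 0.5, 0.8)
  cue1 <- delay1 <- numeric(length(vals))
  for (i in seq_along(vals)) {
    tr <- simulate_circuit_trial(p0, stimulus_protocol(c(A = vals[i], B = 0.5)))
    cue1[i] <- viewchoice:::trace_window_mean(tr, "V2", 500, 1000)
    delay1[i] <- viewchoice:::trace_window_mean(tr, "V2", 1000, 1500)
  }
  expect_true(all(diff(cue1) > 0))     # positive tuning at cue1
  expect_true(all(diff(delay1) < 0))   # reversed (negative) tuning in the delay
  expect_true(all(delay1 < 0))
})

test_that("the choice margin grows with the value difference at eta = 0", {
  p0 <- circuit_params(eta = 0)
  margins <- vapply(c(0.1, 0.3, 0.5, 0.7), function(dv) {
    viewchoice:::circuit_run(p0, cbind(A = 0.5 - dv / 2, B = 0.5 + dv / 2),
                             "A", "B")$readout$margin_view
  }, numeric(1))
  expect_true(all(diff(margins) > 0))
})

test_that("noisy decision accuracy increases with the value difference", {
  set.seed(31)
  acc <- vapply(c(0.1, 0.7), function(dv) {
    n <- 50
    v1 <- runif(n, 0, 1 - dv); v2 <- v1 + dv
    flip <- runif(n) < 0.5
    ro <- viewchoice:::circuit_run(
      circuit_params(), cbind(A = ifelse(flip, v2, v1),
                              B = ifelse(flip, v1, v2)),
      rep("A", n), rep("B", n))$readout
    corr <- ifelse(ro$v_second > ro$v_first, "second", "first")
    mean(ro$view_choice == corr, na.rm = TRUE)
  }, numeric(1))
  expect_gt(acc[2], acc[1])
  expect_gt(acc[2], 0.85)
})

test_that("decided noisy trials separate fully and synapses stay in range", {
  set.seed(32)
  n <- 40
  ro_run <- viewchoice:::circuit_run(circuit_params(),
                                     cbind(A = rep(0.2, n), B = rep(0.8, n)),
                                     rep("A", n), rep("B", n))
  ro <- ro_run$readout
  expect_gt(mean(ro$decided), 0.6)
  expect_true(all(ro$margin_view[ro$decided] > 0.2))
  # depression variables within (0, 1]; facilitation positive, bounded,
  # and at 1 before any stimulus
  tr1 <- simulate_circuit_trial(circuit_params(eta = 0),
                                stimulus_protocol(c(A = 0.3, B = 0.7)))
  for (w in c("wA1", "wB1", "wA2", "wB2")) {
    expect_true(all(tr1$states[, w] > 0 & tr1$states[, w] <= 1))
  }
  wf <- tr1$states[, "wF"]
  expect_true(all(wf > 0 & wf < 12))
  expect_equal(wf[tr1$time <= 500][1], 1, tolerance = 1e-3)
})

test_that("object-sequence units are pairwise symmetric at eta = 0", {
  tr <- simulate_circuit_trial(circuit_params(eta = 0),
                               stimulus_protocol(c(A = 0.3, B = 0.7)))
  # "A second" responds like "B first" and vice versa
  expect_equal(tr$states[, "A2"], tr$states[, "B1"], tolerance = 1e-10)
  expect_equal(tr$states[, "B2"], tr$states[, "A1"], tolerance = 1e-10)
})

test_that("the integrator tracks a 10x finer-step oracle", {
  pr <- stimulus_protocol(c(A = 0.3, B = 0.7))
  tr1 <- simulate_circuit_trial(circuit_params(eta = 0), pr,
                                record_every = 40L)
  tr2 <- simulate_circuit_trial(circuit_params(eta = 0, dt = 0.05), pr,
                                record_every = 400L)
  expect_identical(tr1$view_choice, tr2$view_choice)
  expect_identical(tr1$object_choice, tr2$object_choice)
  expect_lt(abs(tr1$margin_view - tr2$margin_view), 0.02)
  err <- abs(tr1$states - tr2$states)
  expect_lt(max(err[, c("V1", "V2", "M1", "M2", "C1", "C2")]), 0.05)
  expect_lt(max(err), 0.12)
})

test_that("the switch subsystem has the saddle-node bifurcation structure", {
  bd <- switch_bifurcation(circuit_params(), c(-5, 1, 3))
  low <- bd[bd$b == -5, ]
  expect_equal(nrow(low), 1L)           # single stable low state
  expect_true(low$stable && low$rE < 0.1)
  mid <- bd[bd$b == 1, ]
  expect_equal(nrow(mid), 3L)           # bistable: 2 stable + 1 unstable
  expect_equal(sum(mid$stable), 2L)
  hi <- bd[bd$b == 3, ]
  expect_equal(nrow(hi), 1L)            # high state only
  expect_true(hi$stable && hi$rE > 0.9)
  # self-consistency: residuals of reported fixed points below 1e-8
  p <- circuit_params()
  sigE <- function(u) 1 / (1 + exp(-u))
  sigI <- function(u) 1 / (1 + exp(-u / 3))
  for (i in seq_len(nrow(bd))) {
    rE <- bd$rE[i]; rI <- bd$rI[i]; b <- bd$b[i]
    expect_lt(abs(-rE + sigE(p$wEE * rE - p$wEI * rI + p$IE + b)), 1e-8)
    expect_lt(abs(-rI + sigI(p$wIE * rE - p$wII * rI + p$II)), 1e-8)
  }
})

test_that("the decision stage switches from non-competing to winner-take-all", {
  rm <- decision_regime(circuit_params(), c(0, 0.1, 0.9, 1))
  expect_equal(rm$regime[rm$I0 <= 0.1], rep("non_competing", 2))
  expect_equal(rm$regime[rm$I0 >= 0.9], rep("winner_take_all", 2))
})

test_that("ablation variants reproduce their qualitative failure modes", {
  grid <- c(0.2, 0.5, 0.8)
  osv <- run_ablation("object_specific_view", value_grid = grid)
  expect_true(osv$verdict$second_always)

  ns <- run_ablation("no_switch", value_grid = grid)
  expect_true(ns$verdict$never_decides)

  pt <- run_ablation("positive_tuned_wMC08", value_grid = grid)
  expect_equal(pt$verdict$frac_higher_value, 1)
  expect_false(pt$verdict$many_objects_extensible)

  cl <- run_ablation("classical_simultaneous", value_grid = grid)
  expect_equal(cl$verdict$frac_higher_value, 1)
  expect_false(cl$verdict$many_objects_extensible)
})

test_that("the many-objects extension picks the best of every ordered pair", {
  ov <- c(A = 0.1, B = 0.4, C = 0.6, D = 0.9)
  p0 <- circuit_params(eta = 0)
  for (i in names(ov)) for (j in names(ov)) {
    if (i == j) next
    out <- simulate_many_objects(p0, ov, c(i, j))
    expect_identical(out$object_choice, names(which.max(ov[c(i, j)])))
  }
  expect_error(simulate_many_objects(p0, ov, c("A", "Z")), "member")
})

test_that("equal-value pairs split evenly under noise in the many-object set", {
  set.seed(33)
  n <- 60
  vals <- cbind(A = rep(0.5, n), B = rep(0.5, n),
                C = rep(0.2, n), D = rep(0.8, n))
  ro <- viewchoice:::circuit_run(circuit_params(), vals,
                                 rep("A", n), rep("B", n))$readout
  pa <- mean(ro$object_choice == "A", na.rm = TRUE)
  expect_gt(pa, 0.3); expect_lt(pa, 0.7)
})
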