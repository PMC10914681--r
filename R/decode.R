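#' Build a pseudo-population for decoding
#'
#' Aggregates separately recorded (or synthetically generated) neurons into
#' a pseudo-population: each neuron contributes a response vector and a
#' per-trial group label; neurons lacking the minimum trial count in any
#' group are excluded (and listed); group sizes are set to the per-group
#' minimum across included neurons; and each decoding repetition randomly
#' matches trials across neurons within groups.
#'
#' @param responses list of per-neuron numeric response vectors (z-scored
#'   rates for one task window), or a single matrix (trials x neurons) when
#'   all neurons share trials.
#' @param groups list of per-neuron group labels (or one vector).
#' @param min_trials minimum trials per group for inclusion (5, 10 or 15 in
#'   the standard configurations).
#' @return An object of class \code{pseudo_population}: \code{responses},
#'   \code{groups}, \code{levels}, \code{n_per_group}, \code{kept},
#'   \code{excluded}.
#' @seealso \code{\link{pseudo_from_recording}}, \code{\link{decode_population}}
#' @export
build_pseudopopulation <- function(responses, groups, min_trials = 5) {
  if (is.matrix(responses)) {
    responses <- lapply(seq_len(ncol(responses)), function(j) responses[, j])
  }
  if (!is.list(groups)) groups <- rep(list(groups), length(responses))
  stopifnot(length(responses) == length(groups))
  levels_all <- sort(unique(unlist(lapply(groups, unique))))
  if (length(levels_all) < 2L) stopf("grouping must yield at least 2 groups")
  counts <- vapply(groups, function(g)
    vapply(levels_all, function(l) sum(g == l), numeric(1)),
    numeric(length(levels_all)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(levels_all))
  ok <- apply(counts >= min_trials, 2, all)
  if (!any(ok)) stopf("no neuron passes the %d-trial filter", min_trials)
  n_per_group <- apply(counts[, ok, drop = FALSE], 1, min)
  structure(list(responses = responses[ok], groups = groups[ok],
                 levels = levels_all,
                 n_per_group = setNames(n_per_group, levels_all),
                 kept = which(ok), excluded = which(!ok),
                 min_trials = min_trials),
            class = "pseudo_population")
}

#' @export
print.pseudo_population <- function(x, ...) {
  cat(sprintf("Pseudo-population: %d neurons (%d excluded by %d-trial filter)\n",
              length(x$responses), length(x$excluded), x$min_trials))
  cat("  groups:", paste(sprintf("%s (n=%d)", x$levels, x$n_per_group),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Pseudo-population from a recording set
#'
#' Convenience wrapper: z-scores the epoch activity of a
#' \code{recording_set} and builds the pseudo-population for a per-trial
#' grouping variable.
#'
#' @param recording a \code{recording_set}.
#' @param groups per-trial labels (length = trials), NA trials dropped.
#' @param epoch task epoch to decode from.
#' @param min_trials inclusion filter.
#' @param neurons optional subset of neuron indices.
#' @export
pseudo_from_recording <- function(recording, groups, epoch = "cue2",
                                  min_trials = 5, neurons = NULL) {
  zs <- zscore_epochs(recording)
  z <- zs$z[, , epoch, drop = TRUE]
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (!is.null(neurons)) z <- z[match(neurons, zs$kept), , drop = FALSE]
  keep <- !is.na(groups)
  build_pseudopopulation(t(z[, keep, drop = FALSE]), groups[keep],
                         min_trials = min_trials)
}

# One random within-group trial matching: X (sum n_g x neurons), y labels.
draw_matching <- function(pseudo) {
  nl <- length(pseudo$levels)
  ng <- pseudo$n_per_group
  X <- matrix(NA_real_, sum(ng), length(pseudo$responses))
  y <- factor(rep(pseudo$levels, ng), levels = pseudo$levels)
  for (j in seq_along(pseudo$responses)) {
    r <- pseudo$responses[[j]]; g <- pseudo$groups[[j]]
    col <- unlist(lapply(seq_len(nl), function(k) {
      idx <- which(g == pseudo$levels[k])
      sample(r[idx], ng[k])
    }))
    X[, j] <- col
  }
  list(X = X, y = y)
}

# Leave-one-out accuracy of the linear maximum-margin classifier.
loo_svm <- function(X, y, cost = 1) {
  n <- nrow(X)
  correct <- logical(n)
  for (i in seq_len(n)) {
    fit <- e1071::svm(X[-i, , drop = FALSE], y[-i], kernel = "linear",
                      cost = cost, scale = FALSE)
    correct[i] <- predict(fit, X[i, , drop = FALSE]) == y[i]
  }
  mean(correct)
}

# Leave-one-out nearest-neighbor accuracy (Euclidean; ties broken by the
# lowest trial index).
loo_nn <- function(X, y) {
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  pred <- y[apply(D, 1, which.min)]
  mean(pred == y)
}

# 80/20 split accuracy (single stratified split per call).
split_acc <- function(X, y, method, cost = 1, train_frac = 0.8) {
  idx <- unlist(lapply(levels(y), function(l) {
    w <- which(y == l)
    sample(w, max(1, round(train_frac * length(w))))
  }))
  test <- setdiff(seq_len(nrow(X)), idx)
  if (!length(test)) return(NA_real_)
  if (method == "svm") {
    fit <- e1071::svm(X[idx, , drop = FALSE], y[idx], kernel = "linear",
                      cost = cost, scale = FALSE)
    mean(predict(fit, X[test, , drop = FALSE]) == y[test])
  } else {
    D <- outer(rowSums(X[test, , drop = FALSE]^2),
               rowSums(X[idx, , drop = FALSE]^2), `+`) -
      2 * X[test, , drop = FALSE] %*% t(X[idx, , drop = FALSE])
    pred <- y[idx][apply(D, 1, which.min)]
    mean(pred == y[test])
  }
}

#' Decode a grouping variable from a pseudo-population
#'
#' Linear maximum-margin (SVM, cost 1) or nearest-neighbor decoding with
#' leave-one-out cross-validation, repeated over random within-group trial
#' matchings; significance against label-shuffled data by two-sided
#' rank-sum.
#'
#' @param pseudo a \code{pseudo_population} (two or more groups; multi-class
#'   uses the SVM's one-vs-one voting).
#' @param method \code{"svm"} or \code{"nn"}.
#' @param n_matchings decoding repetitions with fresh trial matchings
#'   (150 for SVM and 500 for NN in the standard configuration).
#' @param n_shuffles label shuffles for the null distribution (1000 unless
#'   configured down).
#' @param cv \code{"loo"} (default) or \code{"split"} (80/20).
#' @param seed integer seed.
#' @return An object of class \code{decode_result}: \code{accuracy} (\%)
#'   per matching, \code{mean_accuracy}, \code{sd_accuracy},
#'   \code{shuffle_accuracy}, \code{p} (rank-sum), \code{scheme}.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(100, 2), 10), matrix(rnorm(100, -2), 10))
#' ps <- build_pseudopopulation(X, rep(c("a", "b"), each = 10), min_trials = 5)
#' decode_population(ps, "nn", n_matchings = 3, n_shuffles = 20, seed = 2)$mean_accuracy
#' @export
decode_population <- function(pseudo, method = c("svm", "nn"),
                              n_matchings = if (method[1] == "nn") 500 else 150,
                              n_shuffles = 1000, cv = c("loo", "split"),
                              seed = NULL) {
  method <- match.arg(method)
  cv <- match.arg(cv)
  stopifnot(inherits(pseudo, "pseudo_population"))
  if (any(pseudo$n_per_group < 2L)) stopf("degenerate group with < 2 trials")
  acc_fun <- function(X, y) {
    if (cv == "loo") {
      if (method == "svm") loo_svm(X, y) else loo_nn(X, y)
    } else {
      split_acc(X, y, method)
    }
  }
  acc <- shuf <- NULL
  with_seed(seed, {
    acc <- vapply(seq_len(n_matchings), function(r) {
      m <- draw_matching(pseudo)
      100 * acc_fun(m$X, m$y)
    }, numeric(1))
    shuf <- vapply(seq_len(n_shuffles), function(r) {
      m <- draw_matching(pseudo)
      100 * acc_fun(m$X, sample(m$y))
    }, numeric(1))
  })
  p <- tryCatch(suppressWarnings(wilcox.test(acc, shuf)$p.value),
                error = function(e) NA_real_)
  structure(list(accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = sd(acc), shuffle_accuracy = shuf,
                 p = p, method = method, cv = cv,
                 scheme = sprintf("%d-class %s (%s)", length(pseudo$levels),
                                  method, cv),
                 n_neurons = length(pseudo$responses)),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("Decoding (%s): %.1f%% +/- %.1f (n = %d neurons)\n",
              x$scheme, x$mean_accuracy, x$sd_accuracy %||% NA, x$n_neurons))
  if (length(x$shuffle_accuracy))
    cat(sprintf("  shuffle %.1f%%; rank-sum p = %.3g\n",
                mean(x$shuffle_accuracy), x$p))
  invisible(x)
}

#' Cross-condition generalization decoding
#'
#' Trains the classifier on one condition and evaluates it on another
#' (e.g., train on the A-then-B viewing sequence, test on B-then-A). With
#' \code{recode_rule = "invert_by_sequence"} the test-set group labels are
#' inverted, providing the decoder with the viewing sequence and recovering
#' label correspondence for object-choice decoding from a view-based code.
#'
#' @param pseudo_train,pseudo_test \code{pseudo_population}s over the same
#'   neurons (same order) with identical group levels.
#' @param method \code{"svm"} or \code{"nn"}.
#' @param recode_rule \code{"none"} or \code{"invert_by_sequence"}.
#' @param n_matchings repetitions; \code{n_shuffles} label shuffles.
#' @param seed integer seed.
#' @return A \code{decode_result}.
#' @export
cross_condition_decode <- function(pseudo_train, pseudo_test,
                                   method = c("svm", "nn"),
                                   recode_rule = c("none", "invert_by_sequence"),
                                   n_matchings = 50, n_shuffles = 200,
                                   seed = NULL) {
  method <- match.arg(method)
  recode_rule <- match.arg(recode_rule)
  if (length(pseudo_train$responses) != length(pseudo_test$responses))
    stopf("train and test populations must share the neuron list")
  if (!identical(pseudo_train$levels, pseudo_test$levels))
    stopf("train and test groups must share levels")
  recode <- function(y) {
    if (recode_rule == "none") return(y)
    factor(pseudo_train$levels[3 - as.integer(y)], levels = levels(y))
  }
  if (recode_rule == "invert_by_sequence" && length(pseudo_train$levels) != 2L)
    stopf("label inversion requires two groups")
  acc <- shuf <- NULL
  with_seed(seed, {
    acc <- vapply(seq_len(n_matchings), function(r) {
      tr <- draw_matching(pseudo_train)
      te <- draw_matching(pseudo_test)
      yte <- recode(te$y)
      if (method == "svm") {
        fit <- e1071::svm(tr$X, tr$y, kernel = "linear", cost = 1, scale = FALSE)
        100 * mean(predict(fit, te$X) == yte)
      } else {
        D <- outer(rowSums(te$X^2), rowSums(tr$X^2), `+`) -
          2 * te$X %*% t(tr$X)
        pred <- tr$y[apply(D, 1, which.min)]
        100 * mean(pred == yte)
      }
    }, numeric(1))
    shuf <- vapply(seq_len(n_shuffles), function(r) {
      tr <- draw_matching(pseudo_train)
      te <- draw_matching(pseudo_test)
      ys <- sample(recode(te$y))
      if (method == "svm") {
        fit <- e1071::svm(tr$X, sample(tr$y), kernel = "linear", cost = 1,
                          scale = FALSE)
        100 * mean(predict(fit, te$X) == ys)
      } else {
        D <- outer(rowSums(te$X^2), rowSums(tr$X^2), `+`) -
          2 * te$X %*% t(tr$X)
        pred <- sample(tr$y)[apply(D, 1, which.min)]
        100 * mean(pred == ys)
      }
    }, numeric(1))
  })
  p <- tryCatch(suppressWarnings(wilcox.test(acc, shuf)$p.value),
                error = function(e) NA_real_)
  structure(list(accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = sd(acc), shuffle_accuracy = shuf, p = p,
                 method = method, cv = "cross-condition",
                 scheme = sprintf("cross-condition %s (recode: %s)", method,
                                  recode_rule),
                 n_neurons = length(pseudo_train$responses)),
            class = "decode_result")
}

#' Conjunction (sequence x view-choice) decoding
#'
#' Multi-class decoding of the four conjunctions of viewing sequence and
#' view-based choice with the linear maximum-margin classifier (one-vs-one
#' voting). Chance is 25\%.
#'
#' @param pseudo a 4-group \code{pseudo_population}.
#' @param n_matchings,n_shuffles,seed as in \code{\link{decode_population}}.
#' @return A \code{decode_result} with an additional \code{per_class}
#'   accuracy vector and \code{confusion} matrix (summed over matchings).
#' @export
conjunction_decode <- function(pseudo, n_matchings = 20, n_shuffles = 100,
                               seed = NULL) {
  stopifnot(inherits(pseudo, "pseudo_population"))
  if (length(pseudo$levels) != 4L) stopf("conjunction decoding needs 4 groups")
  if (any(pseudo$n_per_group < 2L)) stopf("a conjunction class is missing or degenerate")
  conf <- matrix(0, 4, 4, dimnames = list(pseudo$levels, pseudo$levels))
  acc <- shuf <- NULL
  with_seed(seed, {
    acc <- vapply(seq_len(n_matchings), function(r) {
      m <- draw_matching(pseudo)
      n <- nrow(m$X)
      pred <- factor(rep(NA_character_, n), levels = pseudo$levels)
      for (i in seq_len(n)) {
        fit <- e1071::svm(m$X[-i, , drop = FALSE], m$y[-i], kernel = "linear",
                          cost = 1, scale = FALSE)
        pred[i] <- predict(fit, m$X[i, , drop = FALSE])
      }
      conf <<- conf + table(m$y, pred)
      100 * mean(pred == m$y)
    }, numeric(1))
    shuf <- vapply(seq_len(n_shuffles), function(r) {
      m <- draw_matching(pseudo)
      ys <- sample(m$y)
      100 * loo_svm_multiclass(m$X, ys)
    }, numeric(1))
  })
  per_class <- diag(conf) / rowSums(conf) * 100
  p <- tryCatch(suppressWarnings(wilcox.test(acc, shuf)$p.value),
                error = function(e) NA_real_)
  structure(list(accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = sd(acc), shuffle_accuracy = shuf, p = p,
                 per_class = per_class, confusion = conf,
                 method = "svm", cv = "loo",
                 scheme = "4-class conjunction svm (loo)",
                 n_neurons = length(pseudo$responses)),
            class = "decode_result")
}

loo_svm_multiclass <- function(X, y) {
  n <- nrow(X)
  correct <- logical(n)
  for (i in seq_len(n)) {
    fit <- e1071::svm(X[-i, , drop = FALSE], y[-i], kernel = "linear",
                      cost = 1, scale = FALSE)
    correct[i] <- predict(fit, X[i, , drop = FALSE]) == y[i]
  }
  mean(correct)
}

#' View-choice decoding by decision difficulty terciles
#'
#' Splits trials by terciles of the unsigned value difference between the
#' first- and second-viewed option and decodes the view-based choice within
#' each tercile.
#'
#' @param recording a \code{recording_set}.
#' @param value_difference per-trial |first - second| value difference
#'   (defaults to the attached session values).
#' @param epoch task window.
#' @param method,min_trials,n_matchings,n_shuffles,seed decoding settings.
#' @return List of \code{decode_result}s named easy/middle/hard (terciles
#'   with too few trials are skipped with a NULL entry).
#' @export
decode_by_difficulty <- function(recording, value_difference = NULL,
                                 epoch = "cue2", method = "svm",
                                 min_trials = 5, n_matchings = 20,
                                 n_shuffles = 100, seed = NULL) {
  tr <- recording$behavior$trials
  dv <- value_difference %||% abs(tr$value_first - tr$value_second)
  qs <- quantile(dv, c(1 / 3, 2 / 3), type = 1)
  terc <- cut(dv, c(-Inf, qs, Inf), labels = c("hard", "middle", "easy"))
  out <- setNames(vector("list", 3), c("easy", "middle", "hard"))
  for (lv in names(out)) {
    sel <- terc == lv
    groups <- ifelse(sel, tr$view_choice, NA)
    res <- tryCatch({
      ps <- pseudo_from_recording(recording, groups, epoch = epoch,
                                  min_trials = min_trials)
      decode_population(ps, method, n_matchings = n_matchings,
                        n_shuffles = n_shuffles,
                        seed = child_seed(seed, match(lv, names(out))))
    }, error = function(e) NULL)
    out[[lv]] <- res
  }
  structure(out, class = "difficulty_decode")
}

#' @export
print.difficulty_decode <- function(x, ...) {
  for (lv in names(x)) {
    if (is.null(x[[lv]])) cat(sprintf("  %s: skipped\n", lv))
    else cat(sprintf("  %s: %.1f%%\n", lv, x[[lv]]$mean_accuracy))
  }
  invisible(x)
}

#' Decoding accuracy as a function of sample size
#'
#' Randomly subsamples neurons (without replacement) at each size and
#' reports mean and SD accuracy over repetitions.
#'
#' @param pseudo a \code{pseudo_population}.
#' @param sizes neuron counts to test (max must not exceed the population).
#' @param reps repetitions per size.
#' @param method decoder; \code{n_matchings} per repetition kept small.
#' @param seed integer seed.
#' @return Data frame: size, mean_accuracy, sd_accuracy.
#' @export
accuracy_vs_samplesize <- function(pseudo, sizes, reps = 100, method = "nn",
                                   n_matchings = 1, seed = NULL) {
  if (any(sizes < 1)) stopf("sizes must be positive")
  if (max(sizes) > length(pseudo$responses))
    stopf("size exceeds population size")
  rows <- NULL
  with_seed(seed, {
    rows <- lapply(sizes, function(sz) {
      acc <- vapply(seq_len(reps), function(r) {
        idx <- sample(seq_along(pseudo$responses), sz)
        sub <- pseudo
        sub$responses <- pseudo$responses[idx]
        sub$groups <- pseudo$groups[idx]
        m <- draw_matching(sub)
        if (method == "nn") 100 * loo_nn(m$X, m$y) else 100 * loo_svm(m$X, m$y)
      }, numeric(1))
      data.frame(size = sz, mean_accuracy = mean(acc), sd_accuracy = sd(acc))
    })
  })
  do.call(rbind, rows)
}

#' Nucleus-level value decoding with a group-mean nearest-neighbor readout
#'
#' For each nucleus, selects the neurons with the strongest value
#' regression coefficients (top \code{n_top}) and decodes low vs high value
#' by comparing each held-out trial vector with the group-mean activity
#' vectors of the two value groups (Euclidean distance, leave-one-out).
#'
#' @param recording a \code{recording_set}.
#' @param n_top neurons per nucleus (20 in the standard configuration).
#' @param epoch task window (first-cue period).
#' @param n_matchings,seed decoding settings.
#' @return Data frame: nucleus, n_neurons, accuracy (\%).
#' @export
nucleus_value_decode <- function(recording, n_top = 20, epoch = "cue1",
                                 n_matchings = 20, seed = NULL) {
  beh <- recording$behavior
  tr <- beh$trials
  zs <- zscore_epochs(recording)
  z <- zs$z[, , epoch, drop = TRUE]
  pop <- recording$population[zs$kept, ]
  vfirst <- tr$value_first
  coefv <- vapply(seq_len(nrow(z)), function(i)
    abs(coef(neuron_glm(data.frame(v = vfirst), z[i, ]))[["v"]]), numeric(1))
  lo_hi <- cut(vfirst, quantile(vfirst, c(0, 1 / 3, 2 / 3, 1), type = 1),
               include.lowest = TRUE, labels = c("low", "mid", "high"))
  groups <- ifelse(lo_hi == "mid", NA, as.character(lo_hi))
  rows <- lapply(unique(pop$nucleus), function(nuc) {
    idx <- which(pop$nucleus == nuc)
    idx <- idx[order(coefv[idx], decreasing = TRUE)][seq_len(min(n_top, length(idx)))]
    ps <- tryCatch(build_pseudopopulation(
      t(z[idx, !is.na(groups), drop = FALSE]), groups[!is.na(groups)],
      min_trials = 2), error = function(e) NULL)
    if (is.null(ps)) return(NULL)
    acc <- NULL
    with_seed(child_seed(seed, match(nuc, unique(pop$nucleus))), {
      acc <- vapply(seq_len(n_matchings), function(r) {
        m <- draw_matching(ps)
        100 * loo_mean_nn(m$X, m$y)
      }, numeric(1))
    })
    data.frame(nucleus = nuc, n_neurons = length(idx), accuracy = mean(acc))
  })
  do.call(rbind, rows)
}

# Leave-one-out classification against group-mean vectors.
loo_mean_nn <- function(X, y) {
  n <- nrow(X)
  lv <- levels(y)
  correct <- logical(n)
  for (i in seq_len(n)) {
    mus <- vapply(lv, function(l)
      colMeans(X[setdiff(which(y == l), i), , drop = FALSE]),
      numeric(ncol(X)))
    d <- apply(mus, 2, function(mu) sum((X[i, ] - mu)^2))
    correct[i] <- lv[which.min(d)] == y[i]
  }
  mean(correct)
}
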