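#' Condition-mean population matrix and RSA correlation matrix
#'
#' Computes, per neuron, the mean z-scored activity in each condition of a
#' condition specification (e.g., object x value-quartile, or choice x
#' sequence), normalizes the condition-by-neuron matrix column-wise (per
#' neuron: mean removed, divided by SD), and returns the condition x
#' condition Pearson correlation matrix computed across neurons.
#' Row/column order follows the condition table and is preserved across
#' calls.
#'
#' @param recording a \code{recording_set}.
#' @param condition_spec data frame: one row per condition, with a
#'   \code{condition} id column and attribute columns (e.g. \code{object},
#'   \code{value_level}, \code{view_choice}, \code{sequence}); plus an
#'   assignment function mapping trials to conditions via
#'   \code{assign_conditions}.
#' @param condition_of per-trial condition ids (character, NA = unused
#'   trial), or a named list of such vectors keyed by epoch (e.g.
#'   \code{list(cue1 = ..., cue2 = ...)}) to pool condition means over
#'   several viewing periods; must realize every condition in
#'   \code{condition_spec}.
#' @param epoch task window used for the condition means, or \code{"bins"}
#'   with \code{window} = c(from, to) ms for a custom window.
#' @param window optional c(from, to) ms window on the bin grid.
#' @return List of class \code{rsa_matrix}: \code{conditions},
#'   \code{condition_means} (condition x neuron, normalized), \code{R}
#'   (correlations), \code{epoch}.
#' @export
condition_rsa <- function(recording, condition_spec, condition_of,
                          epoch = "cue1", window = NULL) {
  stopifnot(inherits(recording, "recording_set"))
  conds <- condition_spec$condition
  if (!is.list(condition_of)) {
    condition_of <- setNames(list(condition_of), epoch)
  }
  missing <- setdiff(conds, unique(unlist(condition_of)))
  if (length(missing))
    stopf("unrealized condition(s): %s", paste(missing, collapse = ", "))
  zs <- zscore_epochs(recording)
  zlist <- lapply(names(condition_of), function(ep) {
    if (is.null(window)) {
      z <- zs$z[, , ep, drop = TRUE]
      if (is.null(dim(z))) z <- matrix(z, nrow = 1)
      z
    } else {
      sel <- recording$bins$start >= window[1] & recording$bins$end <= window[2]
      raw <- apply(recording$counts[zs$kept, , sel, drop = FALSE], c(1, 2), sum)
      raw / ((window[2] - window[1]) / 1000)
    }
  })
  # pool (epoch, trial) samples per condition
  zall <- do.call(cbind, zlist)
  call <- unlist(condition_of)
  M <- vapply(conds, function(cn) {
    rowMeans(zall[, which(call == cn), drop = FALSE])
  }, numeric(nrow(zall)))                   # neurons x conditions
  M <- t(M)                                 # conditions x neurons
  # per-neuron (column) normalization
  mu <- colMeans(M); sdv <- apply(M, 2, sd)
  ok <- sdv > 0
  Mn <- sweep(sweep(M[, ok, drop = FALSE], 2, mu[ok]), 2, sdv[ok], "/")
  R <- cor(t(Mn))
  dimnames(R) <- list(conds, conds)
  structure(list(conditions = condition_spec, condition_means = Mn, R = R,
                 epoch = if (is.null(window)) epoch else
                   sprintf("[%d,%d) ms", window[1], window[2])),
            class = "rsa_matrix")
}

#' @export
print.rsa_matrix <- function(x, ...) {
  cat(sprintf("RSA matrix: %d conditions (%s window)\n", nrow(x$R), x$epoch))
  print(round(x$R, 2))
  invisible(x)
}

#' Standard condition specifications for RSA
#'
#' \code{value_conditions()} crosses the two objects with four value
#' quartiles (mean-centered level codes -2.25, -0.75, 0.75, 2.25);
#' \code{choice_conditions()} crosses view-based choice with viewing
#' sequence (optionally with the chosen side).
#'
#' @param with_side include left/right choice in the choice conditions.
#' @return Data frame with a \code{condition} column and attribute columns.
#' @export
value_conditions <- function() {
  expand.grid(object = c("A", "B"), value_level = c(-2.25, -0.75, 0.75, 2.25),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    within({condition <- paste0(object, "_q", match(value_level,
                                                    c(-2.25, -0.75, 0.75, 2.25)))})
}

#' @rdname value_conditions
#' @export
choice_conditions <- function(with_side = FALSE) {
  cc <- expand.grid(view_choice = c("first", "second"),
                    sequence = c("AB", "BA"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (with_side) cc <- merge(cc, data.frame(side = c("left", "right")))
  cc$object <- ifelse((cc$sequence == "AB") == (cc$view_choice == "first"),
                      "A", "B")
  cc$condition <- paste0(cc$sequence, "_", cc$view_choice,
                         if (with_side) paste0("_", cc$side) else "")
  cc
}

#' Assign trials to value-RSA conditions
#'
#' Value quartiles are computed per object from the session values (stable
#' ranking; boundary ties broken by trial order), crossed with the viewed
#' object. With \code{both_periods = TRUE} the assignment is returned for
#' the first- and second-cue viewing periods separately (a list keyed by
#' epoch), so \code{\link{condition_rsa}} pools condition means over both
#' viewing periods, the standard configuration for the value RSA.
#'
#' @param behavior a value-augmented \code{session_behavior}.
#' @param both_periods pool both viewing periods.
#' @return Character vector of condition ids per trial (first-cue framing),
#'   or a list \code{list(cue1 = ..., cue2 = ...)}.
#' @export
assign_value_conditions <- function(behavior, both_periods = FALSE) {
  tr <- behavior$trials
  one <- function(obj_col) {
    out <- rep(NA_character_, nrow(tr))
    for (obj in c("A", "B")) {
      sel <- which(tr[[obj_col]] == obj)
      v <- tr[[paste0("value.", obj)]][sel]
      q <- ceiling(4 * rank(v, ties.method = "first") / length(v))
      out[sel] <- paste0(obj, "_q", q)
    }
    out
  }
  if (!both_periods) return(one("obj_first"))
  list(cue1 = one("obj_first"), cue2 = one("obj_second"))
}

#' Assign trials to choice-RSA conditions
#' @param behavior a \code{session_behavior}.
#' @param with_side cross conditions with the chosen side.
#' @export
assign_choice_conditions <- function(behavior, with_side = FALSE) {
  tr <- behavior$trials
  base <- paste0(ifelse(tr$obj_first == "A", "AB", "BA"), "_", tr$view_choice)
  if (with_side) paste0(base, "_", tr$chosen_side) else base
}

#' Model templates for RSA regression
#'
#' Builds the named similarity templates over a condition specification:
#' \describe{
#'   \item{identity}{1 on the diagonal, 0 elsewhere.}
#'   \item{object}{1 for condition pairs sharing the object, 0 otherwise.}
#'   \item{view_value}{pairwise products of the mean-centered value-level
#'     codes (-2.25, -0.75, 0.75, 2.25).}
#'   \item{object_value}{elementwise product of the object-identity and
#'     view-based value templates (value similarity within object only).}
#'   \item{view_value_ordinal}{ordinal variant: adjacent value levels
#'     equally similar, uniform similarity for equal levels.}
#'   \item{object_choice}{1 for pairs choosing the same object.}
#'   \item{view_choice}{1 for pairs sharing the view-based choice.}
#'   \item{left_choice}{1 for pairs sharing the chosen side.}
#' }
#'
#' @param condition_spec condition data frame (attribute columns determine
#'   which templates are available).
#' @param templates template names to build.
#' @return List of class \code{template_set}: named condition x condition
#'   matrices in the specification's condition order.
#' @examples
#' ts <- build_templates(value_conditions(),
#'                       c("identity", "object", "view_value", "object_value"))
#' ts$view_value[1, 8]
#' @export
build_templates <- function(condition_spec, templates) {
  cs <- condition_spec
  n <- nrow(cs)
  need <- function(col, tpl) if (is.null(cs[[col]]))
    stopf("template '%s' needs condition attribute '%s'", tpl, col)
  out <- lapply(templates, function(tp) {
    m <- switch(tp,
      identity = diag(n),
      object = { need("object", tp)
        outer(cs$object, cs$object, `==`) * 1 },
      view_value = { need("value_level", tp)
        outer(cs$value_level, cs$value_level) },
      object_value = { need("object", tp); need("value_level", tp)
        (outer(cs$object, cs$object, `==`) * 1) *
          outer(cs$value_level, cs$value_level) },
      view_value_ordinal = { need("value_level", tp)
        lv <- match(cs$value_level, sort(unique(cs$value_level)))
        mx <- length(unique(lv)) - 1
        (mx - abs(outer(lv, lv, `-`))) / mx },
      object_choice = { need("object", tp)
        outer(cs$object, cs$object, `==`) * 1 },
      view_choice = { need("view_choice", tp)
        outer(cs$view_choice, cs$view_choice, `==`) * 1 },
      left_choice = { need("side", tp)
        outer(cs$side, cs$side, `==`) * 1 },
      stopf("unknown template '%s'", tp))
    dimnames(m) <- list(cs$condition, cs$condition)
    m
  })
  names(out) <- templates
  structure(out, class = "template_set")
}

#' Template regression of an RSA matrix with permutation inference
#'
#' Vectorizes the neuronal RSA matrix (full matrix by default, upper
#' triangle in unique-cells mode) and regresses it on the concatenated
#' templates. Significance is assessed non-parametrically: the rows
#' (conditions) of the condition-by-neuron matrix are shuffled jointly, the
#' correlation matrix recomputed, and the regression repeated; the critical
#' |t| is the (1 - p_crit) quantile across permutations. Differences
#' between template coefficients are tested against permuted t-differences.
#' Partial R-squared is reported per template.
#'
#' @param rsa an \code{rsa_matrix}.
#' @param templates a \code{template_set}.
#' @param n_perm number of permutations (10000 in the standard
#'   configuration).
#' @param p_crit permutation criterion (0.001 standard).
#' @param unique_cells use only the upper triangle (robustness check).
#' @param seed integer seed.
#' @return An object of class \code{rsa_regression}: coefficient table
#'   (estimate, t, partial_r2, critical |t|, significant), the permutation
#'   t matrix, and pairwise coefficient-difference tests.
#' @export
rsa_regression <- function(rsa, templates, n_perm = 10000, p_crit = 0.001,
                           unique_cells = FALSE, seed = NULL) {
  stopifnot(inherits(rsa, "rsa_matrix"), inherits(templates, "template_set"))
  n <- nrow(rsa$R)
  if (!all(vapply(templates, function(m) all(dim(m) == n), logical(1))))
    stopf("templates not conformable with the RSA matrix")
  sel <- if (unique_cells) upper.tri(rsa$R, diag = FALSE) else
    matrix(TRUE, n, n)
  if (sum(sel) <= length(templates) + 1L)
    stopf("more templates than informative cells")
  X <- vapply(templates, function(m) m[sel], numeric(sum(sel)))
  fit <- neuron_glm(X, rsa$R[sel])
  tobs <- fit$coefficients$t[-1]

  Mn <- rsa$condition_means
  tperm <- NULL
  with_seed(seed, {
    tperm <- t(vapply(seq_len(n_perm), function(r) {
      Mp <- Mn[sample.int(n), , drop = FALSE]
      Rp <- suppressWarnings(cor(t(Mp)))
      Rp[!is.finite(Rp)] <- 0
      f <- tryCatch(neuron_glm(X, Rp[sel]), error = function(e) NULL)
      if (is.null(f)) rep(NA_real_, length(templates))
      else f$coefficients$t[-1]
    }, numeric(length(templates))))
  })
  crit <- apply(abs(tperm), 2, quantile, probs = 1 - p_crit, na.rm = TRUE)
  coefs <- data.frame(
    template = names(templates),
    estimate = fit$coefficients$estimate[-1],
    t = tobs,
    partial_r2 = fit$coefficients$partial_r2[-1],
    critical_t = crit,
    significant = abs(tobs) > crit)

  # pairwise coefficient-difference tests
  k <- length(templates)
  diffs <- NULL
  if (k >= 2) {
    pairs <- utils::combn(k, 2)
    diffs <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      dobs <- tobs[a] - tobs[b]
      dperm <- tperm[, a] - tperm[, b]
      dcrit <- quantile(abs(dperm), 1 - p_crit, na.rm = TRUE)
      data.frame(template_a = names(templates)[a],
                 template_b = names(templates)[b],
                 t_diff = dobs, critical_diff = unname(dcrit),
                 significant = abs(dobs) > dcrit)
    }))
  }
  structure(list(coefficients = coefs, differences = diffs, tperm = tperm,
                 n_perm = n_perm, p_crit = p_crit,
                 unique_cells = unique_cells, fit = fit),
            class = "rsa_regression")
}

#' @export
print.rsa_regression <- function(x, ...) {
  cat(sprintf("RSA template regression (%s cells, %d permutations):\n",
              if (x$unique_cells) "unique" else "all", x$n_perm))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Sliding-window RSA template attribution
#'
#' Computes the RSA template regression in 200-ms windows stepped at 20 ms
#' and returns the partial R-squared time course per template. On
#' circuit-generated data the object-identity structure peaks at the first
#' cue, view-based choice structure at the second cue, and object-choice
#' structure later still.
#'
#' @param recording a \code{recording_set}.
#' @param condition_spec,condition_of as in \code{\link{condition_rsa}}.
#' @param templates a \code{template_set}.
#' @param window_ms window width; \code{step_ms} stride.
#' @param span c(from, to) ms limits.
#' @return Data frame: window center plus one partial-R2 column per
#'   template.
#' @export
sliding_rsa <- function(recording, condition_spec, condition_of, templates,
                        window_ms = 200, step_ms = 20, span = c(-500, 2000)) {
  starts <- seq(span[1], span[2] - window_ms, by = step_ms)
  sel_any <- !is.na(condition_of)
  rows <- lapply(starts, function(s0) {
    rs <- tryCatch(condition_rsa(recording, condition_spec, condition_of,
                                 window = c(s0, s0 + window_ms)),
                   error = function(e) NULL)
    if (is.null(rs)) return(NULL)
    X <- vapply(templates, function(m) m[matrix(TRUE, nrow(m), ncol(m))],
                numeric(length(rs$R)))
    f <- tryCatch(neuron_glm(X, as.vector(rs$R)), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    out <- data.frame(center = s0 + window_ms / 2)
    for (j in seq_along(templates))
      out[[names(templates)[j]]] <- f$coefficients$partial_r2[j + 1]
    out
  })
  do.call(rbind, rows)
}
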