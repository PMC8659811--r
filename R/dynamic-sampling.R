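#' @title One-vs-Rest staging trainer with transfer selection and dynamic sampling
#' @description Decomposes the multi-label stage problem into four binary
#'   One-vs-Rest (OvR) tasks, selects a transfer-learning source for
#'   small-sample stages by label co-occurrence, and trains each binary CNN
#'   with the dynamic-sampling iteration: draw a balanced block, train, score
#'   all samples, multiplicatively boost the sampling probability of
#'   misclassified / low-confidence samples, renormalize each class to half
#'   the block size, repeat.
#' @name staging_trainer
NULL

#' Construct a multi-label stage dataset
#'
#' @param x List of feature objects (typically document matrices).
#' @param y List of character vectors, each a subset of
#'   `c("I","II","III","IV")`; an empty set marks a non-NSCLC sample.
#' @return A list of class `multilabel_dataset`.
#' @export
multilabel_dataset <- function(x, y) {
  stopifnot(length(x) == length(y))
  y <- lapply(y, function(s) sort(unique(as.character(s))))
  bad <- !vapply(y, function(s) all(s %in% stage_levels), logical(1))
  if (any(bad)) stop("labels must be subsets of {I, II, III, IV}")
  structure(list(x = x, y = y, labels = stage_levels),
            class = "multilabel_dataset")
}

#' One-vs-Rest split
#'
#' For each stage label, every sample appears exactly once: positive iff the
#' label is in its stage set, negative otherwise.
#'
#' @param S A [multilabel_dataset()].
#' @return Named list (one per stage) of `ovr_dataset` objects with fields
#'   `label`, `x`, `y_pos` (logical), `Npos`, `Nneg`, `N`.
#' @export
ovr_split <- function(S) {
  stopifnot(inherits(S, "multilabel_dataset"))
  if (!length(S$x)) stop("dataset is empty")
  out <- lapply(stage_levels, function(li) {
    y_pos <- vapply(S$y, function(s) li %in% s, logical(1))
    structure(list(label = li, x = S$x, y_pos = y_pos,
                   Npos = sum(y_pos), Nneg = sum(!y_pos),
                   N = length(y_pos)),
              class = "ovr_dataset")
  })
  stats::setNames(out, stage_levels)
}

#' Label co-occurrence matrix
#'
#' `F[li, lj]` counts the samples whose stage set contains both `li` and
#' `lj`; the diagonal counts samples containing `li`. Symmetric by
#' construction.
#'
#' @param S A [multilabel_dataset()].
#' @return A 4x4 integer matrix with stage dimnames, class
#'   `cooccurrence_matrix`.
#' @export
cooccurrence <- function(S) {
  stopifnot(inherits(S, "multilabel_dataset"))
  F_ <- matrix(0L, 4, 4, dimnames = list(stage_levels, stage_levels))
  for (s in S$y) {
    for (a in s) for (b in s) F_[a, b] <- F_[a, b] + 1L
  }
  structure(F_, class = c("cooccurrence_matrix", class(F_)))
}

#' Select the transfer-learning source label
#'
#' Returns the label `lj != li` with the largest co-occurrence `F[li, lj]`.
#' Ties are broken by the larger positive-sample count, then by the fixed
#' severity order IV > III > II > I. If every off-diagonal count is zero
#' (strictly single-label data), falls back to the label with the largest
#' positive count.
#'
#' @param F A [cooccurrence()] matrix.
#' @param li Target stage label.
#' @param sizes Named positive-sample counts per label.
#' @return A stage label.
#' @export
select_source_label <- function(F, li, sizes) {
  stopifnot(li %in% stage_levels, all(stage_levels %in% names(sizes)))
  others <- setdiff(stage_levels, li)
  f <- as.numeric(F[li, others])
  pref <- match(others, rev(stage_levels))   # 1 = IV ... 4 = I
  if (all(f == 0)) {
    ord <- order(-as.numeric(sizes[others]), pref)
    return(others[ord[1]])
  }
  ord <- order(-f, -as.numeric(sizes[others]), pref)
  others[ord[1]]
}

#' Initialize dynamic-sampling probabilities
#'
#' Each positive sample starts at `M / (2 * Npos)` and each negative at
#' `M / (2 * Nneg)`, so each class's probabilities sum to `M/2` and a
#' sampling pass draws `M/2` of each class in expectation. Entries are
#' capped at 1 (a probability compared against a uniform draw cannot
#' usefully exceed 1).
#'
#' @param ds An `ovr_dataset`.
#' @param M Training block size per iteration (`>= 2`).
#' @return A list of class `sampling_state`: `probs` (length `N`), `t = 1`,
#'   `M`.
#' @export
init_sampling_probs <- function(ds, M) {
  stopifnot(inherits(ds, "ovr_dataset"), M >= 2)
  if (ds$Npos == 0 || ds$Nneg == 0) {
    stop("cannot balance a one-class OvR set (Npos=", ds$Npos,
         ", Nneg=", ds$Nneg, ")")
  }
  probs <- ifelse(ds$y_pos, M / (2 * ds$Npos), M / (2 * ds$Nneg))
  structure(list(probs = pmin(probs, 1), t = 1L, M = M),
            class = "sampling_state")
}

#' Draw a balanced training block
#'
#' Each sample is included independently iff a uniform `[0,1)` draw falls at
#' or below its current sampling probability. Consumes the caller's RNG
#' stream; wrap in a seeded context for reproducibility.
#'
#' @param ds An `ovr_dataset`.
#' @param state A `sampling_state` whose length matches `ds$N`.
#' @return A list with `idx` (selected indices), `is_pos` (provenance flags
#'   for the selected samples), `n_pos`, `n_neg`.
#' @export
sample_balanced <- function(ds, state) {
  stopifnot(inherits(state, "sampling_state"),
            length(state$probs) == ds$N)
  draws <- stats::runif(ds$N)
  idx <- which(draws <= state$probs)
  list(idx = idx, is_pos = ds$y_pos[idx],
       n_pos = sum(ds$y_pos[idx]), n_neg = sum(!ds$y_pos[idx]))
}

#' Update sampling probabilities from classifier confidences
#'
#' A positive sample's probability is multiplied by `exp(1 - eta)` (low
#' confidence in the true class boosts it); a negative's by `exp(eta)` (a
#' confidently-positive-scored negative, i.e. a hard negative, is boosted).
#' Each class is then rescaled so its probabilities again sum to `M/2`, and
#' entries are capped at 1.
#'
#' @param state A `sampling_state`.
#' @param eta Numeric vector in `[0, 1]`: positive-class probability of
#'   every sample under the current model (evaluation mode).
#' @param ds The matching `ovr_dataset`.
#' @return The updated `sampling_state`, with `t` incremented.
#' @export
update_sampling_probs <- function(state, eta, ds) {
  stopifnot(inherits(state, "sampling_state"),
            length(eta) == ds$N, length(state$probs) == ds$N)
  if (any(eta < 0 | eta > 1)) stop("eta entries must lie in [0, 1]")
  p <- state$probs * ifelse(ds$y_pos, exp(1 - eta), exp(eta))
  sum_pos <- sum(p[ds$y_pos])
  sum_neg <- sum(p[!ds$y_pos])
  if (sum_pos <= 0 || sum_neg <= 0) stop("degenerate sampling state: class sum is 0")
  p[ds$y_pos]  <- state$M * p[ds$y_pos]  / (2 * sum_pos)
  p[!ds$y_pos] <- state$M * p[!ds$y_pos] / (2 * sum_neg)
  structure(list(probs = pmin(p, 1), t = state$t + 1L, M = state$M),
            class = "sampling_state")
}

#' Iterative training with dynamic sampling
#'
#' Runs `E` iterations of draw-block / train / score / update-probabilities
#' on one OvR task, starting from `init_model` (either a transferred source
#' model or a fresh one). With `dynamic = FALSE` the same gradient budget
#' (`E` rounds of `inner_epochs` on blocks of comparable size) is spent on
#' plain uniform draws of size `M` from the full imbalanced set -- the
#' baseline used to measure what dynamic sampling buys.
#'
#' @param ds An `ovr_dataset` whose `x` are document matrices.
#' @param init_model A `cnn_model` used as initialisation.
#' @param E Number of outer iterations (`>= 1`).
#' @param M Block size per iteration.
#' @param seed Master seed for the sampling stream.
#' @param inner_epochs SGD epochs on each drawn block (default 1).
#' @param dynamic Use the dynamic-sampling scheme (default `TRUE`).
#' @return A list with `model` (final `cnn_model`), `log` (one row per
#'   iteration: `iteration`, `n_pos`, `n_neg`, `loss`, `mean_eta_pos`,
#'   `mean_eta_neg`), and `state` (final `sampling_state`, or `NULL` when
#'   `dynamic = FALSE`).
#' @export
train_with_dynamic_sampling <- function(ds, init_model, E, M, seed = 1L,
                                        inner_epochs = 1L, dynamic = TRUE) {
  stopifnot(inherits(ds, "ovr_dataset"), inherits(init_model, "cnn_model"),
            E >= 1, M >= 2)
  model <- init_model
  state <- if (dynamic) init_sampling_probs(ds, M) else NULL
  log_rows <- vector("list", E)
  sample_seed <- derive_seed(seed, "sampling")
  for (t in seq_len(E)) {
    drawn <- with_seed(sample_seed + t, {
      if (dynamic) {
        d <- sample_balanced(ds, state)
        tries <- 0L
        while (!length(d$idx) && tries < 10L) {
          d <- sample_balanced(ds, state)
          tries <- tries + 1L
        }
        if (!length(d$idx)) stop("empty training block after 10 resampling attempts")
        d
      } else {
        idx <- sample.int(ds$N, min(M, ds$N))
        list(idx = idx, is_pos = ds$y_pos[idx],
             n_pos = sum(ds$y_pos[idx]), n_neg = sum(!ds$y_pos[idx]))
      }
    })
    block <- lapply(drawn$idx, function(j)
      list(x = ds$x[[j]], y = as.integer(ds$y_pos[j])))
    model <- cnn_train(model, block, epochs = inner_epochs,
                       seed = derive_seed(seed, "inner") + t)
    eta <- cnn_predict(model, ds$x)
    if (dynamic) state <- update_sampling_probs(state, eta, ds)
    log_rows[[t]] <- data.frame(
      iteration = t, n_pos = drawn$n_pos, n_neg = drawn$n_neg,
      loss = utils::tail(model$history, 1),
      mean_eta_pos = mean(eta[ds$y_pos]),
      mean_eta_neg = mean(eta[!ds$y_pos])
    )
  }
  list(model = model, log = do.call(rbind, log_rows), state = state)
}
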