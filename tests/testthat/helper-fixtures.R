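# Shared fixture builders: all synthetic, generated in code at test time.

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  expr
}

# A separable imbalanced OvR task: positives carry a +shift bump on the
# first embedding column over a short token span, negatives are pure noise.
make_separable_ovr <- function(seed, Npos = 25, Nneg = 475, num = 8, n = 6,
                               shift = 1.5, label = "I") {
  set.seed(seed)
  mk <- function(pos) {
    X <- matrix(rnorm(num * n, 0, 0.5), num, n)
    if (pos) {
      r <- sample(seq_len(num - 2L), 1)
      X[r:(r + 2), 1] <- X[r:(r + 2), 1] + shift
    }
    X
  }
  x <- c(lapply(seq_len(Npos), function(i) mk(TRUE)),
         lapply(seq_len(Nneg), function(i) mk(FALSE)))
  structure(list(label = label, x = x,
                 y_pos = c(rep(TRUE, Npos), rep(FALSE, Nneg)),
                 Npos = Npos, Nneg = Nneg, N = Npos + Nneg),
            class = "ovr_dataset")
}

# A 20-sample linearly separable document set for CNN training checks.
make_separable_docs <- function(seed = 1, per_class = 10, num = 5, n = 4,
                                shift = 2) {
  set.seed(seed)
  mk <- function(cls) {
    X <- matrix(rnorm(num * n, 0, 0.3), num, n)
    X[, 1] <- X[, 1] + if (cls == 1L) shift else -shift
    list(x = X, y = cls)
  }
  c(lapply(seq_len(per_class), function(i) mk(1L)),
    lapply(seq_len(per_class), function(i) mk(0L)))
}

# Random multi-label stage sets (features are just indices).
make_random_multilabel <- function(seed, n = 50) {
  set.seed(seed)
  y <- lapply(seq_len(n), function(i) {
    k <- sample(0:3, 1, prob = c(.2, .5, .25, .05))
    if (k == 0) character(0) else sample(stage_levels, k)
  })
  multilabel_dataset(as.list(seq_len(n)), y)
}

# Exhaustive pair-count oracle for the co-occurrence matrix.
brute_cooccurrence <- function(y) {
  F_ <- matrix(0L, 4, 4, dimnames = list(stage_levels, stage_levels))
  for (a in stage_levels) for (b in stage_levels) {
    F_[a, b] <- sum(vapply(y, function(s) (a %in% s) && (b %in% s), logical(1)))
  }
  F_
}

# Brute-force AUC: fraction of correctly ordered (pos, neg) pairs, ties 1/2.
brute_auc <- function(scores, truths) {
  pos <- scores[as.logical(truths)]
  neg <- scores[!as.logical(truths)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# The paired transfer-vs-random protocol shared by the property test and the
# acceptance run: stage I is rare, II/III/IV are large, records flow through
# the full text pipeline.
run_transfer_pair <- function(seed, n_patients = 500, max_ep = 30, thr = 0.5) {
  cc <- cohort_config(n_patients = n_patients,
                      stage_proportions = c(I = .05, II = .25,
                                            III = .30, IV = .30),
                      cooccurrence_rate = 0.2, seed = seed)
  cohort <- generate_cohort(cc)
  corpus <- lapply(cohort, render_text)
  emb <- train_skipgram(corpus, n = 12, d = 2, epochs = 2, seed = seed)
  xs <- lapply(corpus, embed_document, model = emb, max_len = 24)
  S <- multilabel_dataset(xs, lapply(cohort, `[[`, "stages"))
  ovr <- ovr_split(S)
  F_ <- cooccurrence(S)
  sizes <- vapply(ovr, `[[`, integer(1), "Npos")
  src <- select_source_label(F_, "I", sizes)
  init_src <- cnn_model(12, lr = 0.1, batch_size = 16, dropout_rate = 0.25,
                        seed = seed)
  fit_src <- train_with_dynamic_sampling(
    ovr[[src]], init_src, E = 5, M = min(2L * ovr[[src]]$Npos, 200L),
    seed = seed)
  dsI <- ovr$I
  set.seed(seed + 17)
  neg_idx <- sample(which(!dsI$y_pos), dsI$Npos)
  idx <- c(which(dsI$y_pos), neg_idx)
  bal <- lapply(idx, function(j)
    list(x = dsI$x[[j]], y = as.integer(dsI$y_pos[j])))
  epochs_to <- function(init) {
    m <- init
    for (ep in seq_len(max_ep)) {
      m <- cnn_train(m, bal, epochs = 1, seed = seed * 100 + ep)
      if (cnn_loss(m, bal) <= thr) return(ep)
    }
    max_ep + 1L
  }
  rnd <- cnn_model(12, lr = 0.1, batch_size = 16, dropout_rate = 0.25,
                   seed = seed + 55)
  c(transfer = epochs_to(fit_src$model), random = epochs_to(rnd))
}

# The paired dynamic-vs-plain recall protocol (1:19 imbalance, separable).
run_imbalance_pair <- function(seed) {
  ds <- make_separable_ovr(1000 + seed)
  init <- cnn_model(6, windows = c(2, 3), lr = 0.1, batch_size = 16,
                    dropout_rate = 0.25, seed = seed)
  recall_of <- function(fit) {
    eta <- cnn_predict(fit$model, ds$x)
    sum(eta >= 0.5 & ds$y_pos) / ds$Npos
  }
  dyn <- train_with_dynamic_sampling(ds, init, E = 10, M = 2L * ds$Npos,
                                     seed = seed, dynamic = TRUE)
  pla <- train_with_dynamic_sampling(ds, init, E = 10, M = 2L * ds$Npos,
                                     seed = seed, dynamic = FALSE)
  c(dynamic = recall_of(dyn), plain = recall_of(pla))
}
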