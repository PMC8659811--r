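test_that("One-vs-Rest split partitions every sample by label membership", {
  S <- multilabel_dataset(
    as.list(1:4),
    list(c("III", "IV"), character(0), "I", c("I", "II"))
  )
  ovr <- ovr_split(S)
  # multi-label sample positive in both of its stage sets
  expect_true(ovr$III$y_pos[1])
  expect_true(ovr$IV$y_pos[1])
  # unlabeled sample negative everywhere
  expect_true(all(!vapply(ovr, function(d) d$y_pos[2], logical(1))))
  for (d in ovr) {
    expect_identical(d$Npos + d$Nneg, 4L)
    expect_identical(d$N, 4L)
  }
  expect_identical(ovr$I$Npos, 2L)
  expect_error(ovr_split(multilabel_dataset(list(), list())), "empty")
})

test_that("co-occurrence counts match the exhaustive pair-count oracle", {
  S <- multilabel_dataset(as.list(1:3),
                          list(c("III", "IV"), c("III", "IV"), "IV"))
  F_ <- cooccurrence(S)
  expect_identical(F_["III", "IV"], 2L)
  expect_identical(F_["IV", "IV"], 3L)
  # single-label data has an identically zero off-diagonal
  S1 <- multilabel_dataset(as.list(1:3), list("I", "II", "II"))
  F1 <- cooccurrence(S1)
  expect_true(all(F1[upper.tri(F1)] == 0L))
  # oracle equivalence and symmetry on random multi-label datasets
  for (seed in 1:25) {
    S_r <- make_random_multilabel(seed, n = 40)
    F_r <- cooccurrence(S_r)
    expect_identical(unclass(F_r), brute_cooccurrence(S_r$y))
    expect_identical(unclass(F_r), t(unclass(F_r)))
  }
})

test_that("source-label selection follows argmax, tie-break, and fallback", {
  F_ <- matrix(0L, 4, 4, dimnames = list(stage_levels, stage_levels))
  sizes <- c(I = 10, II = 50, III = 300, IV = 500)
  # tie on F between III and IV: larger positive count wins
  F_["I", c("II", "III", "IV")] <- c(5L, 9L, 9L)
  expect_identical(select_source_label(F_, "I", sizes), "IV")
  # unique argmax
  F_["I", c("II", "III", "IV")] <- c(5L, 9L, 2L)
  expect_identical(select_source_label(F_, "I", sizes), "III")
  # equal sizes too: fixed severity order IV > III
  F_["I", c("II", "III", "IV")] <- c(0L, 7L, 7L)
  sizes_eq <- c(I = 10, II = 50, III = 300, IV = 300)
  expect_identical(select_source_label(F_, "I", sizes_eq), "IV")
  # all off-diagonal zero: largest positive count
  F0 <- matrix(0L, 4, 4, dimnames = list(stage_levels, stage_levels))
  expect_identical(select_source_label(F0, "I", sizes), "IV")
  expect_identical(select_source_label(F0, "IV", sizes), "III")
})

test_that("initial sampling probabilities split the block between classes", {
  ds <- make_separable_ovr(1, Npos = 20, Nneg = 80)
  st <- init_sampling_probs(ds, M = 20)
  expect_equal(unique(st$probs[ds$y_pos]), 0.5)
  expect_equal(unique(st$probs[!ds$y_pos]), 0.125)
  expect_identical(st$t, 1L)
  # raw value above 1 is capped
  ds_small <- make_separable_ovr(2, Npos = 10, Nneg = 90)
  st_cap <- init_sampling_probs(ds_small, M = 100)
  expect_equal(unique(st_cap$probs[ds_small$y_pos]), 1.0)  # raw 5.0, capped
  # boundary: M = 2 Npos = 2 Nneg makes every entry exactly 1
  ds_eq <- make_separable_ovr(3, Npos = 15, Nneg = 15)
  st_eq <- init_sampling_probs(ds_eq, M = 30)
  expect_true(all(st_eq$probs == 1))
  ds_deg <- make_separable_ovr(4, Npos = 5, Nneg = 0)
  expect_error(init_sampling_probs(ds_deg, M = 4), "one-class")
})

test_that("balanced sampling includes each sample by its own coin flip", {
  ds <- make_separable_ovr(5, Npos = 10, Nneg = 40)
  st <- init_sampling_probs(ds, M = 20)
  st_all <- st; st_all$probs[] <- 1
  expect_identical(sample_balanced(ds, st_all)$idx, seq_len(ds$N))
  st_none <- st; st_none$probs[] <- 0
  expect_length(sample_balanced(ds, st_none)$idx, 0)
  draw <- with_seed_local(99, sample_balanced(ds, st))
  expect_identical(draw$is_pos, ds$y_pos[draw$idx])
})

test_that("sampled class counts concentrate around half the block size", {
  # uncapped regime: Npos = 100, Nneg = 400, M = 100 -> probs 0.5 / 0.125
  ds <- make_separable_ovr(6, Npos = 100, Nneg = 400, num = 4, n = 2)
  st <- init_sampling_probs(ds, M = 100)
  reps <- 10000
  set.seed(424)
  counts <- matrix(0, reps, 2)
  for (r in seq_len(reps)) {
    u <- runif(ds$N)
    sel <- u <= st$probs
    counts[r, ] <- c(sum(sel & ds$y_pos), sum(sel & !ds$y_pos))
  }
  # binomial oracle for the mean of each class count over `reps` draws
  var_pos <- sum(st$probs[ds$y_pos] * (1 - st$probs[ds$y_pos]))
  var_neg <- sum(st$probs[!ds$y_pos] * (1 - st$probs[!ds$y_pos]))
  expect_lt(abs(mean(counts[, 1]) - 50), 3 * sqrt(var_pos / reps))
  expect_lt(abs(mean(counts[, 2]) - 50), 3 * sqrt(var_neg / reps))
})

test_that("probability updates boost hard samples and conserve class mass", {
  ds <- make_separable_ovr(7, Npos = 40, Nneg = 160)
  st <- init_sampling_probs(ds, M = 20)   # probs 0.25 / 0.0625, uncapped
  M_half <- st$M / 2
  set.seed(31)
  for (cycle in 1:5) {
    eta <- runif(ds$N, 0.05, 0.95)
    st <- update_sampling_probs(st, eta, ds)
    expect_equal(sum(st$probs[ds$y_pos]), M_half, tolerance = 1e-9)
    expect_equal(sum(st$probs[!ds$y_pos]), M_half, tolerance = 1e-9)
  }
  expect_identical(st$t, 6L)
  expect_error(update_sampling_probs(st, rep(2, ds$N), ds), "\\[0, 1\\]")
})

test_that("the update preserves closed-form probability ratios", {
  ds <- make_separable_ovr(8, Npos = 2, Nneg = 38)
  st <- init_sampling_probs(ds, M = 2)    # positives both at 0.5
  eta <- rep(0.5, ds$N)
  eta[ds$y_pos] <- c(0.2, 0.8)
  st2 <- update_sampling_probs(st, eta, ds)
  p_pos <- st2$probs[ds$y_pos]
  # multiplicative law: P(a)/P(b) = exp(1-0.2)/exp(1-0.8) = exp(0.6),
  # untouched by the common normalization factor
  expect_equal(p_pos[1] / p_pos[2], exp(0.6), tolerance = 1e-12)
  # boundary multipliers: eta = 1 on a positive leaves it at exp(0) = 1
  # relative to the class, eta = 0 boosts by e
  eta01 <- rep(0.5, ds$N); eta01[ds$y_pos] <- c(1, 0)
  st3 <- update_sampling_probs(st, eta01, ds)
  p3 <- st3$probs[ds$y_pos]
  expect_equal(p3[2] / p3[1], exp(1), tolerance = 1e-12)
})

test_that("attention is monotone in confidence within each class", {
  ds <- make_separable_ovr(9, Npos = 5, Nneg = 45)
  st <- init_sampling_probs(ds, M = 4)
  eta <- rep(0.5, ds$N)
  eta[which(ds$y_pos)] <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  neg_idx <- which(!ds$y_pos)[1:5]
  eta[neg_idx] <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  st2 <- update_sampling_probs(st, eta, ds)
  # positives: lower eta (poorly recognized) => strictly higher probability
  expect_true(all(diff(st2$probs[which(ds$y_pos)]) < 0))
  # negatives: higher eta (hard negative) => strictly higher probability
  expect_true(all(diff(st2$probs[neg_idx]) > 0))
})

test_that("one full-probability iteration reduces to plain training", {
  ds <- make_separable_ovr(10, Npos = 10, Nneg = 10, num = 6, n = 4)
  init <- cnn_model(4, windows = c(2, 3), dropout_rate = 0, lr = 0.1,
                    batch_size = 8, seed = 12)
  # M = 2 Npos = 2 Nneg = N: every probability is 1, the block is the set
  fit <- train_with_dynamic_sampling(ds, init, E = 1, M = 20, seed = 77)
  expect_identical(fit$log$n_pos, 10L)
  expect_identical(fit$log$n_neg, 10L)
  full_block <- lapply(seq_len(ds$N), function(j)
    list(x = ds$x[[j]], y = as.integer(ds$y_pos[j])))
  expected <- cnn_train(init, full_block, epochs = 1,
                        seed = derive_seed(77, "inner") + 1L)
  expect_equal(fit$model$fc_W, expected$fc_W, tolerance = 1e-15)
  expect_equal(fit$model$kernels, expected$kernels, tolerance = 1e-15)
})

test_that("dynamic-sampling training is deterministic and fully logged", {
  ds <- make_separable_ovr(11, Npos = 15, Nneg = 85, num = 6, n = 4)
  init <- cnn_model(4, windows = c(2, 3), lr = 0.1, batch_size = 8,
                    dropout_rate = 0.25, seed = 1)
  fit1 <- train_with_dynamic_sampling(ds, init, E = 4, M = 30, seed = 5)
  fit2 <- train_with_dynamic_sampling(ds, init, E = 4, M = 30, seed = 5)
  expect_identical(fit1$model, fit2$model)
  expect_identical(fit1$log, fit2$log)
  expect_identical(names(fit1$log),
                   c("iteration", "n_pos", "n_neg", "loss",
                     "mean_eta_pos", "mean_eta_neg"))
  expect_identical(nrow(fit1$log), 4L)
  expect_identical(fit1$state$t, 5L)
})

test_that("dynamic sampling recovers minority recall lost to imbalance", {
  # 1:19 imbalance, separable structure, identical gradient budget
  res <- vapply(1:4, run_imbalance_pair, numeric(2))
  expect_gte(median(res["dynamic", ]), median(res["plain", ]))
})
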