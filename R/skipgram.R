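#' @title Skip-gram word vectors and document matrices
#' @description A small skip-gram trainer (SGD on the log-likelihood of
#'   context words given the center word) and the mapping from a token
#'   sequence to its two-dimensional word-vector matrix.
#' @name text_vectors
NULL

#' Context set of a center word
#'
#' Tokens within `d` positions before or after position `i` (the center
#' itself excluded).
#'
#' @param tokens Character vector.
#' @param i Center position (1-based).
#' @param d Window half-width.
#' @return Character vector of context tokens, in order.
#' @export
#' @examples
#' context_window(c("a", "b", "c"), 2, 1)  # "a" "c"
context_window <- function(tokens, i, d) {
  idx <- setdiff(max(1L, i - d):min(length(tokens), i + d), i)
  tokens[idx]
}

# All (center, context) index pairs of a corpus under window d, as a
# 2-column integer matrix of vocabulary indices.
skipgram_pairs <- function(corpus, vocab, d) {
  out <- vector("list", length(corpus))
  for (s in seq_along(corpus)) {
    ids <- match(corpus[[s]], vocab)
    len <- length(ids)
    if (len < 2L) next
    centers <- contexts <- integer(0)
    for (i in seq_len(len)) {
      ctx <- setdiff(max(1L, i - d):min(len, i + d), i)
      centers <- c(centers, rep.int(ids[i], length(ctx)))
      contexts <- c(contexts, ids[ctx])
    }
    out[[s]] <- cbind(centers, contexts)
  }
  do.call(rbind, out)
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Train skip-gram word embeddings
#'
#' Stochastic gradient ascent on the log-likelihood of observed context
#' words within a `d`-window of each center word. For vocabularies up to
#' `exact_softmax_limit` tokens the full-vocabulary softmax is used; above
#' it, negative sampling with `negatives` draws from the 3/4-power unigram
#' distribution.
#'
#' @param corpus List of token character vectors (non-empty).
#' @param n Embedding dimension (default 64).
#' @param d Context window half-width (default 2).
#' @param epochs Passes over all center-context pairs (default 5).
#' @param seed Integer seed; training is deterministic in it.
#' @param lr SGD learning rate.
#' @param negatives Negative samples per pair when negative sampling is used.
#' @param exact_softmax_limit Vocabulary size above which negative sampling
#'   replaces the exact softmax.
#' @return An object of class `embedding_model`: `vocabulary` (ordered token
#'   list), `n`, `d`, `vectors` (V x n matrix, one row per token), and
#'   training metadata.
#' @export
#' @examples
#' m <- train_skipgram(list(c("a", "b"), c("a", "c")), n = 4, epochs = 2, seed = 1)
#' dim(m$vectors)
train_skipgram <- function(corpus, n = 64L, d = 2L, epochs = 5L, seed = 1L,
                           lr = 0.05, negatives = 5L,
                           exact_softmax_limit = 1000L) {
  if (!length(corpus) || !any(lengths(corpus) > 0)) {
    stop("corpus must contain at least one non-empty token sequence")
  }
  stopifnot(n >= 1, d >= 1, epochs >= 1)
  vocab <- sort(unique(unlist(corpus)))
  V <- length(vocab)
  pairs <- skipgram_pairs(corpus, vocab, d)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("corpus has no center-context pairs (all sequences length < 2)")
  }
  counts <- tabulate(match(unlist(corpus), vocab), nbins = V)
  neg_prob <- counts^0.75 / sum(counts^0.75)
  use_exact <- V <= exact_softmax_limit

  with_seed(derive_seed(seed, "skipgram"), {
    W <- matrix(stats::runif(V * n, -0.5, 0.5) / n, V, n)  # input vectors
    C <- matrix(0, V, n)                                   # output vectors
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(pairs))
      for (p in ord) {
        c_id <- pairs[p, 1L]; o_id <- pairs[p, 2L]
        w <- W[c_id, ]
        if (use_exact) {
          probs <- softmax_vec(as.numeric(C %*% w))
          gs <- probs; gs[o_id] <- gs[o_id] - 1   # d(-logp)/d(scores)
          gw <- as.numeric(crossprod(C, gs))
          C <- C - lr * tcrossprod(gs, w)
          W[c_id, ] <- w - lr * gw
        } else {
          negs <- sample.int(V, negatives, replace = TRUE, prob = neg_prob)
          ids <- c(o_id, negs)
          lab <- c(1, numeric(negatives))
          sig <- 1 / (1 + exp(-as.numeric(C[ids, , drop = FALSE] %*% w)))
          gs <- sig - lab
          gw <- as.numeric(crossprod(C[ids, , drop = FALSE], gs))
          C[ids, ] <- C[ids, , drop = FALSE] - lr * tcrossprod(gs, w)
          W[c_id, ] <- w - lr * gw
        }
      }
    }
    rownames(W) <- vocab
    structure(list(
      vocabulary = vocab, n = as.integer(n), d = as.integer(d),
      vectors = W,
      meta = list(epochs = as.integer(epochs), seed = as.integer(seed),
                  lr = lr, method = if (use_exact) "softmax" else "negative_sampling")
    ), class = "embedding_model")
  })
}

#' Map a token sequence to its document matrix
#'
#' The first `min(length(tokens), max_len)` rows are the tokens' embedding
#' vectors in order; remaining rows are zero padding; longer sequences keep
#' the prefix. Out-of-vocabulary tokens map to the zero UNK vector.
#'
#' @param tokens Character vector.
#' @param model An `embedding_model`.
#' @param max_len Number of rows of the result (default 64).
#' @return A `max_len` x `n` numeric matrix of class `document_matrix`.
#' @export
#' @examples
#' m <- train_skipgram(list(c("a", "b", "c")), n = 4, epochs = 1, seed = 1)
#' dim(embed_document(c("a", "b"), m, max_len = 5))
embed_document <- function(tokens, model, max_len = 64L) {
  stopifnot(inherits(model, "embedding_model"), max_len >= 1)
  X <- matrix(0, max_len, model$n)
  keep <- utils::head(tokens, max_len)
  if (length(keep)) {
    hit <- match(keep, model$vocabulary)
    in_vocab <- which(!is.na(hit))
    if (length(in_vocab)) {
      X[in_vocab, ] <- model$vectors[hit[in_vocab], , drop = FALSE]
    }
  }
  structure(X, class = c("document_matrix", class(X)))
}

#' Write/read embeddings in word2vec text format
#'
#' First line `"<vocab_size> <dim>"`, then one `"token v1 ... vn"` line per
#' vocabulary entry.
#'
#' @param model An `embedding_model`.
#' @param path File path.
#' @return `write_embeddings()` returns `path` invisibly; `read_embeddings()`
#'   an `embedding_model` (window/metadata restored from a `#meta` trailer
#'   line if present).
#' @export
write_embeddings <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(model$vocabulary), model$n), con)
  for (i in seq_along(model$vocabulary)) {
    writeLines(paste(model$vocabulary[i],
                     paste(sprintf("%.17g", model$vectors[i, ]),
                           collapse = " ")), con)
  }
  writeLines(sprintf("#meta d=%d epochs=%d seed=%d", model$d,
                     model$meta$epochs, model$meta$seed), con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  V <- hdr[1]; n <- hdr[2]
  vocab <- character(V)
  W <- matrix(0, V, n)
  for (i in seq_len(V)) {
    parts <- strsplit(trimws(lines[i + 1L]), " +")[[1]]
    vocab[i] <- parts[1]
    W[i, ] <- as.numeric(parts[-1])
  }
  rownames(W) <- vocab
  d <- 2L; epochs <- NA_integer_; seed <- NA_integer_
  meta_line <- grep("^#meta ", lines, value = TRUE)
  if (length(meta_line)) {
    kv <- strsplit(sub("^#meta ", "", meta_line[1]), " ")[[1]]
    vals <- stats::setNames(
      as.integer(sub(".*=", "", kv)), sub("=.*", "", kv))
    d <- vals[["d"]]; epochs <- vals[["epochs"]]; seed <- vals[["seed"]]
  }
  structure(list(vocabulary = vocab, n = n, d = d, vectors = W,
                 meta = list(epochs = epochs, seed = seed, lr = NA_real_,
                             method = "loaded")),
            class = "embedding_model")
}
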