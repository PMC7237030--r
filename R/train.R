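## embedding training: config, elementary steps, the four trainers, S3 methods

#' Training configuration for concept embeddings
#'
#' Defaults follow the hyperparameter set conventional for biomedical concept
#' embeddings trained on PubMed-scale corpora: 200-dimensional vectors,
#' window 20, 5 negative samples, down-sampling threshold 0.001, minimum
#' occurrence 5, learning rate 0.025, 10 epochs, and character n-grams of
#' length 2-3 for the fastText variant. `negative` and `subsample_threshold`
#' apply to the word2vec-family objectives only; the n-gram bounds apply to
#' fastText only; the remaining parameters apply to all methods.
#'
#' @param dimension vector dimension (> 0).
#' @param window maximum context window; the effective window per center is
#'   drawn uniformly from `1..window` and never crosses a sentence boundary.
#' @param negative number of negative samples per positive pair.
#' @param subsample_threshold frequency threshold for down-sampling, in (0, 1].
#' @param min_count minimum token occurrence kept in the vocabulary.
#' @param learning_rate initial learning rate (linearly decayed for the
#'   window-based methods; AdaGrad-scaled for GloVe).
#' @param epochs number of training passes.
#' @param ngram_min,ngram_max character n-gram length bounds (fastText).
#' @param seed integer seed; fixed seed + single worker is bit-reproducible.
#' @param glove_xmax,glove_alpha GloVe weighting-function cap and exponent.
#' @return a `training_config` list.
#' @export
training_config <- function(dimension = 200L, window = 20L, negative = 5L,
                            subsample_threshold = 0.001, min_count = 5L,
                            learning_rate = 0.025, epochs = 10L,
                            ngram_min = 2L, ngram_max = 3L, seed = 1L,
                            glove_xmax = 10, glove_alpha = 0.75) {
  stopifnot(dimension > 0, window >= 1, negative >= 0,
            subsample_threshold > 0, subsample_threshold <= 1,
            min_count >= 1, learning_rate > 0, epochs >= 1,
            ngram_min <= ngram_max, glove_xmax > 0)
  structure(list(dimension = as.integer(dimension), window = as.integer(window),
                 negative = as.integer(negative),
                 subsample_threshold = subsample_threshold,
                 min_count = as.integer(min_count),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 ngram_min = as.integer(ngram_min),
                 ngram_max = as.integer(ngram_max), seed = as.integer(seed),
                 glove_xmax = glove_xmax, glove_alpha = glove_alpha),
            class = "training_config")
}

#' One negative-sampling update
#'
#' The elementary skip-gram / cbow step with negative sampling. With input
#' representation `u` (`center_rep`), positive output vector `v+`
#' (`context_vec`) and negative output vectors `v-`, the loss is
#' `-log sigma(u . v+) - sum log sigma(-u . v-)`. Returned gradients are the
#' exact analytic partial derivatives; updates are the gradients scaled by
#' `-lr` (gradient descent). In cbow mode `center_rep` is the mean of
#' `n_context` context-word input vectors and the input-side update is
#' divided equally among them (`update_per_context`).
#'
#' @param center_rep input-side representation (center word in skip-gram,
#'   averaged context in cbow).
#' @param context_vec output vector of the predicted token.
#' @param negative_vecs matrix of negative output vectors (rows), or `NULL`.
#' @param lr learning rate.
#' @param mode `"skipgram"` or `"cbow"`.
#' @param n_context number of context words averaged into `center_rep`
#'   (cbow mode).
#' @return list with `loss`, gradients (`grad_input`, `grad_context`,
#'   `grad_negatives`) and lr-scaled updates (`update_input`,
#'   `update_per_context`, `update_context`, `update_negatives`).
#' @export
sgns_step <- function(center_rep, context_vec, negative_vecs = NULL,
                      lr = 0.025, mode = c("skipgram", "cbow"),
                      n_context = 1L) {
  mode <- match.arg(mode)
  if (length(center_rep) != length(context_vec))
    stop_cv("dimension mismatch between center and context vectors")
  if (!is.null(negative_vecs)) {
    negative_vecs <- rbind(negative_vecs)
    if (ncol(negative_vecs) != length(center_rep))
      stop_cv("dimension mismatch in negative vectors")
  }
  p_pos <- 1 / (1 + exp(-sum(center_rep * context_vec)))
  loss <- -log(p_pos)
  grad_input <- (p_pos - 1) * context_vec
  grad_context <- (p_pos - 1) * center_rep
  grad_negatives <- NULL
  if (!is.null(negative_vecs) && nrow(negative_vecs)) {
    dots <- as.numeric(negative_vecs %*% center_rep)
    p_neg <- 1 / (1 + exp(-dots))
    loss <- loss - sum(log(1 - p_neg))
    grad_input <- grad_input + as.numeric(crossprod(negative_vecs, p_neg))
    grad_negatives <- p_neg %o% center_rep
  }
  per_ctx <- if (mode == "cbow") grad_input / n_context else grad_input
  list(loss = loss,
       grad_input = grad_input,
       grad_context = grad_context,
       grad_negatives = grad_negatives,
       update_input = -lr * grad_input,
       update_per_context = -lr * per_ctx,
       update_context = -lr * grad_context,
       update_negatives = if (is.null(grad_negatives)) NULL else -lr * grad_negatives)
}

#' GloVe weighting function
#'
#' `f(x) = (x / xmax)^alpha` for `x < xmax`, else 1.
#' @param x co-occurrence count(s), positive.
#' @param xmax cap (default 10).
#' @param alpha exponent (default 0.75).
#' @return weights in (0, 1].
#' @export
glove_weight <- function(x, xmax = 10, alpha = 0.75) {
  ifelse(x < xmax, (x / xmax)^alpha, 1)
}

#' One GloVe weighted-least-squares term
#'
#' For a non-zero co-occurrence `x_ij`, the loss term is
#' `f(x_ij) (w_i . w~_j + b_i + b~_j - log x_ij)^2`. Returned gradients are
#' exact analytic partials; when AdaGrad accumulators are supplied the
#' corresponding scaled updates are also returned.
#'
#' @param x_ij co-occurrence weight (> 0; zero entries are never evaluated).
#' @param w_i,w_j word and context parameter vectors.
#' @param b_i,b_j word and context biases.
#' @param lr learning rate (for the AdaGrad-scaled updates).
#' @param xmax,alpha weighting-function parameters.
#' @param hist optional list of AdaGrad accumulators
#'   (`w_i`, `w_j`, `b_i`, `b_j`), squared-gradient sums initialized at 1.
#' @return list with `loss`, `grad_w_i`, `grad_w_j`, `grad_b_i`, `grad_b_j`
#'   and, given `hist`, the AdaGrad-scaled `update_*` entries plus the
#'   advanced accumulators.
#' @export
glove_step <- function(x_ij, w_i, w_j, b_i, b_j, lr = 0.025, xmax = 10,
                       alpha = 0.75, hist = NULL) {
  if (x_ij <= 0) stop_cv("glove_step is only defined for positive co-occurrence counts")
  f <- glove_weight(x_ij, xmax, alpha)
  diff <- sum(w_i * w_j) + b_i + b_j - log(x_ij)
  g <- 2 * f * diff
  out <- list(loss = f * diff^2,
              grad_w_i = g * w_j, grad_w_j = g * w_i,
              grad_b_i = g, grad_b_j = g)
  if (!is.null(hist)) {
    out$update_w_i <- -lr * out$grad_w_i / sqrt(hist$w_i)
    out$update_w_j <- -lr * out$grad_w_j / sqrt(hist$w_j)
    out$update_b_i <- -lr * out$grad_b_i / sqrt(hist$b_i)
    out$update_b_j <- -lr * out$grad_b_j / sqrt(hist$b_j)
    out$hist <- list(w_i = hist$w_i + out$grad_w_i^2,
                     w_j = hist$w_j + out$grad_w_j^2,
                     b_i = hist$b_i + out$grad_b_i^2,
                     b_j = hist$b_j + out$grad_b_j^2)
  }
  out
}

#' Distance-weighted global co-occurrence table
#'
#' For every in-sentence ordered token pair at distance `d <= window`, adds
#' weight `1/d` to both the `(i, j)` and `(j, i)` cells, yielding a symmetric
#' sparse matrix. Windows never cross sentence boundaries.
#'
#' @param corpus a `concept_corpus` or list of character-vector sentences.
#' @param vocab a `concept_vocab`; tokens outside it are dropped.
#' @param window maximum co-occurrence distance.
#' @return a symmetric `dgCMatrix` with the vocabulary as dimnames.
#' @export
build_cooccurrence <- function(corpus, vocab, window = 20L) {
  sentences <- index_sentences(corpus, vocab)
  V <- nrow(vocab)
  if (!length(sentences) || V == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(V, V),
                                dimnames = list(vocab$token, vocab$token)))
  tr <- cpp_build_cooccurrence(sentences, V, as.integer(window))
  Matrix::sparseMatrix(i = tr$i + 1L, j = tr$j + 1L, x = tr$x, dims = c(V, V),
                       dimnames = list(vocab$token, vocab$token))
}

## map sentences to 0-based vocabulary indices, dropping filtered tokens and
## resulting empty sentences
index_sentences <- function(corpus, vocab) {
  sentences <- if (inherits(corpus, "concept_corpus")) corpus$sentences else corpus
  idx <- lapply(sentences, function(s) {
    m <- match(s, vocab$token)
    as.integer(m[!is.na(m)] - 1L)
  })
  idx[lengths(idx) > 0L]
}

#' Train concept embeddings
#'
#' Fits one of four embedding models on a tokenized concept corpus: `cbow`
#' and `skipgram` (word2vec objectives with negative sampling), `glove`
#' (AdaGrad factorization of the distance-weighted global co-occurrence
#' matrix, final vectors `w + w_context`), or `fasttext` (skip-gram with
#' character n-gram subwords, where the n-gram representation is disabled
#' for concept tokens so that each normalized bio-concept is learned as an
#' atomic unit). Training is single-threaded and bit-reproducible for a
#' fixed seed.
#'
#' @param corpus a `concept_corpus` (see [tokenize_corpus()]) or a list of
#'   character-vector sentences.
#' @param method one of `"cbow"`, `"skipgram"`, `"glove"`, `"fasttext"`.
#' @param config a [training_config()].
#' @return an object of class `concept_embeddings` with components `vectors`
#'   (vocabulary-by-dimension matrix), `vocab`, `method`, `config`,
#'   `epoch_loss`, and for fastText additionally `ngram_vectors` and
#'   `ngram_index` (per-token n-gram rows).
#' @seealso [predict.concept_embeddings()], [token_representation()],
#'   [save_embeddings()]
#' @export
train_embeddings <- function(corpus,
                             method = c("cbow", "skipgram", "glove", "fasttext"),
                             config = training_config()) {
  method <- match.arg(method)
  vocab <- build_vocab(corpus, config$min_count)
  if (!nrow(vocab))
    stop_cv("vocabulary is empty after min_count filtering; nothing to train on")
  sentences <- index_sentences(corpus, vocab)
  V <- nrow(vocab)

  res <- list()
  if (method == "glove") {
    tr <- cpp_build_cooccurrence(sentences, V, config$window)
    fit <- cpp_train_glove(tr$i, tr$j, tr$x, V, config$dimension,
                           config$glove_xmax, config$glove_alpha,
                           config$learning_rate, config$epochs,
                           as.double(config$seed))
    vectors <- fit$w + fit$w_context
    res$epoch_loss <- as.numeric(fit$epoch_loss)
  } else {
    use_ngrams <- method == "fasttext"
    ngram_index <- vector("list", V)
    ngram_dict <- character(0)
    if (use_ngrams) {
      grams <- lapply(seq_len(V), function(i)
        subword_ngrams(vocab$token[i], vocab$is_concept[i],
                       config$ngram_min, config$ngram_max))
      ngram_dict <- unique(unlist(grams, use.names = FALSE))
      ngram_index <- lapply(grams, function(g)
        as.integer(match(g, ngram_dict) - 1L))
    }
    fit <- cpp_train_w2v(sentences, as.numeric(vocab$count), config$dimension,
                         config$window, config$negative,
                         config$subsample_threshold, config$learning_rate,
                         config$epochs, as.double(config$seed),
                         method == "cbow", use_ngrams, ngram_index,
                         length(ngram_dict))
    vectors <- fit$vectors
    res$epoch_loss <- as.numeric(fit$epoch_loss)
    if (use_ngrams) {
      res$ngram_vectors <- fit$ngram_vectors
      rownames(res$ngram_vectors) <- ngram_dict
      res$ngram_index <- lapply(ngram_index, `+`, 1L)
    }
  }
  rownames(vectors) <- vocab$token
  structure(c(list(vectors = vectors, vocab = vocab, method = method,
                   config = config, call = match.call()),
              res),
            class = "concept_embeddings")
}

#' Composed representation of tokens under a trained model
#'
#' For cbow, skip-gram and GloVe this is the stored vector. For fastText an
#' ordinary word is represented as its word vector plus the sum of its
#' character n-gram vectors, while a concept token is exactly its stored
#' word vector (no subword contribution). Out-of-vocabulary ordinary words
#' back off to the sum of their known n-gram vectors under fastText; concept
#' tokens never back off.
#'
#' @param model a `concept_embeddings` object (or plain matrix of vectors).
#' @param tokens character vector of tokens.
#' @return matrix with one row per token.
#' @export
token_representation <- function(model, tokens) {
  vecs <- embedding_vectors(model, compose = FALSE)
  out <- matrix(NA_real_, length(tokens), ncol(vecs),
                dimnames = list(tokens, NULL))
  in_vocab <- tokens %in% rownames(vecs)
  out[in_vocab, ] <- vecs[tokens[in_vocab], , drop = FALSE]
  fasttext <- inherits(model, "concept_embeddings") &&
    identical(model$method, "fasttext")
  if (fasttext) {
    for (k in which(in_vocab)) {
      i <- match(tokens[k], model$vocab$token)
      gi <- model$ngram_index[[i]]
      if (length(gi))
        out[k, ] <- out[k, ] + colSums(model$ngram_vectors[gi, , drop = FALSE])
    }
    for (k in which(!in_vocab)) {
      if (is_concept_token(tokens[k]))
        stop_cv("concept token %s is out of vocabulary and never backs off to n-grams",
                dQuote(tokens[k]))
      g <- subword_ngrams(tokens[k], FALSE,
                          model$config$ngram_min, model$config$ngram_max)
      g <- intersect(g, rownames(model$ngram_vectors))
      if (!length(g))
        stop_cv("token %s is out of vocabulary and shares no known n-grams",
                dQuote(tokens[k]))
      out[k, ] <- colSums(model$ngram_vectors[g, , drop = FALSE])
    }
  } else if (any(!in_vocab)) {
    stop_cv("token(s) out of vocabulary: %s",
            paste(dQuote(tokens[!in_vocab]), collapse = ", "))
  }
  out
}

## vectors usable by downstream evaluators; accepts a plain named matrix too
embedding_vectors <- function(x, compose = TRUE) {
  if (is.matrix(x)) return(x)
  if (!inherits(x, "concept_embeddings"))
    stop_cv("expected a concept_embeddings object or a named matrix")
  if (compose && identical(x$method, "fasttext"))
    return(token_representation_all(x))
  x$vectors
}

token_representation_all <- function(model) {
  out <- model$vectors
  for (i in seq_len(nrow(out))) {
    gi <- model$ngram_index[[i]]
    if (length(gi))
      out[i, ] <- out[i, ] + colSums(model$ngram_vectors[gi, , drop = FALSE])
  }
  out
}

#' @method as.matrix concept_embeddings
#' @export
as.matrix.concept_embeddings <- function(x, compose = TRUE, ...) {
  embedding_vectors(x, compose = compose)
}

#' @method print concept_embeddings
#' @export
print.concept_embeddings <- function(x, ...) {
  cat(sprintf("Concept embeddings (%s): %d tokens x %d dimensions\n",
              x$method, nrow(x$vectors), ncol(x$vectors)))
  cat(sprintf("  concept tokens: %d; ordinary words: %d\n",
              sum(x$vocab$is_concept), sum(!x$vocab$is_concept)))
  if (!is.null(x$epoch_loss))
    cat(sprintf("  final mean epoch loss: %.4f (%d epochs)\n",
                tail(x$epoch_loss, 1), length(x$epoch_loss)))
  invisible(x)
}

#' @method summary concept_embeddings
#' @export
summary.concept_embeddings <- function(object, ...) {
  v <- embedding_vectors(object)
  norms <- sqrt(rowSums(v^2))
  out <- list(method = object$method,
              n_tokens = nrow(v), dimension = ncol(v),
              n_concepts = sum(object$vocab$is_concept),
              epoch_loss = object$epoch_loss,
              norm_summary = summary(norms))
  class(out) <- "summary.concept_embeddings"
  out
}

#' @method print summary.concept_embeddings
#' @export
print.summary.concept_embeddings <- function(x, ...) {
  cat(sprintf("Concept embeddings (%s)\n", x$method))
  cat(sprintf("  vocabulary: %d tokens (%d concepts), dimension %d\n",
              x$n_tokens, x$n_concepts, x$dimension))
  if (!is.null(x$epoch_loss)) {
    cat("  mean loss by epoch:\n")
    print(round(x$epoch_loss, 4))
  }
  cat("  vector norms:\n")
  print(x$norm_summary)
  invisible(x)
}

#' @export
predict.concept_embeddings <- function(object, newdata, ...) {
  token_representation(object, newdata)
}

#' Two-dimensional projection of concept vectors
#'
#' Plots the first two principal components of the (composed) vectors,
#' highlighting concept tokens.
#' @param x a `concept_embeddings` object.
#' @param concepts_only plot concept tokens only (default `TRUE`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.concept_embeddings <- function(x, concepts_only = TRUE, ...) {
  v <- embedding_vectors(x)
  if (concepts_only && any(x$vocab$is_concept))
    v <- v[x$vocab$is_concept, , drop = FALSE]
  pc <- prcomp(v, rank. = 2)
  graphics::plot(pc$x[, 1], pc$x[, 2], xlab = "PC1", ylab = "PC2",
                 main = sprintf("concept embeddings (%s)", x$method), ...)
  invisible(pc)
}

#' Write embeddings in word2vec text format
#'
#' Header line `"V D"`, then one line per token: the token followed by `D`
#' values. For fastText the composed representations are written, so concept
#' tokens serialize as their stored word vectors.
#'
#' @param model a `concept_embeddings` object or named matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_embeddings <- function(model, path) {
  v <- embedding_vectors(model)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(v), ncol(v)), con)
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(rownames(v)[i], paste(formatC(v[i, ], format = "g", digits = 9),
                                collapse = " ")), "")
  writeLines(body, con)
  invisible(path)
}

#' Read embeddings in word2vec text format
#'
#' @param path file path.
#' @return a named matrix (tokens as rownames) of class
#'   `c("loaded_embeddings", "matrix", ...)`.
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop_cv("empty embedding file %s", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2L) stop_cv("malformed word2vec header: %s", dQuote(lines[1]))
  V <- suppressWarnings(as.integer(hdr[1]))
  D <- suppressWarnings(as.integer(hdr[2]))
  if (is.na(V) || is.na(D)) stop_cv("non-numeric word2vec header: %s", dQuote(lines[1]))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != V)
    stop_cv("word2vec format error: header declares %d rows, file has %d", V,
            length(body))
  parts <- strsplit(body, "\\s+")
  tokens <- vapply(parts, `[`, "", 1L)
  mat <- matrix(NA_real_, V, D, dimnames = list(tokens, NULL))
  for (i in seq_len(V)) {
    vals <- suppressWarnings(as.numeric(parts[[i]][-1L]))
    if (length(vals) != D || anyNA(vals))
      stop_cv("word2vec format error at row %d: expected %d numeric values", i, D)
    mat[i, ] <- vals
  }
  mat
}
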