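## vocabulary construction, frequency subsampling, negative sampling, subwords

#' Build a frequency-filtered vocabulary
#'
#' Counts tokens over a corpus and drops those occurring fewer than
#' `min_count` times. Order is deterministic: descending count, ties broken
#' lexicographically. Concept flags are propagated from the corpus (a token
#' annotated as a concept anywhere is flagged).
#'
#' @param corpus a `concept_corpus` (see [tokenize_corpus()]), or a plain
#'   list of character-vector sentences.
#' @param min_count minimum occurrence count to retain a token (default 5).
#' @return a `concept_vocab`: data frame with columns `token`, `count`,
#'   `is_concept`, and attribute `total_count` (sum of retained counts).
#' @export
build_vocab <- function(corpus, min_count = 5L) {
  sentences <- if (inherits(corpus, "concept_corpus")) corpus$sentences else corpus
  toks <- unlist(sentences, use.names = FALSE)
  if (!length(toks)) {
    v <- data.frame(token = character(0), count = integer(0),
                    is_concept = logical(0), stringsAsFactors = FALSE)
    attr(v, "total_count") <- 0L
    class(v) <- c("concept_vocab", "data.frame")
    return(v)
  }
  tab <- table(toks)
  token <- names(tab)
  count <- as.integer(tab)
  if (inherits(corpus, "concept_corpus")) {
    fl <- unlist(corpus$concept_flags, use.names = FALSE)
    concept_set <- unique(toks[fl])
    is_concept <- token %in% concept_set
  } else {
    is_concept <- is_concept_token(token)
  }
  keep <- count >= min_count
  v <- data.frame(token = token[keep], count = count[keep],
                  is_concept = is_concept[keep], stringsAsFactors = FALSE)
  v <- v[order(-v$count, v$token, method = "radix"), , drop = FALSE]
  rownames(v) <- NULL
  attr(v, "total_count") <- sum(v$count)
  class(v) <- c("concept_vocab", "data.frame")
  v
}

#' Subsampling keep-probability for frequent tokens
#'
#' Classic down-sampling rule: a token whose corpus frequency fraction is `f`
#' is kept with probability `min(1, sqrt(t / f))` for threshold `t`. Monotone
#' non-increasing in `f`; tokens rarer than the threshold are always kept.
#'
#' @param freq_fraction token count divided by total corpus count, in (0, 1].
#' @param threshold down-sampling threshold (default 0.001). Vectorized over
#'   `freq_fraction`.
#' @return keep probabilities in (0, 1].
#' @export
keep_probability <- function(freq_fraction, threshold = 0.001) {
  if (any(freq_fraction <= 0) || any(freq_fraction > 1))
    stop_cv("freq_fraction must lie in (0, 1]")
  if (threshold <= 0) stop_cv("threshold must be positive")
  pmin(1, sqrt(threshold / freq_fraction))
}

#' Unigram-power negative-sampling distribution
#'
#' Noise distribution for negative sampling: probability proportional to
#' `count^power` (default power 0.75, the convention of the word2vec family).
#'
#' @param vocab a `concept_vocab`.
#' @param power exponent applied to counts.
#' @param seed integer seed making draws reproducible.
#' @return a `negative_sampler`: list with `tokens`, `prob` (sums to 1) and
#'   `draw(n)`, a function returning `n` token indices (1-based into the
#'   vocabulary order).
#' @export
negative_sampler <- function(vocab, power = 0.75, seed = 1L) {
  if (!nrow(vocab)) stop_cv("cannot build a negative sampler on an empty vocabulary")
  w <- vocab$count^power
  prob <- w / sum(w)
  rng_state <- new.env(parent = emptyenv())
  with_seed(seed, assign("state", get(".Random.seed", globalenv()), rng_state))
  draw <- function(n) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", rng_state$state, globalenv())
    out <- sample.int(length(prob), n, replace = TRUE, prob = prob)
    assign("state", get(".Random.seed", globalenv()), rng_state)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    out
  }
  structure(list(tokens = vocab$token, prob = prob, draw = draw),
            class = "negative_sampler")
}

#' Character n-grams of a token, with concept masking
#'
#' For ordinary words, returns the character n-grams of the boundary-padded
#' token `<token>` for lengths `nmin..nmax`, excluding the full padded token
#' itself (whose role is played by the separate word vector). For concept
#' tokens the set is empty: a normalized bio-concept is an atomic unit and
#' receives no subword representation.
#'
#' @param token a single token.
#' @param is_concept is this a concept token (masks all n-grams)?
#' @param nmin,nmax minimum / maximum n-gram length (defaults 2 and 3).
#' @return character vector of distinct n-grams (possibly empty).
#' @export
subword_ngrams <- function(token, is_concept = is_concept_token(token),
                           nmin = 2L, nmax = 3L) {
  if (nmin > nmax) stop_cv("nmin must not exceed nmax")
  if (isTRUE(is_concept)) return(character(0))
  padded <- paste0("<", token, ">")
  L <- nchar(padded)
  out <- character(0)
  for (n in seq.int(nmin, nmax)) {
    if (n > L) next
    starts <- seq_len(L - n + 1L)
    out <- c(out, substring(padded, starts, starts + n - 1L))
  }
  unique(setdiff(out, padded))
}
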