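# shared fixtures; heavyweight artifacts (default synthetic corpus, trained
# models) are built once per session and memoized

.fixture_cache <- new.env(parent = emptyenv())

default_synth <- function() {
  if (is.null(.fixture_cache$corpus)) {
    cfg <- synth_config() # 8 clusters x 5 concepts, 2000 docs, seed 7
    .fixture_cache$config <- cfg
    .fixture_cache$lines <- generate_corpus(cfg)
    .fixture_cache$docs <- parse_pubtator(.fixture_cache$lines)
    .fixture_cache$corpus <- tokenize_corpus(.fixture_cache$docs)
    .fixture_cache$info <- synth_concepts(cfg)
  }
  list(config = .fixture_cache$config, lines = .fixture_cache$lines,
       docs = .fixture_cache$docs, corpus = .fixture_cache$corpus,
       info = .fixture_cache$info)
}

trained_model <- function(method, seed = 11L) {
  key <- paste0("model_", method, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    fx <- default_synth()
    .fixture_cache[[key]] <-
      train_embeddings(fx$corpus, method, training_config(seed = seed))
  }
  .fixture_cache[[key]]
}

# mean within- and cross-cluster cosine of the planted concepts
cluster_cosine_margin <- function(embedding, info) {
  v <- as.matrix(embedding)[info$token, , drop = FALSE]
  cs <- tcrossprod(v / sqrt(rowSums(v^2)))
  same <- outer(info$cluster, info$cluster, "==")
  ut <- upper.tri(cs)
  c(within = mean(cs[ut & same]), cross = mean(cs[ut & !same]))
}

# central-difference numerical gradient
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

rel_err <- function(analytic, numeric) {
  denom <- max(sqrt(sum(analytic^2)), 1e-8)
  sqrt(sum((analytic - numeric)^2)) / denom
}

# one-document PubTator block used across parser tests
tiny_block <- function() {
  c("1000|t|MLN4924 is studied.",
    "1000|a|It inhibits growth.",
    "1000\t0\t7\tMLN4924\tChemical\tMESH:C539933",
    "")
}

make_ann <- function(start, end, mention, type = "Gene", id = "1") {
  data.frame(start = as.integer(start), end = as.integer(end),
             mention = mention, type = type,
             concept_id = id, stringsAsFactors = FALSE)
}
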