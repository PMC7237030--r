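## PPI prediction harness: balanced pair datasets from scored tables and a
## two-hidden-layer feed-forward classifier over concatenated concept vectors

#' Read a scored protein-pair table
#'
#' STRING `protein.links`-style dialect: whitespace- or tab-separated with a
#' header naming at least two protein columns and score channels. Columns
#' named `combined_score`/`combined` and `experimental` are recognized as
#' the two score channels.
#'
#' @param path file path.
#' @return data frame with columns `protein_a`, `protein_b`, `combined`,
#'   `experimental`.
#' @export
read_string_links <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  pa <- which(nm %in% c("protein1", "protein_a", "proteina"))[1]
  pb <- which(nm %in% c("protein2", "protein_b", "proteinb"))[1]
  co <- which(nm %in% c("combined_score", "combined"))[1]
  ex <- which(nm %in% c("experimental", "experiments", "experimental_score"))[1]
  if (is.na(pa) || is.na(pb))
    stop_cv("pair table must name two protein columns (protein1/protein2)")
  data.frame(protein_a = as.character(df[[pa]]),
             protein_b = as.character(df[[pb]]),
             combined = if (!is.na(co)) as.numeric(df[[co]]) else NA_real_,
             experimental = if (!is.na(ex)) as.numeric(df[[ex]]) else NA_real_,
             stringsAsFactors = FALSE)
}

## accept both the reader's schema (protein_a/combined) and the STRING-style
## header (protein1/combined_score)
as_pair_table <- function(table) {
  nm <- tolower(names(table))
  ren <- c(protein1 = "protein_a", protein2 = "protein_b",
           combined_score = "combined", experiments = "experimental",
           experimental_score = "experimental")
  hit <- nm %in% names(ren)
  names(table)[hit] <- ren[nm[hit]]
  for (col in c("protein_a", "protein_b"))
    if (is.null(table[[col]]))
      stop_cv("pair table lacks a %s column", col)
  if (is.null(table$combined)) table$combined <- NA_real_
  if (is.null(table$experimental)) table$experimental <- NA_real_
  table
}

#' Clean a scored pair table
#'
#' Drops self-pairs and de-duplicates unordered pairs, keeping the maximum
#' score per channel.
#'
#' @param table data frame as returned by [read_string_links()].
#' @return cleaned data frame with `protein_a < protein_b` per row.
#' @export
clean_pair_table <- function(table) {
  table <- as_pair_table(table)
  a <- pmin(table$protein_a, table$protein_b)
  b <- pmax(table$protein_a, table$protein_b)
  keep <- a != b
  key <- paste(a, b, sep = "\t")[keep]
  df <- data.frame(protein_a = a[keep], protein_b = b[keep],
                   combined = table$combined[keep],
                   experimental = table$experimental[keep],
                   stringsAsFactors = FALSE)
  if (anyDuplicated(key)) {
    agg_max <- function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    combined <- tapply(df$combined, key, agg_max)
    experimental <- tapply(df$experimental, key, agg_max)
    u <- !duplicated(key)
    df <- df[u, , drop = FALSE]
    k <- paste(df$protein_a, df$protein_b, sep = "\t")
    df$combined <- as.numeric(combined[k])
    df$experimental <- as.numeric(experimental[k])
  }
  rownames(df) <- NULL
  df
}

#' Build a balanced, split PPI dataset
#'
#' Positives are the table pairs with both proteins in the embedding
#' vocabulary that pass the mode's filter: `"combined"` keeps any pair with
#' a positive combined score, `"experimental_700"` keeps pairs whose
#' experimental score is strictly greater than 700. An equal number of
#' negatives is drawn as a seeded uniform sample of unordered in-vocabulary
#' pairs absent from the positive set. Instances are split, stratified by
#' label, into 63% train / 7% validation / 30% test (the validation carve
#' being 10% of the 70% training portion).
#'
#' @param table cleaned pair table (see [clean_pair_table()]).
#' @param mode `"combined"` or `"experimental_700"`.
#' @param vocabulary character vector of proteins with embedding vectors.
#' @param seed integer seed for the negative sample and the split.
#' @return a `ppi_dataset`: data frame (`protein_a`, `protein_b`, `label`
#'   0/1, `split`) with attributes `mode` and `seed`.
#' @export
build_ppi_dataset <- function(table, mode = c("combined", "experimental_700"),
                              vocabulary, seed = 1L) {
  mode <- match.arg(mode)
  table <- as_pair_table(table)
  vocabulary <- unique(vocabulary)
  in_vocab <- table$protein_a %in% vocabulary & table$protein_b %in% vocabulary
  pass <- if (mode == "combined") !is.na(table$combined) & table$combined > 0
          else !is.na(table$experimental) & table$experimental > 700
  pos <- table[in_vocab & pass, c("protein_a", "protein_b"), drop = FALSE]
  n_pos <- nrow(pos)
  if (!n_pos) stop_cv("no positive pairs under mode %s", dQuote(mode))
  pos_keys <- paste(pos$protein_a, pos$protein_b, sep = "\t")

  n_prot <- length(vocabulary)
  n_candidates <- choose(n_prot, 2) - n_pos
  if (n_candidates < n_pos)
    stop_cv("cannot draw %d negatives: only %d non-positive pairs exist",
            n_pos, n_candidates)

  neg <- with_seed(seed + 1L, {
    keys <- character(0)
    while (length(keys) < n_pos) {
      m <- 2L * (n_pos - length(keys)) + 16L
      a <- vocabulary[sample.int(n_prot, m, replace = TRUE)]
      b <- vocabulary[sample.int(n_prot, m, replace = TRUE)]
      lo <- pmin(a, b); hi <- pmax(a, b)
      k <- paste(lo, hi, sep = "\t")
      ok <- lo != hi & !(k %in% pos_keys) & !(k %in% keys)
      keys <- c(keys, unique(k[ok]))
    }
    keys <- keys[seq_len(n_pos)]
    parts <- strsplit(keys, "\t", fixed = TRUE)
    data.frame(protein_a = vapply(parts, `[`, "", 1L),
               protein_b = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  })

  df <- rbind(cbind(pos, label = 1L), cbind(neg, label = 0L))
  rownames(df) <- NULL
  df$split <- NA_character_
  with_seed(seed + 2L, {
    for (lab in c(0L, 1L)) {
      idx <- sample(which(df$label == lab))
      n <- length(idx)
      n_test <- round(0.30 * n)
      n_val <- round(0.10 * (n - n_test))
      df$split[idx[seq_len(n_test)]] <- "test"
      if (n_val > 0)
        df$split[idx[n_test + seq_len(n_val)]] <- "validation"
      if (n_test + n_val < n)
        df$split[idx[(n_test + n_val + 1):n]] <- "train"
    }
  })
  structure(df, mode = mode, seed = seed,
            class = c("ppi_dataset", "data.frame"))
}

#' Feature vector for a protein pair
#'
#' Concatenation of the two concept vectors, `[v(p1); v(p2)]` (length twice
#' the embedding dimension). Symmetric compositions are available for
#' sensitivity checks.
#'
#' @param p1,p2 protein concept ids (vectorized; equal length).
#' @param embedding embedding covering both proteins.
#' @param composition `"concat"` (default), `"sum"` or `"absdiff"`.
#' @return feature matrix, one row per pair.
#' @export
featurize_pair <- function(p1, p2, embedding,
                           composition = c("concat", "sum", "absdiff")) {
  composition <- match.arg(composition)
  vecs <- embedding_vectors(embedding)
  missing <- setdiff(unique(c(p1, p2)), rownames(vecs))
  if (length(missing))
    stop_cv("missing vector(s) for protein(s): %s",
            paste(head(missing, 5), collapse = ", "))
  v1 <- vecs[p1, , drop = FALSE]
  v2 <- vecs[p2, , drop = FALSE]
  switch(composition,
         concat = cbind(v1, v2),
         sum = v1 + v2,
         absdiff = abs(v1 - v2))
}

#' Train the PPI pair classifier
#'
#' A feed-forward artificial neural network with two hidden layers over the
#' concatenated pair features: input `2d`, ReLU hidden layers, one sigmoid
#' output. The validation split selects the best epoch (by validation AUC);
#' runs are seeded and single-threaded, hence reproducible.
#'
#' @param dataset a `ppi_dataset` from [build_ppi_dataset()].
#' @param embedding embedding covering all dataset proteins.
#' @param hidden hidden-layer sizes (default `c(256, 64)`).
#' @param dropout dropout rate on hidden activations (default 0.2).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs maximum epochs (default 40).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed.
#' @param composition pair feature composition, see [featurize_pair()].
#' @return a `ppi_model`; use [predict.ppi_model()] for scores.
#' @export
train_ppi_model <- function(dataset, embedding, hidden = c(256L, 64L),
                            dropout = 0.2, lr = 1e-3, epochs = 40L,
                            batch_size = 32L, seed = 1L,
                            composition = "concat") {
  feats <- featurize_pair(dataset$protein_a, dataset$protein_b, embedding,
                          composition)
  tr <- dataset$split == "train"
  va <- dataset$split == "validation"
  val_metric <- function(scores, y)
    if (length(unique(y)) < 2L) 0 else evaluate_binary(scores, y)$auc
  has_val <- any(va)
  net <- mlp_fit(feats[tr, , drop = FALSE], dataset$label[tr], hidden,
                 n_out = 1L, task = "binary", dropout = dropout, lr = lr,
                 epochs = epochs, batch_size = batch_size, seed = seed,
                 x_val = if (has_val) feats[va, , drop = FALSE],
                 y_val = if (has_val) dataset$label[va],
                 val_metric = if (has_val) val_metric)
  structure(list(net = net, hidden = hidden, dropout = dropout, lr = lr,
                 composition = composition, seed = seed,
                 mode = attr(dataset, "mode")),
            class = "ppi_model")
}

#' @method print ppi_model
#' @export
print.ppi_model <- function(x, ...) {
  cat(sprintf("<ppi_model: hidden %s, best epoch %d (val AUC %.4f)>\n",
              paste(x$hidden, collapse = "/"), x$net$best_epoch,
              x$net$best_metric))
  invisible(x)
}

#' Predict interaction scores for protein pairs
#'
#' @param object a `ppi_model`.
#' @param dataset a `ppi_dataset` (or data frame with `protein_a`,
#'   `protein_b`).
#' @param embedding the embedding used at training time.
#' @param split optional split name to restrict to (`"test"` etc.).
#' @param ... unused.
#' @return numeric vector of interaction probabilities.
#' @export
predict.ppi_model <- function(object, dataset, embedding, split = NULL, ...) {
  if (!is.null(split)) dataset <- dataset[dataset$split == split, , drop = FALSE]
  feats <- featurize_pair(dataset$protein_a, dataset$protein_b, embedding,
                          object$composition)
  mlp_predict(object$net, feats)
}

#' Binary classification metrics
#'
#' Precision, recall and F1 at threshold 0.5, and AUC by the rank
#' (Mann-Whitney) formulation with tied scores averaged.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical).
#' @param threshold score threshold for the confusion counts (default 0.5).
#' @return list with `precision`, `recall`, `f1`, `auc`.
#' @export
evaluate_binary <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (any(!is.finite(scores))) stop_cv("non-finite prediction scores")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_cv("AUC is undefined when only one class is present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1, auc = auc)
}
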