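## DDI sentence classification: averaged-sentence-embedding network (SEN),
## optional drug concept vectors, positive-class micro-F1, multi-seed runs

#' Read DDI instances from JSON-lines
#'
#' One JSON object per line with fields `instance_id`, `tokens` (array),
#' `drug1` and `drug2` (objects with `index`, 1-based token position, and
#' `concept_id`) and `label` (one of mechanism, effect, advice, int,
#' negative).
#'
#' @param path file path.
#' @return list of `ddi_instance` objects.
#' @export
read_ddi_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    obj <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
    inst <- ddi_instance(obj$instance_id, unlist(obj$tokens),
                         obj$drug1$index, obj$drug1$concept_id,
                         obj$drug2$index, obj$drug2$concept_id, obj$label)
    inst
  })
}

#' Write DDI instances as JSON-lines
#'
#' @param instances list of `ddi_instance` objects.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ddi_jsonl <- function(instances, path) {
  lines <- vapply(instances, function(x)
    as.character(jsonlite::toJSON(unclass(x), auto_unbox = TRUE)), "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a DDI instance
#'
#' @param instance_id identifier.
#' @param tokens sentence tokens.
#' @param drug1_index,drug2_index 1-based token indices of the two drug
#'   mentions.
#' @param drug1_id,drug2_id drug concept ids.
#' @param label one of mechanism, effect, advice, int, negative.
#' @return a `ddi_instance`.
#' @export
ddi_instance <- function(instance_id, tokens, drug1_index, drug1_id,
                         drug2_index, drug2_id, label) {
  if (!label %in% DDI_CLASSES)
    stop_cv("unknown DDI label %s (expected one of %s)", dQuote(label),
            paste(DDI_CLASSES, collapse = ", "))
  if (drug1_index < 1L || drug1_index > length(tokens) ||
      drug2_index < 1L || drug2_index > length(tokens))
    stop_cv("drug token index out of range in instance %s", instance_id)
  structure(list(instance_id = as.character(instance_id),
                 tokens = as.character(tokens),
                 drug1 = list(index = as.integer(drug1_index),
                              concept_id = as.character(drug1_id)),
                 drug2 = list(index = as.integer(drug2_index),
                              concept_id = as.character(drug2_id)),
                 label = label),
            class = "ddi_instance")
}

#' Averaged sentence vector
#'
#' Unweighted mean of the available token vectors; out-of-vocabulary tokens
#' are dropped and counted. The embedder is pluggable: any named vector
#' matrix works (a contextual sentence embedder can be substituted upstream
#' by precomputing token vectors).
#'
#' @param tokens character vector of sentence tokens.
#' @param embedder named vector matrix or `concept_embeddings`.
#' @return mean vector with attribute `n_dropped`.
#' @export
sentence_vector <- function(tokens, embedder) {
  vecs <- embedding_vectors(embedder)
  present <- tokens %in% rownames(vecs)
  if (!any(present))
    stop_cv("all %d sentence tokens are out of vocabulary", length(tokens))
  out <- colMeans(vecs[tokens[present], , drop = FALSE])
  attr(out, "n_dropped") <- sum(!present)
  out
}

#' Feature vector for a DDI instance
#'
#' Without concept vectors: the averaged sentence vector (length `s`). With
#' a concept embedding: the sentence vector concatenated with the two drug
#' concept vectors (length `s + 2d`); a drug whose concept vector is missing
#' contributes a zero block (counted in attribute `n_missing_drug`).
#'
#' @param instance a `ddi_instance`.
#' @param embedder word/sentence embedder for [sentence_vector()].
#' @param concepts optional concept embedding for the two drug vectors.
#' @return numeric feature vector.
#' @export
featurize_ddi <- function(instance, embedder, concepts = NULL) {
  sv <- sentence_vector(instance$tokens, embedder)
  if (is.null(concepts)) return(sv)
  cv <- embedding_vectors(concepts)
  d <- ncol(cv)
  missing <- 0L
  grab <- function(id) {
    if (id %in% rownames(cv)) cv[id, ] else { missing <<- missing + 1L; rep(0, d) }
  }
  out <- c(sv, grab(instance$drug1$concept_id), grab(instance$drug2$concept_id))
  attr(out, "n_missing_drug") <- missing
  out
}

featurize_ddi_all <- function(instances, embedder, concepts = NULL) {
  do.call(rbind, lapply(instances, function(x) {
    f <- featurize_ddi(x, embedder, concepts)
    attributes(f) <- NULL
    f
  }))
}

#' Train the SEN drug-drug interaction classifier
#'
#' Feed-forward network over averaged sentence vectors (optionally
#' concatenated with the two drug concept vectors), with a softmax over the
#' five classes (mechanism, effect, advice, int, negative). Seeded runs are
#' reproducible.
#'
#' @param instances training `ddi_instance` list (must cover >= 2 classes).
#' @param embedder word embedder for the sentence vectors.
#' @param concepts optional concept embedding (see [featurize_ddi()]).
#' @param hidden hidden-layer sizes (default 128).
#' @param dropout dropout rate (default 0.3).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 60).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed.
#' @return a `sen_model`; use [predict.sen_model()].
#' @export
train_sen <- function(instances, embedder, concepts = NULL, hidden = 128L,
                      dropout = 0.3, lr = 1e-3, epochs = 60L,
                      batch_size = 32L, seed = 1L) {
  labels <- vapply(instances, `[[`, "", "label")
  if (length(unique(labels)) < 2L)
    stop_cv("training instances must cover at least two classes")
  y <- match(labels, DDI_CLASSES)
  feats <- featurize_ddi_all(instances, embedder, concepts)
  net <- mlp_fit(feats, y, hidden, n_out = length(DDI_CLASSES),
                 task = "multiclass", dropout = dropout, lr = lr,
                 epochs = epochs, batch_size = batch_size, seed = seed)
  structure(list(net = net, classes = DDI_CLASSES,
                 uses_concepts = !is.null(concepts), hidden = hidden,
                 seed = seed),
            class = "sen_model")
}

#' @method print sen_model
#' @export
print.sen_model <- function(x, ...) {
  cat(sprintf("<sen_model: hidden %s, %s drug concept vectors>\n",
              paste(x$hidden, collapse = "/"),
              if (x$uses_concepts) "with" else "without"))
  invisible(x)
}

#' Predict DDI classes
#'
#' @param object a `sen_model`.
#' @param instances list of `ddi_instance` objects.
#' @param embedder word embedder used at training time.
#' @param concepts concept embedding used at training time (or `NULL`).
#' @param type `"class"` (default) or `"prob"`.
#' @param ... unused.
#' @return character vector of predicted labels, or a probability matrix.
#' @export
predict.sen_model <- function(object, instances, embedder, concepts = NULL,
                              type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (object$uses_concepts && is.null(concepts))
    stop_cv("this model was trained with drug concept vectors; supply `concepts`")
  feats <- featurize_ddi_all(instances, embedder,
                             if (object$uses_concepts) concepts)
  probs <- mlp_predict(object$net, feats)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

#' DDI classification metrics
#'
#' Per-class precision/recall/F1 for the four positive classes from
#' one-vs-rest confusion counts, and the micro-averaged metrics pooled over
#' the positive classes only (the DDIExtraction convention: a gold-negative
#' instance predicted positive is a false positive; a gold-positive
#' instance predicted negative is a false negative; negative-negative
#' outcomes contribute nothing).
#'
#' @param predictions character vector of predicted labels.
#' @param gold character vector of gold labels, aligned with `predictions`.
#' @return a `ddi_metrics` list: `per_class` data frame, `micro_precision`,
#'   `micro_recall`, `micro_f1`, and `empty_positive` (`TRUE` when no
#'   positive counts exist at all, in which case the metrics are reported
#'   as 0).
#' @export
evaluate_ddi <- function(predictions, gold) {
  if (length(predictions) != length(gold))
    stop_cv("predictions and gold labels differ in length")
  bad <- setdiff(unique(c(predictions, gold)), DDI_CLASSES)
  if (length(bad))
    stop_cv("unknown label(s): %s", paste(dQuote(bad), collapse = ", "))
  positive <- setdiff(DDI_CLASSES, "negative")
  per_class <- do.call(rbind, lapply(positive, function(cl) {
    tp <- sum(predictions == cl & gold == cl)
    fp <- sum(predictions == cl & gold != cl)
    fn <- sum(predictions != cl & gold == cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               precision = p, recall = r,
               f1 = if (p + r > 0) 2 * p * r / (p + r) else 0,
               stringsAsFactors = FALSE)
  }))
  TP <- sum(per_class$tp); FP <- sum(per_class$fp); FN <- sum(per_class$fn)
  empty <- (TP + FP + FN) == 0L
  mp <- if (TP + FP > 0) TP / (TP + FP) else 0
  mr <- if (TP + FN > 0) TP / (TP + FN) else 0
  mf <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  structure(list(per_class = per_class, micro_precision = mp,
                 micro_recall = mr, micro_f1 = mf, empty_positive = empty),
            class = "ddi_metrics")
}

#' @method print ddi_metrics
#' @export
print.ddi_metrics <- function(x, ...) {
  cat("DDI classification metrics (positive classes)\n")
  print(x$per_class[, c("class", "precision", "recall", "f1")],
        row.names = FALSE)
  cat(sprintf("micro P = %.4f, R = %.4f, F1 = %.4f%s\n", x$micro_precision,
              x$micro_recall, x$micro_f1,
              if (x$empty_positive) " (no positive outcomes)" else ""))
  invisible(x)
}

#' Average an experiment over consecutive seeds
#'
#' Runs a seeded experiment with seeds `base_seed .. base_seed + n - 1` and
#' returns the arithmetic mean of every numeric metric, alongside the
#' per-run values. The standard protocol for reporting neural classifiers
#' whose training is seed-sensitive.
#'
#' @param experiment function of one argument (the seed) returning a named
#'   numeric vector, a `ddi_metrics`, or any list of scalars.
#' @param n number of runs (default 5).
#' @param base_seed first seed.
#' @return list with `mean` (named numeric) and `runs` (data frame, one row
#'   per run with its seed).
#' @export
repeated_runs <- function(experiment, n = 5L, base_seed = 1L) {
  seeds <- base_seed + seq_len(n) - 1L
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    res <- tryCatch(experiment(seeds[k]), error = function(e)
      stop_cv("run %d (seed %d) failed: %s", k, seeds[k], conditionMessage(e)))
    if (inherits(res, "ddi_metrics"))
      res <- c(micro_precision = res$micro_precision,
               micro_recall = res$micro_recall, micro_f1 = res$micro_f1)
    rows[[k]] <- as.data.frame(as.list(unlist(res)))
  }
  runs <- do.call(rbind, rows)
  runs <- cbind(seed = seeds, runs)
  list(mean = colMeans(runs[, -1L, drop = FALSE]), runs = runs)
}
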