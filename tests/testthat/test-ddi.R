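toy_instance <- function(id = "i1", label = "mechanism",
                         tokens = c("the", "Chemical_MESH_C900001", "blocks",
                                    "Chemical_MESH_C900002", "uptake"),
                         i1 = 2L, i2 = 4L) {
  ddi_instance(id, tokens, i1, tokens[i1], i2, tokens[i2], label)
}

test_that("DDI instances validate and round-trip through JSON-lines", {
  inst <- toy_instance()
  expect_s3_class(inst, "ddi_instance")
  expect_error(toy_instance(label = "bogus"), "unknown DDI label")
  expect_error(toy_instance(i2 = 99L), "out of range")

  path <- withr::local_tempfile(fileext = ".jsonl")
  insts <- generate_ddi_corpus(3, seed = 5)
  write_ddi_jsonl(insts, path)
  back <- read_ddi_jsonl(path)
  expect_identical(back, insts)
})

test_that("sentence vectors average available token vectors", {
  emb <- rbind(a = c(1, 0), b = c(0, 1), c = c(4, 4))
  sv <- sentence_vector(c("a", "b"), emb)
  expect_equal(as.numeric(sv), c(0.5, 0.5))
  expect_identical(attr(sv, "n_dropped"), 0L)

  one <- sentence_vector("c", emb)
  expect_equal(as.numeric(one), c(4, 4))

  dropped <- sentence_vector(c("a", "zzz", "b"), emb)
  expect_identical(attr(dropped, "n_dropped"), 1L)
  expect_equal(as.numeric(dropped), c(0.5, 0.5))
  expect_error(sentence_vector(c("x", "y"), emb), "out of vocabulary")

  # duplicated tokens weight the mean by count, as a brute-force sum does
  dup <- c("a", "a", "b")
  expect_equal(as.numeric(sentence_vector(dup, emb)),
               unname((emb["a", ] * 2 + emb["b", ]) / 3))
})

test_that("DDI features have length s or s + 2d with zero fallback", {
  inst <- toy_instance()
  emb <- random_unit_embedding(inst$tokens, dim = 7, seed = 1)
  f0 <- featurize_ddi(inst, emb)
  expect_length(f0, 7)
  conc <- random_unit_embedding(c("Chemical_MESH_C900001",
                                  "Chemical_MESH_C900002"), dim = 5, seed = 2)
  f1 <- featurize_ddi(inst, emb, conc)
  expect_length(f1, 7 + 2 * 5)
  expect_identical(attr(f1, "n_missing_drug"), 0L)
  # a missing drug vector becomes a zero block
  conc1 <- conc[1, , drop = FALSE]
  f2 <- featurize_ddi(inst, emb, conc1)
  expect_identical(attr(f2, "n_missing_drug"), 1L)
  expect_equal(unname(f2[(7 + 5 + 1):(7 + 10)]), rep(0, 5))
})

test_that("DDI metrics match hand-worked counts and handle edge cases", {
  gold <- c("mechanism", "mechanism", "effect")
  pred <- rep("mechanism", 3)
  m <- evaluate_ddi(pred, gold)
  expect_equal(m$per_class$f1[m$per_class$class == "mechanism"], 0.8)
  expect_equal(m$per_class$f1[m$per_class$class == "effect"], 0)
  expect_equal(m$micro_precision, 2 / 3)
  expect_equal(m$micro_recall, 2 / 3)
  expect_equal(m$micro_f1, 2 / 3)

  all_right <- evaluate_ddi(gold, gold)
  expect_equal(all_right$micro_f1, 1)
  expect_equal(all_right$per_class$f1[all_right$per_class$class %in%
                                        c("mechanism", "effect")], c(1, 1))

  vac <- evaluate_ddi(rep("negative", 4), rep("negative", 4))
  expect_true(vac$empty_positive)
  expect_equal(vac$micro_f1, 0)

  expect_error(evaluate_ddi(c("mechanism", "oops"), gold[1:2]), "unknown label")
  expect_error(evaluate_ddi("mechanism", gold), "differ in length")
})

test_that("micro metrics equal exhaustive confusion-matrix enumeration", {
  # independent oracle: build the 5x5 confusion matrix and pool counts
  oracle <- function(pred, gold) {
    classes <- c("mechanism", "effect", "advice", "int", "negative")
    cm <- matrix(0, 5, 5, dimnames = list(classes, classes))
    for (k in seq_along(pred)) cm[pred[k], gold[k]] <- cm[pred[k], gold[k]] + 1
    pos <- classes[1:4]
    TP <- sum(diag(cm)[pos])
    FP <- sum(cm[pos, ]) - TP
    FN <- sum(cm[, pos]) - TP
    p <- if (TP + FP > 0) TP / (TP + FP) else 0
    r <- if (TP + FN > 0) TP / (TP + FN) else 0
    c(p = p, r = r, f = if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  classes <- c("mechanism", "effect", "advice", "int", "negative")
  gold_sets <- list(c("mechanism", "effect", "negative"),
                    c("int", "int", "advice"),
                    c("negative", "negative", "mechanism"))
  grid <- expand.grid(a = classes, b = classes, c = classes,
                      stringsAsFactors = FALSE)
  for (gold in gold_sets) {
    for (row in seq_len(nrow(grid))) {
      pred <- unlist(grid[row, ], use.names = FALSE)
      m <- evaluate_ddi(pred, gold)
      o <- oracle(pred, gold)
      expect_equal(m$micro_precision, unname(o["p"]))
      expect_equal(m$micro_recall, unname(o["r"]))
      expect_equal(m$micro_f1, unname(o["f"]))
    }
  }
  # invariance to instance order
  set.seed(9)
  gold <- sample(classes, 40, replace = TRUE)
  pred <- sample(classes, 40, replace = TRUE)
  perm <- sample(40)
  expect_equal(evaluate_ddi(pred, gold)$micro_f1,
               evaluate_ddi(pred[perm], gold[perm])$micro_f1)
})

test_that("SEN learns trigger-determined classes from averaged sentences", {
  train_i <- generate_ddi_corpus(60, concept_dependent = FALSE, seed = 21)
  test_i <- generate_ddi_corpus(30, concept_dependent = FALSE, seed = 22)
  vocab <- unique(unlist(lapply(c(train_i, test_i), `[[`, "tokens")))
  wemb <- random_unit_embedding(vocab, dim = 50, seed = 23)
  model <- train_sen(train_i, wemb, seed = 24)
  gold <- vapply(test_i, `[[`, "", "label")
  pred <- predict(model, test_i, wemb)
  expect_gte(evaluate_ddi(pred, gold)$micro_f1, 0.9)
  # same seed: identical predictions
  model2 <- train_sen(train_i, wemb, seed = 24)
  expect_identical(predict(model2, test_i, wemb), pred)
  one_class <- Filter(function(x) x$label == "advice", train_i)
  expect_error(train_sen(one_class, wemb), "two classes")
})

test_that("concept vectors that encode the label lift concept-dependent accuracy", {
  tr <- generate_ddi_corpus(60, concept_dependent = TRUE, seed = 31)
  te <- generate_ddi_corpus(30, concept_dependent = TRUE, seed = 32,
                            drug_offset = 40) # held-out drugs
  vocab <- unique(unlist(lapply(c(tr, te), `[[`, "tokens")))
  wemb <- random_unit_embedding(vocab, dim = 50, seed = 33)
  drugs <- unique(unlist(lapply(c(tr, te), function(x)
    c(x$drug1$concept_id, x$drug2$concept_id))))
  conc <- ddi_concept_embedding(drugs, seed = 34)
  gold <- vapply(te, `[[`, "", "label")
  f_sentence <- evaluate_ddi(predict(train_sen(tr, wemb, seed = 35), te, wemb),
                             gold)$micro_f1
  m_conc <- train_sen(tr, wemb, concepts = conc, seed = 35)
  f_concept <- evaluate_ddi(predict(m_conc, te, wemb, conc), gold)$micro_f1
  expect_gt(f_concept, f_sentence)
  expect_gte(f_concept, 0.9) # the planted mechanism is fully recoverable
})

test_that("multi-seed averaging is the arithmetic mean and order-invariant", {
  fixed <- function(seed) c(f1 = 0.5 + 0.2 * (seed %% 2))
  out <- repeated_runs(fixed, n = 2, base_seed = 0)
  expect_equal(unname(out$mean["f1"]), 0.6)
  expect_identical(nrow(out$runs), 2L)

  const <- function(seed) c(a = 0.25, b = 0.75)
  out2 <- repeated_runs(const, n = 5, base_seed = 10)
  expect_equal(unname(out2$mean), c(0.25, 0.75))
  # order invariance over the seed list
  vals <- function(seed) c(m = sin(seed))
  m1 <- repeated_runs(vals, n = 4, base_seed = 1)$mean
  m2 <- mean(sin(4:1))
  expect_equal(unname(m1["m"]), m2)

  failing <- function(seed) if (seed == 3) stop("boom") else c(x = 1)
  expect_error(repeated_runs(failing, n = 3, base_seed = 2), "run 2")
})
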