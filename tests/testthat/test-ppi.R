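make_links <- function() {
  df <- data.frame(
    protein1 = c("p1", "p2", "p3", "p4", "p1", "p5"),
    protein2 = c("p2", "p1", "p4", "p3", "p1", "p6"),
    experimental = c(800, 750, 700, 650, 900, 900),
    combined_score = c(900, 850, 800, 700, 950, 950),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(.local_envir = parent.frame())
  write.table(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("pair tables read, clean and de-duplicate", {
  tab <- read_string_links(make_links())
  expect_named(tab, c("protein_a", "protein_b", "combined", "experimental"))
  clean <- clean_pair_table(tab)
  # self pair p1-p1 dropped; p1-p2/p2-p1 merged keeping max scores
  expect_identical(nrow(clean), 3L)
  r12 <- clean[clean$protein_a == "p1" & clean$protein_b == "p2", ]
  expect_equal(r12$experimental, 800)
  expect_equal(r12$combined, 900)
  expect_false(any(clean$protein_a == clean$protein_b))
})

test_that("experimental-700 filtering is strict and classes balance", {
  tab <- clean_pair_table(read_string_links(make_links()))
  vocab <- c("p1", "p2", "p3", "p4", "p5", "p6")
  ds <- build_ppi_dataset(tab, "experimental_700", vocab, seed = 1)
  pos <- ds[ds$label == 1, ]
  keys <- paste(pos$protein_a, pos$protein_b)
  # 800 and 900 pass; exactly 700 and 650 are excluded
  expect_setequal(keys, c("p1 p2", "p5 p6"))
  expect_identical(sum(ds$label == 1), sum(ds$label == 0))
  # negatives never collide with the positive pair set
  negk <- paste(ds$protein_a[ds$label == 0], ds$protein_b[ds$label == 0])
  expect_length(intersect(negk, keys), 0)

  ds_c <- build_ppi_dataset(tab, "combined", vocab, seed = 1)
  expect_identical(sum(ds_c$label == 1), 3L)
  expect_error(build_ppi_dataset(tab, "experimental_700", c("p1", "p9"), 1),
               "no positive pairs")
})

test_that("splits are disjoint, exhaustive and in 63/7/30 proportion", {
  cfg <- synth_config(n_clusters = 5, concepts_per_cluster = 5, n_documents = 1)
  tab <- generate_ppi_table(cfg)
  vocab <- synth_concepts(cfg)$token
  ds <- build_ppi_dataset(tab, "experimental_700", vocab, seed = 3)
  expect_setequal(unique(ds$split), c("train", "validation", "test"))
  expect_identical(sum(table(ds$split)), nrow(ds))
  prop <- table(ds$split) / nrow(ds)
  expect_lt(abs(prop[["test"]] - 0.30), 0.02)
  expect_lt(abs(prop[["validation"]] - 0.07), 0.02)
  # balance preserved within each split (stratified)
  for (s in c("train", "validation", "test")) {
    lab <- ds$label[ds$split == s]
    expect_equal(sum(lab == 1), sum(lab == 0), tolerance = 1)
  }
  # the documented toy arithmetic: 10 instances split 6/1/3
  lab10 <- data.frame(protein_a = sprintf("q%02d", 1:10),
                      protein_b = sprintf("r%02d", 1:10),
                      experimental = 900, combined_score = 900)
  vocab10 <- c(lab10$protein_a, lab10$protein_b, sprintf("s%02d", 1:10))
  ds10 <- build_ppi_dataset(lab10, "experimental_700", vocab10, seed = 4)
  pos_split <- table(ds10$split[ds10$label == 1])
  expect_identical(as.integer(pos_split[c("train", "validation", "test")]),
                   c(6L, 1L, 3L))
})

test_that("pair features concatenate the two protein vectors", {
  emb <- rbind(pA = c(1, 2), pB = c(3, 4), pZ = c(0, 0))
  f <- featurize_pair("pA", "pB", emb)
  expect_identical(unname(f[1, ]), c(1, 2, 3, 4))
  expect_identical(ncol(f), 2L * ncol(emb))
  # swapping order permutes the halves exactly
  g <- featurize_pair("pB", "pA", emb)
  expect_identical(unname(g[1, ]), c(3, 4, 1, 2))
  expect_identical(unname(featurize_pair("pZ", "pZ", emb)[1, ]), rep(0, 4))
  expect_error(featurize_pair("pA", "missing", emb), "missing vector")
  # a 200-dimensional embedding gives 400-long features
  big <- matrix(0, 2, 200, dimnames = list(c("a", "b"), NULL))
  expect_identical(ncol(featurize_pair("a", "b", big)), 400L)
})

test_that("binary metrics match closed forms and the brute-force AUC oracle", {
  perfect <- evaluate_binary(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)

  # all predicted positive: recall 1, precision = prevalence
  allpos <- evaluate_binary(rep(0.9, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(allpos$recall, 1)
  expect_equal(allpos$precision, 0.3)

  set.seed(21)
  for (i in 1:15) {
    n <- sample(10:100, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1) # coarse => ties exercised
    auc <- evaluate_binary(scores, labels)$auc
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    acc <- 0
    for (p in pos) for (q in neg)
      acc <- acc + (p > q) + 0.5 * (p == q)
    expect_equal(auc, acc / (length(pos) * length(neg)))
    # invariance under strictly monotone transforms
    expect_equal(evaluate_binary(exp(scores), labels)$auc, auc)
  }
  expect_error(evaluate_binary(c(0.1, 0.9), c(1, 1)), "one class")
})

test_that("the pair classifier separates planted structure and not permuted labels", {
  cfg <- synth_config(n_clusters = 16, concepts_per_cluster = 16,
                      n_documents = 1)
  tab <- generate_ppi_table(cfg)
  emb <- planted_embedding(cfg, dim = 16, noise = 0.15, seed = 3)
  ds <- build_ppi_dataset(tab, "experimental_700", rownames(emb), seed = 4)
  m <- train_ppi_model(ds, emb, seed = 5)
  test_lab <- ds$label[ds$split == "test"]
  sc <- predict(m, ds, emb, split = "test")
  ev <- evaluate_binary(sc, test_lab)
  expect_gte(ev$auc, 0.95)

  # determinism: same seed, same predictions
  m2 <- train_ppi_model(ds, emb, seed = 5)
  expect_identical(predict(m2, ds, emb, split = "test"), sc)

  # permuted labels: chance-level AUC
  dsp <- ds
  dsp$label <- local({
    set.seed(42)
    sample(ds$label)
  })
  mp <- train_ppi_model(dsp, emb, seed = 5)
  scp <- predict(mp, dsp, emb, split = "test")
  evp <- evaluate_binary(scp, dsp$label[dsp$split == "test"])
  expect_gte(evp$auc, 0.45)
  expect_lte(evp$auc, 0.55)
})
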