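test_that("GMT and drug-gene readers parse their formats", {
  gmt <- withr::local_tempfile()
  writeLines(c("setA\tdesc A\tg1\tg2\tg3", "setB\tdesc B\tg2\tg4"), gmt)
  sets <- read_gmt(gmt)
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(sets$setB, c("g2", "g4"))
  writeLines("broken\tonly-two-fields", gmt)
  expect_error(read_gmt(gmt), "malformed GMT")

  dg <- withr::local_tempfile()
  writeLines(c("drug1\tg1", "drug1\tg2", "drug2\tg3", "drug1\tg1"), dg)
  memb <- read_drug_gene(dg)
  expect_identical(memb$drug1, c("g1", "g2"))
  expect_identical(memb$drug2, "g3")
})

test_that("group construction caps, balances and excludes correctly", {
  universe <- sprintf("g%03d", 1:600)
  memb <- list(drug_small = universe[1:3],
               drug_big = universe[1:250],
               drug_single = universe[5],
               drug_outside = c("zz1", "zz2"))
  expect_warning(ds <- build_groups(memb, universe, cap = 100, seed = 2),
                 regexp = NA)
  ids <- vapply(ds$groups, `[[`, "", "group_id")
  expect_setequal(ids, c("drug_small", "drug_big"))
  g_small <- ds$groups[[match("drug_small", ids)]]
  expect_length(g_small$related, 3)
  expect_length(g_small$unrelated, 3)
  expect_length(intersect(g_small$unrelated, memb$drug_small), 0)
  g_big <- ds$groups[[match("drug_big", ids)]]
  expect_length(g_big$related, 100) # cap
  # unrelated excludes the drug's FULL membership, not just the capped subset
  expect_length(intersect(g_big$unrelated, memb$drug_big), 0)
  expect_identical(ds$n_skipped, 2L)

  # reproducible under a fixed seed
  ds2 <- build_groups(memb, universe, cap = 100, seed = 2)
  expect_identical(ds2$groups, ds$groups)
  # too few complement concepts: group skipped with warning
  expect_warning(build_groups(list(d = letters[1:5]), letters[1:6], seed = 1),
                 "skipped")
})

test_that("normalization spans [0,1] and is affine-invariant", {
  expect_equal(unname(normalize_pair_scores(c(1, 2, 3))), c(0, 0.5, 1))
  set.seed(31)
  for (i in 1:20) {
    raw <- rnorm(sample(5:50, 1))
    n1 <- normalize_pair_scores(raw)
    expect_equal(min(n1), 0)
    expect_equal(max(n1), 1)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(normalize_pair_scores(a * raw + b), n1, tolerance = 1e-10)
    expect_identical(order(n1), order(raw)) # order-preserving
  }
  expect_error(normalize_pair_scores(rep(0.4, 6)), "degenerate")
  expect_error(normalize_pair_scores(1), "at least two")
})

test_that("set similarity averages all unordered within-set pairs", {
  scores <- c(0.2, 0.4, 0.6)
  names(scores) <- c("a\tb", "a\tc", "b\tc")
  expect_equal(set_similarity(c("a", "b", "c"), scores), 0.4)
  expect_equal(set_similarity(c("b", "a"), scores), 0.2)
  const <- setNames(rep(0.7, 3), names(scores))
  expect_equal(set_similarity(c("a", "b", "c"), const), 0.7)
  expect_error(set_similarity(c("a", "d"), scores), "missing pair")
  expect_error(set_similarity("a", scores), "at least two")

  # brute-force double-loop oracle on larger sets
  set.seed(8)
  ids <- sprintf("c%02d", 1:10)
  keys <- conceptvec:::within_set_pairs(ids)
  sc <- setNames(runif(length(keys)), keys)
  acc <- 0; n <- 0
  for (i in 1:9) for (j in (i + 1):10) {
    acc <- acc + sc[conceptvec:::pair_key(ids[i], ids[j])]
    n <- n + 1
  }
  expect_equal(set_similarity(ids, sc), unname(acc / n))
  expect_identical(n, choose(10L, 2L))
})

test_that("group similarity difference hits its extremes and errors", {
  # pairs engineered to the extremes: related cosine 1, unrelated cosine -1
  vecs <- rbind(r1 = c(1, 0), r2 = c(2, 0), u1 = c(0, 1), u2 = c(0, -3),
                r3 = c(0.6, 0.6), r4 = c(3, 3), u3 = c(1, 1e-3),
                u4 = c(-1, -1e-3))
  ds <- structure(list(groups = list(
    list(group_id = "g1", related = c("r1", "r2"), unrelated = c("u1", "u2")),
    list(group_id = "g2", related = c("r3", "r4"), unrelated = c("u3", "u4"))),
    universe = rownames(vecs), n_skipped = 0L, seed = 1L),
    class = "group_dataset")
  res <- group_similarity_difference(ds, vecs)
  expect_equal(res$metric, 100)
  expect_identical(res$n_groups, 2L)

  expect_error(group_similarity_difference(ds, vecs[1:4, ]), "missing")
})

test_that("the metric is invariant under positive affine maps of the vectors' cosines", {
  # scaling all vectors leaves cosines (hence the metric) unchanged
  set.seed(77)
  toks <- sprintf("t%02d", 1:30)
  memb <- lapply(1:6, function(i) sample(toks, 5))
  names(memb) <- paste0("e", 1:6)
  ds <- build_groups(memb, toks, seed = 3)
  v <- matrix(rnorm(30 * 8), 30, dimnames = list(toks, NULL))
  m1 <- group_similarity_difference(ds, v)$metric
  m2 <- group_similarity_difference(ds, 3.7 * v)$metric
  expect_equal(m1, m2, tolerance = 1e-10)
})

test_that("exchangeable labels give a null-centered metric", {
  # many groups of iid random unit vectors: |metric| stays within 2 points
  set.seed(55)
  toks <- sprintf("n%04d", 1:2000)
  memb <- lapply(1:220, function(i) sample(toks, 6))
  names(memb) <- paste0("s", 1:220)
  ds <- build_groups(memb, toks, seed = 4)
  emb <- random_unit_embedding(toks, dim = 64, seed = 5)
  res <- group_similarity_difference(ds, emb)
  expect_lt(abs(res$metric), 2)
  # label-shuffled baseline of a structured embedding is also null-centered
  fx_cfg <- synth_config(n_documents = 1)
  pl <- planted_embedding(fx_cfg, seed = 6)
  sets <- lapply(split(synth_concepts(fx_cfg)$token, synth_concepts(fx_cfg)$cluster),
                 identity)
  names(sets) <- paste0("cluster", seq_along(sets))
  ds2 <- build_groups(sets, rownames(pl), seed = 7)
  sb <- shuffled_baseline(ds2, pl, n_perm = 100, seed = 8)
  expect_lt(abs(sb$metric), 2)
  # while the planted embedding itself scores far above the baseline
  expect_gt(group_similarity_difference(ds2, pl)$metric, 20)
})
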