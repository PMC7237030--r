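test_that("PubTator blocks parse into annotated documents", {
  docs <- parse_pubtator(tiny_block())
  expect_length(docs, 1)
  doc <- docs[[1]]
  expect_identical(doc$doc_id, "1000")
  expect_identical(doc$title, "MLN4924 is studied.")
  expect_identical(nrow(doc$annotations), 1L)
  expect_identical(doc$annotations$concept_id, "MESH:C539933")
  expect_identical(doc$annotations$mention, "MLN4924")

  expect_length(parse_pubtator(character(0)), 0)
  expect_length(parse_pubtator(""), 0)
})

test_that("malformed and inconsistent annotation lines are rejected", {
  bad_fields <- c("1000|t|MLN4924 is studied.", "1000|a|x.",
                  "1000\t0\t7\tMLN4924\tChemical", "")
  expect_error(parse_pubtator(bad_fields), "parse error at line 3")

  bad_mention <- c("1000|t|MLN4924 is studied.", "1000|a|x.",
                   "1000\t0\t7\tWRONG\tChemical\tMESH:C539933", "")
  expect_error(parse_pubtator(bad_mention), "integrity error.*1000")

  bad_span <- c("1000|t|Short.", "1000|a|x.",
                "1000\t0\t99\tShort\tChemical\tMESH:C1", "")
  expect_error(parse_pubtator(bad_span), "outside text")

  bad_type <- c("1000|t|MLN4924 is studied.", "1000|a|x.",
                "1000\t0\t7\tMLN4924\tWidget\tMESH:C539933", "")
  expect_error(parse_pubtator(bad_type), "unknown concept type")
})

test_that("both offset dialects are honoured", {
  # mention sits in the abstract: offsets differ by the separator convention
  title <- "A title."
  abstract <- "MLN4924 works."
  base_nl <- nchar(title) + 1L
  blk <- function(start) c(sprintf("7|t|%s", title), sprintf("7|a|%s", abstract),
                           sprintf("7\t%d\t%d\tMLN4924\tChemical\tMESH:C539933",
                                   start, start + 7L), "")
  expect_silent(parse_pubtator(blk(base_nl), dialect = "newline"))
  expect_silent(parse_pubtator(blk(base_nl), dialect = "space"))
  doc <- parse_pubtator(blk(base_nl))[[1]]
  expect_identical(document_text(doc, "newline"),
                   paste(title, abstract, sep = "\n"))
  expect_identical(document_text(doc, "space"),
                   paste(title, abstract, sep = " "))
})

test_that("write_pubtator round-trips parsed corpora exactly", {
  fx <- default_synth()
  docs <- fx$docs[1:50]
  lines <- write_pubtator(docs)
  docs2 <- parse_pubtator(lines)
  expect_identical(docs2, docs)
  # and a second generation with the same config is byte-identical
  expect_identical(generate_corpus(fx$config), fx$lines)
})

test_that("overlap resolution keeps the longest span with deterministic ties", {
  # nested shorter span dropped
  a <- rbind(make_ann(0, 10, "x"), make_ann(2, 5, "y"))
  expect_identical(resolve_overlaps(a)$start, 0L)
  # equal length: earliest start wins
  b <- rbind(make_ann(0, 7, "x"), make_ann(3, 10, "y"))
  expect_identical(resolve_overlaps(b)$start, 0L)
  # disjoint spans unchanged
  d <- rbind(make_ann(0, 3, "x"), make_ann(5, 9, "y"))
  expect_identical(resolve_overlaps(d), d)
  # same span: type priority Gene > Chemical
  e <- rbind(make_ann(0, 5, "x", "Chemical", "C1"),
             make_ann(0, 5, "x", "Gene", "G1"))
  expect_identical(resolve_overlaps(e)$type, "Gene")
  # same span and type: lexicographic id
  f <- rbind(make_ann(0, 5, "x", "Gene", "B"), make_ann(0, 5, "x", "Gene", "A"))
  expect_identical(resolve_overlaps(f)$concept_id, "A")
})

test_that("overlap resolution is idempotent and yields disjoint spans", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(1:8, 1)
    start <- sort(sample(0:30, n, replace = TRUE))
    len <- sample(1:10, n, replace = TRUE)
    ann <- make_ann(start, start + len, mention = letters[seq_len(n)],
                    type = sample(c("Gene", "Chemical", "Disease"), n, TRUE),
                    id = as.character(sample(99, n)))
    ann <- ann[order(ann$start, ann$end), ]
    once <- resolve_overlaps(ann)
    if (nrow(once) > 1)
      expect_true(all(once$start[-1] >= once$end[-nrow(once)]))
    expect_identical(resolve_overlaps(once), once)
  }
})

test_that("concept tokens normalize identifiers", {
  expect_identical(concept_token("Disease", "MESH:D008288"),
                   "Disease_MESH_D008288")
  expect_identical(concept_token("Gene", "2099"), "Gene_2099")
  expect_identical(concept_token("Chemical", "MESH:C539933"),
                   "Chemical_MESH_C539933")
  expect_error(concept_token("Gene", ""), "non-empty")
  expect_error(concept_token("Widget", "1"), "unknown concept type")
  expect_true(is_concept_token("Gene_2099"))
  expect_false(is_concept_token("growth"))
})

test_that("substitution emits one concept token per resolved annotation", {
  doc <- parse_pubtator(c("1|t|MLN4924 inhibits growth.", "1|a|.",
                          "1\t0\t7\tMLN4924\tChemical\tMESH:C539933", ""))[[1]]
  td <- substitute_and_tokenize(doc)
  expect_identical(td$sentences[[1]],
                   c("Chemical_MESH_C539933", "inhibits", "growth"))
  expect_identical(td$concept_flags[[1]], c(TRUE, FALSE, FALSE))

  # no annotations: plain lowercased tokens
  plain <- parse_pubtator(c("2|t|Cancer Cells Grow.", "2|a|.", ""))[[1]]
  td2 <- substitute_and_tokenize(plain)
  expect_identical(td2$sentences[[1]], c("cancer", "cells", "grow"))
  expect_false(any(unlist(td2$concept_flags)))

  # entire text a single annotated mention
  whole <- parse_pubtator(c("3|t|MLN4924", "3|a|",
                            "3\t0\t7\tMLN4924\tChemical\tMESH:C539933", ""))[[1]]
  td3 <- substitute_and_tokenize(whole)
  expect_identical(unlist(td3$sentences), "Chemical_MESH_C539933")
})

test_that("token conservation holds over the synthetic corpus", {
  fx <- default_synth()
  for (doc in fx$docs[1:30]) {
    td <- substitute_and_tokenize(doc)
    n_concept <- sum(unlist(td$concept_flags))
    expect_identical(n_concept, nrow(doc$annotations))
    n_words <- sum(lengths(td$sentences)) - n_concept
    plain_text <- document_text(doc)
    # every annotation span is a single token in the rewrite
    expect_true(all(unlist(td$sentences)[unlist(td$concept_flags)] %in%
                      concept_token(doc$annotations$type,
                                    doc$annotations$concept_id)))
    expect_gt(n_words, 0)
  }
})

test_that("tokenization is deterministic and sentence splitting is config-driven", {
  fx <- default_synth()
  docs <- fx$docs[1:20]
  c1 <- tokenize_corpus(docs)
  c2 <- tokenize_corpus(docs)
  expect_identical(c1, c2)
  whole <- tokenize_corpus(docs, corpus_rules(split_sentences = FALSE))
  expect_identical(length(whole$sentences), length(docs))
  expect_identical(sum(lengths(whole$sentences)), sum(lengths(c1$sentences)))
})

test_that("write_corpus emits one sentence per line plus a vocabulary report", {
  fx <- default_synth()
  corp <- tokenize_corpus(fx$docs[1:10])
  dir <- withr::local_tempdir()
  paths <- write_corpus(corp, dir)
  lines <- readLines(paths[["corpus"]])
  expect_identical(length(lines), length(corp$sentences))
  vb <- read.delim(paths[["vocab"]], stringsAsFactors = FALSE)
  expect_identical(sort(names(vb)), sort(c("token", "count", "is_concept")))
  expect_identical(sum(vb$count), sum(lengths(corp$sentences)))
})
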