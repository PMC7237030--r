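## seeded synthetic fixtures with planted structure for every pipeline stage

#' Configuration for the synthetic corpus generator
#'
#' The generator plants cluster structure among gene concept tokens: every
#' sentence has a home cluster, and each concept slot is filled from the
#' home cluster with probability `within_cluster_prob` (else from a
#' uniformly random other cluster), so within-cluster co-occurrence exceeds
#' cross-cluster co-occurrence whenever `within_cluster_prob > 0.5`. The
#' defaults (8 clusters of 5 concepts, 2,000 documents of 3 sentences,
#' seed 7) are the package's reference desk-scale condition: large enough
#' that all four trainers recover the clusters, small enough to train in
#' minutes on one CPU.
#'
#' @param n_clusters number of planted clusters.
#' @param concepts_per_cluster concepts per cluster.
#' @param n_documents number of generated abstracts.
#' @param sentences_per_doc sentences per abstract.
#' @param concepts_per_sentence concept slots per sentence.
#' @param within_cluster_prob probability a slot is filled from the home
#'   cluster; must exceed 0.5 for the structure to be detectable.
#' @param filler_vocab_size size of the ordinary-word filler vocabulary.
#' @param filler_per_sentence filler words per sentence.
#' @param seed integer seed; output is byte-identical for equal seeds.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_clusters = 8L, concepts_per_cluster = 5L,
                         n_documents = 2000L, sentences_per_doc = 3L,
                         concepts_per_sentence = 4L,
                         within_cluster_prob = 0.8,
                         filler_vocab_size = 200L, filler_per_sentence = 6L,
                         seed = 7L) {
  if (within_cluster_prob <= 0.5 || within_cluster_prob > 1)
    stop_cv("within_cluster_prob must lie in (0.5, 1] for detectable structure")
  counts <- c(n_clusters, concepts_per_cluster, n_documents, sentences_per_doc,
              concepts_per_sentence, filler_vocab_size, filler_per_sentence)
  if (any(counts < 1)) stop_cv("all synthetic counts must be positive")
  structure(list(n_clusters = as.integer(n_clusters),
                 concepts_per_cluster = as.integer(concepts_per_cluster),
                 n_documents = as.integer(n_documents),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 concepts_per_sentence = as.integer(concepts_per_sentence),
                 within_cluster_prob = within_cluster_prob,
                 filler_vocab_size = as.integer(filler_vocab_size),
                 filler_per_sentence = as.integer(filler_per_sentence),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Planted concept inventory of a synthetic configuration
#'
#' @param config a [synth_config()].
#' @return data frame with `cluster`, `concept_id` (numeric Gene id as in
#'   real annotations), `mention` (surface form) and `token` (the concept
#'   token appearing in the trained vocabulary, e.g. `Gene_900101`).
#' @export
synth_concepts <- function(config) {
  k <- rep(seq_len(config$n_clusters), each = config$concepts_per_cluster)
  m <- rep(seq_len(config$concepts_per_cluster), config$n_clusters)
  id <- sprintf("9%03d%02d", k, m)
  data.frame(cluster = k, concept_id = id, mention = paste0("G", id),
             token = concept_token("Gene", id), stringsAsFactors = FALSE)
}

synth_fillers <- function(config) sprintf("filler%04d", seq_len(config$filler_vocab_size))

#' Generate a PubTator-format corpus with planted clusters
#'
#' Emits annotated abstracts whose Gene annotations follow the planted
#' cluster co-occurrence of `config`; every mention carries a correct
#' annotation line, so the output round-trips through [parse_pubtator()]
#' with zero integrity errors (newline offset dialect).
#'
#' @param config a [synth_config()].
#' @param path optional output file.
#' @return character vector of PubTator lines (invisibly when written).
#' @export
generate_corpus <- function(config, path = NULL) {
  info <- synth_concepts(config)
  fillers <- synth_fillers(config)
  K <- config$n_clusters
  cluster_members <- split(seq_len(nrow(info)), info$cluster)

  lines <- vector("list", config$n_documents)
  with_seed(config$seed, {
    for (d in seq_len(config$n_documents)) {
      pmid <- as.character(9000000L + d)
      title <- sprintf("Synthetic abstract %d.", d)
      parts <- character(0)
      ann <- list()
      pos <- 0L
      for (s in seq_len(config$sentences_per_doc)) {
        home <- sample.int(K, 1L)
        others <- setdiff(seq_len(K), home)
        cl <- vapply(seq_len(config$concepts_per_sentence), function(slot) {
          if (runif(1L) < config$within_cluster_prob || !length(others)) home
          else others[sample.int(length(others), 1L)]
        }, 0L)
        concept_rows <- vapply(cl, function(k) {
          mem <- cluster_members[[k]]
          mem[sample.int(length(mem), 1L)]
        }, 0L)
        words <- fillers[sample.int(length(fillers),
                                    config$filler_per_sentence, replace = TRUE)]
        items <- c(info$mention[concept_rows], words)
        is_mention <- c(rep(TRUE, length(concept_rows)), rep(FALSE, length(words)))
        ord <- sample.int(length(items))
        for (t in ord) {
          if (pos > 0L) { parts <- c(parts, " "); pos <- pos + 1L }
          start <- pos
          parts <- c(parts, items[t])
          pos <- pos + nchar(items[t])
          if (is_mention[t])
            ann[[length(ann) + 1L]] <-
              c(start = start, end = pos, row = concept_rows[t])
        }
        parts <- c(parts, ".")
        pos <- pos + 1L
      }
      abstract <- paste(parts, collapse = "")
      offset <- nchar(title) + 1L # newline separator dialect
      ann_lines <- vapply(ann, function(a) {
        row <- a[["row"]]
        sprintf("%s\t%d\t%d\t%s\tGene\t%s", pmid, a[["start"]] + offset,
                a[["end"]] + offset, info$mention[row], info$concept_id[row])
      }, "")
      lines[[d]] <- c(sprintf("%s|t|%s", pmid, title),
                      sprintf("%s|a|%s", pmid, abstract), ann_lines, "")
    }
  })
  out <- unlist(lines, use.names = FALSE)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Gene sets equal to the planted clusters, in GMT format
#'
#' @param config a [synth_config()].
#' @param path optional output file.
#' @return character vector of GMT lines (one per cluster; members are the
#'   cluster's concept tokens).
#' @export
generate_gene_sets <- function(config, path = NULL) {
  info <- synth_concepts(config)
  lines <- vapply(seq_len(config$n_clusters), function(k)
    paste(c(sprintf("cluster_%02d", k), sprintf("planted cluster %d", k),
            info$token[info$cluster == k]), collapse = "\t"), "")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Scored protein-pair table with planted structure
#'
#' Every within-cluster pair receives experimental (and combined) score
#' `pos_score`; a seeded sample of cross-cluster pairs receives
#' `neg_score`. With the defaults the scores straddle the 700 cutoff, so
#' experimental-700 filtering recovers exactly the within-cluster pairs.
#'
#' @param config a [synth_config()].
#' @param pos_score score of within-cluster pairs (> 700).
#' @param neg_score score of sampled cross-cluster pairs (<= 700).
#' @param n_negative number of scored cross-cluster rows (default: as many
#'   as the positives).
#' @param seed integer seed (default: the config seed).
#' @return data frame with columns `protein1`, `protein2`, `experimental`,
#'   `combined_score` (write with `write.table(..., row.names = FALSE,
#'   quote = FALSE)` for the STRING-style dialect).
#' @export
generate_ppi_table <- function(config, pos_score = 900, neg_score = 100,
                               n_negative = NULL, seed = config$seed) {
  if (!(pos_score > 700 && 700 >= neg_score))
    stop_cv("need pos_score > 700 >= neg_score")
  info <- synth_concepts(config)
  pos <- do.call(rbind, lapply(split(info$token, info$cluster), function(toks) {
    if (length(toks) < 2L) return(NULL)
    cmb <- utils::combn(toks, 2L)
    data.frame(protein1 = cmb[1L, ], protein2 = cmb[2L, ],
               stringsAsFactors = FALSE)
  }))
  rownames(pos) <- NULL
  n_neg <- n_negative %||% nrow(pos)
  pos_key <- paste(pmin(pos$protein1, pos$protein2),
                   pmax(pos$protein1, pos$protein2), sep = "\t")
  neg <- with_seed(seed + 17L, {
    keys <- character(0)
    while (length(keys) < n_neg) {
      a <- info$token[sample.int(nrow(info), 2L * n_neg + 8L, replace = TRUE)]
      b <- info$token[sample.int(nrow(info), 2L * n_neg + 8L, replace = TRUE)]
      k <- paste(pmin(a, b), pmax(a, b), sep = "\t")
      ok <- a != b & !(k %in% pos_key) & !(k %in% keys)
      keys <- c(keys, unique(k[ok]))
    }
    keys <- keys[seq_len(n_neg)]
    parts <- strsplit(keys, "\t", fixed = TRUE)
    data.frame(protein1 = vapply(parts, `[`, "", 1L),
               protein2 = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  })
  out <- rbind(cbind(pos, experimental = pos_score, combined_score = pos_score),
               cbind(neg, experimental = neg_score, combined_score = neg_score))
  rownames(out) <- NULL
  out
}

drug_token_pool <- function(n, offset = 0L) {
  concept_token("Chemical", sprintf("MESH:C9%05d", offset + seq_len(n)))
}

#' Latent interaction group of a synthetic drug concept
#'
#' The planted class-determining attribute of a synthetic drug: the numeric
#' part of its identifier modulo 5. In the concept-dependent DDI corpus the
#' label is a function of the two drugs' groups, so it is recoverable from
#' concept vectors that encode the group but not from surface tokens of
#' held-out drugs.
#'
#' @param drug_token synthetic drug concept token
#'   (`Chemical_MESH_C9xxxxx`).
#' @return integer group in `0..4`.
#' @export
ddi_drug_group <- function(drug_token) {
  num <- suppressWarnings(as.integer(sub("^Chemical_MESH_C", "", drug_token)))
  if (anyNA(num)) stop_cv("not a synthetic drug concept token")
  num %% 5L
}

#' Templated DDI sentence corpus
#'
#' Generates balanced five-class drug-drug interaction instances with two
#' synthetic drug mentions each. In trigger mode (`concept_dependent =
#' FALSE`) a class-specific trigger token determines the label, so sentence
#' features alone suffice. In concept-dependent mode the label is a
#' function of the two drug concepts (`(group1 + group2) mod 5`, see
#' [ddi_drug_group()]) and the trigger slot is filled at random, so
#' sentence-only features carry no label signal for held-out drugs.
#'
#' @param n_per_class instances per class (>= 1).
#' @param concept_dependent switch between the two planted mechanisms.
#' @param seed integer seed.
#' @param n_drugs size of the synthetic drug pool.
#' @param drug_offset offset into the drug id space, for generating train
#'   and test corpora over disjoint drug pools.
#' @param path optional JSON-lines output file.
#' @return list of `ddi_instance` objects (invisibly when written).
#' @export
generate_ddi_corpus <- function(n_per_class = 40L, concept_dependent = FALSE,
                                seed = 1L, n_drugs = 20L, drug_offset = 0L,
                                path = NULL) {
  if (n_per_class < 1L) stop_cv("n_per_class must be at least 1")
  drugs <- drug_token_pool(n_drugs, drug_offset)
  triggers <- c(mechanism = "metabolism", effect = "potentiates",
                advice = "avoid", int = "interacts", negative = "unrelated")
  fillers <- c("the", "combination", "of", "therapy", "patients", "clinical",
               "dose", "study", "reported", "with", "treatment", "observed")
  instances <- list()
  with_seed(seed, {
    for (cls in DDI_CLASSES) {
      for (r in seq_len(n_per_class)) {
        if (concept_dependent) {
          repeat {
            pair <- drugs[sample.int(length(drugs), 2L)]
            g <- sum(ddi_drug_group(pair)) %% 5L
            if (DDI_CLASSES[g + 1L] == cls) break
          }
          mid <- unname(triggers[sample.int(5L, 1L)])
        } else {
          pair <- drugs[sample.int(length(drugs), 2L)]
          mid <- unname(triggers[[cls]])
        }
        tokens <- c(fillers[sample.int(length(fillers), 2L, replace = TRUE)],
                    pair[1L],
                    fillers[sample.int(length(fillers), 2L, replace = TRUE)],
                    mid,
                    fillers[sample.int(length(fillers), 2L, replace = TRUE)],
                    pair[2L],
                    fillers[sample.int(length(fillers), 1L, replace = TRUE)])
        instances[[length(instances) + 1L]] <-
          ddi_instance(sprintf("synddi_%s_%03d", cls, r), tokens,
                       drug1_index = 3L, drug1_id = pair[1L],
                       drug2_index = 9L, drug2_id = pair[2L], label = cls)
      }
    }
    instances <- instances[sample.int(length(instances))]
  })
  if (is.null(path)) return(instances)
  write_ddi_jsonl(instances, path)
  invisible(instances)
}

#' Planted separable embedding for the synthetic clusters
#'
#' Each concept vector is its cluster's random unit centroid plus isotropic
#' noise, so within-cluster pairs are close and the concatenated pair
#' features are separable by construction. Used to exercise the evaluation
#' harnesses independently of the trainers.
#'
#' @param config a [synth_config()].
#' @param dim embedding dimension (default 16).
#' @param noise noise standard deviation around the centroid (default 0.15).
#' @param seed integer seed.
#' @return named vector matrix over the planted concept tokens.
#' @export
planted_embedding <- function(config, dim = 16L, noise = 0.15,
                              seed = config$seed) {
  info <- synth_concepts(config)
  with_seed(seed, {
    centers <- matrix(rnorm(config$n_clusters * dim), config$n_clusters)
    centers <- centers / sqrt(rowSums(centers^2))
    out <- centers[info$cluster, , drop = FALSE] +
      noise * matrix(rnorm(nrow(info) * dim), nrow(info))
    rownames(out) <- info$token
    out
  })
}

#' Independent random token embedding
#'
#' I.i.d. random unit vectors, one per token: the null embedding that
#' carries no relatedness signal. Also serves as a generic static word
#' embedder for synthetic sentences.
#'
#' @param tokens character vector of tokens.
#' @param dim embedding dimension.
#' @param seed integer seed.
#' @return named vector matrix.
#' @export
random_unit_embedding <- function(tokens, dim = 50L, seed = 1L) {
  tokens <- unique(tokens)
  with_seed(seed, {
    m <- matrix(rnorm(length(tokens) * dim), length(tokens))
    m <- m / sqrt(rowSums(m^2))
    rownames(m) <- tokens
    m
  })
}

#' Concept embedding encoding the planted drug groups
#'
#' Drug vectors are a one-hot encoding of the latent group (see
#' [ddi_drug_group()]) plus noise: concept features that expose exactly the
#' information the concept-dependent DDI labels depend on.
#'
#' @param drug_tokens drug concept tokens.
#' @param dim embedding dimension (>= 5).
#' @param noise noise standard deviation.
#' @param seed integer seed.
#' @return named vector matrix.
#' @export
ddi_concept_embedding <- function(drug_tokens, dim = 10L, noise = 0.05,
                                  seed = 1L) {
  stopifnot(dim >= 5L)
  drug_tokens <- unique(drug_tokens)
  g <- ddi_drug_group(drug_tokens)
  with_seed(seed, {
    m <- noise * matrix(rnorm(length(drug_tokens) * dim), length(drug_tokens))
    m[cbind(seq_along(drug_tokens), g + 1L)] <-
      m[cbind(seq_along(drug_tokens), g + 1L)] + 1
    rownames(m) <- drug_tokens
    m
  })
}
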