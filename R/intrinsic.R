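## intrinsic evaluation: related/unrelated groups and the group-level
## similarity-difference statistic

#' Read a GMT gene-set file
#'
#' MSigDB-style format: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file path.
#' @return named list of character vectors (set members); descriptions kept
#'   as the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop_cv("malformed GMT line %d: expected name, description and >= 1 member",
            bad[1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "descriptions") <- vapply(parts, `[`, "", 2L)
  sets
}

#' Read a drug-gene interaction table
#'
#' CTD-style two-column TSV (`drug_id<TAB>gene_id`, optional header).
#'
#' @param path TSV file path.
#' @param header does the file carry a header line?
#' @return named list: drug id to character vector of interacting gene ids.
#' @export
read_drug_gene <- function(path, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          col.names = if (header) NULL else c("drug_id", "gene_id"),
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  lapply(split(df[[2]], df[[1]]), unique)
}

#' Build related/unrelated concept groups
#'
#' For each entity (a drug, a gene set, ...), the related set is its
#' membership intersected with the shared-vocabulary universe (a seeded
#' random subset of size `cap` when larger), and the unrelated set is a
#' seeded uniform sample, of equal size, from the universe minus the
#' entity's full membership. Entities with fewer than two usable members
#' yield no group (no within-set pair exists); entities whose complement is
#' too small to sample from are skipped with a warning.
#'
#' @param membership named list: entity id to character vector of concept ids.
#' @param universe character vector of eligible concept ids (typically the
#'   embedding vocabulary shared across compared methods).
#' @param cap maximum related-set size (default 100).
#' @param seed integer seed for the random subsets and unrelated samples.
#' @return a `group_dataset`: list with `groups` (each `group_id`, `related`,
#'   `unrelated`), `universe`, `n_skipped`, `seed`.
#' @export
build_groups <- function(membership, universe, cap = 100L, seed = 1L) {
  universe <- unique(universe)
  groups <- list()
  n_skipped <- 0L
  with_seed(seed, {
    for (ent in names(membership)) {
      related <- intersect(membership[[ent]], universe)
      if (length(related) > cap)
        related <- sample(related, cap)
      if (length(related) < 2L) { n_skipped <- n_skipped + 1L; next }
      candidates <- setdiff(universe, membership[[ent]])
      if (length(candidates) < length(related)) {
        warning(sprintf("group %s skipped: only %d non-member concepts available for %d related",
                        ent, length(candidates), length(related)), call. = FALSE)
        n_skipped <- n_skipped + 1L
        next
      }
      unrelated <- sample(candidates, length(related))
      groups[[length(groups) + 1L]] <-
        list(group_id = ent, related = related, unrelated = unrelated)
    }
  })
  structure(list(groups = groups, universe = universe,
                 n_skipped = n_skipped, seed = seed),
            class = "group_dataset")
}

#' @method print group_dataset
#' @export
print.group_dataset <- function(x, ...) {
  sizes <- vapply(x$groups, function(g) length(g$related), 0L)
  cat(sprintf("<group_dataset: %d group(s), %d skipped, universe %d, mean set size %.1f>\n",
              length(x$groups), x$n_skipped, length(x$universe),
              if (length(sizes)) mean(sizes) else 0))
  invisible(x)
}

#' Normalize raw pair similarities
#'
#' Z-score standardization over all pairs of the dataset for one embedding,
#' followed by min-max normalization to `[0, 1]`. Both transforms are
#' affine, so the result is invariant under positive affine transforms of
#' the raw scores and order-preserving.
#'
#' @param raw numeric vector of raw cosine similarities (>= 2 values; names,
#'   typically pair keys, are preserved).
#' @return normalized scores spanning exactly `[0, 1]`.
#' @export
normalize_pair_scores <- function(raw) {
  if (length(raw) < 2L) stop_cv("need at least two pair scores to normalize")
  s <- sd(raw)
  if (s == 0)
    stop_cv("degenerate pair scores: all raw similarities are equal")
  z <- (raw - mean(raw)) / s
  (z - min(z)) / (max(z) - min(z))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\t")

within_set_pairs <- function(concepts) {
  cmb <- utils::combn(sort(concepts), 2L)
  pair_key(cmb[1L, ], cmb[2L, ])
}

#' Mean pairwise similarity of a concept set
#'
#' Arithmetic mean of the normalized scores of all `choose(n, 2)` unordered
#' within-set pairs.
#'
#' @param concepts character vector of >= 2 concept ids.
#' @param scores named numeric vector of (normalized) pair scores, names
#'   built by `pair_key` (sorted ids joined by a tab); as produced inside
#'   [group_similarity_difference()].
#' @return the mean score.
#' @export
set_similarity <- function(concepts, scores) {
  if (length(concepts) < 2L)
    stop_cv("set similarity needs at least two concepts")
  keys <- within_set_pairs(concepts)
  missing <- setdiff(keys, names(scores))
  if (length(missing))
    stop_cv("missing pair score(s): %s",
            paste(gsub("\t", " - ", missing[seq_len(min(3, length(missing)))]),
                  collapse = ", "))
  mean(scores[keys])
}

## raw cosines for every within-set pair of every group, named by pair key
collect_raw_pair_scores <- function(dataset, vecs) {
  concepts <- unique(unlist(lapply(dataset$groups,
                                   function(g) c(g$related, g$unrelated)),
                            use.names = FALSE))
  missing <- setdiff(concepts, rownames(vecs))
  if (length(missing))
    stop_cv("concept(s) missing from the embedding: %s%s",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5) else "")
  cos <- pairwise_cosine(vecs[concepts, , drop = FALSE])
  keys <- unique(unlist(lapply(dataset$groups, function(g)
    c(within_set_pairs(g$related), within_set_pairs(g$unrelated))),
    use.names = FALSE))
  ab <- strsplit(keys, "\t", fixed = TRUE)
  a <- vapply(ab, `[`, "", 1L)
  b <- vapply(ab, `[`, "", 2L)
  stats::setNames(cos[cbind(match(a, concepts), match(b, concepts))], keys)
}

#' Group-level similarity difference of an embedding
#'
#' The intrinsic relatedness statistic: all within-set pair cosines of the
#' dataset are normalized once (Z-score then min-max, per dataset and
#' embedding), each group contributes `set_similarity(related) -
#' set_similarity(unrelated)`, and the mean over groups is reported in
#' percentage points. Higher values mean the embedding separates related
#' concept sets from matched random sets more strongly; an uninformative
#' embedding scores near 0.
#'
#' @param dataset a `group_dataset` from [build_groups()].
#' @param embedding a `concept_embeddings` object or named vector matrix
#'   covering all dataset concepts.
#' @return list with `metric` (mean difference x 100), `per_group` data
#'   frame (`group_id`, `related_similarity`, `unrelated_similarity`,
#'   `difference`), `n_groups`.
#' @export
group_similarity_difference <- function(dataset, embedding) {
  if (!length(dataset$groups)) stop_cv("dataset has no groups")
  vecs <- embedding_vectors(embedding)
  raw <- collect_raw_pair_scores(dataset, vecs)
  scores <- normalize_pair_scores(raw)
  per_group <- do.call(rbind, lapply(dataset$groups, function(g) {
    rs <- set_similarity(g$related, scores)
    us <- set_similarity(g$unrelated, scores)
    data.frame(group_id = g$group_id, related_similarity = rs,
               unrelated_similarity = us, difference = rs - us,
               stringsAsFactors = FALSE)
  }))
  list(metric = 100 * mean(per_group$difference), per_group = per_group,
       n_groups = nrow(per_group))
}

#' Label-shuffled baseline of the intrinsic statistic
#'
#' Recomputes the group similarity difference after randomly permuting the
#' concept-to-vector assignment over the dataset universe, and averages over
#' `n_perm` permutations. Under shuffling, related and unrelated sets are
#' exchangeable, so the statistic is centered at 0; the averaged estimate is
#' the permutation-null baseline an informative embedding must exceed.
#'
#' @param dataset a `group_dataset`.
#' @param embedding embedding covering the dataset universe.
#' @param n_perm number of permutations averaged (default 50).
#' @param seed integer seed.
#' @return list with `metric` (mean over permutations, percentage points)
#'   and `per_perm` (the individual permutation values).
#' @export
shuffled_baseline <- function(dataset, embedding, n_perm = 50L, seed = 1L) {
  vecs <- embedding_vectors(embedding)
  universe <- dataset$universe
  missing <- setdiff(universe, rownames(vecs))
  if (length(missing))
    stop_cv("universe concept(s) missing from the embedding: %s",
            paste(head(missing, 5), collapse = ", "))
  base <- vecs[universe, , drop = FALSE]
  vals <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    shuffled <- base[sample(nrow(base)), , drop = FALSE]
    rownames(shuffled) <- universe
    group_similarity_difference(dataset, shuffled)$metric
  }, 0))
  list(metric = mean(vals), per_perm = vals)
}
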