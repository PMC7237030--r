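## concept-level vector utilities: cosine, averaged-name baseline, coverage

#' Cosine similarity
#'
#' @param u,v non-zero numeric vectors of equal dimension.
#' @return `u . v / (|u| |v|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop_cv("vectors differ in dimension")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop_cv("cosine similarity is undefined for a zero-norm vector")
  sum(u * v) / (nu * nv)
}

## all pairwise cosines among the rows of a matrix, as a dense symmetric matrix
pairwise_cosine <- function(mat) {
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) stop_cv("zero-norm vector in cosine computation")
  normed <- mat / norms
  tcrossprod(normed)
}

#' Read a concept-name map
#'
#' TSV with two columns: concept id, tab, descriptive name. Names are
#' tokenized with the corpus preprocessing rules so that name words line up
#' with word-embedding vocabularies.
#'
#' @param path TSV file path.
#' @param lowercase lowercase name words (default `TRUE`).
#' @return named list: concept id to character vector of name words.
#' @export
read_concept_names <- function(path, lowercase = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop_cv("malformed concept-name line %d: expected 'id<TAB>name'", bad[1])
  ids <- vapply(parts, `[`, "", 1L)
  words <- lapply(parts, function(p) tokenize_plain(p[2], lowercase))
  if (any(lengths(words) == 0L))
    stop_cv("concept %s has an empty name after preprocessing",
            ids[which(lengths(words) == 0L)[1]])
  stats::setNames(words, ids)
}

#' Averaged-name concept vector baseline
#'
#' Represents a concept by the unweighted mean of the word vectors of its
#' descriptive name (e.g. "torsin family 3 member A"), the standard baseline
#' when a word embedding has no entry for the normalized concept itself.
#' Name words missing from the word embedding are dropped; a fully
#' out-of-vocabulary name is an error because the concept is unrepresentable.
#'
#' @param concept_id concept identifier present in `names_map`.
#' @param names_map named list from [read_concept_names()], or a character
#'   vector of name words.
#' @param words word embedding (matrix with word rownames, or
#'   `concept_embeddings`).
#' @return the mean vector, with attribute `n_dropped` (count of
#'   out-of-vocabulary name words).
#' @export
average_name_vector <- function(concept_id, names_map, words) {
  name_words <- if (is.list(names_map)) {
    if (is.null(names_map[[concept_id]]))
      stop_cv("no name on record for concept %s", dQuote(concept_id))
    names_map[[concept_id]]
  } else as.character(names_map)
  vecs <- embedding_vectors(words)
  present <- name_words %in% rownames(vecs)
  if (!any(present))
    stop_cv("concept %s is unrepresentable: none of its %d name word(s) are in the word embedding",
            dQuote(concept_id), length(name_words))
  out <- colMeans(vecs[name_words[present], , drop = FALSE])
  attr(out, "n_dropped") <- sum(!present)
  out
}

#' Cross-embedding vocabulary coverage of a concept set
#'
#' For each named vocabulary source, counts how many target concepts it
#' contains, and reports each source's share of the union of covered
#' concepts.
#'
#' @param vocabularies named list of character vectors (token sets).
#' @param targets character vector of concept ids of interest.
#' @return data frame with columns `source`, `covered`, `share`, plus
#'   attribute `union_count`.
#' @export
vocabulary_coverage <- function(vocabularies, targets) {
  if (!length(targets)) stop_cv("target concept set is empty")
  targets <- unique(targets)
  covered_sets <- lapply(vocabularies, function(v) intersect(targets, v))
  union_count <- length(unique(unlist(covered_sets, use.names = FALSE)))
  out <- data.frame(source = names(vocabularies),
                    covered = lengths(covered_sets),
                    share = if (union_count > 0)
                      lengths(covered_sets) / union_count else 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "union_count") <- union_count
  out
}
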