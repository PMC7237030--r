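## corpus ingestion: PubTator parsing, overlap resolution, concept substitution

#' Preprocessing rules for corpus construction
#'
#' Controls how annotated abstracts are rewritten into training sentences.
#' Non-concept text is lowercased and punctuation is mapped to token
#' boundaries (digits are kept); concept tokens are emitted case-preserved.
#'
#' @param lowercase lowercase non-concept text before tokenization.
#' @param split_sentences emit one sentence per line so that training windows
#'   never cross sentence boundaries; set `FALSE` to keep each abstract as a
#'   single window (both conventions are seen in the literature and the choice
#'   is deliberately exposed).
#' @param dialect offset convention of the PubTator file: annotation offsets
#'   counted over `title + "\n" + abstract` (`"newline"`) or
#'   `title + " " + abstract` (`"space"`). Both exist in the wild.
#' @return an object of class `corpus_rules`.
#' @export
corpus_rules <- function(lowercase = TRUE, split_sentences = TRUE,
                         dialect = c("newline", "space")) {
  dialect <- match.arg(dialect)
  structure(list(lowercase = isTRUE(lowercase),
                 split_sentences = isTRUE(split_sentences),
                 dialect = dialect),
            class = "corpus_rules")
}

doc_separator <- function(dialect) if (dialect == "space") " " else "\n"

#' Full text of an annotated document
#'
#' Title and abstract concatenated in the coordinate space the annotation
#' offsets refer to (0-based, end-exclusive).
#' @param doc a `pubtator_document`.
#' @param dialect offset convention, see [corpus_rules()].
#' @return a single string.
#' @export
document_text <- function(doc, dialect = c("newline", "space")) {
  dialect <- match.arg(dialect)
  paste(doc$title, doc$abstract, sep = doc_separator(dialect))
}

empty_annotations <- function() {
  data.frame(start = integer(0), end = integer(0), mention = character(0),
             type = character(0), concept_id = character(0),
             stringsAsFactors = FALSE)
}

new_pubtator_document <- function(doc_id, title, abstract, annotations) {
  structure(list(doc_id = doc_id, title = title, abstract = abstract,
                 annotations = annotations),
            class = "pubtator_document")
}

#' @method print pubtator_document
#' @export
print.pubtator_document <- function(x, ...) {
  cat(sprintf("<pubtator_document %s: %d annotation(s), %d chars>\n",
              x$doc_id, nrow(x$annotations),
              nchar(x$title) + nchar(x$abstract) + 1L))
  invisible(x)
}

#' Parse PubTator-format annotated abstracts
#'
#' Reads the line-oriented PubTator dialect: a `PMID|t|title` line, a
#' `PMID|a|abstract` line, then tab-separated annotation lines
#' (`pmid, start, end, mention, type, concept_id`); documents are separated
#' by blank lines. Every annotation is checked against the text: a mention
#' that does not equal the referenced character slice is an integrity error,
#' because downstream substitution would silently corrupt the corpus.
#'
#' @param input path to a PubTator file, or a character vector of lines
#'   (anything containing a newline is treated as raw text).
#' @param dialect offset convention, see [corpus_rules()].
#' @return a list of `pubtator_document` objects, annotations sorted by
#'   `(start, end)`.
#' @export
parse_pubtator <- function(input, dialect = c("newline", "space")) {
  dialect <- match.arg(dialect)
  lines <- if (length(input) == 1L && !grepl("\n", input) &&
               file.exists(input)) readLines(input, warn = FALSE)
           else if (length(input) == 1L && grepl("\n", input))
             strsplit(input, "\n", fixed = TRUE)[[1]]
           else as.character(input)

  docs <- list()
  block <- list(doc_id = NULL, title = NULL, abstract = "",
                ann = list(), ann_lines = integer(0))
  flush_block <- function(block) {
    if (is.null(block$doc_id)) return(NULL)
    ann <- if (length(block$ann)) do.call(rbind, block$ann) else empty_annotations()
    if (nrow(ann)) {
      ann <- ann[order(ann$start, ann$end, match(ann$type, names(TYPE_PRIORITY)),
                       ann$concept_id), , drop = FALSE]
      rownames(ann) <- NULL
    }
    doc <- new_pubtator_document(block$doc_id, block$title %||% "",
                                 block$abstract, ann)
    text <- document_text(doc, dialect)
    n <- nchar(text)
    for (k in seq_len(nrow(ann))) {
      s <- ann$start[k]; e <- ann$end[k]
      if (s < 0L || e <= s || e > n)
        stop_cv("integrity error in document %s: span [%d,%d) outside text of length %d",
                doc$doc_id, s, e, n)
      slice <- substr(text, s + 1L, e)
      if (!identical(slice, ann$mention[k]))
        stop_cv("integrity error in document %s: mention %s != text slice %s at [%d,%d)",
                doc$doc_id, dQuote(ann$mention[k]), dQuote(slice), s, e)
    }
    doc
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) {
      d <- flush_block(block)
      if (!is.null(d)) docs[[length(docs) + 1L]] <- d
      block <- list(doc_id = NULL, title = NULL, abstract = "",
                    ann = list(), ann_lines = integer(0))
      next
    }
    m <- regmatches(ln, regexec("^([^|\t]+)\\|([ta])\\|(.*)$", ln))[[1]]
    if (length(m) == 4L) {
      if (is.null(block$doc_id)) block$doc_id <- m[2]
      if (m[3] == "t") block$title <- m[4] else block$abstract <- m[4]
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 6L)
      stop_cv("parse error at line %d: expected 6 tab-separated fields, got %d",
              i, length(fields))
    if (!fields[5] %in% CONCEPT_TYPES)
      stop_cv("parse error at line %d: unknown concept type %s", i, dQuote(fields[5]))
    start <- suppressWarnings(as.integer(fields[2]))
    end <- suppressWarnings(as.integer(fields[3]))
    if (is.na(start) || is.na(end))
      stop_cv("parse error at line %d: non-integer offsets", i)
    block$ann[[length(block$ann) + 1L]] <- data.frame(
      start = start, end = end, mention = fields[4], type = fields[5],
      concept_id = fields[6], stringsAsFactors = FALSE)
  }
  d <- flush_block(block)
  if (!is.null(d)) docs[[length(docs) + 1L]] <- d
  docs
}

#' Serialize documents back to PubTator format
#'
#' Inverse of [parse_pubtator()]: `parse_pubtator(write_pubtator(docs))`
#' reproduces the documents exactly.
#'
#' @param docs list of `pubtator_document` objects.
#' @param path optional file path; when `NULL` the lines are returned.
#' @return character vector of lines (invisibly when written to `path`).
#' @export
write_pubtator <- function(docs, path = NULL) {
  out <- unlist(lapply(docs, function(d) {
    ann <- d$annotations
    ann_lines <- if (nrow(ann))
      sprintf("%s\t%d\t%d\t%s\t%s\t%s", d$doc_id, ann$start, ann$end,
              ann$mention, ann$type, ann$concept_id)
    else character(0)
    c(sprintf("%s|t|%s", d$doc_id, d$title),
      sprintf("%s|a|%s", d$doc_id, d$abstract),
      ann_lines, "")
  }), use.names = FALSE)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Resolve overlapping annotations deterministically
#'
#' Among overlapping candidate spans the longest wins; ties are broken by
#' earliest start, then by a fixed type priority
#' (Gene > Mutation > Chemical > Disease > CellLine > Species), then by
#' lexicographic concept id. The result is a pairwise-disjoint set of spans
#' and the operation is idempotent.
#'
#' @param annotations annotation data frame (columns `start`, `end`,
#'   `mention`, `type`, `concept_id`), sorted by `(start, end)`.
#' @return annotation data frame with pairwise-disjoint spans, sorted by
#'   `(start, end)`.
#' @export
resolve_overlaps <- function(annotations) {
  if (!nrow(annotations)) return(annotations)
  len <- annotations$end - annotations$start
  pri <- TYPE_PRIORITY[annotations$type]
  ord <- order(-len, annotations$start, -pri,
               annotations$concept_id, method = "radix")
  kept <- integer(0)
  for (k in ord) {
    s <- annotations$start[k]; e <- annotations$end[k]
    clash <- any(annotations$start[kept] < e & s < annotations$end[kept])
    if (!clash) kept <- c(kept, k)
  }
  out <- annotations[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalized concept token for a typed identifier
#'
#' The token substituted for an annotated mention: the concept type joined to
#' the identifier with every non-alphanumeric character of the identifier
#' mapped to an underscore, e.g. `("Disease", "MESH:D008288")` becomes
#' `"Disease_MESH_D008288"`.
#'
#' @param concept_type one of Gene, Disease, Chemical, Mutation, Species,
#'   CellLine (vectorized).
#' @param concept_id non-empty identifier string (vectorized).
#' @return character vector of concept tokens.
#' @export
concept_token <- function(concept_type, concept_id) {
  if (any(!concept_type %in% CONCEPT_TYPES))
    stop_cv("unknown concept type(s): %s",
            paste(setdiff(concept_type, CONCEPT_TYPES), collapse = ", "))
  if (any(!nzchar(concept_id)) || any(is.na(concept_id)))
    stop_cv("concept_id must be non-empty")
  paste0(concept_type, "_", gsub("[^A-Za-z0-9]", "_", concept_id))
}

#' Does a token look like a concept token?
#'
#' Fallback pattern match used when the `is_concept` flag from corpus
#' construction is unavailable (e.g. embeddings loaded from disk).
#' @param token character vector.
#' @return logical vector.
#' @export
is_concept_token <- function(token) {
  grepl(paste0("^(", paste(CONCEPT_TYPES, collapse = "|"), ")_."), token)
}

tokenize_plain <- function(text, lowercase = TRUE) {
  if (lowercase) text <- tolower(text)
  toks <- strsplit(gsub("[^[:alnum:]]+", " ", text), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

## split a non-annotated text segment at sentence-final punctuation followed
## by whitespace; returns the pieces (boundaries lie between them)
split_segment <- function(segment) {
  strsplit(segment, "(?<=[.!?])[\"')\\]]*\\s+", perl = TRUE)[[1]]
}

#' Substitute concept tokens and tokenize one document
#'
#' Rewrites an annotated document into sentences of training tokens: each
#' resolved annotation span becomes exactly one case-preserved concept token,
#' and the non-annotated text between spans is sentence-split, lowercased and
#' punctuation-stripped according to `rules`. Annotation spans are never
#' split: a span over a sentence boundary keeps its sentences merged.
#'
#' @param doc a `pubtator_document` whose annotations are overlap-resolved
#'   (this is checked).
#' @param rules a [corpus_rules()] object.
#' @return a `tokenized_document`: list with `doc_id`, `sentences` (list of
#'   character vectors) and `concept_flags` (parallel list of logicals).
#' @export
substitute_and_tokenize <- function(doc, rules = corpus_rules()) {
  ann <- doc$annotations
  if (nrow(ann) > 1L) {
    disjoint <- all(ann$start[-1L] >= ann$end[-nrow(ann)])
    if (!disjoint)
      stop_cv("document %s has overlapping annotations; run resolve_overlaps() first",
              doc$doc_id)
  }
  text <- document_text(doc, rules$dialect)

  sentences <- list(); flags <- list()
  cur <- character(0); cur_f <- logical(0)
  flush <- function() {
    if (length(cur)) {
      sentences[[length(sentences) + 1L]] <<- cur
      flags[[length(flags) + 1L]] <<- cur_f
      cur <<- character(0); cur_f <<- logical(0)
    }
  }
  emit_segment <- function(segment) {
    if (!nzchar(segment)) return(invisible())
    pieces <- if (rules$split_sentences) split_segment(segment) else segment
    for (p in seq_along(pieces)) {
      toks <- tokenize_plain(pieces[p], rules$lowercase)
      cur <<- c(cur, toks); cur_f <<- c(cur_f, rep(FALSE, length(toks)))
      if (rules$split_sentences && p < length(pieces)) flush()
    }
    ## a segment ending in sentence-final punctuation + whitespace closes the
    ## sentence even when the next token is an annotation
    if (rules$split_sentences &&
        grepl("[.!?][\"')\\]]*\\s+$", segment, perl = TRUE)) flush()
    invisible()
  }

  pos <- 0L
  for (k in seq_len(nrow(ann))) {
    emit_segment(substr(text, pos + 1L, ann$start[k]))
    cur <- c(cur, concept_token(ann$type[k], ann$concept_id[k]))
    cur_f <- c(cur_f, TRUE)
    pos <- ann$end[k]
  }
  emit_segment(substr(text, pos + 1L, nchar(text)))
  flush()

  structure(list(doc_id = doc$doc_id, sentences = sentences,
                 concept_flags = flags),
            class = "tokenized_document")
}

#' Build a tokenized training corpus from annotated documents
#'
#' Applies [resolve_overlaps()] and [substitute_and_tokenize()] to every
#' document and pools the sentences.
#'
#' @param docs list of `pubtator_document` objects (from [parse_pubtator()]).
#' @param rules a [corpus_rules()] object.
#' @return a `concept_corpus`: list with `sentences` (list of character
#'   vectors), `concept_flags` (parallel list of logicals) and `doc_ids`
#'   (per-sentence document id).
#' @export
tokenize_corpus <- function(docs, rules = corpus_rules()) {
  sentences <- list(); flags <- list(); ids <- character(0)
  for (doc in docs) {
    doc$annotations <- resolve_overlaps(doc$annotations)
    td <- substitute_and_tokenize(doc, rules)
    sentences <- c(sentences, td$sentences)
    flags <- c(flags, td$concept_flags)
    ids <- c(ids, rep(doc$doc_id, length(td$sentences)))
  }
  structure(list(sentences = sentences, concept_flags = flags, doc_ids = ids),
            class = "concept_corpus")
}

#' @method print concept_corpus
#' @export
print.concept_corpus <- function(x, ...) {
  n_tok <- sum(lengths(x$sentences))
  n_con <- sum(unlist(x$concept_flags, use.names = FALSE))
  cat(sprintf("<concept_corpus: %d sentence(s), %d token(s), %d concept token(s)>\n",
              length(x$sentences), n_tok, n_con))
  invisible(x)
}

#' Write a corpus as plain text plus a vocabulary report
#'
#' Emits `corpus.txt` (one sentence per line, space-separated tokens) and
#' `vocab.tsv` (token, count, is_concept) under `dir`.
#'
#' @param corpus a `concept_corpus`.
#' @param dir output directory, created if missing.
#' @return invisibly, the two file paths.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  corpus_path <- file.path(dir, "corpus.txt")
  vocab_path <- file.path(dir, "vocab.tsv")
  writeLines(vapply(corpus$sentences, paste, "", collapse = " "), corpus_path)
  v <- build_vocab(corpus, min_count = 1L)
  utils::write.table(v, vocab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(corpus = corpus_path, vocab = vocab_path))
}
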