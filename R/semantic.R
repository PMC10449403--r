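# Semantic-information metrics: median description length, lexical entropy,
# mean pairwise embedding distance.

#' Frozen English stopword list
#'
#' Returns the stopword list shipped with the package: a snapshot of a
#' standard English function-word list, frozen in `inst/extdata/` so results
#' never depend on an external resource. Spatial prepositions that carry
#' scene-relevant content ("over", "under", "above", "below", "behind") are
#' deliberately retained as content words and are absent from the list.
#'
#' @return character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "scenebudget",
                      mustWork = TRUE)
  words <- readLines(path, encoding = "UTF-8")
  words <- trimws(words)
  words[nzchar(words) & !startsWith(words, "#")]
}

#' Tokenize a description
#'
#' Lowercases, replaces punctuation with spaces (so hyphenated words split at
#' the hyphen), splits on whitespace, and drops stopwords. Token order and
#' duplicates are preserved.
#'
#' @param text a character string (possibly empty).
#' @param stopwords character vector of lowercase stopwords.
#' @return character vector of surviving tokens (possibly empty).
#' @examples
#' tokenize("The quick brown fox jumps over the lazy dog")
#' @export
tokenize <- function(text, stopwords = default_stopwords()) {
  if (length(text) != 1 || !is.character(text)) {
    stop("'text' must be a single character string")
  }
  x <- tolower(text)
  x <- gsub("[[:punct:]]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  toks[!(toks %in% stopwords)]
}

#' Description length in words
#'
#' Raw whitespace-delimited word count, before any lowercasing, punctuation
#' stripping or stopword removal, so that length reflects the full utterance.
#' Set `after_tokenization = TRUE` to count surviving tokens instead.
#'
#' @param text a character string.
#' @param after_tokenization count post-tokenization tokens instead of raw words.
#' @param stopwords stopword list used when `after_tokenization = TRUE`.
#' @return non-negative integer word count.
#' @export
description_length <- function(text, after_tokenization = FALSE,
                               stopwords = default_stopwords()) {
  if (length(text) != 1 || !is.character(text)) {
    stop("'text' must be a single character string")
  }
  if (after_tokenization) return(length(tokenize(text, stopwords)))
  words <- strsplit(trimws(text), "\\s+")[[1]]
  sum(nzchar(words))
}

#' Lexical entropy of a description set
#'
#' Pools tokens from all of an image's descriptions, builds a frequency
#' histogram over word types, and returns its Shannon entropy in bits. More
#' unique words, and flatter usage across them, give higher entropy.
#'
#' @param descriptions character vector of descriptions for one image.
#' @param stopwords stopword list for [tokenize()].
#' @return entropy in bits.
#' @export
lexical_entropy <- function(descriptions, stopwords = default_stopwords()) {
  if (length(descriptions) < 1) stop("empty corpus: no descriptions")
  toks <- unlist(lapply(descriptions, tokenize, stopwords = stopwords))
  if (length(toks) == 0) {
    stop("empty corpus: no tokens survive tokenization")
  }
  shannon_entropy(normalize_prob(as.numeric(table(toks)), "token histogram"))
}

#' Embedding table
#'
#' A word-embedding lookup: a numeric matrix with one row per vocabulary word
#' (rownames are the vocabulary). Looking up an out-of-vocabulary word is an
#' error, never a silent default.
#'
#' @param vectors numeric matrix, one row per word, `d >= 2` columns.
#' @param vocabulary character vector of words (defaults to rownames).
#' @return an `embedding_table` object (a matrix with class attribute).
#' @export
embedding_table <- function(vectors, vocabulary = rownames(vectors)) {
  vectors <- as.matrix(vectors)
  if (is.null(vocabulary) || length(vocabulary) != nrow(vectors)) {
    stop("'vocabulary' must name every row of 'vectors'")
  }
  if (ncol(vectors) < 2) stop("embedding dimension must be >= 2")
  if (anyDuplicated(vocabulary)) stop("duplicate words in vocabulary")
  rownames(vectors) <- vocabulary
  class(vectors) <- c("embedding_table", class(vectors))
  vectors
}

lookup_vectors <- function(emb, words) {
  stopifnot(inherits(emb, "embedding_table"))
  miss <- setdiff(unique(words), rownames(emb))
  if (length(miss)) {
    stop("out-of-vocabulary word(s): ", paste(utils::head(miss, 5), collapse = ", "))
  }
  unclass(emb)[words, , drop = FALSE]
}

cosine_distance <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for zero vectors")
  1 - sum(u * v) / (nu * nv)
}

#' Mean pairwise embedding distance of a description set
#'
#' For each description, forms all unordered pairs of surviving token
#' positions (a description with k in-vocabulary tokens contributes
#' `choose(k, 2)` pairs; duplicated tokens contribute zero-distance pairs),
#' computes the cosine distance `1 - cos` for each pair, averages within the
#' description, then averages across descriptions that produced at least one
#' valid pair. Pairs containing an out-of-vocabulary token are skipped.
#'
#' @param descriptions character vector of descriptions for one image.
#' @param emb an [embedding_table()].
#' @param stopwords stopword list for [tokenize()].
#' @return mean cosine distance in `[0, 2]`.
#' @export
mean_pairwise_distance <- function(descriptions, emb,
                                   stopwords = default_stopwords()) {
  if (length(descriptions) < 1) stop("empty corpus: no descriptions")
  per_desc <- vapply(descriptions, function(d) {
    toks <- tokenize(d, stopwords)
    toks <- toks[toks %in% rownames(emb)]
    k <- length(toks)
    if (k < 2) return(NA_real_)
    v <- lookup_vectors(emb, toks)
    nrm <- sqrt(rowSums(v^2))
    if (any(nrm == 0)) stop("cosine distance undefined for zero vectors")
    cs <- tcrossprod(v / nrm) # cosine similarity matrix
    d2 <- 1 - cs[upper.tri(cs)]
    mean(d2)
  }, numeric(1), USE.NAMES = FALSE)
  if (all(is.na(per_desc))) {
    stop("no valid pairs: every description has fewer than 2 in-vocabulary tokens")
  }
  mean(per_desc, na.rm = TRUE)
}

#' Semantic features for one image's descriptions
#'
#' @param descriptions character vector of descriptions for one image.
#' @param emb an [embedding_table()].
#' @param stopwords stopword list.
#' @param image_id identifier attached to the output and to error messages.
#' @param length_after_tokenization count description length after
#'   tokenization instead of raw words.
#' @return one-row data.frame with columns `image_id`, `median_length`,
#'   `lexical_entropy`, `mean_pairwise_distance`.
#' @export
aggregate_semantic_features <- function(descriptions, emb,
                                        stopwords = default_stopwords(),
                                        image_id = "image",
                                        length_after_tokenization = FALSE) {
  if (length(descriptions) < 2) {
    stop("image '", image_id, "': need at least 2 descriptions")
  }
  res <- tryCatch({
    lens <- vapply(descriptions, description_length, numeric(1),
                   after_tokenization = length_after_tokenization,
                   stopwords = stopwords, USE.NAMES = FALSE)
    data.frame(
      image_id = image_id,
      median_length = stats::median(lens),
      lexical_entropy = lexical_entropy(descriptions, stopwords),
      mean_pairwise_distance = mean_pairwise_distance(descriptions, emb,
                                                      stopwords),
      stringsAsFactors = FALSE
    )
  }, error = function(e) {
    stop("image '", image_id, "': ", conditionMessage(e), call. = FALSE)
  })
  res
}

#' Semantic feature table for a description corpus
#'
#' Applies [aggregate_semantic_features()] per image. Images whose
#' descriptions yield no valid embedding pair are dropped with a warning
#' rather than imputed.
#'
#' @param corpus data.frame with columns `image_id`, `description`, or a
#'   named list of character vectors (one element per image).
#' @param emb an [embedding_table()].
#' @param stopwords stopword list.
#' @param length_after_tokenization see [aggregate_semantic_features()].
#' @return data.frame with columns `image_id`, `median_length`,
#'   `lexical_entropy`, `mean_pairwise_distance`.
#' @export
compute_semantic_features <- function(corpus, emb,
                                      stopwords = default_stopwords(),
                                      length_after_tokenization = FALSE) {
  if (is.data.frame(corpus)) {
    if (!all(c("image_id", "description") %in% names(corpus))) {
      stop("corpus data.frame needs columns 'image_id' and 'description'")
    }
    corpus <- split(as.character(corpus$description),
                    as.character(corpus$image_id))
  }
  if (!is.list(corpus) || is.null(names(corpus))) {
    stop("corpus must be a data.frame or a named list of description vectors")
  }
  rows <- list()
  for (id in names(corpus)) {
    row <- tryCatch(
      aggregate_semantic_features(corpus[[id]], emb, stopwords, image_id = id,
                                  length_after_tokenization =
                                    length_after_tokenization),
      error = function(e) {
        warning("dropping image '", id, "': ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(row)) rows[[id]] <- row
  }
  if (length(rows) == 0) stop("no image yielded valid semantic features")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a description corpus
#'
#' CSV files must have columns `image_id,description`; JSON files must map
#' image ids to arrays of strings.
#'
#' @param path CSV or JSON file.
#' @return named list of character vectors, one per image.
#' @export
read_descriptions <- function(path) {
  if (!file.exists(path)) stop("descriptions file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(lapply(x, as.character))
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "description") %in% names(tab))) {
    stop("descriptions CSV needs columns 'image_id' and 'description'")
  }
  split(as.character(tab$description), as.character(tab$image_id))
}

#' Read a plain-text embedding table
#'
#' One word per line followed by its vector components, whitespace-separated
#' (the common plain-text word-vector format). An optional first line with
#' two integers (vocabulary size, dimension) is skipped.
#'
#' @param path text file of word vectors.
#' @return an [embedding_table()].
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop("embeddings file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 2 && !anyNA(suppressWarnings(as.integer(first)))) {
    lines <- lines[-1]
  }
  parts <- strsplit(trimws(lines), "\\s+")
  words <- vapply(parts, `[[`, character(1), 1)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]),
                   numeric(length(parts[[1]]) - 1)))
  embedding_table(vecs, words)
}

#' Write an embedding table as plain text
#'
#' @param emb an [embedding_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_table"))
  m <- unclass(emb)
  lines <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 10, trim = TRUE)),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
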