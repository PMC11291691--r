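# LSA semantic space construction.
#
# The space is built from a corpus of short word responses: a word-by-word
# co-occurrence table whose contexts are whole responses, a log(1 + x)
# transform, a truncated SVD, and unit-normalised word vectors.

#' Build a corpus object from word responses
#'
#' @param responses List of character vectors, one vector per response
#'   context. Tokens are lowercased.
#' @return A `qcla_corpus` list with `responses`, `vocabulary` (sorted unique
#'   words) and `word_frequency` (total token counts).
#' @export
corpus <- function(responses) {
  if (length(responses) == 0L) {
    stop_qcla("corpus: no responses", "qcla_validation_error")
  }
  responses <- lapply(responses, function(r) tolower(r[nzchar(r)]))
  responses <- responses[lengths(responses) > 0L]
  if (length(responses) == 0L) {
    stop_qcla("corpus: all responses empty", "qcla_validation_error")
  }
  tokens <- unlist(responses, use.names = FALSE)
  freq <- table(tokens)
  structure(
    list(
      responses = responses,
      vocabulary = sort(names(freq)),
      word_frequency = setNames(as.integer(freq), names(freq))
    ),
    class = "qcla_corpus"
  )
}

#' Read a corpus from a plain-text file
#'
#' One response per line, whitespace-separated lowercase tokens.
#'
#' @param path Text file path.
#' @return A `qcla_corpus`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- corpus(strsplit(trimws(lines), "\\s+"))
  attr(out, "path") <- path
  out
}

#' Write a corpus to a plain-text file
#'
#' @param x A `qcla_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  writeLines(vapply(x$responses, paste, "", collapse = " "), path)
  invisible(path)
}

#' @export
print.qcla_corpus <- function(x, ...) {
  cat(sprintf(
    "qcla corpus: %d responses, %d unique words, %d tokens\n",
    length(x$responses), length(x$vocabulary),
    sum(x$word_frequency)
  ))
  invisible(x)
}

#' Word-by-word co-occurrence counts over response contexts
#'
#' Each response is a context and counts are context-level: within one
#' response duplicate tokens count once, and a pair co-occurring in several
#' responses counts once per response. Entry (i, j) with i != j is the number
#' of responses containing both words; the diagonal holds the number of
#' responses containing the word.
#'
#' @param x A `qcla_corpus`.
#' @return A symmetric sparse [Matrix::Matrix] indexed by the vocabulary.
#' @export
build_cooccurrence <- function(x) {
  if (!inherits(x, "qcla_corpus")) x <- corpus(x)
  vocab <- x$vocabulary
  # binary response-by-word incidence; crossprod gives context-level counts
  ij <- do.call(rbind, lapply(seq_along(x$responses), function(i) {
    cbind(i, match(unique(x$responses[[i]]), vocab))
  }))
  inc <- Matrix::sparseMatrix(
    i = ij[, 1L], j = ij[, 2L], x = 1,
    dims = c(length(x$responses), length(vocab)),
    dimnames = list(NULL, vocab)
  )
  counts <- Matrix::crossprod(inc)
  methods::as(counts, "CsparseMatrix")
}

#' log(1 + x) transform of a co-occurrence table
#'
#' Elementwise natural `log(1 + count)`; zero cells stay zero, so sparsity
#' and symmetry are preserved.
#'
#' @param m Nonnegative matrix (dense or sparse).
#' @return Matrix of the same shape and sparsity.
#' @export
log_transform <- function(m) {
  if (any(m < 0)) {
    stop_qcla("log_transform: negative entries", "qcla_validation_error")
  }
  if (inherits(m, "sparseMatrix")) {
    m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
    m@x <- log1p(m@x)
    m
  } else {
    log1p(m)
  }
}

# Force the largest-magnitude entry of each left singular vector positive;
# resolves the SVD sign indeterminacy so builds are bit-reproducible.
canonicalize_signs <- function(u) {
  flip <- vapply(seq_len(ncol(u)), function(j) {
    u[which.max(abs(u[, j])), j] < 0
  }, logical(1L))
  u[, flip] <- -u[, flip, drop = FALSE]
  u
}

#' Build the semantic space by truncated SVD
#'
#' Word vectors are the rows of U S (left singular vectors scaled by the
#' singular values, so dimensions are ordered by accounted variance),
#' truncated to the first `k` dimensions and renormalised to unit length.
#' Sign indeterminacy is resolved by forcing the largest-magnitude entry of
#' each singular vector positive, making the build reproducible bit for bit.
#'
#' @param log_matrix The log-transformed co-occurrence matrix, with
#'   vocabulary dimnames (as produced by [log_transform()] on
#'   [build_cooccurrence()] output).
#' @param k Number of leading dimensions to keep (default 300); clamped to
#'   the numerical rank with a logged note when it exceeds it.
#' @param weighting `"us"` (default) scales U by the singular values before
#'   normalising; `"u"` uses the raw left singular vectors.
#' @return A `semantic_space` list: `vocabulary`, `vectors` (one unit-norm
#'   row per word), `singular_values`, `k`, `weighting`.
#' @export
build_space <- function(log_matrix, k = 300L, weighting = c("us", "u")) {
  weighting <- match.arg(weighting)
  vocab <- colnames(log_matrix)
  if (is.null(vocab)) vocab <- as.character(seq_len(ncol(log_matrix)))
  m <- as.matrix(log_matrix)
  if (k < 1L || k > ncol(m)) {
    stop_qcla("build_space: k must be in [1, ncol]", "qcla_validation_error")
  }
  sv <- svd(m)
  rank <- sum(sv$d > max(dim(m)) * .Machine$double.eps * sv$d[1L])
  if (k > rank) {
    qcla_log("k = ", k, " exceeds rank ", rank, "; clamped")
    k <- rank
  }
  u <- canonicalize_signs(sv$u[, seq_len(k), drop = FALSE])
  vectors <- if (weighting == "us") {
    sweep(u, 2L, sv$d[seq_len(k)], "*")
  } else {
    u
  }
  norms <- sqrt(rowSums(vectors^2))
  zero <- norms < .Machine$double.eps
  if (any(zero)) {
    qcla_log(sum(zero), " word(s) with degenerate projection left unnormalised")
    norms[zero] <- 1
  }
  vectors <- vectors / norms
  dimnames(vectors) <- list(vocab, paste0("dim", seq_len(k)))
  structure(
    list(
      vocabulary = vocab,
      vectors = vectors,
      singular_values = sv$d[seq_len(k)],
      k = k,
      weighting = weighting
    ),
    class = "semantic_space"
  )
}

#' Build a semantic space straight from a corpus
#'
#' Convenience wrapper: co-occurrence, log(1 + x), SVD.
#'
#' @inheritParams build_space
#' @param x A `qcla_corpus` or list of token vectors.
#' @return A `semantic_space`.
#' @export
train_space <- function(x, k = 300L, weighting = "us") {
  if (!inherits(x, "qcla_corpus")) x <- corpus(x)
  space <- build_space(log_transform(build_cooccurrence(x)),
                       k = k, weighting = weighting)
  space$word_frequency <- x$word_frequency[space$vocabulary]
  space
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf(
    "qcla semantic space: %d words x %d dimensions (%s weighting)\n",
    length(x$vocabulary), x$k, x$weighting
  ))
  invisible(x)
}

#' Cosine similarity
#'
#' @param v1,v2 Numeric vectors of equal length and nonzero norm.
#' @return Dot product over norms, clipped to `[-1, 1]`.
#' @export
cosine <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    stop_qcla("cosine: length mismatch", "qcla_validation_error")
  }
  n1 <- l2_norm(v1)
  n2 <- l2_norm(v2)
  if (n1 == 0 || n2 == 0) {
    stop_qcla("cosine: zero vector", "qcla_validation_error")
  }
  max(-1, min(1, sum(v1 * v2) / (n1 * n2)))
}

#' Serialize a semantic space
#'
#' Two-file format: a TSV of `word<TAB>v1..vk` plus a JSON sidecar holding
#' `k`, the singular values, the weighting and an optional corpus checksum.
#'
#' @param space A `semantic_space`.
#' @param path TSV path; the sidecar is written at `<path>.json`.
#' @param corpus_path Optional corpus file to checksum into the sidecar.
#' @return `path`, invisibly.
#' @export
write_space <- function(space, path, corpus_path = NULL) {
  tab <- data.frame(word = space$vocabulary,
                    space$vectors, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    k = space$k,
    weighting = space$weighting,
    singular_values = space$singular_values,
    corpus_md5 = if (!is.null(corpus_path)) {
      unname(tools::md5sum(corpus_path))
    } else {
      NA_character_
    },
    word_frequency = as.list(space$word_frequency)
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a serialized semantic space
#'
#' @param path TSV path written by [write_space()].
#' @return A `semantic_space`.
#' @export
read_space <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vectors <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(vectors) <- tab$word
  space <- structure(
    list(
      vocabulary = tab$word,
      vectors = vectors,
      singular_values = as.numeric(meta$singular_values),
      k = as.integer(meta$k),
      weighting = meta$weighting
    ),
    class = "semantic_space"
  )
  if (!is.null(meta$word_frequency) && length(meta$word_frequency)) {
    space$word_frequency <- unlist(meta$word_frequency)[space$vocabulary]
  }
  space
}
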