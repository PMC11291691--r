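# Response embedding: a descriptive-word response becomes one unit-norm
# vector, the normalised sum of its in-vocabulary word vectors.

normalize_tokens <- function(words) {
  w <- tolower(trimws(words))
  w <- gsub("[^a-z0-9'_-]", "", w)
  w[nzchar(w)]
}

#' Embed a descriptive-word response
#'
#' Sums the semantic vectors of the in-vocabulary words and normalises the
#' result to unit length. Tokens are lowercased and stripped of punctuation
#' before lookup; out-of-vocabulary words are skipped and counted. The
#' elicitation asks for five words, but any positive count is accepted (a
#' note is logged when the count differs from five).
#'
#' @param words Character vector of response words.
#' @param space A `semantic_space`.
#' @return A `response_vector` list: `vector` (unit norm), `n_known`,
#'   `source_words` (the in-vocabulary tokens used).
#' @export
embed_response <- function(words, space) {
  if (length(words) == 0L) {
    stop_qcla("embed_response: no words supplied", "qcla_validation_error")
  }
  tokens <- normalize_tokens(words)
  if (length(tokens) != 5L) {
    qcla_log("response has ", length(tokens), " usable tokens (expected 5)")
  }
  idx <- match(tokens, space$vocabulary)
  known <- tokens[!is.na(idx)]
  if (length(known) == 0L) {
    stop_qcla(
      paste0("no in-vocabulary words in response: ",
             paste(tokens, collapse = ", ")),
      "qcla_missing_representation"
    )
  }
  v <- colSums(space$vectors[idx[!is.na(idx)], , drop = FALSE])
  nrm <- l2_norm(v)
  if (nrm < .Machine$double.eps) {
    stop_qcla("response vectors cancel to zero", "qcla_missing_representation")
  }
  structure(
    list(vector = v / nrm, n_known = length(known), source_words = known),
    class = "response_vector"
  )
}

#' Embed a table of response records
#'
#' Applies [embed_response()] to every record; records whose words are all
#' out of vocabulary are excluded (reported, not raised) so downstream
#' models see only embeddable rows.
#'
#' @param records Response data frame with a `words` column
#'   (semicolon-separated), or a list of word vectors.
#' @param space A `semantic_space`.
#' @return List with `matrix` (one unit-norm row per kept record, in input
#'   order), `kept` (row indices embedded) and `excluded` (row indices
#'   dropped).
#' @export
embed_table <- function(records, space) {
  word_lists <- if (is.data.frame(records)) {
    response_words(records)
  } else {
    records
  }
  n <- length(word_lists)
  rows <- vector("list", n)
  kept <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      suppressMessages(embed_response(word_lists[[i]], space)),
      qcla_missing_representation = function(e) NULL
    )
    if (!is.null(res)) {
      rows[[i]] <- res$vector
      kept[i] <- TRUE
    }
  }
  if (any(!kept)) {
    qcla_log(sum(!kept), " record(s) excluded: all words out of vocabulary")
  }
  mat <- do.call(rbind, rows[kept])
  if (is.null(mat)) mat <- matrix(numeric(0), 0L, space$k)
  colnames(mat) <- colnames(space$vectors)
  list(matrix = mat, kept = which(kept), excluded = which(!kept))
}
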