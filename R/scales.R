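# Rating-scale scoring and alexithymia stratification.
#
# Five instruments are supported: PHQ-9 and GAD-7 (items 0-3), SWLS and HILS
# (items 1-7), and the 24-item PAQ (items 1-7) used for the alexithymia
# median split.

.scale_registry <- list(
  PHQ9 = list(name = "PHQ9", n_items = 9L,  item_min = 0L, item_max = 3L),
  GAD7 = list(name = "GAD7", n_items = 7L,  item_min = 0L, item_max = 3L),
  SWLS = list(name = "SWLS", n_items = 5L,  item_min = 1L, item_max = 7L),
  HILS = list(name = "HILS", n_items = 5L,  item_min = 1L, item_max = 7L),
  PAQ  = list(name = "PAQ",  n_items = 24L, item_min = 1L, item_max = 7L)
)

#' Rating-scale definition
#'
#' Returns the item count and item bounds for one of the five supported
#' rating scales: PHQ-9 (9 items, 0-3), GAD-7 (7 items, 0-3), SWLS and HILS
#' (5 items each, 1-7), PAQ (24 items, 1-7).
#'
#' @param name Scale name, one of `"PHQ9"`, `"GAD7"`, `"SWLS"`, `"HILS"`,
#'   `"PAQ"`.
#' @return A `scale_definition` list with `name`, `n_items`, `item_min`,
#'   `item_max`, `total_min`, `total_max`.
#' @examples
#' scale_definition("PHQ9")$total_max  # 27
#' @export
scale_definition <- function(name) {
  name <- toupper(name)
  name <- sub("-", "", name, fixed = TRUE)
  if (!name %in% names(.scale_registry)) {
    stop_qcla(sprintf("unknown scale '%s'", name), "qcla_structural_error")
  }
  def <- .scale_registry[[name]]
  def$total_min <- def$n_items * def$item_min
  def$total_max <- def$n_items * def$item_max
  class(def) <- "scale_definition"
  def
}

#' Score a rating scale from item-level answers
#'
#' Totals are plain sums of the supplied item values; items must be supplied
#' already oriented (no reverse keying is applied).
#'
#' @param items Integer vector of item answers, in item order.
#' @param definition A [scale_definition()].
#' @return Integer total, guaranteed within the scale's total range.
#' @examples
#' score_scale(rep(3, 9), scale_definition("PHQ9"))  # 27
#' @export
score_scale <- function(items, definition) {
  if (!inherits(definition, "scale_definition")) {
    definition <- scale_definition(definition)
  }
  if (length(items) != definition$n_items) {
    stop_qcla(
      sprintf(
        "%s expects %d items, got %d",
        definition$name, definition$n_items, length(items)
      ),
      "qcla_structural_error"
    )
  }
  bad <- which(is.na(items) | items < definition$item_min |
                 items > definition$item_max)
  if (length(bad) > 0L) {
    stop_qcla(
      sprintf(
        "%s item %d out of range [%d, %d] (value: %s)",
        definition$name, bad[1L], definition$item_min, definition$item_max,
        as.character(items[bad[1L]])
      ),
      "qcla_validation_error"
    )
  }
  as.integer(sum(items))
}

#' Split participants into low/high alexithymia groups
#'
#' Applies the PAQ median-split rule: totals at or below the threshold are
#' labelled `"low"`, totals above it `"high"`. The published threshold is 68.
#'
#' @param paq_totals Integer vector of PAQ totals (range 24-168).
#' @param threshold Split point; totals `<= threshold` are low. Default 68.
#' @return Factor with levels `c("low", "high")`, same length as input.
#' @examples
#' paq_split(c(68, 69))  # low, high
#' @export
paq_split <- function(paq_totals, threshold = 68L) {
  if (length(paq_totals) == 0L) {
    stop_qcla("paq_split: empty input", "qcla_validation_error")
  }
  def <- scale_definition("PAQ")
  if (any(paq_totals < def$total_min | paq_totals > def$total_max,
          na.rm = TRUE)) {
    stop_qcla(
      sprintf("PAQ totals must lie in [%d, %d]", def$total_min, def$total_max),
      "qcla_validation_error"
    )
  }
  factor(ifelse(paq_totals <= threshold, "low", "high"),
         levels = c("low", "high"))
}

#' Integer median threshold for a median split
#'
#' Sample median of the supplied totals, floored to an integer when the
#' even-n midpoint is fractional, so the threshold has the same integer form
#' as a published split point.
#'
#' @param paq_totals Integer vector, non-empty.
#' @return Integer threshold usable in [paq_split()].
#' @examples
#' median_threshold(c(60, 70))  # 65
#' @export
median_threshold <- function(paq_totals) {
  if (length(paq_totals) == 0L) {
    stop_qcla("median_threshold: empty input", "qcla_validation_error")
  }
  as.integer(floor(median(as.numeric(paq_totals))))
}

scale_item_columns <- function(scale) {
  def <- scale_definition(scale)
  paste0(tolower(def$name), "_", seq_len(def$n_items))
}

#' Read a response table from CSV
#'
#' Expects the study's flat layout: `respondent_id, narrative_id, phase,
#' condition, words, phq9_1..phq9_9, gad7_1..gad7_7, swls_1..swls_5,
#' hils_1..hils_5, paq_1..paq_24`, where `words` holds a semicolon-separated
#' descriptive-word list.
#'
#' @param path CSV file path.
#' @return A data frame of response records.
#' @export
read_responses <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c(
    "respondent_id", "narrative_id", "phase", "condition", "words",
    unlist(lapply(c("PHQ9", "GAD7", "SWLS", "HILS", "PAQ"),
                  scale_item_columns))
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_qcla(
      paste0("missing columns: ", paste(missing, collapse = ", ")),
      "qcla_structural_error"
    )
  }
  df
}

#' Split the semicolon-separated word field into word lists
#'
#' @param records Response data frame with a `words` column.
#' @return List of character vectors, one per row.
#' @export
response_words <- function(records) {
  lapply(strsplit(records$words, ";", fixed = TRUE), trimws)
}

#' Score all five scales for a response table
#'
#' Computes `phq9_total`, `gad7_total`, `swls_total`, `hils_total` and
#' `paq_total` from the item columns. Records with missing or out-of-range
#' items on any scale are excluded (no imputation), with the exclusion count
#' logged; incomplete surveys are dropped, not patched.
#'
#' @param records Response data frame in the [read_responses()] layout.
#' @return The kept rows with five `<scale>_total` columns appended; excluded
#'   row indices are attached as `attr(, "excluded")`.
#' @export
score_scales <- function(records) {
  scales <- c("PHQ9", "GAD7", "SWLS", "HILS", "PAQ")
  n <- nrow(records)
  totals <- matrix(NA_integer_, nrow = n, ncol = length(scales),
                   dimnames = list(NULL, paste0(tolower(scales), "_total")))
  ok <- rep(TRUE, n)
  for (s in scales) {
    def <- scale_definition(s)
    items <- as.matrix(records[, scale_item_columns(s), drop = FALSE])
    valid <- rowSums(is.na(items)) == 0L &
      rowSums(items < def$item_min | items > def$item_max) == 0L
    totals[valid, paste0(tolower(s), "_total")] <-
      as.integer(rowSums(items[valid, , drop = FALSE]))
    ok <- ok & valid
  }
  if (any(!ok)) {
    qcla_log(sum(!ok), " record(s) excluded for missing/out-of-range items")
  }
  out <- cbind(records[ok, , drop = FALSE],
               as.data.frame(totals[ok, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "excluded") <- which(!ok)
  out
}
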