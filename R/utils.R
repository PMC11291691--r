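#' @keywords internal
"_PACKAGE"

#' @importFrom stats chisq.test coef cor.test median pf predict rnorm sd
#'   t.test var.test setNames quantile
#' @importFrom utils read.csv write.csv head
#' @importFrom methods as
NULL

# Canonical ordering of the four emotion conditions used everywhere:
# confusion matrices, class_order of classifiers, report tables.
#' Canonical emotion class order
#'
#' The fixed ordering (harmony, satisfaction, depression, anxiety) used for
#' classifier class order, confusion-matrix rows/columns and report tables.
#'
#' @return Character vector of the four emotion labels.
#' @export
emotion_levels <- function() {
  c("harmony", "satisfaction", "depression", "anxiety")
}

# Run code with a temporary RNG state seeded by `seed`, restoring the caller's
# state afterwards so library internals never perturb user-level randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stream-specific child seed from a master seed; keeps independent
# stages (corpus, phase 1, phase 2, folds, permutations) decoupled while
# remaining a deterministic function of one user-facing integer.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) * 10007L + as.integer(stream)) %% 2147483629L
}

# Package-level diagnostic logging: exclusions, clamps, fallbacks. These are
# informative conditions, not warnings, so tests stay quiet by default.
qcla_log <- function(...) {
  message("[qcla] ", ...)
}

# Undefined-marker convention: metrics whose denominator is zero are NA_real_
# in memory and rendered as an en dash in reports.
format_metric <- function(x, digits = 2) {
  out <- ifelse(is.na(x), "–", formatC(x, format = "f", digits = digits))
  unname(out)
}

l2_norm <- function(v) sqrt(sum(v^2))

stop_qcla <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "qcla_error")))
}
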