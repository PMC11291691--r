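# Synthetic two-phase study generator.
#
# Emulates the structure the analysis assumes: four emotion conditions with
# emotion-specific vocabularies (harmony and satisfaction overlapping most),
# Zipf-skewed word frequencies, condition-congruent rating-scale elevations
# that also bleed onto the same-valence sibling scale, and a narrator
# alexithymia (PAQ) score whose high values make word choice noisier, so
# narratives by high-PAQ authors are harder to classify.

#' Configuration for the synthetic study generator
#'
#' Defaults describe the emulated study conditions: 116 Phase-1 narrators
#' and 232 Phase-2 evaluators (balanced over the four emotions), emotion
#' vocabularies of 150 words with elevated harmony-satisfaction sharing,
#' Zipf-weighted word draws, word-choice noise 0.15 for low-PAQ and 0.35
#' for high-PAQ narrators, a 5-point congruent scale-total shift with 80%
#' bleed onto the same-valence sibling scale, item SD 1.5, and PAQ drawn
#' from a normal(68, 20) truncated to its 24-168 range so the conventional
#' split point 68 is typical.
#'
#' @param n_phase1 Number of Phase-1 narrators.
#' @param n_phase2 Number of Phase-2 evaluators.
#' @param vocab_per_emotion Words in each emotion's vocabulary.
#' @param overlap_hs Fraction of vocabulary shared between harmony and
#'   satisfaction.
#' @param overlap_da Fraction shared between depression and anxiety.
#' @param overlap_other Fraction shared between cross-valence pairs.
#' @param word_noise_low,word_noise_high Probability a drawn word comes
#'   from a non-target emotion's vocabulary, for low-/high-PAQ narrators;
#'   `word_noise_high >= word_noise_low` encodes that high-alexithymia
#'   narratives are harder to evaluate.
#' @param scale_effect Mean shift, in total-score points, of the
#'   condition-congruent rating scale.
#' @param cross_effect Fraction of `scale_effect` applied to the
#'   same-valence sibling scale (harmony-satisfaction, depression-anxiety).
#' @param scale_attenuation_high Multiplier on the evaluators' scale shift
#'   when the narrative's author is high-PAQ (scale-mediated difficulty).
#' @param scale_noise Item-level SD before rounding and clipping.
#' @param paq_mean,paq_sd Narrator PAQ total distribution (truncated to the
#'   scale range).
#' @param paq_threshold Split point between low and high alexithymia.
#' @param zipf_exponent Zipf exponent for within-vocabulary word weights.
#' @param corpus_responses Number of corpus responses.
#' @param corpus_lengths Candidate response lengths for the corpus
#'   (emulating 3/5/10-word elicitations).
#' @param corpus_noise Word-choice noise for corpus responses.
#' @param seed Master seed; all generator stages derive their streams from
#'   it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_phase1 = 116L,
                             n_phase2 = 232L,
                             vocab_per_emotion = 150L,
                             overlap_hs = 0.20,
                             overlap_da = 0.10,
                             overlap_other = 0.02,
                             word_noise_low = 0.15,
                             word_noise_high = 0.35,
                             scale_effect = 5,
                             cross_effect = 0.8,
                             scale_attenuation_high = 0.6,
                             scale_noise = 1.5,
                             paq_mean = 68,
                             paq_sd = 20,
                             paq_threshold = 68L,
                             zipf_exponent = 1.0,
                             corpus_responses = 3000L,
                             corpus_lengths = c(3L, 5L, 10L),
                             corpus_noise = 0.15,
                             seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$overlap_hs, cfg$overlap_da, cfg$overlap_other,
             cfg$word_noise_low, cfg$word_noise_high, cfg$corpus_noise)
  if (any(probs < 0 | probs > 1)) {
    stop_qcla("synthetic_config: probabilities must lie in [0, 1]",
              "qcla_validation_error")
  }
  if (cfg$word_noise_high < cfg$word_noise_low) {
    stop_qcla("synthetic_config: word_noise_high must be >= word_noise_low",
              "qcla_validation_error")
  }
  if (cfg$vocab_per_emotion < 1L) {
    stop_qcla("synthetic_config: vocabularies must be nonempty",
              "qcla_validation_error")
  }
  cfg$vocabularies <- build_vocabularies(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

# Emotion vocabularies with controlled pairwise sharing. Shared words are
# named for the pair they bridge so planted-signal tests can find them.
build_vocabularies <- function(cfg) {
  emo <- emotion_levels()
  abbr <- c(harmony = "har", satisfaction = "sat",
            depression = "dep", anxiety = "anx")
  pair_frac <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "_")
    switch(key,
           harmony_satisfaction = cfg$overlap_hs,
           anxiety_depression = cfg$overlap_da,
           cfg$overlap_other)
  }
  pairs <- utils::combn(emo, 2L, simplify = FALSE)
  shared <- list()
  n_shared_in <- setNames(integer(length(emo)), emo)
  for (p in pairs) {
    n_sh <- round(pair_frac(p[1L], p[2L]) * cfg$vocab_per_emotion)
    if (n_sh > 0L) {
      words <- sprintf("%s%s_s%03d", abbr[[p[1L]]], abbr[[p[2L]]],
                       seq_len(n_sh))
      shared[[paste(p, collapse = "_")]] <- list(pair = p, words = words)
      n_shared_in[p] <- n_shared_in[p] + n_sh
    }
  }
  vocabs <- lapply(emo, function(e) {
    own <- sprintf("%s_w%03d", abbr[[e]],
                   seq_len(max(1L, cfg$vocab_per_emotion - n_shared_in[[e]])))
    sh <- unlist(lapply(shared, function(s) {
      if (e %in% s$pair) s$words else character(0)
    }), use.names = FALSE)
    # interleave shared words through the rank order (every third rank) so
    # they are not all rare under the Zipf weighting
    n_total <- length(own) + length(sh)
    out <- character(0)
    i_own <- 1L; i_sh <- 1L
    for (r in seq_len(n_total)) {
      take_shared <- (r %% 3L == 0L) && i_sh <= length(sh)
      if (take_shared) {
        out <- c(out, sh[i_sh]); i_sh <- i_sh + 1L
      } else if (i_own <= length(own)) {
        out <- c(out, own[i_own]); i_own <- i_own + 1L
      } else if (i_sh <= length(sh)) {
        out <- c(out, sh[i_sh]); i_sh <- i_sh + 1L
      }
    }
    out
  })
  setNames(vocabs, emo)
}

zipf_weights <- function(n, s) {
  w <- 1 / seq_len(n)^s
  w / sum(w)
}

# Draw n words for one response: each word comes from the target emotion's
# vocabulary with probability 1 - noise, otherwise from a uniformly chosen
# other emotion; within a vocabulary, draws are Zipf-weighted by rank.
sample_words <- function(emotion, n, noise, cfg) {
  emo <- emotion_levels()
  sources <- ifelse(stats::runif(n) < noise,
                    sample(setdiff(emo, emotion), n, replace = TRUE),
                    emotion)
  vapply(sources, function(src) {
    v <- cfg$vocabularies[[src]]
    sample(v, 1L, prob = zipf_weights(length(v), cfg$zipf_exponent))
  }, character(1L), USE.NAMES = FALSE)
}

# Congruent-scale map and same-valence siblings.
congruent_scale <- c(harmony = "HILS", satisfaction = "SWLS",
                     depression = "PHQ9", anxiety = "GAD7")
sibling_condition <- c(harmony = "satisfaction", satisfaction = "harmony",
                       depression = "anxiety", anxiety = "depression")
baseline_item_mean <- c(PHQ9 = 0.7, GAD7 = 0.7, SWLS = 3.0, HILS = 3.0)

# Integer item draws around a shifted mean, clipped to the scale bounds.
draw_items <- function(scale, mu, cfg) {
  def <- scale_definition(scale)
  items <- round(rnorm(def$n_items, mean = mu, sd = cfg$scale_noise))
  pmin(pmax(items, def$item_min), def$item_max)
}

scale_items_for_condition <- function(condition, cfg, attenuation = 1) {
  out <- list()
  for (s in c("PHQ9", "GAD7", "SWLS", "HILS")) {
    def <- scale_definition(s)
    shift_total <- if (congruent_scale[[condition]] == s) {
      cfg$scale_effect
    } else if (congruent_scale[[sibling_condition[[condition]]]] == s) {
      cfg$cross_effect * cfg$scale_effect
    } else {
      0
    }
    mu <- baseline_item_mean[[s]] + attenuation * shift_total / def$n_items
    out[[s]] <- draw_items(s, mu, cfg)
  }
  out
}

record_row <- function(respondent_id, narrative_id, phase, condition,
                       words, items, paq_items, narrator_paq) {
  row <- data.frame(
    respondent_id = respondent_id,
    narrative_id = narrative_id,
    phase = phase,
    condition = condition,
    words = paste(words, collapse = ";"),
    stringsAsFactors = FALSE
  )
  for (s in c("PHQ9", "GAD7", "SWLS", "HILS")) {
    row[scale_item_columns(s)] <- as.list(items[[s]])
  }
  row[scale_item_columns("PAQ")] <- as.list(paq_items)
  row$narrator_paq <- narrator_paq
  row
}

draw_paq_items <- function(cfg) {
  def <- scale_definition("PAQ")
  repeat {
    target <- rnorm(1L, cfg$paq_mean, cfg$paq_sd)
    if (target >= def$total_min && target <= def$total_max) break
  }
  draw_items("PAQ", target / def$n_items, cfg)
}

#' Generate a synthetic descriptive-word corpus
#'
#' Responses of 3, 5 or 10 words (emulating varied elicitation prompts),
#' emotions assigned round-robin, words drawn from the emotion-conditioned
#' Zipf-weighted mixture. Deterministic for a fixed config seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A `qcla_corpus`.
#' @export
generate_corpus <- function(cfg) {
  with_seed(child_seed(cfg$seed, 101L), {
    emo <- rep_len(emotion_levels(), cfg$corpus_responses)
    lens <- sample(cfg$corpus_lengths, cfg$corpus_responses, replace = TRUE)
    responses <- lapply(seq_len(cfg$corpus_responses), function(i) {
      sample_words(emo[i], lens[i], cfg$corpus_noise, cfg)
    })
    corpus(responses)
  })
}

#' Generate Phase-1 narrator records
#'
#' Each narrator gets a balanced (round-robin) emotion condition, a PAQ
#' total from the configured truncated-normal distribution, five descriptive
#' words whose noise level depends on their own PAQ group, and rating-scale
#' items with the condition-congruent scale elevated.
#'
#' @param cfg A [synthetic_config()].
#' @return Data frame of `ResponseRecord` rows (phase 1); `narrative_id`
#'   equals the narrator's `respondent_id`.
#' @export
generate_phase1 <- function(cfg) {
  if (cfg$n_phase1 == 0L) return(NULL)
  with_seed(child_seed(cfg$seed, 102L), {
    conditions <- rep_len(emotion_levels(), cfg$n_phase1)
    rows <- lapply(seq_len(cfg$n_phase1), function(i) {
      id <- sprintf("p1_%03d", i)
      paq_items <- draw_paq_items(cfg)
      paq_total <- sum(paq_items)
      noise <- if (paq_total > cfg$paq_threshold) {
        cfg$word_noise_high
      } else {
        cfg$word_noise_low
      }
      words <- sample_words(conditions[i], 5L, noise, cfg)
      items <- scale_items_for_condition(conditions[i], cfg)
      record_row(id, id, 1L, conditions[i], words, items, paq_items,
                 narrator_paq = paq_total)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate Phase-2 evaluator records
#'
#' Each evaluator is assigned one Phase-1 narrative (cycled so coverage is
#' balanced) and responds to its condition: their five words are drawn with
#' noise set by the narrator's PAQ group (high-alexithymia narratives are
#' harder to read), their scale shift is attenuated for high-PAQ narratives,
#' and their own PAQ is drawn fresh. `narrative_id` references the Phase-1
#' narrative, so grouped cross-validation keeps a narrative's rows together.
#'
#' @param phase1 Output of [generate_phase1()].
#' @param cfg A [synthetic_config()].
#' @return Data frame of Phase-2 `ResponseRecord` rows.
#' @export
generate_phase2 <- function(phase1, cfg) {
  if (is.null(phase1) || nrow(phase1) == 0L) {
    stop_qcla("generate_phase2: phase1 records required",
              "qcla_validation_error")
  }
  with_seed(child_seed(cfg$seed, 103L), {
    order1 <- sample(nrow(phase1))
    narr_idx <- rep_len(order1, cfg$n_phase2)
    rows <- lapply(seq_len(cfg$n_phase2), function(i) {
      narr <- phase1[narr_idx[i], ]
      high <- narr$narrator_paq > cfg$paq_threshold
      noise <- if (high) cfg$word_noise_high else cfg$word_noise_low
      attenuation <- if (high) cfg$scale_attenuation_high else 1
      words <- sample_words(narr$condition, 5L, noise, cfg)
      items <- scale_items_for_condition(narr$condition, cfg, attenuation)
      record_row(sprintf("p2_%03d", i), narr$narrative_id, 2L,
                 narr$condition, words, items, draw_paq_items(cfg),
                 narrator_paq = narr$narrator_paq)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic study
#'
#' Corpus plus Phase-1 and Phase-2 response tables, with scale totals
#' already scored.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `corpus`, `phase1`, `phase2` and `records`
#'   (the scored row-bound phases), plus the `config`.
#' @export
simulate_study <- function(cfg = synthetic_config()) {
  corpus <- generate_corpus(cfg)
  phase1 <- generate_phase1(cfg)
  phase2 <- generate_phase2(phase1, cfg)
  records <- suppressMessages(score_scales(rbind(phase1, phase2)))
  list(corpus = corpus, phase1 = phase1, phase2 = phase2,
       records = records, config = cfg)
}

#' Write a simulated study to disk
#'
#' Emits `corpus.txt` (one response per line), `phase1.csv`, `phase2.csv`
#' and `provenance.json` (generator parameters, seed and file checksums).
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus_path <- file.path(dir, "corpus.txt")
  write_corpus(sim$corpus, corpus_path)
  p1 <- file.path(dir, "phase1.csv")
  p2 <- file.path(dir, "phase2.csv")
  write.csv(sim$phase1, p1, row.names = FALSE)
  write.csv(sim$phase2, p2, row.names = FALSE)
  cfg <- sim$config
  cfg$vocabularies <- NULL
  jsonlite::write_json(
    list(
      config = unclass(cfg),
      checksums = as.list(tools::md5sum(c(corpus_path, p1, p2)))
    ),
    file.path(dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
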