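#' Default planted vocabulary for the synthetic generator
#'
#' Builds disjoint per-(stage, role) keyword lists, a shared background word
#' list, and two outcome "drift" lexicons (words whose probability grows over
#' conversation time in positive resp. negative conversations). Words are
#' synthetic identifiers: the analyses are bag-of-words, so surface realism is
#' irrelevant, and synthetic identifiers guarantee the planted channels are
#' disjoint from the marker, hedge, and psycholinguistic category lexicons.
#'
#' @param n_stages Number of conversation stages.
#' @param keywords_per_stage Keywords per (stage, role) cell.
#' @param n_background Plain background words.
#' @param n_drift Words per outcome drift lexicon.
#' @return List with `keywords` (per role, a list of per-stage word vectors),
#'   `background` (all background words incl. drift words), `drift_positive`,
#'   `drift_negative`.
#' @export
default_vocab <- function(n_stages = 5, keywords_per_stage = 10,
                          n_background = 60, n_drift = 15) {
  # word identifiers must survive tokenization unchanged: lowercase
  # alphanumeric only
  kw <- function(role) {
    lapply(seq_len(n_stages), function(s)
      sprintf("%sstage%dkw%02d", role, s, seq_len(keywords_per_stage)))
  }
  list(keywords = list(counselor = kw("c"), texter = kw("t")),
       background = sprintf("bg%03d", seq_len(n_background)),
       drift_positive = sprintf("uplift%02d", seq_len(n_drift)),
       drift_negative = sprintf("gloom%02d", seq_len(n_drift)))
}

#' Configuration of the synthetic conversation-corpus generator
#'
#' Every planted effect of the generator is parameterized here. Defaults are
#' the corpus conditions used throughout the package's validation: 10
#' counselors (alternating quality 0.8 / 0.5) with 40 conversations each,
#' 5 left-to-right stages with keyword weight 0.8, outcome-dependent lexical
#' drift growing linearly over conversation fifths, marker coordination with
#' base exhibit probability 0.2 and increment delta = 0.1, outcome-dependent
#' counselor style (hedges, check questions), an outcome-dependent situation
#' setter length shift, and psycholinguistic category schedules for texter
#' tense / pronoun focus / sentiment.
#'
#' @param n_counselors Number of counselors (conversations are assigned
#'   round-robin).
#' @param n_conversations Total conversations.
#' @param n_stages Number of ordered stages.
#' @param vocab Planted vocabulary, see [default_vocab()].
#' @param keyword_weight Probability that a core token is a stage-role
#'   keyword (the rest come from the background channel).
#' @param stage_advance_prob Numeric vector of per-stage advance
#'   probabilities (last entry forced to 0), or a list with elements `high`
#'   and `low` applied by counselor quality (above / at-or-below
#'   `quality_split`).
#' @param counselor_quality Per-counselor probability that a conversation is
#'   positive; recycled to `n_counselors`.
#' @param quality_split Quality threshold separating the `high` / `low`
#'   advance-probability regimes when `stage_advance_prob` is a list.
#' @param drift_strength Outcome-dependent lexical drift of counselor
#'   language: in chunk `c` of `n_chunks`, each counselor core token is
#'   replaced by a word from the outcome's drift lexicon with probability
#'   `drift_strength * (c-1)/(n_chunks-1)` — no drift in the first chunk,
#'   growing linearly to `drift_strength` in the last.
#' @param n_chunks Number of conversation-time chunks the drift and category
#'   schedules are defined over.
#' @param markers Named list of marker word lists used for coordination
#'   injection; `NULL` disables the channel.
#' @param base_marker_prob Baseline exhibit probability (scalar or named per
#'   marker).
#' @param coordination_delta Exhibit-probability increment when the previous
#'   message exhibited the marker (scalar or named per marker).
#' @param length_model Per-role negative-binomial message-length parameters:
#'   `list(counselor = c(mu=, size=), texter = c(mu=, size=))`.
#' @param setter Situation-setter model: `list(mu=, size=, min_tokens=,
#'   length_effect=)`. The second texter message is the setter; its length is
#'   a negative-binomial draw truncated at `min_tokens`, plus `length_effect`
#'   tokens in positive conversations. The first texter message is kept short
#'   (2--6 tokens) so the setter is the first long texter message.
#' @param style_probs Outcome-dependent counselor response-style injection
#'   probabilities: `list(hedge = c(positive=, negative=), check_question =
#'   c(positive=, negative=))`.
#' @param cat_rate Probability that a texter background token is drawn from
#'   the psycholinguistic category channel instead of the plain background.
#' @param perspective Linear category schedules over chunks:
#'   `list(future = c(start=, end_positive=, end_negative=), first = ...,
#'   pos = ...)` giving the future share of tense words, first-person share
#'   of pronouns, and positive share of emotion words.
#' @param conv_len Conversation length model: `c(mean=, sd=, min=, max=)`
#'   (Gaussian draw, rounded and clipped).
#' @param seed Integer seed; the same (config, seed) always yields a
#'   byte-identical corpus.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_counselors = 10,
                             n_conversations = 400,
                             n_stages = 5,
                             vocab = default_vocab(n_stages),
                             keyword_weight = 0.8,
                             stage_advance_prob = c(0.20, 0.12, 0.10, 0.15, 0),
                             counselor_quality = rep(c(0.8, 0.5),
                                                     length.out = n_counselors),
                             quality_split = 0.65,
                             drift_strength = 0.25,
                             n_chunks = 5,
                             markers = default_marker_lexicons(),
                             base_marker_prob = 0.2,
                             coordination_delta = 0.1,
                             length_model = list(counselor = c(mu = 16, size = 6),
                                                 texter = c(mu = 11, size = 4)),
                             setter = list(mu = 14, size = 6, min_tokens = 10,
                                           length_effect = 4),
                             style_probs = list(
                               hedge = c(positive = 0.45, negative = 0.20),
                               check_question = c(positive = 0.30,
                                                  negative = 0.10)),
                             cat_rate = 0.3,
                             perspective = list(
                               future = c(start = 0.15, end_positive = 0.45,
                                          end_negative = 0.25),
                               first = c(start = 0.85, end_positive = 0.60,
                                         end_negative = 0.80),
                               pos = c(start = 0.25, end_positive = 0.65,
                                       end_negative = 0.40)),
                             conv_len = c(mean = 45, sd = 8, min = 30, max = 60),
                             seed = 1L) {
  counselor_quality <- rep(counselor_quality, length.out = n_counselors)
  probs <- c(keyword_weight, counselor_quality, cat_rate,
             if (is.list(stage_advance_prob)) unlist(stage_advance_prob)
             else stage_advance_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (!is.null(markers)) {
    base_marker_prob <- rep_named(base_marker_prob, names(markers))
    coordination_delta <- rep_named(coordination_delta, names(markers))
    if (any(base_marker_prob + coordination_delta > 1) ||
        any(base_marker_prob < 0) || any(coordination_delta < 0)) {
      stop("marker probabilities must satisfy 0 <= base, base + delta <= 1")
    }
  }
  # keyword lists must be disjoint across stages within a role
  for (role in names(vocab$keywords)) {
    all_kw <- unlist(vocab$keywords[[role]])
    if (anyDuplicated(all_kw) > 0) {
      stop("stage keyword lists must be disjoint within a role")
    }
  }
  structure(
    list(n_counselors = n_counselors, n_conversations = n_conversations,
         n_stages = n_stages, vocab = vocab, keyword_weight = keyword_weight,
         stage_advance_prob = stage_advance_prob,
         counselor_quality = counselor_quality, quality_split = quality_split,
         drift_strength = drift_strength, n_chunks = n_chunks,
         markers = markers, base_marker_prob = base_marker_prob,
         coordination_delta = coordination_delta,
         length_model = length_model, setter = setter,
         style_probs = style_probs, cat_rate = cat_rate,
         perspective = perspective, conv_len = conv_len,
         seed = as.integer(seed)),
    class = "generator_config")
}

rep_named <- function(x, nm) {
  if (is.null(names(x))) x <- stats::setNames(rep(x, length.out = length(nm)), nm)
  x[nm]
}

# Linear interpolation of a category schedule at chunk c (1-based).
schedule_value <- function(sched, chunk, n_chunks, outcome) {
  endk <- if (outcome == "positive") "end_positive" else "end_negative"
  frac <- if (n_chunks > 1) (chunk - 1) / (n_chunks - 1) else 0
  unname(sched["start"] + (sched[endk] - sched["start"]) * frac)
}

# Category word pools used by the texter psycholinguistic channel: the
# non-wildcard entries of the default category lexicons.
category_pools <- function() {
  lex <- default_category_lexicons()
  lapply(lex, function(w) w[!endsWith(w, "*")])
}

#' Generate a synthetic conversation corpus with planted structure
#'
#' See [generator_config()] for the planted effects. Roles strictly alternate
#' starting with the counselor; the latent stage starts at 1 and advances by
#' at most one per message, never decreasing. Every conversation is labeled
#' (outcome drawn from its counselor's quality).
#'
#' @param config A [generator_config()].
#' @return List with `conversations` (list of [new_conversation()] objects)
#'   and `ground_truth` (class `ground_truth`): per-conversation true stages,
#'   outcome, setter message index, per-message marker exhibit matrices, the
#'   per-counselor quality vector, and the full config echo.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  n_stages <- config$n_stages
  vocab <- config$vocab
  bg <- vocab$background
  n_chunks <- config$n_chunks
  pools <- category_pools()
  counselor_ids <- sprintf("c%03d", seq_len(config$n_counselors))
  quality <- stats::setNames(config$counselor_quality, counselor_ids)
  markers <- config$markers
  n_markers <- length(markers)
  hedge_pool <- default_hedge_words()

  drift_lex <- list(positive = vocab$drift_positive,
                    negative = vocab$drift_negative)
  drift_rate <- function(ch) {
    config$drift_strength *
      (if (n_chunks > 1) (ch - 1) / (n_chunks - 1) else 0)
  }
  # injected words follow a Zipf profile over their list, as function words
  # do in natural text
  zipf <- function(words) (1 / seq_along(words)) / sum(1 / seq_along(words))
  marker_zipf <- lapply(markers, zipf)
  hedge_zipf <- zipf(hedge_pool)

  advance_for <- function(q) {
    ap <- config$stage_advance_prob
    if (is.list(ap)) ap <- if (q > config$quality_split) ap$high else ap$low
    ap <- rep(ap, length.out = n_stages)
    ap[n_stages] <- 0
    ap
  }

  draw_len <- function(role) {
    lm <- config$length_model[[role]]
    max(1L, stats::rnbinom(1, size = lm[["size"]], mu = lm[["mu"]]))
  }

  conversations <- vector("list", config$n_conversations)
  gt_convs <- vector("list", config$n_conversations)

  for (k in seq_len(config$n_conversations)) {
    c_id <- counselor_ids[((k - 1) %% config$n_counselors) + 1]
    q <- quality[[c_id]]
    outcome <- if (stats::runif(1) < q) "positive" else "negative"
    n_msgs <- as.integer(round(stats::rnorm(1, config$conv_len[["mean"]],
                                            config$conv_len[["sd"]])))
    n_msgs <- min(max(n_msgs, config$conv_len[["min"]]), config$conv_len[["max"]])
    roles <- rep(c("counselor", "texter"), length.out = n_msgs)
    chunks <- chunk_assignment(n_msgs, n_chunks)
    adv <- advance_for(q)

    stages <- integer(n_msgs)
    s <- 1L
    for (i in seq_len(n_msgs)) {
      stages[i] <- s
      if (s < n_stages && stats::runif(1) < adv[s]) s <- s + 1L
    }

    exhibits <- if (n_markers > 0) {
      matrix(0L, n_msgs, n_markers, dimnames = list(NULL, names(markers)))
    } else NULL
    prev_exhibit <- stats::setNames(rep(0L, n_markers), names(markers))
    texts <- character(n_msgs)
    final_len <- integer(n_msgs)
    t_idx <- 0L

    for (i in seq_len(n_msgs)) {
      role <- roles[i]
      ch <- chunks[i]
      if (role == "texter") {
        t_idx <- t_idx + 1L
        if (t_idx == 1L) {
          len <- sample(2:6, 1)
        } else if (t_idx == 2L) {
          len <- max(config$setter$min_tokens,
                     stats::rnbinom(1, size = config$setter$size,
                                    mu = config$setter$mu))
          if (outcome == "positive") len <- len + config$setter$length_effect
        } else {
          len <- draw_len("texter")
        }
      } else {
        len <- draw_len("counselor")
      }

      is_kw <- stats::runif(len) < config$keyword_weight
      toks <- character(len)
      n_kw <- sum(is_kw)
      if (n_kw > 0) {
        toks[is_kw] <- sample(vocab$keywords[[role]][[stages[i]]], n_kw,
                              replace = TRUE)
      }
      n_other <- len - n_kw
      if (n_other > 0) {
        other <- character(n_other)
        use_cat <- role == "texter" & stats::runif(n_other) < config$cat_rate
        n_cat <- sum(use_cat)
        if (n_cat > 0) {
          other[use_cat] <- draw_category_words(n_cat, pools,
                                                config$perspective, ch,
                                                n_chunks, outcome)
        }
        n_plain <- n_other - n_cat
        if (n_plain > 0) {
          other[!use_cat] <- sample(bg, n_plain, replace = TRUE)
        }
        toks[!is_kw] <- other
      }

      if (role == "counselor" && config$drift_strength > 0) {
        dr <- stats::runif(len) < drift_rate(ch)
        n_dr <- sum(dr)
        if (n_dr > 0) {
          toks[dr] <- sample(drift_lex[[outcome]], n_dr, replace = TRUE)
        }
      }

      if (role == "counselor") {
        sp <- config$style_probs
        if (stats::runif(1) < sp$hedge[[outcome]]) {
          toks <- c(toks, sample(hedge_pool, 1, prob = hedge_zipf))
        }
        if (stats::runif(1) < sp$check_question[[outcome]]) {
          toks <- c(toks, "sounds", "like")
        }
      }

      if (n_markers > 0) {
        for (m in names(markers)) {
          p <- config$base_marker_prob[[m]] +
            config$coordination_delta[[m]] * prev_exhibit[[m]]
          e <- as.integer(stats::runif(1) < p)
          if (e == 1L) {
            toks <- c(toks, sample(markers[[m]], 1, prob = marker_zipf[[m]]))
          }
          exhibits[i, m] <- e
          prev_exhibit[[m]] <- e
        }
      }

      texts[i] <- paste(toks, collapse = " ")
      final_len[i] <- length(toks)
    }

    # the realized setter: first texter message whose final token count
    # (including injected words) reaches the setter threshold
    setter_pos <- which(roles == "texter" &
                          final_len >= config$setter$min_tokens)
    setter_index <- if (length(setter_pos) > 0) setter_pos[1] - 1L
                    else NA_integer_

    conv_id <- sprintf("conv%05d", k)
    conversations[[k]] <- new_conversation(conv_id, c_id, roles, texts,
                                           outcome = outcome)
    gt_convs[[k]] <- list(conv_id = conv_id, counselor_id = c_id,
                          outcome = outcome, stages = stages,
                          setter_index = setter_index, exhibits = exhibits)
  }

  gt <- structure(list(conversations = gt_convs, quality = quality,
                       config = config),
                  class = "ground_truth")
  list(conversations = conversations, ground_truth = gt)
}

draw_category_words <- function(n, pools, persp, chunk, n_chunks, outcome) {
  channel <- sample(c("tense", "pronoun", "emotion"), n, replace = TRUE)
  out <- character(n)
  n_t <- sum(channel == "tense")
  if (n_t > 0) {
    f <- schedule_value(persp$future, chunk, n_chunks, outcome)
    sub <- sample(c("future", "past", "present"), n_t, replace = TRUE,
                  prob = c(f, (1 - f) / 2, (1 - f) / 2))
    out[channel == "tense"] <- vapply(sub, function(s)
      sample(pools[[s]], 1), character(1))
  }
  n_p <- sum(channel == "pronoun")
  if (n_p > 0) {
    fs <- schedule_value(persp$first, chunk, n_chunks, outcome)
    sub <- ifelse(stats::runif(n_p) < fs, "first_singular", "third_person")
    out[channel == "pronoun"] <- vapply(sub, function(s)
      sample(pools[[s]], 1), character(1))
  }
  n_e <- sum(channel == "emotion")
  if (n_e > 0) {
    ps <- schedule_value(persp$pos, chunk, n_chunks, outcome)
    sub <- ifelse(stats::runif(n_e) < ps, "pos_emo", "neg_emo")
    out[channel == "emotion"] <- vapply(sub, function(s)
      sample(pools[[s]], 1), character(1))
  }
  out
}

#' Export / read planted ground truth
#'
#' Serialized with [jsonlite::serializeJSON()], which preserves the full R
#' structure so the round trip is lossless.
#'
#' @param gt A `ground_truth` object.
#' @param path Output (resp. input) path.
#' @return `path` invisibly (export); the `ground_truth` object (read).
#' @export
export_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  writeLines(as.character(jsonlite::serializeJSON(gt)), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname export_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE),
                                  collapse = "\n"))
}

#' Analytic expected coordination under the generator's exhibit chain
#'
#' In the generator, exhibit indicators of one marker form a two-state Markov
#' chain over messages: P(exhibit | previous exhibited) = base + delta,
#' P(exhibit | previous did not) = base. The stationary exhibit rate is
#' base / (1 - delta), so the expected coordination value
#' P(reply exhibits | initial exhibits) - P(reply exhibits) is
#' `(base + delta) - base / (1 - delta)`.
#'
#' @param base Baseline exhibit probability.
#' @param delta Planted increment.
#' @return Expected coordination value.
#' @export
expected_coordination <- function(base, delta) {
  (base + delta) - base / (1 - delta)
}
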