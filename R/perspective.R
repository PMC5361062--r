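# Shared machinery for the three perspective-change trajectories: each is a
# ratio of lexicon-hit counts pooled over texter messages per
# (conversation-time chunk, outcome group).
trajectory_ratio <- function(convs, num_lex, denom_lex, n_chunks = 5,
                             role = "texter", n_boot = 200, level = 0.95,
                             seed = 1, measure = "measure") {
  lab <- Filter(is_labeled, convs)
  if (length(lab) == 0) stop("no labeled conversations")
  # per conversation: numerator and denominator hit counts per chunk
  per_conv <- lapply(lab, function(cv) {
    ids <- chunk_assignment(length(cv$messages), n_chunks)
    num <- den <- numeric(n_chunks)
    for (i in seq_along(cv$messages)) {
      m <- cv$messages[[i]]
      if (m$role != role) next
      nh <- sum(lexicon_hits(m$tokens, num_lex))
      dh <- sum(lexicon_hits(m$tokens, denom_lex))
      num[ids[i]] <- num[ids[i]] + nh
      den[ids[i]] <- den[ids[i]] + nh + dh
    }
    list(num = num, den = den)
  })
  outcome <- vapply(lab, `[[`, character(1), "outcome")
  ratios <- function(sel) {
    num <- Reduce(`+`, lapply(per_conv[sel], `[[`, "num"))
    den <- Reduce(`+`, lapply(per_conv[sel], `[[`, "den"))
    ifelse(den > 0, num / den, NA_real_)
  }
  out <- list()
  for (grp in c("positive", "negative")) {
    sel <- which(outcome == grp)
    if (length(sel) == 0) next
    pt <- ratios(sel)
    boot <- matrix(NA_real_, n_boot, n_chunks)
    if (n_boot > 0) {
      set.seed(seed)
      for (b in seq_len(n_boot)) {
        boot[b, ] <- ratios(sample(sel, length(sel), replace = TRUE))
      }
    }
    ci <- apply(boot, 2, function(x)
      if (all(is.na(x))) c(NA_real_, NA_real_) else percentile_ci(x, level))
    out[[grp]] <- data.frame(measure = measure, outcome = grp,
                             chunk = seq_len(n_chunks), value = pt,
                             ci_lo = ci[1, ], ci_hi = ci[2, ])
  }
  do.call(rbind, out)
}

#' Temporal orientation trajectory
#'
#' Per conversation-time chunk and outcome group, the share of each tense
#' category among all tense-category tokens in texter messages:
#' `count(tense) / (count(past) + count(present) + count(future))`.
#'
#' @param convs Corpus (labeled conversations are used).
#' @param lexicons Category lexicons, see [default_category_lexicons()].
#' @param n_chunks Conversation-time chunks (default 5).
#' @param n_boot,level,seed Bootstrap (over conversations) settings.
#' @return Data frame: `measure` (`past`/`present`/`future`), `outcome`,
#'   `chunk`, `value`, `ci_lo`, `ci_hi`.
#' @export
temporal_orientation <- function(convs,
                                 lexicons = default_category_lexicons(),
                                 n_chunks = 5, n_boot = 200, level = 0.95,
                                 seed = 1) {
  tenses <- c("past", "present", "future")
  out <- lapply(tenses, function(t) {
    others <- unlist(lexicons[setdiff(tenses, t)])
    trajectory_ratio(convs, lexicons[[t]], others, n_chunks = n_chunks,
                     n_boot = n_boot, level = level, seed = seed,
                     measure = t)
  })
  do.call(rbind, out)
}

#' Self-focus trajectory
#'
#' First-person singular pronouns relative to first-person singular plus
#' third-person pronouns, in texter messages, per chunk and outcome group.
#'
#' @inheritParams temporal_orientation
#' @return Data frame as in [temporal_orientation()] with
#'   `measure = "self_focus"`.
#' @export
self_focus <- function(convs, lexicons = default_category_lexicons(),
                       n_chunks = 5, n_boot = 200, level = 0.95, seed = 1) {
  trajectory_ratio(convs, lexicons$first_singular, lexicons$third_person,
                   n_chunks = n_chunks, n_boot = n_boot, level = level,
                   seed = seed, measure = "self_focus")
}

#' Sentiment trajectory
#'
#' Positive-emotion tokens relative to positive plus negative emotion tokens,
#' in texter messages, per chunk and outcome group. Values below 0.5 mean
#' predominantly negative language.
#'
#' @inheritParams temporal_orientation
#' @return Data frame as in [temporal_orientation()] with
#'   `measure = "sentiment"`.
#' @export
sentiment_ratio <- function(convs, lexicons = default_category_lexicons(),
                            n_chunks = 5, n_boot = 200, level = 0.95,
                            seed = 1) {
  trajectory_ratio(convs, lexicons$pos_emo, lexicons$neg_emo,
                   n_chunks = n_chunks, n_boot = n_boot, level = level,
                   seed = seed, measure = "sentiment")
}
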