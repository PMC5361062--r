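#' Extract adjacent-message exchanges
#'
#' An exchange is an initial utterance by a speaker of role `A_role`
#' immediately followed by a reply of role `B_role`. Consecutive same-role
#' messages are not concatenated: a reply pairs only with the immediately
#' preceding other-role message.
#'
#' @param convs Corpus.
#' @param B_role Role of the repliers (group B, default `"texter"`).
#' @param A_role Role of the initiators (default `"counselor"`).
#' @param markers Named list of marker word lists (wildcards supported, see
#'   [lexicon_hits()]).
#' @return Data frame with one row per exchange: `conv_id`, `speaker`
#'   (identifier of the replier: the counselor id when B is the counselor,
#'   otherwise the conversation id, since each conversation has one texter),
#'   and logical columns `u1_<marker>` / `u2_<marker>` for the exhibit
#'   events of the initial utterance and the reply.
#' @export
extract_exchanges <- function(convs, B_role = "texter",
                              A_role = "counselor",
                              markers = default_marker_lexicons()) {
  rows <- list()
  for (cv in convs) {
    roles <- conv_roles(cv)
    n <- length(roles)
    if (n < 2) next
    speaker <- if (B_role == "counselor") cv$counselor_id else cv$conv_id
    for (i in seq_len(n - 1)) {
      if (roles[i] == A_role && roles[i + 1] == B_role) {
        u1 <- cv$messages[[i]]$tokens
        u2 <- cv$messages[[i + 1]]$tokens
        rec <- list(conv_id = cv$conv_id, speaker = speaker)
        for (m in names(markers)) {
          rec[[paste0("u1_", m)]] <- any(lexicon_hits(u1, markers[[m]]))
          rec[[paste0("u2_", m)]] <- any(lexicon_hits(u2, markers[[m]]))
        }
        rows[[length(rows) + 1]] <- rec
      }
    }
  }
  if (length(rows) == 0) {
    cols <- c("conv_id", "speaker",
              paste0("u1_", names(markers)), paste0("u2_", names(markers)))
    out <- as.data.frame(stats::setNames(
      replicate(length(cols), logical(0), simplify = FALSE), cols))
    out$conv_id <- character(0); out$speaker <- character(0)
    return(out)
  }
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Coordination of a set of exchanges along one marker
#'
#' `C^m = P(reply exhibits m | initial exhibits m) - P(reply exhibits m)`,
#' both probabilities estimated over the given exchanges. Undefined (NA) when
#' no initial utterance exhibits the marker.
#'
#' @param u1,u2 Logical vectors: exhibit indicators of the initial utterances
#'   and replies.
#' @return Coordination value in `[-1, 1]`, or `NA` if undefined.
#' @export
coordination_per_marker <- function(u1, u2) {
  stopifnot(length(u1) == length(u2), length(u1) >= 1)
  if (!any(u1)) return(NA_real_)
  mean(u2[u1]) - mean(u2)
}

#' Speaker-level and group-level coordination
#'
#' For every replier with at least `min_exchanges` exchanges, computes the
#' per-marker coordination values, macro-averages them over the markers that
#' are defined for that speaker, and reports the group value as the
#' unweighted mean over speakers. With `pool = TRUE` the per-marker values
#' are instead computed over all exchanges pooled, and the group value is
#' the macro-average over markers.
#'
#' @param exchanges Data frame from [extract_exchanges()].
#' @param markers Marker names (defaults to those present in `exchanges`).
#' @param min_exchanges Minimum exchanges per speaker (default 10).
#' @param pool Pool exchanges across speakers instead of macro-averaging per
#'   speaker.
#' @return List of class `coordination_result`: `group_value`, `by_speaker`
#'   (data frame `speaker`, `c_value`, `n_exchanges`), `by_marker` (named
#'   vector of pooled per-marker values).
#' @export
coordination <- function(exchanges, markers = NULL, min_exchanges = 10,
                         pool = FALSE) {
  if (is.null(markers)) {
    markers <- sub("^u1_", "", grep("^u1_", names(exchanges), value = TRUE))
  }
  by_marker <- vapply(markers, function(m)
    coordination_per_marker(exchanges[[paste0("u1_", m)]],
                            exchanges[[paste0("u2_", m)]]), numeric(1))
  spk <- split(seq_len(nrow(exchanges)), exchanges$speaker)
  spk <- spk[vapply(spk, length, integer(1)) >= min_exchanges]
  by_speaker <- data.frame(speaker = names(spk),
                           c_value = NA_real_,
                           n_exchanges = vapply(spk, length, integer(1)),
                           stringsAsFactors = FALSE, row.names = NULL)
  for (k in seq_along(spk)) {
    rows <- spk[[k]]
    cm <- vapply(markers, function(m)
      coordination_per_marker(exchanges[[paste0("u1_", m)]][rows],
                              exchanges[[paste0("u2_", m)]][rows]),
      numeric(1))
    if (any(!is.na(cm))) by_speaker$c_value[k] <- mean(cm, na.rm = TRUE)
  }
  defined <- !is.na(by_speaker$c_value)
  group_value <- if (pool) {
    mean(by_marker, na.rm = TRUE)
  } else if (any(defined)) {
    mean(by_speaker$c_value[defined])
  } else NA_real_
  structure(list(group_value = group_value,
                 by_speaker = by_speaker[defined, , drop = FALSE],
                 by_marker = by_marker),
            class = "coordination_result")
}

#' @export
print.coordination_result <- function(x, ...) {
  cat(sprintf("<coordination: group value %.4f over %d speakers>\n",
              x$group_value, nrow(x$by_speaker)))
  invisible(x)
}

#' Coordination on psycholinguistic category markers
#'
#' Same statistic as [coordination()], with category lexicons (e.g. future
#' words, third-person pronouns, positive emotion) as the markers and the
#' texter as the replying group: measures the increase in the texter's
#' probability of using a category word right after the counselor used one.
#' Per-category significance is a Wilcoxon signed-rank test of the
#' per-speaker values against zero.
#'
#' @param convs Corpus.
#' @param category_lexicons Named list of word lists (default
#'   [default_category_lexicons()]).
#' @param B_role,A_role Replier / initiator roles.
#' @param min_exchanges Minimum exchanges per speaker.
#' @return Data frame: `category`, `c_value` (mean over speakers),
#'   `n_speakers`, `p_value`.
#' @export
category_coordination <- function(convs,
                                  category_lexicons = default_category_lexicons(),
                                  B_role = "texter", A_role = "counselor",
                                  min_exchanges = 10) {
  ex <- extract_exchanges(convs, B_role = B_role, A_role = A_role,
                          markers = category_lexicons)
  spk <- split(seq_len(nrow(ex)), ex$speaker)
  spk <- spk[vapply(spk, length, integer(1)) >= min_exchanges]
  out <- lapply(names(category_lexicons), function(m) {
    vals <- vapply(spk, function(rows)
      coordination_per_marker(ex[[paste0("u1_", m)]][rows],
                              ex[[paste0("u2_", m)]][rows]), numeric(1))
    vals <- vals[!is.na(vals)]
    p <- if (length(vals) >= 3 && any(vals != 0)) {
      suppressWarnings(stats::wilcox.test(vals, mu = 0)$p.value)
    } else NA_real_
    data.frame(category = m,
               c_value = if (length(vals)) mean(vals) else NA_real_,
               n_speakers = length(vals), p_value = p)
  })
  do.call(rbind, out)
}

#' Permutation null interval for a group coordination value
#'
#' Shuffles the initial-utterance exhibit flags across exchanges (separately
#' per marker), breaking any initial-reply dependence while preserving the
#' marginal rates, and recomputes the group value.
#'
#' @param exchanges Data frame from [extract_exchanges()].
#' @param n_perm Number of permutations (default 200).
#' @param level Interval level.
#' @param seed Seed.
#' @param ... Passed to [coordination()].
#' @return Numeric vector `c(lo, hi)`.
#' @export
coordination_null <- function(exchanges, n_perm = 200, level = 0.95,
                              seed = 1, ...) {
  u1_cols <- grep("^u1_", names(exchanges), value = TRUE)
  set.seed(seed)
  vals <- vapply(seq_len(n_perm), function(p) {
    perm <- exchanges
    for (cl in u1_cols) perm[[cl]] <- sample(perm[[cl]])
    coordination(perm, ...)$group_value
  }, numeric(1))
  percentile_ci(vals, level)
}
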