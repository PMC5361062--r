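#' Build the model vocabulary with UNK folding
#'
#' Words occurring strictly more than `min_count` times in the corpus are
#' kept; all other tokens are folded into the unknown token `"<unk>"`.
#'
#' @param convs Corpus.
#' @param min_count Frequency cutoff (strict `>`, default 20).
#' @return Character vector of kept words plus `"<unk>"` (last element), with
#'   attribute `coverage`: the fraction of corpus tokens kept.
#' @export
build_vocab <- function(convs, min_count = 20) {
  toks <- unlist(lapply(convs, function(cv) unlist(conv_token_list(cv))))
  if (length(toks) == 0) stop("empty corpus")
  freq <- table(toks)
  kept <- sort(names(freq)[freq > min_count])
  structure(c(kept, "<unk>"),
            coverage = sum(freq[kept]) / length(toks))
}

# Integer token ids per message (unknown words -> unk id), plus role codes
# (1 = counselor, 2 = texter). Cached per conversation for EM.
conv_ids <- function(conv, vocab) {
  unk <- length(vocab)
  list(
    tokens = lapply(conv$messages, function(m) {
      ids <- match(m$tokens, vocab)
      ids[is.na(ids)] <- unk
      ids
    }),
    roles = match(conv_roles(conv), c("counselor", "texter")))
}

#' Initialize the ordered-stage conversation HMM
#'
#' Every (stage, role) emission distribution starts at the corpus unigram
#' distribution of that role, multiplied by a small random perturbation
#' `(1 + perturbation * u)`, `u ~ U(-1, 1)`, and renormalized; advance
#' probabilities start uniform across stages, with the last stage absorbing.
#' The perturbation breaks the symmetry of the exact unigram initialization,
#' which is an EM fixed point.
#'
#' @param convs Corpus.
#' @param n_stages Number of ordered stages (default 5).
#' @param vocab Vocabulary from [build_vocab()].
#' @param perturbation Relative perturbation scale (default 1e-2).
#' @param seed Seed for the perturbation.
#' @param advance_init Initial per-message advance probability, the same at
#'   every stage (default 0.15). The default makes prior expected stage
#'   durations roughly uniform for conversations of typical length; a large
#'   value such as 0.5 implies two-message stages a priori, which pulls the
#'   first E step — and hence the EM basin — toward degenerate
#'   segmentations that collapse early stages.
#' @return An object of class `stage_hmm`: `n_stages`, `vocab`, `emission`
#'   (per role, an `n_stages x V` row-stochastic matrix), `advance_prob`
#'   (`n_stages x 2` matrix, columns counselor/texter, last row 0), and
#'   `loglik_trace`.
#' @export
init_model <- function(convs, n_stages = 5, vocab = build_vocab(convs),
                       perturbation = 1e-2, seed = 1, advance_init = 0.15) {
  V <- length(vocab)
  set.seed(seed)
  emission <- lapply(c(counselor = "counselor", texter = "texter"),
    function(role) {
      toks <- unlist(lapply(convs, function(cv)
        unlist(lapply(cv$messages, function(m)
          if (m$role == role) m$tokens else character(0)))))
      ids <- match(toks, vocab)
      ids[is.na(ids)] <- V
      base <- tabulate(ids, nbins = V)
      if (sum(base) == 0) base <- rep(1, V)
      base <- base / sum(base)
      E <- matrix(rep(base, each = n_stages), nrow = n_stages)
      E <- E * (1 + perturbation * matrix(stats::runif(n_stages * V, -1, 1),
                                          n_stages, V))
      E / rowSums(E)
    })
  advance <- matrix(advance_init, n_stages, 2,
                    dimnames = list(NULL, c("counselor", "texter")))
  advance[n_stages, ] <- 0
  structure(list(n_stages = n_stages, vocab = vocab, emission = emission,
                 advance_prob = advance, loglik_trace = numeric(0)),
            class = "stage_hmm")
}

#' @export
print.stage_hmm <- function(x, ...) {
  cat(sprintf("<stage_hmm: %d stages, vocabulary %d (+UNK), %d EM iterations>\n",
              x$n_stages, length(x$vocab) - 1, length(x$loglik_trace)))
  invisible(x)
}

# n_messages x n_stages matrix of message log emission probabilities:
# log P(message | stage, role) = sum of token log emissions.
message_loglik <- function(model, ids) {
  S <- model$n_stages
  n <- length(ids$tokens)
  logE <- if (!is.null(model$log_emission)) model$log_emission
          else lapply(model$emission, log)
  L <- matrix(0, n, S)
  for (i in seq_len(n)) {
    lE <- logE[[ids$roles[i]]]
    v <- ids$tokens[[i]]
    L[i, ] <- if (length(v) == 0) 0 else rowSums(lE[, v, drop = FALSE])
  }
  L
}

#' Forward-backward pass for one conversation
#'
#' Computes the exact conversation log likelihood and the posterior stage
#' distributions under the left-to-right constraint: conversations start in
#' stage 1 and each message's stage equals or is one above the previous
#' message's stage. A transition (stay / advance) happens after every
#' message, with probability depending on the current stage and the role of
#' the message just produced.
#'
#' @param model A `stage_hmm`.
#' @param conv A `conversation` (or a cached `conv_ids` list).
#' @return List: `loglik`, `gamma` (`n x S` posterior stage marginals, rows
#'   sum to 1), `xi_advance` (`(n-1) x S`: posterior probability that the
#'   transition after message `i` advanced from stage `s`), and `xi_stay`.
#' @export
forward_backward <- function(model, conv) {
  ids <- if (inherits(conv, "conversation")) conv_ids(conv, model$vocab)
         else conv
  S <- model$n_stages
  n <- length(ids$tokens)
  L <- message_loglik(model, ids)
  adv <- model$advance_prob
  log_adv <- log(adv)
  log_stay <- log(1 - adv)

  alpha <- matrix(-Inf, n, S)
  alpha[1, 1] <- L[1, 1]
  if (n > 1) {
    for (i in 2:n) {
      r <- ids$roles[i - 1]
      for (s in seq_len(S)) {
        acc <- alpha[i - 1, s] + log_stay[s, r]
        if (s > 1) acc <- logsumexp(c(acc, alpha[i - 1, s - 1] +
                                        log_adv[s - 1, r]))
        alpha[i, s] <- acc + L[i, s]
      }
    }
  }
  ll <- logsumexp(alpha[n, ])
  if (!is.finite(ll)) stop("conversation has zero probability under model")

  beta <- matrix(-Inf, n, S)
  beta[n, ] <- 0
  if (n > 1) {
    for (i in (n - 1):1) {
      r <- ids$roles[i]
      for (s in seq_len(S)) {
        acc <- log_stay[s, r] + L[i + 1, s] + beta[i + 1, s]
        if (s < S) acc <- logsumexp(c(acc, log_adv[s, r] + L[i + 1, s + 1] +
                                        beta[i + 1, s + 1]))
        beta[i, s] <- acc
      }
    }
  }
  gamma <- exp(alpha + beta - ll)
  gamma <- gamma / rowSums(gamma)

  xi_adv <- xi_stay <- NULL
  if (n > 1) {
    xi_adv <- matrix(0, n - 1, S)
    xi_stay <- matrix(0, n - 1, S)
    for (i in seq_len(n - 1)) {
      r <- ids$roles[i]
      for (s in seq_len(S)) {
        xi_stay[i, s] <- exp(alpha[i, s] + log_stay[s, r] + L[i + 1, s] +
                               beta[i + 1, s] - ll)
        if (s < S) {
          xi_adv[i, s] <- exp(alpha[i, s] + log_adv[s, r] + L[i + 1, s + 1] +
                                beta[i + 1, s + 1] - ll)
        }
      }
    }
  }
  list(loglik = ll, gamma = gamma, xi_advance = xi_adv, xi_stay = xi_stay)
}

#' Fit the conversation model with expectation maximization
#'
#' Alternates forward-backward E steps over the corpus with M steps that
#' re-estimate emissions from expected token counts (mixed with a uniform
#' distribution of weight `smoothing` to keep likelihoods finite) and
#' advance probabilities from expected transition counts. Stops when the
#' relative log-likelihood improvement drops below `tol` or after `max_iter`
#' iterations. The log-likelihood trace is recorded and is non-decreasing.
#'
#' @param model Initialized `stage_hmm`.
#' @param convs Corpus.
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-4).
#' @param smoothing Uniform-mixture weight for emission smoothing
#'   (default 1e-6; 0 gives the exact maximum-likelihood M step).
#' @param verbose Print per-iteration log likelihood.
#' @return The fitted `stage_hmm` with `loglik_trace` filled in.
#' @export
fit_em <- function(model, convs, max_iter = 100, tol = 1e-4,
                   smoothing = 1e-6, verbose = FALSE) {
  S <- model$n_stages
  V <- length(model$vocab)
  cache <- lapply(convs, conv_ids, vocab = model$vocab)
  # per-conversation sparse message-by-word count matrices, split by role
  counts <- lapply(cache, function(ids) {
    n <- length(ids$tokens)
    ii <- rep(seq_len(n), lengths(ids$tokens))
    jj <- unlist(ids$tokens)
    Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, V))
  })
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    model$log_emission <- lapply(model$emission, log)
    em_counts <- list(counselor = matrix(0, S, V), texter = matrix(0, S, V))
    adv_num <- matrix(0, S, 2); adv_den <- matrix(0, S, 2)
    ll <- 0
    for (k in seq_along(cache)) {
      fb <- forward_backward(model, cache[[k]])
      ll <- ll + fb$loglik
      roles <- cache[[k]]$roles
      n <- length(roles)
      for (r in 1:2) {
        rows <- which(roles == r)
        if (length(rows) > 0) {
          rn <- c("counselor", "texter")[r]
          em_counts[[rn]] <- em_counts[[rn]] +
            as.matrix(Matrix::crossprod(
              Matrix::Matrix(fb$gamma[rows, , drop = FALSE], sparse = FALSE),
              counts[[k]][rows, , drop = FALSE]))
        }
      }
      if (n > 1) {
        for (i in seq_len(n - 1)) {
          r <- roles[i]
          adv_num[, r] <- adv_num[, r] + fb$xi_advance[i, ]
          adv_den[, r] <- adv_den[, r] + fb$xi_advance[i, ] + fb$xi_stay[i, ]
        }
      }
    }
    if (!is.finite(ll)) stop("non-finite corpus log likelihood at iteration ", it)
    trace <- c(trace, ll)
    # M step
    model$emission <- lapply(em_counts, function(cnt) {
      tot <- rowSums(cnt)
      E <- cnt / ifelse(tot > 0, tot, 1)
      E[tot == 0, ] <- 1 / V
      (1 - smoothing) * E + smoothing / V
    })
    adv <- ifelse(adv_den > 0, adv_num / adv_den, 0)
    adv[S, ] <- 0
    dimnames(adv) <- dimnames(model$advance_prob)
    model$advance_prob <- adv
    if (verbose) message(sprintf("EM iter %d: loglik %.4f", it, ll))
    if (it > 1 && abs(trace[it] - trace[it - 1]) <
          tol * abs(trace[it - 1])) break
  }
  model$log_emission <- NULL
  model$loglik_trace <- trace
  model
}

#' Most likely stage path of a conversation
#'
#' Viterbi decoding under the left-to-right constraint. Ties are broken
#' toward staying in the current stage.
#'
#' @param model Fitted `stage_hmm`.
#' @param conv A `conversation`.
#' @return An object of class `stage_path`: `stages` (integer vector, one per
#'   message, starting at 1, non-decreasing, increments of at most 1) and
#'   `durations` (messages spent in each stage, summing to the message
#'   count).
#' @export
viterbi_decode <- function(model, conv) {
  ids <- if (inherits(conv, "conversation")) conv_ids(conv, model$vocab)
         else conv
  S <- model$n_stages
  n <- length(ids$tokens)
  L <- message_loglik(model, ids)
  log_adv <- log(model$advance_prob)
  log_stay <- log(1 - model$advance_prob)

  delta <- matrix(-Inf, n, S)
  from_advance <- matrix(FALSE, n, S)
  delta[1, 1] <- L[1, 1]
  if (n > 1) {
    for (i in 2:n) {
      r <- ids$roles[i - 1]
      for (s in seq_len(S)) {
        stay <- delta[i - 1, s] + log_stay[s, r]
        advance <- if (s > 1) delta[i - 1, s - 1] + log_adv[s - 1, r] else -Inf
        # tie broken toward staying
        if (advance > stay) {
          delta[i, s] <- advance + L[i, s]
          from_advance[i, s] <- TRUE
        } else {
          delta[i, s] <- stay + L[i, s]
        }
      }
    }
  }
  stages <- integer(n)
  stages[n] <- which.max(delta[n, ])
  if (n > 1) {
    for (i in n:2) {
      stages[i - 1] <- if (from_advance[i, stages[i]]) stages[i] - 1L
                       else stages[i]
    }
  }
  structure(list(stages = stages,
                 durations = tabulate(stages, nbins = S)),
            class = "stage_path")
}

#' Brute-force likelihood and best path by enumeration
#'
#' Enumerates every monotone stage sequence (start at stage 1, increments of
#' at most 1) for a short conversation and sums / maximizes the exact joint
#' probabilities. Independent oracle for [forward_backward()] and
#' [viterbi_decode()]; cost grows combinatorially, so conversations must be
#' short.
#'
#' @param model A `stage_hmm`.
#' @param conv A `conversation` with few messages (<= ~10).
#' @return List: `loglik`, `best_path` (integer vector), `best_logprob`.
#' @export
brute_force_stage_oracle <- function(model, conv) {
  ids <- if (inherits(conv, "conversation")) conv_ids(conv, model$vocab)
         else conv
  S <- model$n_stages
  n <- length(ids$tokens)
  stopifnot(n <= 12)
  L <- message_loglik(model, ids)
  log_adv <- log(model$advance_prob)
  log_stay <- log(1 - model$advance_prob)

  paths <- list(1L)
  for (i in seq_len(n - 1)) {
    paths <- unlist(lapply(paths, function(p) {
      s <- p[length(p)]
      nxt <- if (s < S) list(c(p, s), c(p, s + 1L)) else list(c(p, s))
      nxt
    }), recursive = FALSE)
  }
  logp <- vapply(paths, function(p) {
    lp <- L[1, 1]
    if (n > 1) {
      for (i in 2:n) {
        r <- ids$roles[i - 1]
        lp <- lp + (if (p[i] == p[i - 1]) log_stay[p[i], r]
                    else log_adv[p[i - 1], r]) + L[i, p[i]]
      }
    }
    lp
  }, numeric(1))
  best <- which.max(logp)
  list(loglik = logsumexp(logp), best_path = paths[[best]],
       best_logprob = logp[best])
}

#' Mean stage durations by counselor group
#'
#' Viterbi-decodes qualifying conversations (length between `min_len` and
#' `max_len` messages, counselor in the split) and averages per-stage
#' durations within each group, giving positive and negative conversations
#' equal weight (the group mean is the average of the positive-conversation
#' mean and the negative-conversation mean). Confidence intervals by
#' counselor bootstrap.
#'
#' @param convs Corpus.
#' @param model Fitted `stage_hmm`.
#' @param split A [split_counselors()] result.
#' @param min_len,max_len Conversation length window in messages
#'   (defaults 40 and 60).
#' @param n_boot Bootstrap resamples over counselors (default 200).
#' @param level CI level.
#' @param seed Bootstrap seed.
#' @return Data frame: `group`, `stage`, `mean_duration`, `ci_lo`, `ci_hi`,
#'   `n_conversations`.
#' @export
stage_durations <- function(convs, model, split, min_len = 40, max_len = 60,
                            n_boot = 200, level = 0.95, seed = 1) {
  S <- model$n_stages
  qual <- Filter(function(cv) {
    n <- length(cv$messages)
    is_labeled(cv) && n >= min_len && n <= max_len &&
      !is.na(split_group(split, cv))
  }, convs)
  if (length(qual) == 0) stop("no qualifying conversations for stage durations")
  dur <- t(vapply(qual, function(cv) viterbi_decode(model, cv)$durations,
                  numeric(S)))
  grp <- vapply(qual, function(cv) split_group(split, cv), character(1))
  out <- vapply(qual, `[[`, character(1), "outcome")
  cid <- vapply(qual, `[[`, character(1), "counselor_id")

  eq_mean <- function(sel) {
    pos <- sel & out == "positive"; neg <- sel & out == "negative"
    if (!any(pos) || !any(neg)) {
      return(colMeans(dur[sel, , drop = FALSE]))
    }
    (colMeans(dur[pos, , drop = FALSE]) +
       colMeans(dur[neg, , drop = FALSE])) / 2
  }

  res <- list()
  for (g in c("more_successful", "less_successful")) {
    sel <- grp == g
    if (!any(sel)) next
    m <- eq_mean(sel)
    ctrs <- unique(cid[sel])
    boot <- matrix(NA_real_, n_boot, S)
    if (n_boot > 0) {
      set.seed(seed)
      for (b in seq_len(n_boot)) {
        res_c <- sample(ctrs, length(ctrs), replace = TRUE)
        idx <- unlist(lapply(res_c, function(cc) which(sel & cid == cc)))
        if (length(idx) == 0) next
        o <- out[idx]
        pos <- o == "positive"; neg <- o == "negative"
        boot[b, ] <- if (any(pos) && any(neg)) {
          (colMeans(dur[idx[pos], , drop = FALSE]) +
             colMeans(dur[idx[neg], , drop = FALSE])) / 2
        } else colMeans(dur[idx, , drop = FALSE])
      }
    }
    ci <- apply(boot, 2, function(x)
      if (all(is.na(x))) c(NA_real_, NA_real_) else percentile_ci(x, level))
    res[[g]] <- data.frame(group = g, stage = seq_len(S), mean_duration = m,
                           ci_lo = ci[1, ], ci_hi = ci[2, ],
                           n_conversations = sum(sel))
  }
  do.call(rbind, res)
}

#' Words most characteristic of each stage
#'
#' Ranks words by the ratio of their stage emission probability to the
#' corpus unigram probability of their role, restricted to words above a
#' corpus frequency floor.
#'
#' @param model Fitted `stage_hmm`.
#' @param convs Corpus (for the frequency floor and unigram reference).
#' @param per_stage Words reported per (stage, role) (default 5).
#' @param min_freq Corpus frequency floor (default 50).
#' @return Data frame: `stage`, `role`, `word`, `lift`.
#' @export
stage_top_words <- function(model, convs, per_stage = 5, min_freq = 50) {
  vocab <- model$vocab
  V <- length(vocab)
  toks <- unlist(lapply(convs, function(cv) unlist(conv_token_list(cv))))
  ids <- match(toks, vocab)
  ids[is.na(ids)] <- V
  freq <- tabulate(ids, nbins = V)
  ok <- freq >= min_freq & vocab != "<unk>"
  out <- list()
  for (role in names(model$emission)) {
    E <- model$emission[[role]]
    base <- colMeans(E)   # stage-average as the unigram reference
    lift <- sweep(E, 2, pmax(base, 1e-12), "/")
    for (s in seq_len(model$n_stages)) {
      l <- lift[s, ]
      l[!ok] <- -Inf
      top <- order(l, decreasing = TRUE)[seq_len(per_stage)]
      out[[length(out) + 1]] <- data.frame(
        stage = s, role = role, word = vocab[top], lift = l[top])
    }
  }
  do.call(rbind, out)
}
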