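#' Balance positive and negative conversations
#'
#' Keeps labeled conversations strictly longer than `min_messages` messages
#' and randomly subsamples the larger outcome class so both classes have
#' equal counts.
#'
#' @param convs Corpus.
#' @param min_messages Length cutoff (strict `>`, default 30).
#' @param seed Subsampling seed.
#' @return List of conversations with equal class counts.
#' @export
balance_dataset <- function(convs, min_messages = 30, seed = 1) {
  lab <- Filter(function(cv) is_labeled(cv) &&
                  length(cv$messages) > min_messages, convs)
  out <- vapply(lab, `[[`, character(1), "outcome")
  pos <- which(out == "positive"); neg <- which(out == "negative")
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both outcome classes must be present")
  }
  n <- min(length(pos), length(neg))
  set.seed(seed)
  keep <- sort(c(if (length(pos) > n) sample(pos, n) else pos,
                 if (length(neg) > n) sample(neg, n) else neg))
  lab[keep]
}

#' Lexicon-ratio message sentiment scorer
#'
#' `(positive hits - negative hits) / (positive + negative hits)`, 0 when the
#' message contains no emotion words. Any scorer with this signature
#' (tokens -> numeric in `[-1, 1]`) can be plugged into
#' [extract_features()].
#'
#' @param tokens Token vector.
#' @param lexicons Category lexicons providing `pos_emo` / `neg_emo`.
#' @return Numeric in `[-1, 1]`.
#' @export
lexicon_sentiment <- function(tokens, lexicons = default_category_lexicons()) {
  p <- sum(lexicon_hits(tokens, lexicons$pos_emo))
  n <- sum(lexicon_hits(tokens, lexicons$neg_emo))
  if (p + n == 0) 0 else (p - n) / (p + n)
}

prefix_messages <- function(conv, x_percent) {
  n <- length(conv$messages)
  k <- max(1L, ceiling(x_percent / 100 * n))
  conv$messages[seq_len(min(k, n))]
}

#' Prefix features of one conversation
#'
#' All features are computed on the first `x_percent` of messages only.
#' Base features use counselor messages: hedge rate and check-question rate
#' (pattern matches per message), mean unigram cosine similarity of each
#' counselor message to the immediately preceding texter message, per-stage
#' Viterbi durations on the prefix, mean message sentiment, and mean message
#' length. Stage conjunctions add each per-message base feature averaged
#' within each decoded stage (0 for stages the prefix never reaches). With
#' `texter_features = TRUE` the same per-message features over texter
#' messages are appended.
#'
#' @param conv A labeled `conversation`.
#' @param x_percent Percent of messages visible (default 80).
#' @param model Fitted `stage_hmm`.
#' @param lexicons Category lexicons (for the default sentiment scorer).
#' @param patterns Response-class patterns (hedge / check question).
#' @param sentiment_fn Message sentiment scorer, see [lexicon_sentiment()].
#' @param conjunctions Include per-stage feature conjunctions (default TRUE).
#' @param texter_features Append texter-message features (default FALSE).
#' @return Named numeric feature vector.
#' @export
extract_features <- function(conv, x_percent = 80, model,
                             lexicons = default_category_lexicons(),
                             patterns = default_response_patterns(),
                             sentiment_fn = NULL, conjunctions = TRUE,
                             texter_features = FALSE) {
  msgs <- prefix_messages(conv, x_percent)
  if (length(msgs) == 0) stop("empty message prefix")
  if (is.null(sentiment_fn)) {
    sentiment_fn <- function(tokens) lexicon_sentiment(tokens, lexicons)
  }
  S <- model$n_stages
  pre <- conv
  pre$messages <- msgs
  path <- viterbi_decode(model, pre)$stages

  match_any <- function(text, pats) {
    any(vapply(pats, function(p) grepl(p, tolower(text), perl = TRUE),
               logical(1)))
  }
  role_features <- function(role, suffix = "") {
    idx <- which(vapply(msgs, function(m) m$role == role, logical(1)))
    k <- length(idx)
    hedge <- check <- sim <- senti <- len <- numeric(k)
    for (j in seq_along(idx)) {
      i <- idx[j]
      m <- msgs[[i]]
      hedge[j] <- match_any(m$text, patterns$hedge)
      check[j] <- match_any(m$text, patterns$check_question)
      senti[j] <- sentiment_fn(m$tokens)
      len[j] <- length(m$tokens)
      prev <- if (i > 1) msgs[[i - 1]] else NULL
      sim[j] <- if (!is.null(prev) && prev$role != role) {
        cosine_sim(table(m$tokens), table(prev$tokens))
      } else 0
    }
    base <- c(hedge_rate = if (k) mean(hedge) else 0,
              check_rate = if (k) mean(check) else 0,
              sim_prev = if (k) mean(sim) else 0,
              sentiment = if (k) mean(senti) else 0,
              msg_len = if (k) mean(len) else 0)
    names(base) <- paste0(names(base), suffix)
    conj <- NULL
    if (conjunctions) {
      st <- path[idx]
      conj <- unlist(lapply(seq_len(S), function(s) {
        sel <- st == s
        v <- if (any(sel)) {
          c(mean(hedge[sel]), mean(check[sel]), mean(sim[sel]),
            mean(senti[sel]), mean(len[sel]))
        } else rep(0, 5)
        stats::setNames(v, sprintf("conj_%s_s%d%s",
                                   c("hedge", "check", "sim", "senti", "len"),
                                   s, suffix))
      }))
    }
    c(base, conj)
  }

  dur <- tabulate(path, nbins = S)
  names(dur) <- sprintf("stage_dur_%d", seq_len(S))
  out <- c(role_features("counselor"), dur)
  if (texter_features) out <- c(out, role_features("texter", suffix = "_t"))
  out
}

#' Feature matrix for a balanced conversation set
#'
#' Applies [extract_features()] to every conversation and optionally appends
#' counselor unigram and bigram count features (n-grams with corpus frequency
#' above `ngram_min_freq` within the visible prefixes).
#'
#' @inheritParams extract_features
#' @param convs List of labeled conversations.
#' @param use_ngrams Append n-gram count features.
#' @param ngram_min_freq Corpus frequency floor for n-gram features
#'   (default 5).
#' @return List: `X` (numeric matrix, rows = conversations), `y` (logical,
#'   TRUE = positive), `ngram_cols` (names of the n-gram columns).
#' @export
build_feature_matrix <- function(convs, x_percent = 80, model,
                                 lexicons = default_category_lexicons(),
                                 patterns = default_response_patterns(),
                                 sentiment_fn = NULL, conjunctions = TRUE,
                                 texter_features = FALSE, use_ngrams = FALSE,
                                 ngram_min_freq = 5) {
  X <- t(vapply(convs, function(cv)
    extract_features(cv, x_percent, model, lexicons, patterns, sentiment_fn,
                     conjunctions, texter_features),
    extract_features(convs[[1]], x_percent, model, lexicons, patterns,
                     sentiment_fn, conjunctions, texter_features)))
  ngram_cols <- character(0)
  if (use_ngrams) {
    grams <- lapply(convs, function(cv) {
      toks <- lapply(prefix_messages(cv, x_percent), function(m)
        if (m$role == "counselor") m$tokens else character(0))
      unlist(lapply(toks, function(t) c(t, bigrams(t))))
    })
    freq <- table(unlist(grams))
    keep <- sort(names(freq)[freq > ngram_min_freq])
    if (length(keep) > 0) {
      N <- t(vapply(grams, function(g) {
        tab <- table(factor(g, levels = keep))
        as.numeric(tab)
      }, numeric(length(keep))))
      colnames(N) <- paste0("ng:", keep)
      ngram_cols <- colnames(N)
      X <- cbind(X, N)
    }
  }
  y <- vapply(convs, function(cv) cv$outcome == "positive", logical(1))
  list(X = X, y = y, ngram_cols = ngram_cols)
}

#' Penalized logistic regression by batch gradient descent
#'
#' Minimizes the mean negative log likelihood plus `lambda/2 * ||w||^2` (L2)
#' or `lambda * ||w||_1` (L1, by proximal soft-thresholding). The intercept
#' is never penalized. The step size is `1 / L` with `L` the Lipschitz
#' constant of the smooth part, so descent is monotone.
#'
#' @param X Numeric feature matrix (standardized columns recommended).
#' @param y Logical or 0/1 labels.
#' @param penalty `"L2"` or `"L1"`.
#' @param lambda Regularization strength (default 1e-2).
#' @param max_iter Maximum iterations (default 2000).
#' @param tol Stop when the max absolute parameter update is below this.
#' @return List: `intercept`, `weights`, `n_iter`, `converged`.
#' @export
fit_logistic <- function(X, y, penalty = c("L2", "L1"), lambda = 1e-2,
                         max_iter = 2000, tol = 1e-8) {
  penalty <- match.arg(penalty)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  Xb <- cbind(1, X)
  L <- (norm(Xb, "2")^2) / (4 * n) + if (penalty == "L2") lambda else 0
  step <- 1 / L
  w <- numeric(p + 1)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xb %*% w)
    mu <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(Xb, mu - y)) / n
    if (penalty == "L2") g[-1] <- g[-1] + lambda * w[-1]
    w_new <- w - step * g
    if (penalty == "L1") {
      w_new[-1] <- sign(w_new[-1]) * pmax(abs(w_new[-1]) - step * lambda, 0)
    }
    delta <- max(abs(w_new - w))
    w <- w_new
    if (delta < tol) {
      return(list(intercept = w[1], weights = w[-1], n_iter = it,
                  converged = TRUE))
    }
  }
  list(intercept = w[1], weights = w[-1], n_iter = max_iter,
       converged = FALSE)
}

logistic_score <- function(fit, X) {
  drop(fit$intercept + X %*% fit$weights)
}

standardize_cols <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
  }
  list(X = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Stratified k-fold cross-validated AUC
#'
#' Folds are stratified by label; features are standardized per fold (center
#' and scale fit on the training split only). Scores of held-out
#' conversations are pooled and AUC is computed per fold by the rank method.
#'
#' @param X Feature matrix.
#' @param y Logical labels.
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param penalty,lambda Passed to [fit_logistic()].
#' @return List of class `cv_result`: `mean_auc`, `mean_accuracy`,
#'   `per_fold` (data frame), `scores` (pooled out-of-fold scores aligned
#'   with rows of `X`), `folds`.
#' @export
cross_validate <- function(X, y, k = 10, seed = 1, penalty = "L2",
                           lambda = 1e-2) {
  n <- length(y)
  set.seed(seed)
  folds <- integer(n)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  scores <- numeric(n)
  per_fold <- data.frame(fold = seq_len(k), auc = NA_real_, acc = NA_real_)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[te])) < 2) {
      stop("fold ", f, " contains a single class; reduce k")
    }
    std <- standardize_cols(X[tr, , drop = FALSE])
    fit <- fit_logistic(std$X, y[tr], penalty = penalty, lambda = lambda)
    Xte <- standardize_cols(X[te, , drop = FALSE], std$center, std$scale)$X
    s <- logistic_score(fit, Xte)
    scores[te] <- s
    per_fold$auc[f] <- auc_rank(s, y[te])
    per_fold$acc[f] <- mean((s > 0) == y[te])
  }
  structure(list(mean_auc = mean(per_fold$auc),
                 mean_accuracy = mean(per_fold$acc),
                 per_fold = per_fold, scores = scores, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: mean AUC %.3f, mean accuracy %.3f over %d folds>\n",
              x$mean_auc, x$mean_accuracy, nrow(x$per_fold)))
  invisible(x)
}

#' Nested feature-set ladder
#'
#' Evaluates an ordered list of nested feature sets by cross-validated AUC,
#' with a paired bootstrap test between consecutive models: held-out scores
#' of both models are resampled over conversations and the p-value is the
#' fraction of resamples in which the larger model does not improve AUC.
#' The penalty follows the feature configuration: L1 when n-gram columns are
#' present in the set, L2 otherwise.
#'
#' @param X Feature matrix (all candidate columns).
#' @param y Logical labels.
#' @param sets Named list of character vectors of column names; sets are
#'   evaluated in order. An empty character vector gives the intercept-only
#'   baseline (AUC 0.5).
#' @param ngram_cols Names of n-gram columns (switches the penalty to L1).
#' @param k,seed,lambda Passed to [cross_validate()].
#' @param n_boot Bootstrap resamples for the paired test (default 500).
#' @return Data frame: `feature_set`, `n_features`, `auc`, `delta_auc`,
#'   `p_vs_previous`.
#' @export
feature_ladder <- function(X, y, sets, ngram_cols = character(0), k = 10,
                           seed = 1, lambda = 1e-2, n_boot = 500) {
  prev_scores <- NULL
  prev_auc <- NA_real_
  rows <- list()
  for (nm in names(sets)) {
    cols <- sets[[nm]]
    if (length(cols) == 0) {
      auc <- 0.5
      scores <- rep(0, length(y))
    } else {
      penalty <- if (any(cols %in% ngram_cols)) "L1" else "L2"
      cv <- cross_validate(X[, cols, drop = FALSE], y, k = k, seed = seed,
                           penalty = penalty, lambda = lambda)
      auc <- cv$mean_auc
      scores <- cv$scores
    }
    p <- NA_real_
    if (!is.null(prev_scores)) {
      set.seed(seed + 1)
      diffs <- vapply(seq_len(n_boot), function(b) {
        idx <- sample(length(y), replace = TRUE)
        if (length(unique(y[idx])) < 2) return(NA_real_)
        a2 <- if (stats::sd(scores[idx]) == 0) 0.5
              else auc_rank(scores[idx], y[idx])
        a1 <- if (stats::sd(prev_scores[idx]) == 0) 0.5
              else auc_rank(prev_scores[idx], y[idx])
        a2 - a1
      }, numeric(1))
      p <- mean(diffs <= 0, na.rm = TRUE)
    }
    rows[[nm]] <- data.frame(feature_set = nm, n_features = length(cols),
                             auc = auc,
                             delta_auc = if (is.na(prev_auc)) NA_real_
                                         else auc - prev_auc,
                             p_vs_previous = p)
    prev_scores <- scores
    prev_auc <- auc
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard nested feature sets in ladder order
#'
#' @param feature_names Column names of the feature matrix.
#' @param ngram_cols N-gram column names.
#' @return Named list of column-name vectors, from the empty baseline up to
#'   the full model.
#' @export
default_feature_sets <- function(feature_names, ngram_cols = character(0)) {
  base <- setdiff(feature_names, ngram_cols)
  dur <- grep("^stage_dur_", base, value = TRUE)
  conj <- grep("^conj_", base, value = TRUE)
  sets <- list(
    none = character(0),
    `+hedges` = "hedge_rate",
    `+check_questions` = c("hedge_rate", "check_rate"),
    `+similarity` = c("hedge_rate", "check_rate", "sim_prev"),
    `+stage_durations` = c("hedge_rate", "check_rate", "sim_prev", dur),
    `+sentiment` = c("hedge_rate", "check_rate", "sim_prev", dur,
                     "sentiment"),
    `+message_length` = c("hedge_rate", "check_rate", "sim_prev", dur,
                          "sentiment", "msg_len"),
    `+stage_conjunctions` = c("hedge_rate", "check_rate", "sim_prev", dur,
                              "sentiment", "msg_len", conj))
  if (length(ngram_cols) > 0) {
    sets$`+ngrams` <- c(sets$`+stage_conjunctions`, ngram_cols)
  }
  sets
}
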