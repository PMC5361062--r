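#' Find the situation setter of a conversation
#'
#' The situation setter is the first long texter message — the message in
#' which the texter first describes why they are texting in. "Long" means at
#' least `min_tokens` tokens.
#'
#' @param conv A `conversation`.
#' @param min_tokens Minimum token count (default 10).
#' @return List with `conv_id`, `index` (0-based message index), `n_tokens`,
#'   and `tokens`; or `NULL` when no texter message qualifies.
#' @export
find_situation_setter <- function(conv, min_tokens = 10) {
  stopifnot(min_tokens >= 1)
  for (m in conv$messages) {
    if (m$role == "texter" && length(m$tokens) >= min_tokens) {
      return(list(conv_id = conv$conv_id, index = m$index,
                  n_tokens = length(m$tokens), tokens = m$tokens))
    }
  }
  NULL
}

# Setters plus the counselor reply and next texter reply, one row per
# conversation that has a setter (and optionally the follow-ups).
setter_frame <- function(convs, min_tokens = 10) {
  rows <- list()
  for (cv in convs) {
    st <- find_situation_setter(cv, min_tokens)
    if (is.null(st)) next
    after <- cv$messages[vapply(cv$messages, function(m)
      m$index > st$index, logical(1))]
    c_reply <- Find(function(m) m$role == "counselor", after)
    t_reply <- if (!is.null(c_reply)) {
      Find(function(m) m$role == "texter" && m$index > c_reply$index, after)
    } else NULL
    rows[[length(rows) + 1]] <- list(
      conv_id = cv$conv_id, counselor_id = cv$counselor_id,
      outcome = if (is.null(cv$outcome)) NA_character_ else cv$outcome,
      n_messages = length(cv$messages),
      setter_index = st$index, setter_len = st$n_tokens,
      setter_tokens = st$tokens,
      c_reply_tokens = if (is.null(c_reply)) NULL else c_reply$tokens,
      c_reply_text = if (is.null(c_reply)) NA_character_ else c_reply$text,
      t_reply_tokens = if (is.null(t_reply)) NULL else t_reply$tokens)
  }
  rows
}

#' Positive-outcome fraction by situation-setter length
#'
#' Bins labeled conversations by the token length of their situation setter
#' and reports the fraction with a positive outcome per bin, with an exact
#' binomial confidence interval. Shorter setters are the more ambiguous
#' openings.
#'
#' @param convs Corpus.
#' @param setter_len_bins Numeric bin edges (right-closed, as in `cut`).
#' @param min_tokens Setter definition threshold (default 10).
#' @param level CI level.
#' @return Data frame: `bin`, `n`, `frac_positive`, `ci_lo`, `ci_hi`;
#'   empty bins carry `n = 0` and `NA` fractions.
#' @export
ambiguity_outcome_table <- function(convs, setter_len_bins,
                                    min_tokens = 10, level = 0.95) {
  sf <- setter_frame(convs, min_tokens)
  sf <- Filter(function(r) !is.na(r$outcome), sf)
  len <- vapply(sf, `[[`, numeric(1), "setter_len")
  pos <- vapply(sf, function(r) r$outcome == "positive", logical(1))
  bin <- cut(len, breaks = setter_len_bins, include.lowest = TRUE)
  out <- lapply(levels(bin), function(b) {
    sel <- which(bin == b)
    if (length(sel) == 0) {
      return(data.frame(bin = b, n = 0L, frac_positive = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    }
    k <- sum(pos[sel]); n <- length(sel)
    ci <- stats::binom.test(k, n, conf.level = level)$conf.int
    data.frame(bin = b, n = n, frac_positive = k / n,
               ci_lo = ci[1], ci_hi = ci[2])
  })
  do.call(rbind, out)
}

#' Counselor-to-texter length ratio by setter length
#'
#' For each conversation with a setter and a following counselor reply, the
#' ratio (counselor reply length) / (setter length), averaged within setter
#' length bins. A value of 1 would mean counselors write exactly as much as
#' the texter.
#'
#' @inheritParams ambiguity_outcome_table
#' @return Data frame: `bin`, `n`, `mean_ratio`.
#' @export
counselor_texter_length_ratio <- function(convs, setter_len_bins,
                                          min_tokens = 10) {
  sf <- Filter(function(r) !is.null(r$c_reply_tokens),
               setter_frame(convs, min_tokens))
  len <- vapply(sf, `[[`, numeric(1), "setter_len")
  ratio <- vapply(sf, function(r)
    length(r$c_reply_tokens) / r$setter_len, numeric(1))
  bin <- cut(len, breaks = setter_len_bins, include.lowest = TRUE)
  out <- lapply(levels(bin), function(b) {
    sel <- which(bin == b)
    data.frame(bin = b, n = length(sel),
               mean_ratio = if (length(sel) == 0) NA_real_
               else mean(ratio[sel]))
  })
  do.call(rbind, out)
}

bigrams <- function(tokens) {
  n <- length(tokens)
  if (n < 2) return(character(0))
  paste(tokens[-n], tokens[-1])
}

#' L2-normalized TF-IDF matrix over a document collection
#'
#' Features are bigrams by default (unigrams behind `unit = "unigram"`); the
#' idf is fit on the collection itself using the smoothed, strictly positive
#' convention `ln((1+N)/(1+df)) + 1`, so that identical documents map to
#' identical nonzero vectors (cosine distance exactly 0) even when a feature
#' occurs in every document. Documents with no features get zero rows.
#'
#' @param token_lists List of token vectors.
#' @param unit `"bigram"` or `"unigram"`.
#' @return Sparse `dgCMatrix`, one row per document, rows L2-normalized.
#' @export
tfidf_matrix <- function(token_lists, unit = c("bigram", "unigram")) {
  unit <- match.arg(unit)
  feats <- lapply(token_lists, function(t)
    if (unit == "bigram") bigrams(t) else t)
  vocabulary <- sort(unique(unlist(feats)))
  n <- length(feats)
  if (length(vocabulary) == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(n, 0)))
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in seq_len(n)) {
    if (length(feats[[d]]) == 0) next
    tab <- table(match(feats[[d]], vocabulary))
    ii <- c(ii, rep(d, length(tab)))
    jj <- c(jj, as.integer(names(tab)))
    xx <- c(xx, as.numeric(tab))
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n, length(vocabulary)),
                            dimnames = list(NULL, vocabulary))
  df <- Matrix::colSums(M > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  M <- M %*% Matrix::Diagonal(x = idf)
  nrm <- sqrt(Matrix::rowSums(M^2))
  nrm[nrm == 0] <- 1
  Matrix::Diagonal(x = 1 / nrm) %*% M
}

# Pairwise cosine-similarity matrix of a row-normalized matrix, with the
# snap-to-1 guard so identical documents are at distance exactly 0.
pairwise_cosine <- function(X) {
  S <- as.matrix(Matrix::tcrossprod(X))
  S[abs(S - 1) < 1e-12] <- 1
  S[S > 1] <- 1
  S
}

#' Cluster near-identical situation setters
#'
#' Setters are embedded as bigram TF-IDF vectors; each setter's neighbors are
#' the other setters within `distance_threshold` cosine distance. Setters
#' with at least `min_neighbors` neighbors seed dense clusters (the seed plus
#' its neighborhood); overlapping clusters are merged by union of members.
#' Construction is order-invariant.
#'
#' @param setter_tokens List of token vectors (one per setter).
#' @param distance_threshold Cosine distance threshold in `[0, 1]`
#'   (default 0.4).
#' @param min_neighbors Minimum neighborhood size to seed a cluster
#'   (default 10).
#' @param unit Feature unit, see [tfidf_matrix()].
#' @return List of clusters, each a list with sorted integer `members`
#'   (indices into `setter_tokens`) and `centers` (the seeds). Clusters are
#'   ordered by their smallest member.
#' @export
cluster_setters <- function(setter_tokens, distance_threshold = 0.4,
                            min_neighbors = 10, unit = "bigram") {
  if (distance_threshold < 0 || distance_threshold > 1) {
    stop("distance_threshold must lie in [0, 1]")
  }
  n <- length(setter_tokens)
  if (n < min_neighbors + 1) {
    stop(sprintf("need at least %d setters, got %d", min_neighbors + 1, n))
  }
  X <- tfidf_matrix(setter_tokens, unit = unit)
  S <- pairwise_cosine(X)
  nbr <- lapply(seq_len(n), function(i) {
    js <- which(1 - S[i, ] <= distance_threshold)
    setdiff(js, i)
  })
  centers <- which(vapply(nbr, length, integer(1)) >= min_neighbors)
  if (length(centers) == 0) return(list())
  # union-find over cluster seeds that share members
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (c0 in centers) for (j in c(c0, nbr[[c0]])) union_(c0, j)
  roots <- vapply(centers, find, integer(1))
  in_cluster <- sort(unique(c(centers, unlist(nbr[centers]))))
  groups <- split(in_cluster, vapply(in_cluster, find, integer(1)))
  out <- lapply(groups, function(mem) {
    list(members = sort(unname(mem)),
         centers = sort(intersect(mem, centers)))
  })
  out <- unname(out)
  out[order(vapply(out, function(cl) cl$members[1], integer(1)))]
}

#' Classify a counselor response to a situation setter
#'
#' Pattern-based booleans (check question, suicide check, thanks, hedge,
#' surprise) matched case-insensitively against the raw counselor reply,
#' plus token lengths and the cosine similarity of the counselor reply and
#' next texter reply to the setter.
#'
#' @param setter_tokens Token vector of the setter.
#' @param counselor_reply Raw counselor reply text.
#' @param next_texter_reply Raw next texter reply text (or `NA`).
#' @param patterns Named list of regex vectors, see
#'   [default_response_patterns()].
#' @param unit Similarity feature unit (default bigram).
#' @return List with one logical per pattern class, `c_len`, `t_len`,
#'   `sim_c`, `sim_t`.
#' @export
classify_response <- function(setter_tokens, counselor_reply,
                              next_texter_reply = NA_character_,
                              patterns = default_response_patterns(),
                              unit = "bigram") {
  reply <- if (is.na(counselor_reply)) "" else tolower(counselor_reply)
  flags <- lapply(patterns, function(pats)
    nzchar(reply) && any(vapply(pats, function(p)
      grepl(p, reply, perl = TRUE), logical(1))))
  c_toks <- tokenize(counselor_reply)
  t_toks <- if (is.na(next_texter_reply)) character(0)
            else tokenize(next_texter_reply)
  X <- tfidf_matrix(list(setter_tokens, c_toks, t_toks), unit = unit)
  S <- pairwise_cosine(X)
  c(flags, list(c_len = length(c_toks), t_len = length(t_toks),
                sim_c = max(0, S[1, 2]), sim_t = max(0, S[1, 3])))
}

#' Templatedness of counselor replies
#'
#' For each reply, the number of other replies within `distance_threshold`
#' cosine distance in TF-IDF space. High counts mean generic, templated
#' responses; low counts mean more creative, tailored ones.
#'
#' @param reply_tokens List of token vectors (>= 2 replies).
#' @param distance_threshold Cosine distance threshold (default 0.4).
#' @param unit Feature unit (default bigram).
#' @return Integer vector of neighbor counts, one per reply.
#' @export
templatedness <- function(reply_tokens, distance_threshold = 0.4,
                          unit = "bigram") {
  stopifnot(length(reply_tokens) >= 2)
  X <- tfidf_matrix(reply_tokens, unit = unit)
  S <- pairwise_cosine(X)
  vapply(seq_len(nrow(S)), function(i)
    sum(1 - S[i, -i] <= distance_threshold), integer(1))
}

#' Group comparison of responses to near-identical situation setters
#'
#' Clusters situation setters, restricts to clustered setters, classifies the
#' counselor reply to each, and compares the more- and less-successful
#' counselor groups. Group means are paired within each setter cluster and
#' compared with a Wilcoxon signed-rank test over clusters (clusters with
#' only one group present are skipped for the test).
#'
#' @param convs Corpus.
#' @param split A [split_counselors()] result.
#' @param min_tokens Setter threshold.
#' @param distance_threshold,min_neighbors Clustering parameters.
#' @param patterns Response-class patterns.
#' @param unit Similarity feature unit.
#' @return Data frame: `stat`, `more_successful`, `less_successful`,
#'   `p_value`, `n_clusters` (clusters contributing to the pairing).
#' @export
response_table <- function(convs, split, min_tokens = 10,
                           distance_threshold = 0.4, min_neighbors = 10,
                           patterns = default_response_patterns(),
                           unit = "bigram") {
  sf <- setter_frame(convs, min_tokens)
  sf <- Filter(function(r) !is.null(r$c_reply_tokens), sf)
  grp <- vapply(sf, function(r) {
    if (r$counselor_id %in% split$more_successful) "more_successful"
    else if (r$counselor_id %in% split$less_successful) "less_successful"
    else NA_character_
  }, character(1))
  keep <- !is.na(grp)
  sf <- sf[keep]; grp <- grp[keep]
  if (length(sf) < min_neighbors + 1) stop("too few setters after filtering")
  cl <- cluster_setters(lapply(sf, `[[`, "setter_tokens"),
                        distance_threshold, min_neighbors, unit = unit)
  if (length(cl) == 0) stop("no dense setter clusters found")
  cluster_of <- rep(NA_integer_, length(sf))
  for (k in seq_along(cl)) cluster_of[cl[[k]]$members] <- k

  stats_of <- function(r) {
    cls <- classify_response(r$setter_tokens, r$c_reply_text,
                             if (is.null(r$t_reply_tokens)) NA_character_
                             else paste(r$t_reply_tokens, collapse = " "),
                             patterns = patterns, unit = unit)
    c(successful = as.numeric(!is.na(r$outcome) && r$outcome == "positive"),
      n_messages = r$n_messages, setter_len = r$setter_len,
      c_resp_len = cls$c_len, t_resp_len = cls$t_len,
      sim_c = cls$sim_c, sim_t = cls$sim_t,
      check_question = as.numeric(cls$check_question),
      suicide_check = as.numeric(cls$suicide_check),
      thanks = as.numeric(cls$thanks), hedge = as.numeric(cls$hedge),
      surprise = as.numeric(cls$surprise))
  }
  vals <- t(vapply(sf, stats_of, numeric(12)))
  in_cl <- !is.na(cluster_of)
  vals <- vals[in_cl, , drop = FALSE]
  grp <- grp[in_cl]; cluster_of <- cluster_of[in_cl]

  out <- lapply(colnames(vals), function(st) {
    by_cl <- split(data.frame(v = vals[, st], g = grp), cluster_of)
    pairs <- vapply(by_cl, function(d) {
      c(more = if (any(d$g == "more_successful"))
          mean(d$v[d$g == "more_successful"]) else NA_real_,
        less = if (any(d$g == "less_successful"))
          mean(d$v[d$g == "less_successful"]) else NA_real_)
    }, numeric(2))
    both <- !is.na(pairs[1, ]) & !is.na(pairs[2, ])
    p <- if (sum(both) >= 3 && any(pairs[1, both] != pairs[2, both])) {
      suppressWarnings(stats::wilcox.test(pairs[1, both], pairs[2, both],
                                          paired = TRUE)$p.value)
    } else NA_real_
    data.frame(stat = st,
               more_successful = mean(vals[grp == "more_successful", st]),
               less_successful = mean(vals[grp == "less_successful", st]),
               p_value = p, n_clusters = sum(both))
  })
  do.call(rbind, out)
}
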