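#' Global inverse conversation frequencies
#'
#' The document unit is the conversation: `idf(w) = ln(N / df(w))` where `N`
#' is the number of conversations and `df(w)` the number of conversations in
#' which `w` occurs (any role). No smoothing: only observed words are present,
#' so `df >= 1`.
#'
#' @param convs List of `conversation` objects.
#' @return Named numeric vector of idf weights.
#' @export
global_idf <- function(convs) {
  if (length(convs) == 0) stop("empty corpus")
  df <- table(unlist(lapply(convs, function(cv)
    unique(unlist(conv_token_list(cv))))))
  idf <- log(length(convs) / as.numeric(df))
  stats::setNames(idf, names(df))
}

# Sparse (V * n_chunks) x n_conversations matrix of per-chunk token counts of
# one role, with chunk boundaries defined over all messages.
build_chunk_count_matrix <- function(convs, vocabulary, n_chunks,
                                     role = "counselor") {
  V <- length(vocabulary)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(convs)) {
    cv <- convs[[j]]
    ids <- chunk_assignment(length(cv$messages), n_chunks)
    for (k in seq_len(n_chunks)) {
      msgs <- cv$messages[ids == k]
      toks <- unlist(lapply(msgs, function(m)
        if (m$role == role) m$tokens else character(0)))
      if (length(toks) == 0) next
      w <- match(toks, vocabulary)
      w <- w[!is.na(w)]
      if (length(w) == 0) next
      tab <- table(w)
      ii <- c(ii, (k - 1L) * V + as.integer(names(tab)))
      jj <- c(jj, rep(j, length(tab)))
      xx <- c(xx, as.numeric(tab))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(V * n_chunks, length(convs)))
}

# Conversation weights implementing counselor-equalized contributions: each
# conversation is scaled by 1 / (number of labeled conversations its
# counselor has in this outcome cell), optionally times a per-counselor
# multiplicity (for bootstrap resampling).
cell_weights <- function(counselor_ids, outcomes, outcome, mult = NULL) {
  w <- numeric(length(outcomes))
  sel <- outcomes == outcome
  if (any(sel)) {
    n_per <- table(counselor_ids[sel])
    w[sel] <- 1 / as.numeric(n_per[counselor_ids[sel]])
    if (!is.null(mult)) w[sel] <- w[sel] * mult[counselor_ids[sel]]
  }
  w
}

tfidf_normalize <- function(mat, idf) {
  mat <- mat * idf
  norms <- sqrt(colSums(mat^2))
  norms[norms == 0] <- 1
  sweep(mat, 2, norms, "/")
}

chunk_distances <- function(M, w_pos, w_neg, V, n_chunks, idf) {
  pos <- matrix(as.numeric(M %*% w_pos), nrow = V)
  neg <- matrix(as.numeric(M %*% w_neg), nrow = V)
  empty <- colSums(pos) == 0 | colSums(neg) == 0
  pos <- tfidf_normalize(pos, idf)
  neg <- tfidf_normalize(neg, idf)
  d <- vapply(seq_len(n_chunks), function(k)
    1 - cosine_sim(pos[, k], neg[, k]), numeric(1))
  d[empty] <- NA_real_
  d
}

#' TF-IDF vector of a (group, outcome, chunk) cell
#'
#' Counselor tokens of the given conversation-time chunk, accumulated over
#' the group's labeled conversations with the given outcome, each
#' conversation weighted by 1 / (its counselor's conversation count in this
#' cell) so every counselor contributes equal mass, multiplied by the global
#' idf and L2-normalized.
#'
#' @param convs Corpus (list of conversations).
#' @param split A [split_counselors()] result.
#' @param group `"more_successful"` or `"less_successful"`.
#' @param outcome `"positive"` or `"negative"`.
#' @param chunk Chunk index in `1..n_chunks`.
#' @param n_chunks Number of conversation-time chunks (default 5).
#' @param idf Idf table; defaults to [global_idf()] of `convs`.
#' @param role Role whose tokens populate the vector (default counselor).
#' @return Named numeric vector (word -> weight) with attribute `empty`
#'   flagging a cell with no tokens.
#' @export
group_chunk_vector <- function(convs, split, group, outcome, chunk,
                               n_chunks = 5, idf = global_idf(convs),
                               role = "counselor") {
  sel <- select_group_convs(convs, split, group)
  vocabulary <- names(idf)
  M <- build_chunk_count_matrix(sel$convs, vocabulary, n_chunks, role)
  w <- cell_weights(sel$counselor_ids, sel$outcomes, outcome)
  mat <- matrix(as.numeric(M %*% w), nrow = length(vocabulary))
  v <- mat[, chunk]
  empty <- sum(v) == 0
  v <- v * idf
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  structure(stats::setNames(as.numeric(v), vocabulary), empty = empty)
}

select_group_convs <- function(convs, split, group) {
  ids <- split[[group]]
  keep <- Filter(function(cv) is_labeled(cv) && cv$counselor_id %in% ids,
                 convs)
  if (length(keep) == 0) stop("no labeled conversations for group ", group)
  list(convs = keep,
       counselor_ids = vapply(keep, `[[`, character(1), "counselor_id"),
       outcomes = vapply(keep, `[[`, character(1), "outcome"))
}

#' Language divergence between positive and negative conversations over time
#'
#' For each conversation-time chunk, the cosine distance between the
#' counselor-language TF-IDF vectors of the group's positive and negative
#' conversations. Confidence intervals come from a member bootstrap:
#' counselors are resampled with replacement and the whole curve recomputed.
#'
#' @inheritParams group_chunk_vector
#' @param n_boot Bootstrap resamples (default 1000).
#' @param level CI level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return Data frame with columns `group`, `chunk`, `distance`, `ci_lo`,
#'   `ci_hi`.
#' @export
adaptability_curve <- function(convs, split, group, n_chunks = 5,
                               idf = global_idf(convs), role = "counselor",
                               n_boot = 1000, level = 0.95, seed = 1) {
  sel <- select_group_convs(convs, split, group)
  vocabulary <- names(idf)
  V <- length(vocabulary)
  M <- build_chunk_count_matrix(sel$convs, vocabulary, n_chunks, role)
  w_pos <- cell_weights(sel$counselor_ids, sel$outcomes, "positive")
  w_neg <- cell_weights(sel$counselor_ids, sel$outcomes, "negative")
  d <- chunk_distances(M, w_pos, w_neg, V, n_chunks, idf)
  if (anyNA(d)) {
    stop("empty chunk cell(s) at chunk ", paste(which(is.na(d)), collapse = ", "),
         " for group ", group)
  }
  counselors <- unique(sel$counselor_ids)
  boot <- matrix(NA_real_, n_boot, n_chunks)
  if (n_boot > 0) {
    set.seed(seed)
    for (b in seq_len(n_boot)) {
      res <- sample(counselors, length(counselors), replace = TRUE)
      mult <- table(factor(res, levels = counselors))
      bw_pos <- cell_weights(sel$counselor_ids, sel$outcomes, "positive",
                             mult = mult)
      bw_neg <- cell_weights(sel$counselor_ids, sel$outcomes, "negative",
                             mult = mult)
      boot[b, ] <- chunk_distances(M, bw_pos, bw_neg, V, n_chunks, idf)
    }
  }
  ci <- apply(boot, 2, function(x)
    if (all(is.na(x))) c(NA_real_, NA_real_) else percentile_ci(x, level))
  data.frame(group = group, chunk = seq_len(n_chunks), distance = d,
             ci_lo = ci[1, ], ci_hi = ci[2, ], stringsAsFactors = FALSE)
}

#' Permuted-outcome null band for the adaptability curve
#'
#' Outcome labels are permuted across the group's labeled conversations and
#' the per-chunk distances recomputed, giving a null interval against which
#' the observed curve can be compared (with no planted drift the observed
#' distances should fall inside the band).
#'
#' @inheritParams adaptability_curve
#' @param n_perm Number of permutations.
#' @return Data frame: `chunk`, `lo`, `hi` (the central `level` interval of
#'   the permutation distribution).
#' @export
adaptability_null <- function(convs, split, group, n_chunks = 5,
                              idf = global_idf(convs), role = "counselor",
                              n_perm = 200, level = 0.95, seed = 1) {
  sel <- select_group_convs(convs, split, group)
  vocabulary <- names(idf)
  V <- length(vocabulary)
  M <- build_chunk_count_matrix(sel$convs, vocabulary, n_chunks, role)
  set.seed(seed)
  perm <- matrix(NA_real_, n_perm, n_chunks)
  for (p in seq_len(n_perm)) {
    out_p <- sample(sel$outcomes, length(sel$outcomes), replace = FALSE)
    w_pos <- cell_weights(sel$counselor_ids, out_p, "positive")
    w_neg <- cell_weights(sel$counselor_ids, out_p, "negative")
    perm[p, ] <- chunk_distances(M, w_pos, w_neg, V, n_chunks, idf)
  }
  ci <- apply(perm, 2, percentile_ci, level = level)
  data.frame(chunk = seq_len(n_chunks), lo = ci[1, ], hi = ci[2, ])
}
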