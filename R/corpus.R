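#' Tokenize raw message text
#'
#' Lowercases and splits on runs of non-alphanumeric characters. Pure-digit
#' tokens are kept (message text in SMS counseling routinely contains numbers
#' such as hotline shortcodes). Deterministic: the same text always yields the
#' same token list.
#'
#' @param text Character scalar (may be empty).
#' @return Character vector of lowercase tokens (length 0 for empty text).
#' @export
#' @examples
#' tokenize("Hi, my name is Sam!")
tokenize <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Construct a conversation record
#'
#' A conversation is an ordered sequence of messages between a counselor and a
#' texter, attributed to one counselor, optionally carrying a binary outcome
#' label (from the texter's post-conversation survey) and a main-issue tag.
#'
#' @param conv_id Conversation identifier (string).
#' @param counselor_id Counselor identifier (string).
#' @param roles Character vector, each element `"counselor"` or `"texter"`.
#' @param texts Character vector of raw message texts, same length as `roles`.
#' @param outcome `"positive"`, `"negative"`, or `NULL` (unlabeled).
#' @param issue Optional issue tag string or `NULL`.
#' @return An object of class `conversation`.
#' @export
new_conversation <- function(conv_id, counselor_id, roles, texts,
                             outcome = NULL, issue = NULL) {
  stopifnot(length(roles) == length(texts), length(roles) >= 1)
  bad <- setdiff(unique(roles), c("counselor", "texter"))
  if (length(bad) > 0) {
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(outcome) && !outcome %in% c("positive", "negative")) {
    stop("outcome must be 'positive', 'negative', or NULL")
  }
  messages <- lapply(seq_along(roles), function(i) {
    list(role = roles[[i]], text = texts[[i]],
         tokens = tokenize(texts[[i]]), index = i - 1L)
  })
  structure(
    list(conv_id = as.character(conv_id),
         counselor_id = as.character(counselor_id),
         outcome = outcome, issue = issue, messages = messages),
    class = "conversation")
}

#' @export
print.conversation <- function(x, ...) {
  lab <- if (is.null(x$outcome)) "unlabeled" else x$outcome
  cat(sprintf("<conversation %s: counselor %s, %d messages, %s>\n",
              x$conv_id, x$counselor_id, length(x$messages), lab))
  invisible(x)
}

conv_roles <- function(conv) vapply(conv$messages, `[[`, character(1), "role")
conv_token_list <- function(conv) lapply(conv$messages, `[[`, "tokens")
is_labeled <- function(conv) !is.null(conv$outcome)

#' Flatten a corpus into a per-message data frame
#'
#' @param convs List of `conversation` objects.
#' @return A data frame with one row per message: `conv_id`, `counselor_id`,
#'   `outcome` (NA when unlabeled), `issue`, `index`, `role`, `text`,
#'   `n_tokens`, and a `tokens` list column.
#' @export
corpus_messages <- function(convs) {
  rows <- lapply(convs, function(cv) {
    n <- length(cv$messages)
    data.frame(
      conv_id = rep(cv$conv_id, n),
      counselor_id = rep(cv$counselor_id, n),
      outcome = rep(if (is.null(cv$outcome)) NA_character_ else cv$outcome, n),
      issue = rep(if (is.null(cv$issue)) NA_character_ else cv$issue, n),
      index = vapply(cv$messages, `[[`, integer(1), "index"),
      role = conv_roles(cv),
      text = vapply(cv$messages, `[[`, character(1), "text"),
      n_tokens = vapply(cv$messages, function(m) length(m$tokens), integer(1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$tokens <- unlist(lapply(convs, conv_token_list), recursive = FALSE)
  out
}

#' Read a JSONL conversation corpus
#'
#' One JSON object per line with fields `conv_id`, `counselor_id`, optional
#' `outcome` and `issue`, and `messages`: an array of `{role, text}` objects.
#' Tokens are populated with [tokenize()].
#'
#' @param path Path to a UTF-8 JSONL file.
#' @return List of `conversation` objects.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) stop(sprintf(
                      "malformed record at line %d: %s", i, conditionMessage(e)),
                      call. = FALSE))
    need <- c("conv_id", "counselor_id", "messages")
    miss <- setdiff(need, names(rec))
    if (length(miss) > 0) {
      stop(sprintf("line %d: missing field(s) %s", i,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    roles <- vapply(rec$messages, function(m) as.character(m$role), character(1))
    if (any(!roles %in% c("counselor", "texter"))) {
      stop(sprintf("line %d: unknown role '%s'", i,
                   setdiff(roles, c("counselor", "texter"))[1]), call. = FALSE)
    }
    texts <- vapply(rec$messages, function(m) as.character(m$text), character(1))
    new_conversation(rec$conv_id, rec$counselor_id, roles, texts,
                     outcome = rec$outcome, issue = rec$issue)
  })
}

#' Write a conversation corpus as JSONL
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, p))` reproduces
#' `x` exactly (tokens are recomputed deterministically from the text).
#'
#' @param convs List of `conversation` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(convs, path) {
  lines <- vapply(convs, function(cv) {
    rec <- list(conv_id = cv$conv_id, counselor_id = cv$counselor_id)
    if (!is.null(cv$outcome)) rec$outcome <- cv$outcome
    if (!is.null(cv$issue)) rec$issue <- cv$issue
    rec$messages <- lapply(cv$messages, function(m)
      list(role = m$role, text = m$text))
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Split counselors into more and less successful groups
#'
#' A counselor is eligible when they have strictly more than `min_labeled`
#' labeled conversations, each with at least `min_messages` messages. Eligible
#' counselors are ranked by success rate (fraction of those qualifying labeled
#' conversations with a positive outcome); the top `top_n` form the
#' more-successful group, the bottom `bottom_n` the less-successful group.
#' Ranking ties are broken by qualifying-conversation count, then by counselor
#' id, so the split is deterministic.
#'
#' @param convs List of `conversation` objects.
#' @param min_labeled Eligibility requires more than this many qualifying
#'   labeled conversations (default 15).
#' @param min_messages Minimum messages for a conversation to qualify
#'   (default 30).
#' @param top_n,bottom_n Sizes of the two groups (defaults 40).
#' @return An object of class `counselor_split`: list with `more_successful`,
#'   `less_successful` (character vectors of counselor ids), `success_rate`
#'   (named numeric over eligible counselors) and `n_labeled` (named integer).
#' @export
split_counselors <- function(convs, min_labeled = 15, min_messages = 30,
                             top_n = 40, bottom_n = 40) {
  lab <- Filter(function(cv) is_labeled(cv) &&
                  length(cv$messages) >= min_messages, convs)
  if (length(lab) == 0) stop("no qualifying labeled conversations in corpus")
  cid <- vapply(lab, `[[`, character(1), "counselor_id")
  pos <- vapply(lab, function(cv) cv$outcome == "positive", logical(1))
  n_lab <- tapply(pos, cid, length)
  rate <- tapply(pos, cid, mean)
  eligible <- names(n_lab)[n_lab > min_labeled]
  if (length(eligible) < top_n + bottom_n) {
    stop(sprintf("only %d eligible counselors; need %d",
                 length(eligible), top_n + bottom_n))
  }
  ord <- eligible[order(-rate[eligible], -n_lab[eligible], eligible)]
  structure(
    list(more_successful = ord[seq_len(top_n)],
         less_successful = rev(ord)[seq_len(bottom_n)],
         success_rate = rate[eligible],
         n_labeled = as.integer(n_lab[eligible]) |>
           stats::setNames(eligible)),
    class = "counselor_split")
}

#' @export
print.counselor_split <- function(x, ...) {
  cat(sprintf("<counselor_split: %d more successful (rate %.3f-%.3f), %d less successful (rate %.3f-%.3f)>\n",
              length(x$more_successful),
              min(x$success_rate[x$more_successful]),
              max(x$success_rate[x$more_successful]),
              length(x$less_successful),
              min(x$success_rate[x$less_successful]),
              max(x$success_rate[x$less_successful])))
  invisible(x)
}

split_group <- function(split, conv) {
  if (conv$counselor_id %in% split$more_successful) "more_successful"
  else if (conv$counselor_id %in% split$less_successful) "less_successful"
  else NA_character_
}

#' Chunk assignment for positions 1..n into k contiguous chunks
#'
#' Chunk sizes differ by at most one; earlier chunks take the larger size when
#' n is not divisible by k.
#'
#' @param n Number of items.
#' @param k Number of chunks.
#' @return Integer vector of length `n` with chunk ids in `1..k`.
#' @export
chunk_assignment <- function(n, k) {
  stopifnot(k >= 1)
  if (n == 0) return(integer(0))
  base <- n %/% k
  rem <- n %% k
  sizes <- rep(base, k) + c(rep(1L, rem), rep(0L, k - rem))
  rep(seq_len(k), times = sizes)
}

#' Partition a conversation's messages into contiguous chunks
#'
#' Used to give every conversation a common relative time axis (fifths by
#' default). Chunk sizes differ by at most one, with earlier chunks larger
#' when the count is not divisible.
#'
#' @param conv A `conversation`.
#' @param n_chunks Number of chunks (default 5).
#' @param role_filter Optional role; when given, only that role's messages are
#'   partitioned.
#' @return List of `n_chunks` lists of messages. Attribute `empty_chunks` is
#'   `TRUE` when some chunks received no messages.
#' @export
chunk_messages <- function(conv, n_chunks = 5, role_filter = NULL) {
  msgs <- conv$messages
  if (!is.null(role_filter)) {
    msgs <- Filter(function(m) m$role == role_filter, msgs)
  }
  ids <- chunk_assignment(length(msgs), n_chunks)
  out <- lapply(seq_len(n_chunks), function(k) msgs[ids == k])
  attr(out, "empty_chunks") <- any(vapply(out, length, integer(1)) == 0)
  out
}
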