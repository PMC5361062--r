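# Shared fixtures and independent oracles. Everything is built in code at
# test time; no stored data.

# A tiny hand-written labeled corpus: 2 counselors, 4 conversations.
tiny_corpus <- function() {
  list(
    new_conversation("v1", "A",
                     c("counselor", "texter", "counselor", "texter"),
                     c("Hi, my name is Sam!", "hello i am sad today",
                       "that sounds like a lot", "yes it is"),
                     outcome = "positive"),
    new_conversation("v2", "A",
                     c("counselor", "texter"),
                     c("hi there welcome", "my exam went badly"),
                     outcome = "negative"),
    new_conversation("v3", "B",
                     c("counselor", "texter", "texter"),
                     c("good evening", "i feel alone", "nobody calls me"),
                     outcome = "positive"),
    new_conversation("v4", "B",
                     c("counselor", "texter"),
                     c("hello again", "still feeling alone"))
  )
}

# Synthetic corpus with n labeled conversations per counselor and a planted
# per-counselor success probability; message content minimal. Used for the
# counselor-split tests.
quality_corpus <- function(qualities, n_per = 40, n_messages = 30, seed = 1) {
  set.seed(seed)
  convs <- list()
  for (ci in seq_along(qualities)) {
    cid <- sprintf("c%02d", ci)
    for (k in seq_len(n_per)) {
      outcome <- if (runif(1) < qualities[ci]) "positive" else "negative"
      roles <- rep(c("counselor", "texter"), length.out = n_messages)
      texts <- rep(c("hello there", "i am here"), length.out = n_messages)
      convs[[length(convs) + 1]] <- new_conversation(
        sprintf("%s_%03d", cid, k), cid, roles, texts, outcome = outcome)
    }
  }
  convs
}

# Random constrained stage HMM with continuous parameters (ties have
# probability zero), for oracle-equivalence tests.
rand_stage_model <- function(S, V, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  E <- lapply(c(counselor = "c", texter = "t"), function(.) {
    M <- matrix(stats::rgamma(S * V, 1), S, V)
    M / rowSums(M)
  })
  adv <- matrix(stats::runif(S * 2, 0.05, 0.9), S, 2,
                dimnames = list(NULL, c("counselor", "texter")))
  adv[S, ] <- 0
  structure(list(n_stages = S,
                 vocab = c(sprintf("w%02d", seq_len(V - 1)), "<unk>"),
                 emission = E, advance_prob = adv,
                 loglik_trace = numeric(0)),
            class = "stage_hmm")
}

rand_short_conv <- function(model, n) {
  roles <- rep(c("counselor", "texter"), length.out = n)
  words <- model$vocab[-length(model$vocab)]
  texts <- vapply(seq_len(n), function(i)
    paste(sample(words, sample(1:5, 1), replace = TRUE), collapse = " "),
    character(1))
  new_conversation("bf", "c1", roles, texts)
}

# Independent bigram TF-IDF cosine-distance oracle: plain loops, no shared
# code with tfidf_matrix()/pairwise_cosine().
oracle_bigram_distances <- function(token_lists) {
  bg <- lapply(token_lists, function(t) {
    n <- length(t)
    if (n < 2) character(0) else paste(t[-n], t[-1])
  })
  n <- length(bg)
  vocabulary <- unique(unlist(bg))
  df <- vapply(vocabulary, function(b)
    sum(vapply(bg, function(d) b %in% d, logical(1))), numeric(1))
  idf <- log((1 + n) / (1 + df)) + 1
  names(idf) <- vocabulary
  vecs <- lapply(bg, function(d) {
    v <- stats::setNames(numeric(length(vocabulary)), vocabulary)
    for (b in d) v[b] <- v[b] + 1
    v <- v * idf
    nr <- sqrt(sum(v^2))
    if (nr > 0) v / nr else v
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- sum(vecs[[i]] * vecs[[j]])
      if (abs(s - 1) < 1e-12) s <- 1
      D[i, j] <- 1 - s
    }
  }
  D
}

# Two-template setter fixture with shared perturbation words; within-template
# distances stay well below 0.6, between-template distances are 1.
template_setters <- function() {
  tA <- tokenize(paste("my boyfriend broke up with me last night and i",
                       "cannot stop crying about it all"))
  tB <- tokenize(paste("i failed my chemistry exam today and my parents",
                       "are going to be so angry with me"))
  altA <- c("night", "morning", "week")
  altB <- c("today", "yesterday", "tonight")
  setters <- c(
    lapply(1:15, function(i) { t <- tA; t[8] <- altA[1 + (i %% 3)]; t }),
    lapply(1:15, function(i) { t <- tB; t[6] <- altB[1 + (i %% 3)]; t }))
  list(setters = setters, members_a = 1:15, members_b = 16:30,
       template_a = tA, template_b = tB)
}

# Hand-built counselor split for fixture tests.
manual_split <- function(more, less) {
  structure(list(more_successful = more, less_successful = less,
                 success_rate = stats::setNames(
                   rep(0.5, length(c(more, less))), c(more, less)),
                 n_labeled = stats::setNames(
                   rep(1L, length(c(more, less))), c(more, less))),
            class = "counselor_split")
}

# Small generator config for fast module tests.
fast_config <- function(..., seed = 1) {
  generator_config(n_counselors = 6, n_conversations = 120, seed = seed, ...)
}

# Reduced pipeline configuration used by the pipeline and determinism tests.
small_pipeline_config <- function(seed = 3) {
  pipeline_config(
    generator = generator_config(n_conversations = 120, n_counselors = 6,
                                 seed = seed),
    split = list(min_labeled = 10, min_messages = 30, top_n = 3,
                 bottom_n = 3),
    adaptability = list(n_chunks = 5, n_boot = 30),
    stages = list(n_stages = 5, min_count = 20, max_iter = 10, tol = 1e-4,
                  min_len = 40, max_len = 60),
    perspective = list(n_chunks = 5, n_boot = 30),
    prediction = list(x_percent = 80, k = 5, lambda = 1e-2,
                      use_ngrams = FALSE, min_messages = 30),
    seed = seed)
}
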