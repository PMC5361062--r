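test_that("vocabulary keeps words strictly above the frequency cutoff", {
  texts <- c(paste(rep("common", 21), collapse = " "),
             paste(rep("edge", 20), collapse = " "),
             "rare")
  convs <- list(new_conversation("v", "A", rep("counselor", 3), texts))
  v <- build_vocab(convs, min_count = 20)
  expect_true("common" %in% v)
  expect_false("edge" %in% v)    # exactly 20 occurrences -> folded to UNK
  expect_false("rare" %in% v)
  expect_equal(attr(v, "coverage"), 21 / 42)

  v0 <- build_vocab(convs, min_count = 0)
  expect_setequal(v0, c("common", "edge", "rare", "<unk>"))
  expect_equal(attr(v0, "coverage"), 1)
  expect_error(build_vocab(list()), "empty")
})

test_that("initialization is the per-role unigram with seeded perturbation", {
  sim <- generate_corpus(fast_config(seed = 15))
  convs <- sim$conversations[1:30]
  vocab <- build_vocab(convs, min_count = 5)

  m0 <- init_model(convs, n_stages = 3, vocab = vocab, perturbation = 0)
  for (role in c("counselor", "texter")) {
    E <- m0$emission[[role]]
    expect_equal(rowSums(E), rep(1, 3))
    expect_equal(E[1, ], E[2, ])   # no perturbation -> identical stages
    expect_equal(E[2, ], E[3, ])
  }
  expect_equal(m0$advance_prob[3, ], c(counselor = 0, texter = 0))

  m1 <- init_model(convs, 3, vocab, perturbation = 1e-2, seed = 5)
  m2 <- init_model(convs, 3, vocab, perturbation = 1e-2, seed = 5)
  expect_equal(m1, m2)
  expect_equal(rowSums(m1$emission$counselor), rep(1, 3))
  expect_false(isTRUE(all.equal(m1$emission$counselor[1, ],
                                m1$emission$counselor[2, ])))
})

test_that("forward-backward matches brute-force enumeration", {
  set.seed(16)
  for (r in 1:25) {
    S <- sample(1:3, 1)
    model <- rand_stage_model(S, sample(4:10, 1))
    cv <- rand_short_conv(model, sample(1:8, 1))
    fb <- forward_backward(model, cv)
    bf <- brute_force_stage_oracle(model, cv)
    expect_equal(fb$loglik, bf$loglik, tolerance = 1e-9)
    # posterior marginals sum to 1 and respect the monotone constraint
    expect_equal(rowSums(fb$gamma), rep(1, length(cv$messages)))
    n <- length(cv$messages)
    if (n > 1) {
      # transition posteriors marginalize to the stage marginals
      for (i in seq_len(n - 1)) {
        expect_equal(sum(fb$xi_stay[i, ]) + sum(fb$xi_advance[i, ]), 1,
                     tolerance = 1e-9)
        expect_equal(fb$xi_stay[i, ] + fb$xi_advance[i, ], fb$gamma[i, ],
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("single-message conversations put all mass on stage 1", {
  model <- rand_stage_model(3, 6, seed = 17)
  cv <- rand_short_conv(model, 1)
  fb <- forward_backward(model, cv)
  expect_equal(fb$gamma[1, ], c(1, 0, 0))
  expect_equal(viterbi_decode(model, cv)$stages, 1L)
})

test_that("with identical emissions posteriors equal the chain occupancy", {
  S <- 3; V <- 6
  model <- rand_stage_model(S, V, seed = 18)
  model$emission <- lapply(model$emission, function(E) {
    E[2, ] <- E[1, ]; E[3, ] <- E[1, ]; E
  })
  n <- 6
  cv <- rand_short_conv(model, n)
  fb <- forward_backward(model, cv)
  # independent occupancy recursion: pure Markov chain marginals
  roles <- match(vapply(cv$messages, `[[`, character(1), "role"),
                 c("counselor", "texter"))
  occ <- matrix(0, n, S); occ[1, 1] <- 1
  for (i in 2:n) {
    r <- roles[i - 1]
    for (s in seq_len(S)) {
      occ[i, s] <- occ[i - 1, s] * (1 - model$advance_prob[s, r]) +
        (if (s > 1) occ[i - 1, s - 1] * model$advance_prob[s - 1, r] else 0)
    }
  }
  expect_equal(fb$gamma, occ, tolerance = 1e-9)
})

test_that("EM increases the likelihood and recovers the 1-stage unigram", {
  sim <- generate_corpus(fast_config(seed = 19))
  convs <- sim$conversations[1:40]
  vocab <- build_vocab(convs, min_count = 10)

  m <- init_model(convs, n_stages = 3, vocab = vocab, seed = 19)
  m <- fit_em(m, convs, max_iter = 8, tol = 1e-12)
  tr <- m$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-1])))
  expect_equal(rowSums(m$emission$counselor), rep(1, 3), tolerance = 1e-12)
  expect_true(all(m$advance_prob >= 0 & m$advance_prob <= 1))
  expect_equal(m$advance_prob[3, ], c(counselor = 0, texter = 0))

  # 1 stage, no smoothing: one M step lands exactly on the role unigram
  m1 <- init_model(convs, n_stages = 1, vocab = vocab, perturbation = 0)
  m1 <- fit_em(m1, convs, max_iter = 1, smoothing = 0)
  V <- length(vocab)
  for (role in c("counselor", "texter")) {
    toks <- unlist(lapply(convs, function(cv)
      unlist(lapply(cv$messages, function(msg)
        if (msg$role == role) msg$tokens else character(0)))))
    ids <- match(toks, vocab); ids[is.na(ids)] <- V
    expect_equal(as.numeric(m1$emission[[role]]),
                 tabulate(ids, V) / length(ids), tolerance = 1e-12)
  }
})

test_that("viterbi equals the enumeration argmax and is monotone", {
  set.seed(20)
  for (r in 1:25) {
    model <- rand_stage_model(sample(1:3, 1), sample(4:10, 1))
    cv <- rand_short_conv(model, sample(1:8, 1))
    vit <- viterbi_decode(model, cv)
    bf <- brute_force_stage_oracle(model, cv)
    expect_identical(vit$stages, bf$best_path)
    expect_equal(vit$stages[1], 1L)
    expect_true(all(diff(vit$stages) %in% c(0L, 1L)))
    expect_equal(sum(vit$durations), length(cv$messages))
  }
})

test_that("stage durations weight the outcome classes equally", {
  sim <- generate_corpus(fast_config(seed = 21))
  convs <- sim$conversations
  sp <- split_counselors(convs, min_labeled = 10, top_n = 3, bottom_n = 3)
  vocab <- build_vocab(convs, min_count = 20)
  model <- fit_em(init_model(convs, 5, vocab, seed = 21), convs,
                  max_iter = 10, tol = 1e-5)
  d <- stage_durations(convs, model, sp, n_boot = 20, seed = 21)
  expect_true(all(c("group", "stage", "mean_duration") %in% names(d)))
  # per-group means stay identical when all negatives are duplicated
  negs <- Filter(function(cv) is_labeled(cv) && cv$outcome == "negative" &&
                   length(cv$messages) >= 40 && length(cv$messages) <= 60,
                 convs)
  negs <- lapply(negs, function(cv) {
    cv$conv_id <- paste0(cv$conv_id, "dup"); cv
  })
  d2 <- stage_durations(c(convs, negs), model, sp, n_boot = 0, seed = 21)
  expect_equal(d2$mean_duration, d$mean_duration, tolerance = 1e-12)
  expect_error(stage_durations(convs, model, sp, min_len = 1000),
               "qualifying")
})

test_that("a planted group gap in stage-2 advance probability is recovered", {
  hits <- vapply(1:6, function(sd) {
    adv_hi <- c(0.20, 0.25, 0.10, 0.15, 0)
    adv_lo <- c(0.20, 0.06, 0.10, 0.15, 0)
    cfg <- generator_config(n_counselors = 6, n_conversations = 180,
                            stage_advance_prob = list(high = adv_hi,
                                                      low = adv_lo),
                            seed = 100 + sd)
    sim <- generate_corpus(cfg)
    sp <- split_counselors(sim$conversations, min_labeled = 10,
                           top_n = 3, bottom_n = 3)
    vocab <- build_vocab(sim$conversations, min_count = 20)
    model <- fit_em(init_model(sim$conversations, 5, vocab, seed = sd),
                    sim$conversations, max_iter = 15, tol = 1e-6)
    d <- stage_durations(sim$conversations, model, sp, n_boot = 0)
    s2 <- stats::setNames(d$mean_duration[d$stage == 2],
                          d$group[d$stage == 2])
    # high-quality group advances faster out of stage 2 -> shorter duration
    unname(s2["more_successful"] < s2["less_successful"])
  }, logical(1))
  expect_gte(sum(hits), 5)
})

test_that("top-word lift ranks planted stage keywords first", {
  sim <- generate_corpus(fast_config(seed = 22))
  convs <- sim$conversations
  vocab <- build_vocab(convs, min_count = 20)
  model <- fit_em(init_model(convs, 5, vocab, seed = 22), convs,
                  max_iter = 15, tol = 1e-6)
  tw <- stage_top_words(model, convs, per_stage = 5, min_freq = 50)
  kw <- sim$ground_truth$config$vocab$keywords
  for (s in 1:5) {
    top_c <- tw$word[tw$stage == s & tw$role == "counselor"]
    expect_gte(length(intersect(top_c, kw$counselor[[s]])), 4)
  }
})
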