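mk_labeled <- function(n_pos, n_neg, n_messages = 32) {
  mk <- function(id, out) new_conversation(
    id, "A", rep(c("counselor", "texter"), length.out = n_messages),
    rep(c("hello there", "i am here"), length.out = n_messages),
    outcome = out)
  c(lapply(seq_len(n_pos), function(i) mk(paste0("p", i), "positive")),
    lapply(seq_len(n_neg), function(i) mk(paste0("n", i), "negative")))
}

test_that("dataset balancing subsamples the larger class reproducibly", {
  convs <- mk_labeled(100, 40)
  bal <- balance_dataset(convs, seed = 1)
  out <- vapply(bal, `[[`, character(1), "outcome")
  expect_equal(as.integer(table(out)), c(40L, 40L))

  tie <- mk_labeled(30, 30)
  expect_length(balance_dataset(tie, seed = 1), 60)

  b1 <- balance_dataset(convs, seed = 9)
  b2 <- balance_dataset(convs, seed = 9)
  expect_equal(vapply(b1, `[[`, character(1), "conv_id"),
               vapply(b2, `[[`, character(1), "conv_id"))

  short <- mk_labeled(10, 10, n_messages = 20)
  expect_error(balance_dataset(short, min_messages = 30), "classes")
  expect_error(balance_dataset(mk_labeled(5, 0)), "classes")
})

test_that("prefix features match hand-computed fixtures", {
  model <- rand_stage_model(1, 6, seed = 29)
  texts_c <- c("maybe this will help",        # hedge
               "tell me more about that",
               "perhaps you could rest",      # hedge
               "what happened next",
               "who was there with you")
  roles <- rep(c("counselor", "texter"), 5)
  texts <- as.vector(rbind(texts_c, rep("i am very tired", 5)))
  cv <- new_conversation("f", "A", roles, texts, outcome = "positive")

  fv <- extract_features(cv, x_percent = 100, model = model,
                         conjunctions = FALSE)
  expect_equal(unname(fv["hedge_rate"]), 2 / 5)
  expect_equal(unname(fv["msg_len"]), mean(lengths(lapply(
    Filter(function(m) m$role == "counselor", cv$messages), `[[`, "tokens"))))
  expect_equal(unname(fv["stage_dur_1"]), 10)  # x=100 covers all messages

  # a conversation never reaching later stages carries zero durations there
  m5 <- rand_stage_model(5, 6, seed = 30)
  m5$advance_prob[, ] <- 0
  fv5 <- extract_features(cv, 100, m5, conjunctions = TRUE)
  expect_equal(unname(fv5[sprintf("stage_dur_%d", 2:5)]), rep(0, 4))
  expect_equal(unname(fv5[sprintf("conj_hedge_s%d", 2:5)]), rep(0, 4))
  expect_equal(unname(fv5["conj_hedge_s1"]), 2 / 5)

  # prefix restriction: x = 20 sees only the first 2 of 10 messages
  fv20 <- extract_features(cv, 20, model, conjunctions = FALSE)
  expect_equal(unname(fv20["stage_dur_1"]), 2)
  expect_equal(unname(fv20["hedge_rate"]), 1)  # only the first counselor msg
})

test_that("batch gradient descent matches an independent optimizer (L2)", {
  set.seed(31)
  n <- 50; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  w_true <- c(1.5, -2, 0.5, 0, 1)
  y <- runif(n) < stats::plogis(X %*% w_true)
  lambda <- 0.05
  fit <- fit_logistic(X, y, penalty = "L2", lambda = lambda, max_iter = 20000,
                      tol = 1e-12)
  obj <- function(w) {
    eta <- w[1] + X %*% w[-1]
    mean(log1p(exp(-ifelse(y, 1, -1) * eta))) +
      lambda / 2 * sum(w[-1]^2)
  }
  ref <- stats::optim(rep(0, p + 1), obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(max(abs(c(fit$intercept, fit$weights) - ref$par)), 1e-3)
})

test_that("L1 solutions satisfy the subgradient optimality conditions", {
  set.seed(32)
  n <- 80; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- runif(n) < stats::plogis(X %*% c(2, -1, 0, 0, 0.5, 0))
  lambda <- 0.08
  fit <- fit_logistic(X, y, penalty = "L1", lambda = lambda,
                      max_iter = 50000, tol = 1e-12)
  mu <- stats::plogis(fit$intercept + drop(X %*% fit$weights))
  g <- drop(crossprod(X, mu - as.numeric(y))) / n
  for (j in seq_len(p)) {
    if (abs(fit$weights[j]) > 1e-8) {
      expect_lt(abs(g[j] + lambda * sign(fit$weights[j])), 1e-4)
    } else {
      expect_lte(abs(g[j]), lambda + 1e-4)
    }
  }
  expect_lt(abs(mean(mu) - mean(y)), 1e-6)  # unpenalized intercept
})

test_that("degenerate logistic fits behave as specified", {
  set.seed(33)
  # linearly separable toy -> training AUC 1
  X <- cbind(c(rnorm(20, -3), rnorm(20, 3)), rnorm(40))
  y <- rep(c(FALSE, TRUE), each = 20)
  fit <- fit_logistic(scale(X), y, lambda = 1e-4)
  expect_equal(auc_rank(logistic_score(fit, scale(X)), y), 1)

  # all-zero features -> intercept-only, fitted probability = class prior
  X0 <- matrix(0, 30, 3)
  y0 <- rep(c(TRUE, FALSE), c(21, 9))
  f0 <- fit_logistic(X0, y0, lambda = 1)
  expect_equal(f0$weights, rep(0, 3))
  expect_equal(stats::plogis(f0$intercept), 0.7, tolerance = 1e-6)
})

test_that("rank AUC equals the trapezoidal ROC integral", {
  skip_if_not_installed("pROC")
  set.seed(34)
  for (r in 1:5) {
    y <- runif(60) < 0.5
    if (length(unique(y)) < 2) next
    s <- rnorm(60) + y
    expect_equal(auc_rank(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("cross-validation is stratified, deterministic, and null-calibrated", {
  set.seed(35)
  X <- matrix(rnorm(120 * 4), 120, 4)
  y <- rep(c(TRUE, FALSE), 60)
  cv1 <- cross_validate(X, y, k = 10, seed = 3)
  cv2 <- cross_validate(X, y, k = 10, seed = 3)
  expect_equal(cv1$folds, cv2$folds)
  expect_equal(cv1$mean_auc, cv2$mean_auc)
  for (f in 1:10) {
    expect_equal(sum(y[cv1$folds == f]), 6)  # stratified folds
  }
  # pure-noise features over 10 seeds: mean AUC near 1/2
  aucs <- vapply(1:10, function(sd) {
    set.seed(100 + sd)
    Xn <- matrix(rnorm(120 * 4), 120, 4)
    cross_validate(Xn, y, k = 10, seed = sd)$mean_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)

  # planted separable signal -> ceiling
  Xs <- cbind(ifelse(y, 2, -2) + rnorm(120, sd = 0.1), X)
  expect_gte(cross_validate(Xs, y, k = 10, seed = 3)$mean_auc, 0.95)
})

test_that("the feature ladder reports nested models and null additions", {
  set.seed(36)
  n <- 150
  y <- rep(c(TRUE, FALSE), length.out = n)
  signal <- ifelse(y, 1, -1) + rnorm(n)
  X <- cbind(hedge_rate = signal, noise1 = rnorm(n), noise2 = rnorm(n),
             dup = signal)
  sets <- list(none = character(0),
               `+hedges` = "hedge_rate",
               `+noise` = c("hedge_rate", "noise1"),
               `+dup` = c("hedge_rate", "noise1", "dup"))
  lad <- feature_ladder(X, y, sets, k = 5, seed = 4, n_boot = 200)
  expect_equal(lad$auc[1], 0.5)
  expect_gt(lad$auc[2], 0.65)          # signal feature lifts AUC
  expect_lt(abs(lad$delta_auc[3]), 0.02)  # pure-noise addition is inert
  expect_lt(abs(lad$delta_auc[4]), 0.02)  # duplicated feature is inert
  expect_lt(lad$p_vs_previous[2], 0.05)
})

test_that("n-gram features follow the frequency floor and L1 route", {
  sim <- generate_corpus(fast_config(seed = 37))
  convs <- sim$conversations
  vocab <- build_vocab(convs, min_count = 20)
  model <- fit_em(init_model(convs, 5, vocab, seed = 37), convs,
                  max_iter = 8, tol = 1e-4)
  bal <- balance_dataset(convs, seed = 37)[1:40]
  fm <- build_feature_matrix(bal, x_percent = 80, model = model,
                             use_ngrams = TRUE, ngram_min_freq = 5)
  expect_gt(length(fm$ngram_cols), 0)
  expect_true(all(startsWith(fm$ngram_cols, "ng:")))
  sets <- default_feature_sets(colnames(fm$X), fm$ngram_cols)
  expect_true("+ngrams" %in% names(sets))
  expect_true(all(sets$`+stage_conjunctions` %in% colnames(fm$X)))
})
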