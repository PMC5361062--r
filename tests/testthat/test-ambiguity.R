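test_that("situation setter is the first texter message of qualifying length", {
  cv <- new_conversation("s", "A",
    c("counselor", "texter", "counselor", "texter", "texter"),
    c("hello can you tell me more",
      "not now",                                        # 2 tokens
      "take your time",
      paste(rep("word", 14), collapse = " "),           # 14 tokens
      paste(rep("word", 20), collapse = " ")))
  st <- find_situation_setter(cv, min_tokens = 10)
  expect_equal(st$index, 3)
  expect_equal(st$n_tokens, 14)

  none <- new_conversation("n", "A", c("counselor", "texter"),
                           c("hi", "short reply"))
  expect_null(find_situation_setter(none, 10))
})

test_that("setter length shift matches the planted outcome effect", {
  cfg <- generator_config(n_conversations = 400, n_counselors = 10,
                          seed = 12)
  sim <- generate_corpus(cfg)
  sf <- crisistalk:::setter_frame(sim$conversations)
  len <- vapply(sf, `[[`, numeric(1), "setter_len")
  out <- vapply(sf, `[[`, character(1), "outcome")
  d <- mean(len[out == "positive"]) - mean(len[out == "negative"])
  se <- sqrt(stats::var(len[out == "positive"]) / sum(out == "positive") +
               stats::var(len[out == "negative"]) / sum(out == "negative"))
  expect_lt(abs(d - cfg$setter$length_effect), 3 * se)
})

test_that("outcome fraction by setter-length bin behaves correctly", {
  mk <- function(id, len, out) new_conversation(
    id, "A", c("counselor", "texter"),
    c("tell me more", paste(rep("w", len), collapse = " ")), outcome = out)
  all_pos <- lapply(1:20, function(i) mk(paste0("p", i), 5 + i, "positive"))
  tab <- ambiguity_outcome_table(all_pos, c(0, 15, 30), min_tokens = 3)
  expect_equal(tab$frac_positive, c(1, 1))

  # single bin marginalizes to the overall positive rate
  mix <- c(all_pos[1:10],
           lapply(1:10, function(i) mk(paste0("n", i), 5 + i, "negative")))
  tab1 <- ambiguity_outcome_table(mix, c(0, 100), min_tokens = 3)
  expect_equal(tab1$frac_positive, 0.5)

  # empty bin flagged
  tab2 <- ambiguity_outcome_table(all_pos, c(0, 15, 30, 100), min_tokens = 3)
  expect_equal(tab2$n[3], 0)
  expect_true(is.na(tab2$frac_positive[3]))

  # planted logistic link between setter length and outcome -> increasing bins
  set.seed(13)
  link <- lapply(1:600, function(i) {
    len <- sample(4:40, 1)
    out <- if (runif(1) < stats::plogis((len - 20) / 5)) "positive"
           else "negative"
    mk(paste0("l", i), len, out)
  })
  tabl <- ambiguity_outcome_table(link, c(0, 12, 20, 28, 40), min_tokens = 3)
  expect_true(all(diff(tabl$frac_positive) > 0))
})

test_that("counselor/texter length ratio matches fixtures", {
  mk <- function(id, setter_len, reply_len) new_conversation(
    id, "A", c("counselor", "texter", "counselor"),
    c("tell me more",
      paste(rep("w", setter_len), collapse = " "),
      paste(rep("r", reply_len), collapse = " ")), outcome = "positive")
  eq <- lapply(1:5, function(i) mk(paste0("e", i), 12, 12))
  tab <- counselor_texter_length_ratio(eq, c(0, 100), min_tokens = 3)
  expect_equal(tab$mean_ratio, 1)
  one <- counselor_texter_length_ratio(list(mk("x", 10, 15)), c(0, 100),
                                       min_tokens = 3)
  expect_equal(one$mean_ratio, 1.5)
})

test_that("clustering recovers planted templates against a brute-force oracle", {
  fx <- template_setters()
  D <- oracle_bigram_distances(fx$setters)
  # the fixture has a clean gap: within-template below, between at 1
  win <- max(D[fx$members_a, fx$members_a], D[fx$members_b, fx$members_b])
  btw <- min(D[fx$members_a, fx$members_b])
  expect_lt(win, 0.6)
  expect_gt(btw, 0.9)

  cl <- cluster_setters(fx$setters, distance_threshold = 0.6,
                        min_neighbors = 10)
  expect_length(cl, 2)
  expect_setequal(cl[[1]]$members, fx$members_a)
  expect_setequal(cl[[2]]$members, fx$members_b)

  # the construction is order-invariant
  perm <- sample(length(fx$setters))
  cl_p <- cluster_setters(fx$setters[perm], 0.6, 10)
  back <- lapply(cl_p, function(c) sort(perm[c$members]))
  expect_setequal(lapply(cl, `[[`, "members"), back)
})

test_that("trivial cluster geometries behave as expected", {
  ident <- lapply(1:12, function(i) tokenize("i feel so alone right now"))
  cl <- cluster_setters(ident, distance_threshold = 0.1, min_neighbors = 10)
  expect_length(cl, 1)
  expect_length(cl[[1]]$members, 12)

  disj <- lapply(1:5, function(i)
    tokenize(paste(sprintf("zz%d%s", i, letters[1:6]), collapse = " ")))
  cl2 <- cluster_setters(c(ident, disj), 0.1, 10)
  expect_length(cl2, 1)
  expect_length(cl2[[1]]$members, 12)

  expect_error(cluster_setters(ident, distance_threshold = 1.4), "threshold")
  expect_error(cluster_setters(ident[1:5], 0.1, min_neighbors = 10),
               "at least")
})

test_that("response classes trigger exactly on their exemplars", {
  pats <- default_response_patterns()
  setter <- tokenize("i lost my job and i do not know what to do")
  cases <- list(
    c("that sounds like a really hard situation", "check_question"),
    c("do you ever feel like you want to die", "suicide_check"),
    c("i appreciate you reaching out", "thanks"),
    c("maybe we can think this through", "hedge"),
    c("oh, this sounds really awful", "surprise"))
  for (cs in cases) {
    cls <- classify_response(setter, cs[1])
    hits <- names(which(unlist(cls[names(pats)])))
    expect_identical(hits, cs[2])
  }
})

test_that("response similarity and degenerate replies behave correctly", {
  setter <- tokenize("my parents are fighting all the time and i hate it")
  same <- classify_response(setter, paste(setter, collapse = " "))
  expect_equal(same$sim_c, 1)
  empty <- classify_response(setter, NA_character_)
  expect_false(any(unlist(empty[names(default_response_patterns())])))
  expect_equal(empty$sim_c, 0)
  expect_equal(empty$c_len, 0)
})

test_that("classification is invariant under tokenization round-trip", {
  texts <- c("Maybe it IS hard -- that sounds like a lot!",
             "Oh, WOW... that's terrible", "I hear you; thank you")
  pats <- default_response_patterns()
  setter <- tokenize("some context words here for the space")
  for (tx in texts) {
    a <- classify_response(setter, tx)
    b <- classify_response(setter, paste(tokenize(tx), collapse = " "))
    expect_equal(a[names(pats)], b[names(pats)])
  }
})

test_that("templatedness counts near-duplicates symmetrically", {
  tA <- tokenize("have you thought about talking to someone you trust")
  tB <- tokenize("what usually helps you calm down in moments like this")
  reps <- c(lapply(1:7, function(i) tA), lapply(1:3, function(i) tB))
  counts <- templatedness(reps, distance_threshold = 0.4)
  expect_equal(counts, c(rep(6L, 7), rep(2L, 3)))

  ident <- lapply(1:10, function(i) tA)
  expect_equal(templatedness(ident, 0.4), rep(9L, 10))
  disj <- lapply(1:4, function(i)
    tokenize(paste(sprintf("q%d%s", i, letters[1:8]), collapse = " ")))
  expect_equal(templatedness(disj, 0.4), rep(0L, 4))

  # symmetry: neighbor counts against the oracle distance matrix
  fx <- template_setters()
  D <- oracle_bigram_distances(fx$setters)
  expected <- vapply(seq_len(nrow(D)), function(i)
    sum(D[i, -i] <= 0.6), integer(1))
  expect_equal(templatedness(fx$setters, 0.6), expected)
})

test_that("response table compares groups over setter clusters", {
  fx <- template_setters()
  set.seed(14)
  convs <- lapply(seq_along(fx$setters), function(i) {
    grp_a <- i %% 2 == 0
    reply <- if (grp_a) "that sounds like a lot to carry maybe we can talk"
             else "ok tell me more about it"
    new_conversation(
      sprintf("rt%02d", i), if (grp_a) sprintf("A%d", i %% 3)
                            else sprintf("B%d", i %% 3),
      c("counselor", "texter", "counselor", "texter"),
      c("hi can you tell me more", paste(fx$setters[[i]], collapse = " "),
        reply, "thanks i guess"),
      outcome = if (grp_a) "positive" else "negative")
  })
  sp <- manual_split(paste0("A", 0:2), paste0("B", 0:2))
  tab <- response_table(convs, sp, min_tokens = 10,
                        distance_threshold = 0.6, min_neighbors = 10)
  expect_true(all(c("stat", "more_successful", "less_successful",
                    "p_value") %in% names(tab)))
  ck <- tab[tab$stat == "check_question", ]
  expect_equal(ck$more_successful, 1)
  expect_equal(ck$less_successful, 0)
  hd <- tab[tab$stat == "hedge", ]
  expect_gt(hd$more_successful, hd$less_successful)
})
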