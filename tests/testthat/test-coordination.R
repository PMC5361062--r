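mk_exchanges <- function(u1, u2, speaker = "s1", marker = "m") {
  df <- data.frame(conv_id = "c", speaker = speaker,
                   stringsAsFactors = FALSE)
  df <- df[rep(1, length(u1)), ]
  df$speaker <- rep(speaker, length.out = length(u1))
  df[[paste0("u1_", marker)]] <- as.logical(u1)
  df[[paste0("u2_", marker)]] <- as.logical(u2)
  rownames(df) <- NULL
  df
}

test_that("exchange extraction follows the adjacency rule", {
  cv <- new_conversation("e", "A", rep(c("counselor", "texter"), 3),
                         rep(c("the plan", "ok sure"), 3))
  ex <- extract_exchanges(list(cv), B_role = "texter")
  expect_equal(nrow(ex), 3)

  # consecutive same-role messages: only the later one starts an exchange
  cv2 <- new_conversation("e2", "A",
                          c("counselor", "counselor", "texter"),
                          c("first note", "second note", "a reply"))
  ex2 <- extract_exchanges(list(cv2))
  expect_equal(nrow(ex2), 1)

  # no adjacent pairs -> empty frame with the right columns
  cv3 <- new_conversation("e3", "A", "texter", "hello")
  ex3 <- extract_exchanges(list(cv3))
  expect_equal(nrow(ex3), 0)
  expect_true("u1_article" %in% names(ex3))

  # synthetic corpus: one exchange per texter message after the first message
  sim <- generate_corpus(fast_config(seed = 23))
  ex4 <- extract_exchanges(sim$conversations)
  expected <- sum(vapply(sim$conversations, function(cv)
    sum(conv_roles(cv) == "texter"), numeric(1)))
  expect_equal(nrow(ex4), expected)
})

test_that("per-marker coordination matches hand counting", {
  # worked 5-exchange fixture: C = 2/3 - 3/5
  u1 <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  u2 <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  expect_equal(coordination_per_marker(u1, u2), 2 / 3 - 3 / 5)

  # independence -> 0
  expect_equal(coordination_per_marker(c(TRUE, TRUE, FALSE, FALSE),
                                       c(TRUE, FALSE, TRUE, FALSE)), 0)
  # saturation: reply always exhibits -> 0
  expect_equal(coordination_per_marker(c(TRUE, FALSE, TRUE),
                                       c(TRUE, TRUE, TRUE)), 0)
  # undefined when the initiator never exhibits
  expect_true(is.na(coordination_per_marker(c(FALSE, FALSE),
                                            c(TRUE, FALSE))))
})

test_that("aggregation macro-averages markers and averages speakers", {
  ex <- mk_exchanges(c(TRUE, TRUE, TRUE, FALSE, FALSE),
                     c(TRUE, TRUE, FALSE, FALSE, TRUE))
  res <- coordination(ex, min_exchanges = 1)
  expect_equal(res$group_value, 2 / 3 - 3 / 5)

  # two markers 0.02 and 0.04 -> speaker value 0.03
  ex2 <- mk_exchanges(rep(c(TRUE, FALSE), 25), rep(c(TRUE, FALSE), 25),
                      marker = "a")
  # craft marker b with a known small coordination on the same exchanges
  ex2$u1_b <- rep(c(TRUE, TRUE, FALSE, FALSE, FALSE), 10)
  ex2$u2_b <- rep(c(TRUE, FALSE, TRUE, FALSE, FALSE), 10)
  ca <- coordination_per_marker(ex2$u1_a, ex2$u2_a)
  cb <- coordination_per_marker(ex2$u1_b, ex2$u2_b)
  res2 <- coordination(ex2, min_exchanges = 1)
  expect_equal(res2$group_value, mean(c(ca, cb)))

  # group value lies between speaker extremes
  ex3 <- rbind(mk_exchanges(rep(TRUE, 12), rep(c(TRUE, FALSE), 6), "s1"),
               mk_exchanges(rep(TRUE, 12), rep(TRUE, 12), "s2"))
  res3 <- coordination(ex3, min_exchanges = 1)
  sv <- res3$by_speaker$c_value
  expect_gte(res3$group_value, min(sv))
  expect_lte(res3$group_value, max(sv))
})

test_that("planted coordination is recovered near its analytic expectation", {
  cfg <- generator_config(n_counselors = 6, n_conversations = 150,
                          cat_rate = 0, seed = 24)
  sim <- generate_corpus(cfg)
  ex <- extract_exchanges(sim$conversations)
  res <- coordination(ex)
  expected <- expected_coordination(0.2, 0.1)
  expect_lt(abs(res$group_value - expected), 0.02)
})

test_that("per-speaker coordination is centered at zero under independence", {
  set.seed(25)
  vals <- replicate(400, {
    n <- 20
    coordination_per_marker(runif(n) < 0.3, runif(n) < 0.3)
  })
  vals <- vals[!is.na(vals)]
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 2 * se + 1e-3)
})

test_that("category coordination flags the planted category only", {
  lex <- default_category_lexicons()[c("future", "pos_emo", "third_person")]
  hits <- vapply(1:5, function(sd) {
    cfg <- generator_config(
      n_counselors = 6, n_conversations = 200, cat_rate = 0,
      markers = lex,
      base_marker_prob = c(future = 0.2, pos_emo = 0.2, third_person = 0.2),
      coordination_delta = c(future = 0.08, pos_emo = 0, third_person = 0),
      seed = 200 + sd)
    sim <- generate_corpus(cfg)
    cc <- category_coordination(sim$conversations, category_lexicons = lex)
    fut <- cc[cc$category == "future", ]
    oth <- cc[cc$category != "future", ]
    fut$p_value < 0.01 && fut$c_value > 0 && all(oth$p_value > 0.01)
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("degenerate corpora never crash the coordination statistics", {
  cv <- new_conversation("d", "A", c("counselor", "texter"),
                         c("the plan is this", "ok"))
  ex <- extract_exchanges(list(cv))
  expect_equal(nrow(ex), 1)
  res <- coordination(ex, min_exchanges = 1)
  expect_true(is.finite(res$group_value) || is.na(res$group_value))
  cc <- category_coordination(list(cv), min_exchanges = 1)
  expect_s3_class(cc, "data.frame")
})
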