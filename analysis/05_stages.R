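#!/usr/bin/env Rscript
# Conversation-stage model: fit the constrained left-to-right message-level
# HMM with EM, decode stage paths, compare fitted stages with the planted
# ones, and report per-group stage durations and stage-characteristic words.

library(crisistalk)

convs <- read_corpus("results/corpus.jsonl")
gt <- read_ground_truth("results/ground_truth.json")
split <- split_counselors(convs, min_labeled = 15, min_messages = 30,
                          top_n = 5, bottom_n = 5)

vocab <- build_vocab(convs, min_count = 20)
cat(sprintf("vocabulary: %d words + UNK (%.1f%% token coverage)\n",
            length(vocab) - 1, 100 * attr(vocab, "coverage")))

model <- init_model(convs, n_stages = 5, vocab = vocab, seed = 1)
model <- fit_em(model, convs, max_iter = 60, tol = 1e-6)
cat(sprintf("EM: %d iterations, final log likelihood %.0f\n",
            length(model$loglik_trace), tail(model$loglik_trace, 1)))

acc <- mean(unlist(lapply(seq_along(convs), function(k)
  viterbi_decode(model, convs[[k]])$stages ==
    gt$conversations[[k]]$stages)))
cat(sprintf("message-level stage accuracy vs planted stages: %.3f\n", acc))

dur <- stage_durations(convs, model, split, n_boot = 200, seed = 1)
write.csv(dur, "results/stage_durations.csv", row.names = FALSE)
print(dur, digits = 3)

tw <- stage_top_words(model, convs, per_stage = 5, min_freq = 50)
write.csv(tw, "results/stage_top_words.csv", row.names = FALSE)

writeLines(as.character(jsonlite::serializeJSON(model)),
           "results/stage_model.json")
cat("wrote results/stage_durations.csv, stage_top_words.csv, stage_model.json\n")
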