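#!/usr/bin/env Rscript
# Generate the synthetic study corpus: 400 two-party counseling conversations
# over 10 counselors (planted quality 0.8 / 0.5), with 5 left-to-right
# stages, outcome-dependent lexical drift, marker coordination, style
# injection, and psycholinguistic category schedules. Writes the corpus and
# the full planted ground truth under results/.

library(crisistalk)

dir.create("results", showWarnings = FALSE)
cfg <- generator_config(seed = 1)
sim <- generate_corpus(cfg)

write_corpus(sim$conversations, "results/corpus.jsonl")
export_ground_truth(sim$ground_truth, "results/ground_truth.json")

msgs <- corpus_messages(sim$conversations)
cat(sprintf("conversations: %d\n", length(sim$conversations)))
cat(sprintf("messages: %d (mean %.1f per conversation)\n", nrow(msgs),
            nrow(msgs) / length(sim$conversations)))
cat(sprintf("mean tokens per message: %.1f\n", mean(msgs$n_tokens)))
cat(sprintf("positive outcome rate: %.3f\n",
            mean(vapply(sim$conversations, function(cv)
              cv$outcome == "positive", logical(1)))))
cat("wrote results/corpus.jsonl and results/ground_truth.json\n")
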