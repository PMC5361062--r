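#!/usr/bin/env Rscript
# Split counselors into more and less successful halves by labeled success
# rate and check the split against the planted per-counselor quality.

library(crisistalk)

convs <- read_corpus("results/corpus.jsonl")
gt <- read_ground_truth("results/ground_truth.json")

split <- split_counselors(convs, min_labeled = 15, min_messages = 30,
                          top_n = 5, bottom_n = 5)
print(split)

planted_high <- names(gt$quality)[gt$quality > 0.65]
agree <- length(intersect(split$more_successful, planted_high)) /
  length(split$more_successful)
cat(sprintf("agreement with planted high-quality group: %.0f%%\n",
            100 * agree))

df <- data.frame(counselor_id = names(split$success_rate),
                 success_rate = as.numeric(split$success_rate),
                 n_labeled = as.integer(split$n_labeled),
                 planted_quality = as.numeric(gt$quality[
                   names(split$success_rate)]),
                 group = ifelse(names(split$success_rate) %in%
                                  split$more_successful, "more_successful",
                         ifelse(names(split$success_rate) %in%
                                  split$less_successful, "less_successful",
                                "middle")))
write.csv(df[order(-df$success_rate), ], "results/counselor_split.csv",
          row.names = FALSE)
cat("wrote results/counselor_split.csv\n")
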