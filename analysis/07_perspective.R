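#!/usr/bin/env Rscript
# Perspective change in the texter over conversation time: temporal
# orientation (past/present/future), self- vs other-focus, and sentiment
# ratio, split by conversation outcome.

library(crisistalk)

convs <- read_corpus("results/corpus.jsonl")

traj <- rbind(temporal_orientation(convs, n_boot = 300, seed = 1),
              self_focus(convs, n_boot = 300, seed = 1),
              sentiment_ratio(convs, n_boot = 300, seed = 1))
write.csv(traj, "results/perspective.csv", row.names = FALSE)

for (m in c("future", "self_focus", "sentiment")) {
  for (out in c("positive", "negative")) {
    v <- traj$value[traj$measure == m & traj$outcome == out]
    cat(sprintf("%-10s %-8s: %s\n", m, out,
                paste(sprintf("%.3f", v), collapse = " ")))
  }
}
cat("wrote results/perspective.csv\n")
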