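#!/usr/bin/env Rscript
# Counselor adaptability: cosine distance between the TF-IDF vectors of
# counselor language in positive vs negative conversations, per conversation
# fifth and counselor group, with counselor-bootstrap CIs and a
# permuted-outcome null band. With planted drift the divergence grows
# monotonically over conversation time.

library(crisistalk)

convs <- read_corpus("results/corpus.jsonl")
split <- split_counselors(convs, min_labeled = 15, min_messages = 30,
                          top_n = 5, bottom_n = 5)
idf <- global_idf(convs)

curves <- do.call(rbind, lapply(c("more_successful", "less_successful"),
  function(g) adaptability_curve(convs, split, g, idf = idf,
                                 n_boot = 500, seed = 1)))
write.csv(curves, "results/adaptability_curve.csv", row.names = FALSE)

nul <- adaptability_null(convs, split, "more_successful", idf = idf,
                         n_perm = 200, seed = 1)
write.csv(nul, "results/adaptability_null.csv", row.names = FALSE)

for (g in unique(curves$group)) {
  d <- curves$distance[curves$group == g]
  cat(sprintf("%s: %s (monotone increase: %s)\n", g,
              paste(sprintf("%.3f", d), collapse = " "),
              all(diff(d) > 0)))
}
cat("wrote results/adaptability_curve.csv and results/adaptability_null.csv\n")
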