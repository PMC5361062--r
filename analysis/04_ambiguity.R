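#!/usr/bin/env Rscript
# Ambiguity analyses: outcome rate by situation-setter length, counselor
# write-more reaction, clustering of near-identical setters, response-class
# comparison between counselor groups, and response templatedness.

library(crisistalk)

convs <- read_corpus("results/corpus.jsonl")
split <- split_counselors(convs, min_labeled = 15, min_messages = 30,
                          top_n = 5, bottom_n = 5)
bins <- c(0, 10, 13, 16, 20, Inf)

amb <- ambiguity_outcome_table(convs, bins)
write.csv(amb, "results/ambiguity_outcome.csv", row.names = FALSE)
cat("positive rate by setter-length bin:\n")
print(amb, digits = 3)

ratio <- counselor_texter_length_ratio(convs, bins)
write.csv(ratio, "results/length_ratio.csv", row.names = FALSE)
cat("counselor/texter length ratio by bin:",
    sprintf("%.2f", ratio$mean_ratio), "\n")

tab3 <- tryCatch(
  response_table(convs, split, distance_threshold = 0.6),
  error = function(e) {
    cat("response table skipped:", conditionMessage(e), "\n")
    NULL
  })
if (!is.null(tab3)) {
  write.csv(tab3, "results/response_table.csv", row.names = FALSE)
  cat("wrote results/response_table.csv\n")
}

# templatedness of the counselor replies to setters
sf <- Filter(function(r) !is.null(r$c_reply_tokens),
             crisistalk:::setter_frame(convs))
counts <- templatedness(lapply(sf, `[[`, "c_reply_tokens"), 0.6)
grp <- vapply(sf, function(r) {
  if (r$counselor_id %in% split$more_successful) "more_successful"
  else if (r$counselor_id %in% split$less_successful) "less_successful"
  else NA_character_
}, character(1))
tmpl <- data.frame(group = grp, neighbors = counts)
tmpl <- tmpl[!is.na(tmpl$group), ]
write.csv(tmpl, "results/templatedness.csv", row.names = FALSE)
cat(sprintf("mean reply neighbors: more successful %.1f, less successful %.1f\n",
            mean(tmpl$neighbors[tmpl$group == "more_successful"]),
            mean(tmpl$neighbors[tmpl$group == "less_successful"])))
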