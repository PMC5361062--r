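#!/usr/bin/env Rscript
# Linguistic coordination (accommodation): how much each side's probability
# of exhibiting a stylistic marker rises right after the partner exhibited
# it, aggregated per speaker and group, in both directions; plus the
# category-marker variant used for perspective change.

library(crisistalk)

convs <- read_corpus("results/corpus.jsonl")
split <- split_counselors(convs, min_labeled = 15, min_messages = 30,
                          top_n = 5, bottom_n = 5)

ex_t <- extract_exchanges(convs, B_role = "texter", A_role = "counselor")
ex_c <- extract_exchanges(convs, B_role = "counselor", A_role = "texter")
co_t <- coordination(ex_t)
co_c <- coordination(ex_c)
cat(sprintf("C(texter -> counselor) = %.4f over %d texters\n",
            co_t$group_value, nrow(co_t$by_speaker)))
cat(sprintf("C(counselor -> texter) = %.4f over %d counselors\n",
            co_c$group_value, nrow(co_c$by_speaker)))
cat(sprintf("analytic expectation from planted base/delta: %.4f\n",
            expected_coordination(0.2, 0.1)))

# split counselor-side coordination by group
grp_of <- function(sp) ifelse(sp %in% split$more_successful, "more_successful",
                       ifelse(sp %in% split$less_successful,
                              "less_successful", NA))
bs <- co_c$by_speaker
bs$group <- grp_of(bs$speaker)
by_grp <- stats::aggregate(c_value ~ group, bs[!is.na(bs$group), ], mean)
print(by_grp, digits = 4)

out <- data.frame(direction = c("texter_to_counselor", "counselor_to_texter"),
                  c_value = c(co_t$group_value, co_c$group_value),
                  n_speakers = c(nrow(co_t$by_speaker), nrow(co_c$by_speaker)))
write.csv(out, "results/coordination.csv", row.names = FALSE)

cat_co <- category_coordination(convs)
write.csv(cat_co, "results/category_coordination.csv", row.names = FALSE)
print(cat_co, digits = 3)
cat("wrote results/coordination.csv and results/category_coordination.csv\n")
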