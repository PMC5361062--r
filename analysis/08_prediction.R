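#!/usr/bin/env Rscript
# Conversation-outcome prediction from message prefixes: balanced dataset,
# penalized logistic regression on counselor features, nested feature
# ladder at x = 80%, and a prefix sweep of cross-validated AUC.

library(crisistalk)

convs <- read_corpus("results/corpus.jsonl")
model <- jsonlite::unserializeJSON(paste(readLines("results/stage_model.json"),
                                         collapse = "\n"))

bal <- balance_dataset(convs, min_messages = 30, seed = 1)
cat(sprintf("balanced dataset: %d conversations\n", length(bal)))

# nested feature ladder at x = 80, with n-grams last (L1 route)
fm <- build_feature_matrix(bal, x_percent = 80, model = model,
                           use_ngrams = TRUE)
sets <- default_feature_sets(colnames(fm$X), fm$ngram_cols)
ladder <- feature_ladder(fm$X, fm$y, sets, ngram_cols = fm$ngram_cols,
                         k = 10, seed = 1)
write.csv(ladder, "results/prediction_ladder.csv", row.names = FALSE)
print(ladder, digits = 3)

# AUC as a function of the visible prefix
sweep <- do.call(rbind, lapply(c(20, 40, 60, 80, 100), function(x) {
  f <- build_feature_matrix(bal, x_percent = x, model = model)
  cv <- cross_validate(f$X, f$y, k = 10, seed = 1)
  data.frame(x_percent = x, auc = cv$mean_auc, accuracy = cv$mean_accuracy)
}))
write.csv(sweep, "results/prefix_auc.csv", row.names = FALSE)
print(sweep, digits = 3)
cat("wrote results/prediction_ladder.csv and results/prefix_auc.csv\n")
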