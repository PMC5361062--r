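#' Default end-to-end pipeline configuration
#'
#' One list drives the whole analysis: corpus source (a path to a JSONL
#' corpus or a [generator_config()]), per-stage parameter blocks, and a
#' global seed. Unknown keys are rejected by [run_pipeline()].
#'
#' @param generator A [generator_config()] (ignored when `corpus_path` set).
#' @param corpus_path Optional path to an existing JSONL corpus.
#' @param seed Global seed.
#' @param split Parameters for [split_counselors()].
#' @param adaptability Parameters for [adaptability_curve()].
#' @param ambiguity Parameters for [response_table()] and
#'   [ambiguity_outcome_table()].
#' @param stages Parameters for [init_model()] / [fit_em()] /
#'   [stage_durations()].
#' @param coordination Parameters for the coordination analyses.
#' @param perspective Parameters for the trajectory analyses.
#' @param prediction Parameters for the outcome-prediction ladder.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            corpus_path = NULL,
                            seed = 1,
                            split = list(min_labeled = 15, min_messages = 30,
                                         top_n = 5, bottom_n = 5),
                            adaptability = list(n_chunks = 5, n_boot = 200),
                            ambiguity = list(min_tokens = 10,
                                             distance_threshold = 0.4,
                                             min_neighbors = 10,
                                             bins = c(0, 8, 12, 16, 24, Inf)),
                            stages = list(n_stages = 5, min_count = 20,
                                          max_iter = 50, tol = 1e-4,
                                          min_len = 40, max_len = 60),
                            coordination = list(min_exchanges = 10),
                            perspective = list(n_chunks = 5, n_boot = 200),
                            prediction = list(x_percent = 80, k = 10,
                                              lambda = 1e-2,
                                              use_ngrams = FALSE,
                                              min_messages = 30)) {
  structure(list(generator = generator, corpus_path = corpus_path,
                 seed = seed, split = split, adaptability = adaptability,
                 ambiguity = ambiguity, stages = stages,
                 coordination = coordination, perspective = perspective,
                 prediction = prediction),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields mirror [pipeline_config()]; the `generator` block mirrors
#' [generator_config()]. Unknown keys raise an error.
#'
#' @param path YAML file.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$generator)) {
    gknown <- names(formals(generator_config))
    gunknown <- setdiff(names(raw$generator), gknown)
    if (length(gunknown) > 0) {
      stop("unknown generator key(s): ", paste(gunknown, collapse = ", "))
    }
    raw$generator <- do.call(generator_config, raw$generator)
  }
  do.call(pipeline_config, raw)
}

write_csv_stable <- function(df, path) {
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the corpus, builds the counselor split, and runs the
#' adaptability, ambiguity, stage-model, coordination, perspective, and
#' prediction analyses, writing one CSV per analysis plus a JSON manifest
#' (seed, input hash, file hashes) under `out_dir`. Deterministic: the same
#' config and seed produce byte-identical CSV outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param verbose Log per-stage progress.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  if (!is.null(config$corpus_path)) {
    if (!file.exists(config$corpus_path)) {
      stop("corpus path does not exist: ", config$corpus_path)
    }
    say("reading corpus from %s", config$corpus_path)
    convs <- read_corpus(config$corpus_path)
    gt <- NULL
  } else {
    gen <- config$generator
    gen$seed <- config$seed
    say("generating synthetic corpus (%d conversations, seed %d)",
        gen$n_conversations, gen$seed)
    sim <- generate_corpus(gen)
    convs <- sim$conversations
    gt <- sim$ground_truth
    write_corpus(convs, file.path(out_dir, "corpus.jsonl"))
  }

  say("splitting counselors")
  split <- do.call(split_counselors, c(list(convs), config$split))
  split_df <- data.frame(
    counselor_id = c(split$more_successful, split$less_successful),
    group = rep(c("more_successful", "less_successful"),
                c(length(split$more_successful),
                  length(split$less_successful))))
  split_df$success_rate <- split$success_rate[split_df$counselor_id]
  write_csv_stable(split_df, file.path(out_dir, "split.csv"))

  say("adaptability curves")
  idf <- global_idf(convs)
  ad <- do.call(rbind, lapply(c("more_successful", "less_successful"),
    function(g) do.call(adaptability_curve,
                        c(list(convs, split, g, idf = idf,
                               seed = config$seed), config$adaptability))))
  write_csv_stable(ad, file.path(out_dir, "adaptability.csv"))

  say("ambiguity analyses")
  amb_cfg <- config$ambiguity
  amb_out <- ambiguity_outcome_table(convs, amb_cfg$bins, amb_cfg$min_tokens)
  write_csv_stable(amb_out, file.path(out_dir, "ambiguity_outcome.csv"))
  ratio <- counselor_texter_length_ratio(convs, amb_cfg$bins,
                                         amb_cfg$min_tokens)
  write_csv_stable(ratio, file.path(out_dir, "length_ratio.csv"))
  tab3 <- tryCatch(
    response_table(convs, split, min_tokens = amb_cfg$min_tokens,
                   distance_threshold = amb_cfg$distance_threshold,
                   min_neighbors = amb_cfg$min_neighbors),
    error = function(e) {
      say("response table skipped: %s", conditionMessage(e))
      NULL
    })
  if (!is.null(tab3)) {
    write_csv_stable(tab3, file.path(out_dir, "response_table.csv"))
  }

  say("stage model (EM)")
  st <- config$stages
  vocab <- build_vocab(convs, min_count = st$min_count)
  model <- init_model(convs, n_stages = st$n_stages, vocab = vocab,
                      seed = config$seed)
  model <- fit_em(model, convs, max_iter = st$max_iter, tol = st$tol)
  dur <- stage_durations(convs, model, split, min_len = st$min_len,
                         max_len = st$max_len, seed = config$seed)
  write_csv_stable(dur, file.path(out_dir, "stage_durations.csv"))
  tw <- stage_top_words(model, convs)
  write_csv_stable(tw, file.path(out_dir, "stage_top_words.csv"))

  say("coordination")
  co_cfg <- config$coordination
  ex_t <- extract_exchanges(convs, B_role = "texter", A_role = "counselor")
  ex_c <- extract_exchanges(convs, B_role = "counselor", A_role = "texter")
  co <- data.frame(
    direction = c("texter_to_counselor", "counselor_to_texter"),
    c_value = c(coordination(ex_t, min_exchanges = co_cfg$min_exchanges)$group_value,
                coordination(ex_c, min_exchanges = co_cfg$min_exchanges)$group_value))
  cat_co <- category_coordination(convs,
                                  min_exchanges = co_cfg$min_exchanges)
  write_csv_stable(co, file.path(out_dir, "coordination.csv"))
  write_csv_stable(cat_co, file.path(out_dir, "category_coordination.csv"))

  say("perspective trajectories")
  pp <- config$perspective
  traj <- rbind(
    temporal_orientation(convs, n_chunks = pp$n_chunks, n_boot = pp$n_boot,
                         seed = config$seed),
    self_focus(convs, n_chunks = pp$n_chunks, n_boot = pp$n_boot,
               seed = config$seed),
    sentiment_ratio(convs, n_chunks = pp$n_chunks, n_boot = pp$n_boot,
                    seed = config$seed))
  write_csv_stable(traj, file.path(out_dir, "perspective.csv"))

  say("outcome prediction ladder")
  pr <- config$prediction
  bal <- balance_dataset(convs, min_messages = pr$min_messages,
                         seed = config$seed)
  fm <- build_feature_matrix(bal, x_percent = pr$x_percent, model = model,
                             use_ngrams = pr$use_ngrams)
  sets <- default_feature_sets(colnames(fm$X), fm$ngram_cols)
  ladder <- feature_ladder(fm$X, fm$y, sets, ngram_cols = fm$ngram_cols,
                           k = pr$k, seed = config$seed, lambda = pr$lambda)
  write_csv_stable(ladder, file.path(out_dir, "prediction_ladder.csv"))

  csvs <- sort(list.files(out_dir, pattern = "\\.csv$", full.names = TRUE))
  manifest <- list(
    seed = config$seed,
    n_conversations = length(convs),
    corpus_source = if (is.null(config$corpus_path)) "synthetic"
                    else config$corpus_path,
    files = stats::setNames(as.list(unname(tools::md5sum(csvs))),
                            basename(csvs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(split = split, adaptability = ad, ambiguity = amb_out,
                 response_table = tab3, model = model, durations = dur,
                 coordination = co, category_coordination = cat_co,
                 perspective = traj, ladder = ladder, manifest = manifest,
                 ground_truth = gt))
}
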