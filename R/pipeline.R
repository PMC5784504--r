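# End-to-end orchestration: generate -> index -> featurize/encode ->
# train -> evaluate -> export, from one declarative configuration.

#' Pipeline run configuration
#'
#' @param task `"mutation_gene"` or `"mutation_drug"`.
#' @param level `"document"` (feature classifier) or `"sentence"` (CNN).
#' @param model `"random_forest"`, `"decision_tree"` (document level) or
#'   `"cnn"` (sentence level).
#' @param seed master seed; all stage seeds derive from it.
#' @param generator a [generator_config()].
#' @param cnn a [cnn_config()] (sentence level only).
#' @param use_search_scores fuse the four search-score features.
#' @param folds document-level cross-validation folds.
#' @param repetitions,test_pos,test_neg sentence-level sub-sampling
#'   protocol.
#' @param out_dir optional directory for artifacts (metrics, relation
#'   table, run log).
#' @return list of class `mrx_run_config`.
#' @export
run_config <- function(task = c("mutation_drug", "mutation_gene"),
                       level = c("document", "sentence"),
                       model = NULL, seed = 1L,
                       generator = generator_config(seed = seed),
                       cnn = cnn_config(seed = seed),
                       use_search_scores = TRUE,
                       folds = 10L, repetitions = 5L,
                       test_pos = 100L, test_neg = 100L,
                       out_dir = NULL) {
  task <- match.arg(task); level <- match.arg(level)
  if (is.null(model)) model <- if (level == "document") "random_forest" else "cnn"
  if (level == "document" && !model %in% c("random_forest", "decision_tree")) {
    stop("configuration error: document level requires a feature classifier ",
         "(random_forest or decision_tree), got '", model, "'")
  }
  if (level == "sentence" && model != "cnn") {
    stop("configuration error: sentence level uses the cnn model")
  }
  structure(as.list(environment()), class = "mrx_run_config")
}

#' Run the full extraction pipeline on a generated corpus
#'
#' Document level: featurize all candidates against the background index
#' and run balanced stratified cross-validation. Sentence level: build the
#' distant-supervision sentence dataset, encode it, and run repeated
#' random sub-sampling validation of the CNN; predicted relations above
#' threshold are exported as a relation table. Rerunning with an identical
#' configuration reproduces identical metrics.
#'
#' @param config a [run_config()].
#' @return list with `metrics`, `config_hash`, and stage artifacts
#'   (`truth`, plus `features` or `dataset`/`relations`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "mrx_run_config"))
  partner_kind <- if (config$task == "mutation_gene") "gene" else "drug"
  hash <- sum(utils::head(utf8ToInt(paste(
    config$task, config$level, config$model, config$seed,
    config$generator$seed, collapse = "|")), 512) * 7L) %% 1000000007L
  gen <- generate_corpus(config$generator)
  index <- build_index(gen$background)
  gold_doc <- gen$truth$doc_relations[
    gen$truth$doc_relations$partner_kind == partner_kind, , drop = FALSE]
  out <- list(config_hash = hash, truth = gen$truth)
  if (config$level == "document") {
    feats <- featurize_candidates(gen$corpus, partner_kind, gold_doc,
                                  if (config$use_search_scores) index else NULL)
    fnames <- if (config$use_search_scores) DOC_FEATURE_NAMES else
      DOC_FEATURE_NAMES[1:4]
    cv <- cross_validate(feats, config$model, folds = config$folds,
                         seed = config$seed, feature_names = fnames)
    out$features <- feats
    out$metrics <- cv$mean
    out$per_fold <- cv$per_fold
  } else {
    rel_table <- gold_doc
    ds <- build_pair_sentence_dataset(
      gen$corpus, rel_table,
      proteins = gen$truth$proteins, partner_kind = partner_kind)
    vocab <- cnn_vocab(gen$corpus)
    sc_index <- if (config$use_search_scores) index else NULL
    enc_pos <- encode_dataset(gen$corpus, transform_labels(ds$positives, TRUE),
                              partner_kind, vocab, config$cnn, sc_index)
    enc_neg <- encode_dataset(gen$corpus, transform_labels(ds$negatives, FALSE),
                              partner_kind, vocab, config$cnn, sc_index)
    trainer <- cnn_trainer(config$cnn, vocab)
    val <- subsampling_validation(enc_pos, enc_neg, trainer,
                                  repetitions = config$repetitions,
                                  test_pos = config$test_pos,
                                  test_neg = config$test_neg,
                                  seed = config$seed)
    model <- cnn_train(c(enc_pos, enc_neg), config = config$cnn, vocab = vocab)
    all_pairs <- rbind(ds$positives, ds$negatives)
    probs <- predict(model, c(enc_pos, enc_neg))
    out$dataset <- ds
    out$metrics <- val$mean
    out$per_rep <- val$per_rep
    out$relations <- export_relation_table(all_pairs, probs, partner_kind,
                                           dedupe = TRUE)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      data.frame(metric = names(out$metrics),
                 value = unlist(out$metrics)),
      file.path(config$out_dir, "metrics.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$relations)) {
      utils::write.table(out$relations,
                         file.path(config$out_dir, "relations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(c(
      sprintf("config_hash: %d", hash),
      sprintf("task: %s  level: %s  model: %s", config$task, config$level,
              config$model),
      sprintf("seed: %d", config$seed),
      sprintf("R: %s", R.version.string)
    ), file.path(config$out_dir, "run_log.txt"))
  }
  out
}

transform_labels <- function(df, label) {
  df$label <- rep(label, NROW(df))
  df
}

#' Trainer closure for sub-sampling validation of the CNN
#'
#' Adapts [cnn_train()] to the `(train_pos, train_neg, seed)` interface of
#' [subsampling_validation()].
#'
#' @param config a [cnn_config()].
#' @param vocab from [cnn_vocab()].
#' @param initial_vectors optional pre-trained `mrx_word_vectors`.
#' @return a trainer function returning a probability predictor.
#' @export
cnn_trainer <- function(config, vocab, initial_vectors = NULL) {
  function(train_pos, train_neg, seed) {
    cfg <- config
    cfg$seed <- seed %% 1000000007L
    model <- cnn_train(c(train_pos, train_neg), config = cfg, vocab = vocab,
                       initial_vectors = initial_vectors)
    function(examples) predict(model, examples)
  }
}

#' Assemble the sentence-level synthetic benchmark
#'
#' Generates a corpus, builds the distant-supervision sentence datasets for
#' both partner kinds, encodes them for the CNN (search scores from the
#' background index as scalar features), and draws a fixed-size balanced
#' pool. Deterministic per seed.
#'
#' @param seed integer seed (drives generation and the pool draw).
#' @param n_documents corpus size.
#' @param config a [cnn_config()].
#' @param n_pos,n_neg pool sizes drawn from the encoded datasets.
#' @param use_search_scores attach the four search scores as scalars.
#' @param generator_overrides named list merged into the generator
#'   configuration.
#' @return list with `positives`, `negatives` (encoded example lists),
#'   `vocab`, `corpus`, `background`, `truth`.
#' @export
sentence_benchmark <- function(seed, n_documents = 1000L,
                               config = cnn_config(seed = seed),
                               n_pos = 1600L, n_neg = 1600L,
                               use_search_scores = TRUE,
                               generator_overrides = list()) {
  gcfg <- generator_config(seed = seed, n_documents = n_documents,
                           n_mutations = 150L, n_genes = 40L, n_drugs = 40L,
                           n_background_documents = 300L)
  for (nm in names(generator_overrides)) gcfg[[nm]] <- generator_overrides[[nm]]
  g <- generate_corpus(gcfg)
  index <- if (use_search_scores) build_index(g$background) else NULL
  gold <- g$truth$doc_relations
  vocab <- cnn_vocab(g$corpus)
  pos <- list(); neg <- list()
  for (pk in c("gene", "drug")) {
    ds <- build_pair_sentence_dataset(g$corpus,
                                      gold[gold$partner_kind == pk, ],
                                      proteins = g$truth$proteins,
                                      partner_kind = pk)
    pos[[pk]] <- encode_dataset(g$corpus, transform_labels(ds$positives, TRUE),
                                pk, vocab, config, index)
    neg[[pk]] <- encode_dataset(g$corpus, transform_labels(ds$negatives, FALSE),
                                pk, vocab, config, index)
  }
  pos <- c(pos$gene, pos$drug); neg <- c(neg$gene, neg$drug)
  if (length(pos) < n_pos || length(neg) < n_neg) {
    stop("configuration error: corpus too small for the requested pool (",
         length(pos), " positives, ", length(neg), " negatives)")
  }
  old <- .Random.seed.save(); set.seed(seed + 31L)
  pos <- pos[sample(length(pos), n_pos)]
  neg <- neg[sample(length(neg), n_neg)]
  .Random.seed.restore(old)
  list(positives = pos, negatives = neg, vocab = vocab,
       corpus = g$corpus, background = g$background, truth = g$truth)
}
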