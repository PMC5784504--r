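# small dimensions keep the unit tests fast; the full-size configuration is
# exercised in the acceptance suite
small_cnn_config <- function(epochs = 6L, ...) {
  cnn_config(word_dim = 24L, type_dim = 4L, pos_dim = 4L,
             maps_per_width = 12L, filter_widths = c(2L, 3L),
             max_sentence_len = 16L, epochs = epochs, batch_size = 16L, ...)
}

pair_doc <- function() {
  mutrelex:::assemble_document("P1", list(mutrelex:::render_template(
    c("Word", "{M}", "binds", "{D}", "tightly", "{G}", "nearby"),
    list("{M}" = list(surface = "V600E", kind = "mutation", normalized = "V600E"),
         "{D}" = list(surface = "vemu", kind = "drug", normalized = "vemu"),
         "{G}" = list(surface = "BRAF", kind = "gene", normalized = "BRAF")))))
}

test_that("encoding carries aligned token, type and position channels", {
  doc <- pair_doc()
  vocab <- cnn_vocab(corpus(list(doc)))
  cfg <- small_cnn_config()
  e <- encode_sentence(doc, 0L, "V600E", "vemu", "drug", vocab, cfg)
  L <- cfg$max_sentence_len
  expect_length(e$token_ids, L)
  expect_length(e$type_ids, L)
  # mutation at token 2, drug at token 4 (1-based)
  expect_equal(TYPE_ALPHABET[e$type_ids[2]], "target_mutation")
  expect_equal(TYPE_ALPHABET[e$type_ids[4]], "target_drug")
  expect_equal(TYPE_ALPHABET[e$type_ids[6]], "other_gene")
  # relative positions are offsets clipped to the window; 0 at the target
  expect_equal(e$pos_mut[1:7] - (L + 1L), (1:7) - 2L)
  expect_equal(e$pos_partner[1:7] - (L + 1L), (1:7) - 4L)
  # exactly one token of each target type
  expect_equal(sum(TYPE_ALPHABET[e$type_ids] == "target_mutation"), 1L)
  expect_equal(sum(TYPE_ALPHABET[e$type_ids] == "target_drug"), 1L)
  # padding uses the reserved ids
  expect_true(all(e$token_ids[8:L] == mutrelex:::PAD_ID))
  expect_true(all(TYPE_ALPHABET[e$type_ids[8:L]] == "pad"))
  expect_true(all(e$pos_mut[8:L] == 2L * L + 2L))
  # swapping targets makes the non-target gene typing the new target
  e2 <- encode_sentence(doc, 0L, "V600E", "BRAF", "gene", vocab, cfg)
  expect_equal(TYPE_ALPHABET[e2$type_ids[6]], "target_gene")
  expect_equal(TYPE_ALPHABET[e2$type_ids[4]], "other_drug")
  # absent target is a contract violation
  expect_error(encode_sentence(doc, 0L, "T790M", "vemu", "drug", vocab, cfg),
               "contract violation")
})

test_that("long sentences truncate to a window holding both targets", {
  toks <- c(paste0("w", 1:20), "{M}", "w21", "{D}", paste0("x", 1:20))
  fill <- list("{M}" = list(surface = "V600E", kind = "mutation", normalized = "V600E"),
               "{D}" = list(surface = "vemu", kind = "drug", normalized = "vemu"))
  doc <- mutrelex:::assemble_document("L1", list(mutrelex:::render_template(toks, fill)))
  cfg <- small_cnn_config()
  vocab <- cnn_vocab(corpus(list(doc)))
  e <- encode_sentence(doc, 0L, "V600E", "vemu", "drug", vocab, cfg)
  expect_equal(e$n_tokens, cfg$max_sentence_len)
  expect_equal(sum(TYPE_ALPHABET[e$type_ids] == "target_mutation"), 1L)
  expect_equal(sum(TYPE_ALPHABET[e$type_ids] == "target_drug"), 1L)
  i_mut <- which(TYPE_ALPHABET[e$type_ids] == "target_mutation")
  i_par <- which(TYPE_ALPHABET[e$type_ids] == "target_drug")
  expect_equal(e$pos_mut[i_mut], cfg$max_sentence_len + 1L)  # offset 0
  expect_equal(i_par - i_mut, 2L)                            # gap preserved
})

make_sep_dataset <- function(n, vocab_docs, cfg, seed = 1,
                             flip_labels = FALSE) {
  # template-separable: trigger word "binds" for positives, "ignores" for
  # negatives
  set.seed(seed)
  docs <- lapply(seq_len(n), function(i) {
    verb <- if (i %% 2 == 0) "binds" else "ignores"
    extra <- sample(c("alpha", "beta", "gamma", "delta"), 2)
    mutrelex:::assemble_document(sprintf("S%d", i), list(
      mutrelex:::render_template(
        c("Study", extra[1], "{M}", verb, "{D}", extra[2]),
        list("{M}" = list(surface = "V600E", kind = "mutation", normalized = "V600E"),
             "{D}" = list(surface = "vemu", kind = "drug", normalized = "vemu")))))
  })
  corp <- corpus(docs)
  vocab <- cnn_vocab(corp)
  labels <- (seq_len(n) %% 2) == 0
  if (flip_labels) labels <- sample(labels)
  list(examples = lapply(seq_len(n), function(i)
    encode_sentence(corp[[i]], 0L, "V600E", "vemu", "drug", vocab, cfg,
                    scalar_features = c(0, 0), label = labels[i])),
    vocab = vocab, labels = labels)
}

test_that("the CNN separates trigger-word templates and is seeded", {
  cfg <- small_cnn_config(seed = 11)
  d <- make_sep_dataset(120, cfg = cfg)
  m <- cnn_train(d$examples, config = cfg, vocab = d$vocab)
  pr <- predict(m, d$examples)
  expect_true(all(pr >= 0 & pr <= 1))
  r <- prf_from_labels(d$labels, pr >= 0.5)
  expect_gte(r$f1, 0.98)
  # two runs with identical seed/config/data agree exactly
  m2 <- cnn_train(d$examples, config = cfg, vocab = d$vocab)
  expect_identical(m$params, m2$params)
  expect_identical(m$history, m2$history)
})

test_that("dev-based epoch selection tracks the best dev F1", {
  cfg <- small_cnn_config(seed = 13, epochs = 4L)
  d <- make_sep_dataset(80, cfg = cfg)
  m <- cnn_train(d$examples[1:60], dev = d$examples[61:80], config = cfg,
                 vocab = d$vocab)
  expect_equal(m$best_dev_f1, max(m$history))
})

test_that("permuted labels keep the classifier near chance", {
  cfg <- small_cnn_config(seed = 17, epochs = 3L)
  d <- make_sep_dataset(160, cfg = cfg, seed = 5, flip_labels = TRUE)
  tr <- d$examples[1:120]; te <- d$examples[121:160]
  m <- cnn_train(tr, config = cfg, vocab = d$vocab)
  r <- prf_from_labels(d$labels[121:160], predict(m, te) >= 0.5)
  expect_gte(r$f1, 0.2)
  expect_lte(r$f1, 0.8)
})

test_that("probabilities are a softmax and empty inputs yield empty output", {
  cfg <- small_cnn_config(seed = 19, epochs = 1L)
  d <- make_sep_dataset(40, cfg = cfg)
  m <- cnn_train(d$examples, config = cfg, vocab = d$vocab)
  expect_identical(predict(m, list()), numeric(0))
  pk <- mutrelex:::pack_encodings(d$examples[1:5])
  fw <- mutrelex:::cnn_forward(m$params, pk, 1:5, cfg)
  expect_equal(rowSums(fw$probs), rep(1, 5))
})

test_that("scalar standardization absorbs uniform translation", {
  cfg <- small_cnn_config(seed = 23, epochs = 2L)
  d <- make_sep_dataset(60, cfg = cfg)
  shift <- function(ex, delta) {
    ex$scalar_features <- ex$scalar_features + delta
    ex
  }
  shifted <- lapply(d$examples, shift, delta = 100)
  m1 <- cnn_train(d$examples, config = cfg, vocab = d$vocab)
  m2 <- cnn_train(shifted, config = cfg, vocab = d$vocab)
  expect_equal(predict(m1, d$examples), predict(m2, shifted), tolerance = 1e-8)
})

test_that("pre-trained vectors of the wrong dimension are rejected", {
  cfg <- small_cnn_config(seed = 29, epochs = 1L)
  d <- make_sep_dataset(20, cfg = cfg)
  wv <- structure(list(vectors = matrix(0, 3, 10,
                                        dimnames = list(c("a", "b", "c"))),
                       dim = 10L), class = "mrx_word_vectors")
  expect_error(cnn_train(d$examples, config = cfg, vocab = d$vocab,
                         initial_vectors = wv),
               "configuration error")
})

test_that("numeric gradients match the analytic backward pass", {
  cfg <- cnn_config(word_dim = 6L, type_dim = 3L, pos_dim = 2L,
                    maps_per_width = 4L, filter_widths = c(2L, 3L),
                    max_sentence_len = 8L, epochs = 1L, batch_size = 4L,
                    seed = 31)
  d <- make_sep_dataset(8, cfg = cfg)
  pk <- mutrelex:::pack_encodings(d$examples)
  pk$S <- matrix(stats::rnorm(length(d$examples) * 2), ncol = 2)
  set.seed(31)
  th <- mutrelex:::init_params(cfg, length(d$vocab), 2L, NULL, d$vocab)
  idx <- 1:4
  mask <- matrix(1, 4, 2 * 4 + 2)
  loss_at <- function(th) {
    fw <- mutrelex:::cnn_forward(th, pk, idx, cfg, dropout_mask = mask)
    y <- pk$y[idx]
    -mean(log(fw$probs[cbind(1:4, ifelse(y, 2, 1))]))
  }
  fw <- mutrelex:::cnn_forward(th, pk, idx, cfg, dropout_mask = mask,
                               keep_interm = TRUE)
  g <- mutrelex:::cnn_backward(th, fw, pk, idx, cfg, mask)
  eps <- 1e-6
  for (nm in c("W_o", "b_o", "W2", "b2", "E_word", "E_pm")) {
    p <- th[[nm]]
    for (probe in seq_len(min(5, length(p)))) {
      i <- if (nm == "E_word") {
        # probe an embedding row that is actually used in the batch
        used <- unique(as.vector(pk$TOK[idx, ]))
        cbindable <- used[probe %% length(used) + 1]
        (probe %% ncol(p)) * nrow(p) + cbindable
      } else probe
      th2 <- th; th2[[nm]][i] <- th2[[nm]][i] + eps
      th3 <- th; th3[[nm]][i] <- th3[[nm]][i] - eps
      num <- (loss_at(th2) - loss_at(th3)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   info = paste(nm, i))
    }
  }
})
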