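test_that("precision/recall/F1 match hand computation", {
  r <- prf(8, 2, 2)
  expect_equal(c(r$precision, r$recall, r$f1), c(0.8, 0.8, 0.8))
  r0 <- prf(0, 0, 5)
  expect_equal(c(r0$precision, r0$recall, r0$f1), c(0, 0, 0))
  r2 <- prf(6, 1, 3)
  expect_equal(r2$precision, 6 / 7)
  expect_equal(r2$recall, 6 / 9)
  expect_equal(r2$f1, 2 * (6 / 7) * (6 / 9) / (6 / 7 + 6 / 9))
  # randomized confusion matrices against an independent formula
  set.seed(9)
  for (i in 1:50) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    r <- prf(tp, fp, fn)
    p <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
    rc <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
    expect_equal(r$precision, p)
    expect_equal(r$recall, rc)
    expect_equal(r$f1, ifelse(p + rc == 0, 0, 2 * p * rc / (p + rc)))
  }
})

test_that("sub-sampling validation holds out balanced test draws", {
  pos <- data.frame(x = 1:60); neg <- data.frame(x = 1:80)
  const_true <- function(train_pos, train_neg, seed) {
    function(examples) rep(1, NROW(examples))
  }
  v <- subsampling_validation(pos, neg, const_true, repetitions = 3,
                              test_pos = 20, test_neg = 20, seed = 4)
  expect_equal(v$mean$precision, 0.5)
  expect_equal(v$mean$recall, 1.0)
  # draws differ across repetitions
  expect_false(identical(v$test_draws[[1]]$pos, v$test_draws[[2]]$pos))
  # deterministic per seed
  v2 <- subsampling_validation(pos, neg, const_true, repetitions = 3,
                               test_pos = 20, test_neg = 20, seed = 4)
  expect_identical(v$test_draws, v2$test_draws)
  expect_error(subsampling_validation(pos, neg, const_true, test_pos = 60,
                                      test_neg = 10),
               "configuration error")
})

test_that("the co-occurrence baseline predicts everything positive", {
  cand <- data.frame(x = 1:40, label = rep(c(TRUE, FALSE), 20))
  pred <- cooccurrence_baseline(cand)
  expect_true(all(pred))
  r <- prf_from_labels(cand$label, pred)
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 1.0)
  expect_equal(r$f1, 2 / 3)
})

test_that("relation table export is threshold-monotone and deduplicated", {
  sent <- data.frame(
    doc_id = c("D1", "D1", "D2", "D2"), sentence_index = c(0L, 1L, 0L, 1L),
    mutation = c("V600E", "V600E", "T790M", "T790M"),
    partner = c("vemu", "vemu", "gefi", "erlo"),
    text = paste("s", 1:4), stringsAsFactors = FALSE)
  p <- c(0.9, 0.7, 0.6, 0.2)
  tab <- export_relation_table(sent, p, "drug", threshold = 0.5)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$probability, sort(tab$probability, decreasing = TRUE))
  # raising the threshold never adds rows
  for (th in seq(0, 1, by = 0.1)) {
    t_lo <- export_relation_table(sent, p, "drug", threshold = th)
    t_hi <- export_relation_table(sent, p, "drug", threshold = th + 0.05)
    expect_lte(nrow(t_hi), nrow(t_lo))
  }
  # dedupe keeps the maximum-probability row per triple
  dd <- export_relation_table(sent, p, "drug", threshold = 0, dedupe = TRUE)
  expect_equal(nrow(dd), 3L)
  expect_equal(dd$probability[dd$mutation == "V600E"], 0.9)
  # empty result keeps the schema
  none <- export_relation_table(sent, p, "drug", threshold = 1.1)
  expect_equal(nrow(none), 0L)
  expect_true(all(c("doc_id", "mutation", "partner", "probability") %in%
                    names(none)))
})

test_that("gold-list comparison partitions into the three buckets", {
  g <- small_gen(seed = 17)
  truth <- g$truth$mutation_drug
  # extracted: first half of the truth; gold: all truth plus a pair that
  # never co-occurs in any sentence
  half <- truth[seq_len(floor(nrow(truth) / 2)), c("mutation", "partner")]
  phantom <- data.frame(mutation = "Z999Z", partner = "drugabXYZ")
  gold <- rbind(truth[, c("mutation", "partner")], phantom)
  cmp <- compare_to_gold_list(half, gold, g$corpus)
  expect_equal(cmp$n_gold, cmp$found + cmp$missed_no_cooccurrence +
                 cmp$missed_other)
  expect_equal(cmp$found, nrow(unique(half)))
  expect_equal(cmp$detail$bucket[cmp$detail$mutation == "Z999Z"],
               "missed_no_cooccurrence")
  # brute-force partition oracle
  cooc_brute <- function(m, p) {
    for (doc in g$corpus) {
      mn <- doc$mentions
      for (s in unique(mn$sentence_index)) {
        sm <- mn[mn$sentence_index == s, ]
        if (m %in% sm$normalized && p %in% sm$normalized) return(TRUE)
      }
    }
    FALSE
  }
  ex_keys <- paste(half$mutation, half$partner)
  for (i in seq_len(nrow(cmp$detail))) {
    m <- cmp$detail$mutation[i]; p <- cmp$detail$partner[i]
    want <- if (paste(m, p) %in% ex_keys) "found"
    else if (!cooc_brute(m, p)) "missed_no_cooccurrence"
    else "missed_other"
    expect_equal(cmp$detail$bucket[i], want, info = paste(m, p))
  }
  # identity: extracted = gold
  all_found <- compare_to_gold_list(gold, gold, g$corpus)
  expect_equal(all_found$found, all_found$n_gold)
})

test_that("feature ablation reuses identical folds across subsets", {
  g <- small_gen(seed = 19)
  idx <- build_index(g$background)
  gold <- g$truth$doc_relations
  f <- featurize_candidates(g$corpus, "gene",
                            gold[gold$partner_kind == "gene", ], idx)
  tab <- feature_ablation(
    f, list(all = DOC_FEATURE_NAMES, baseline = DOC_FEATURE_NAMES[1:4],
            scores = DOC_FEATURE_NAMES[5:8]),
    folds = 5, seed = 23)
  expect_equal(tab$subset, c("all", "baseline", "scores"))
  expect_true(all(tab$f1 >= 0 & tab$f1 <= 1))
  # the full subset equals a plain validation run
  cv <- cross_validate(f, "random_forest", folds = 5, seed = 23)
  expect_equal(tab$f1[tab$subset == "all"], cv$mean$f1)
  # same seed implies identical fold assignment regardless of subset
  cv2 <- cross_validate(f, "random_forest", folds = 5, seed = 23,
                        feature_names = DOC_FEATURE_NAMES[1:4])
  expect_identical(cv$fold_id, cv2$fold_id)
  expect_error(feature_ablation(f, list(bad = "nosuch"), folds = 5),
               "unknown feature")
})
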