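# Metrics, validation protocols, the co-occurrence baseline, relation
# table export and gold-list comparison.

#' Precision / recall / F1 from confusion counts
#'
#' Zero-division (no predicted or no actual positives) yields 0 so that
#' averaging over folds or repetitions is always defined.
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`, `tn`.
#' @export
prf <- function(tp, fp, fn, tn = 0L) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Precision / recall / F1 from label vectors
#' @param truth,pred logical vectors of equal length.
#' @return a [prf()] report.
#' @export
prf_from_labels <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  prf(tp = sum(truth & pred), fp = sum(!truth & pred),
      fn = sum(truth & !pred), tn = sum(!truth & !pred))
}

average_reports <- function(reports) {
  list(precision = mean(vapply(reports, `[[`, numeric(1), "precision")),
       recall = mean(vapply(reports, `[[`, numeric(1), "recall")),
       f1 = mean(vapply(reports, `[[`, numeric(1), "f1")))
}

#' Repeated random sub-sampling validation
#'
#' Per repetition: a fresh balanced test set of `test_pos` positives and
#' `test_neg` negatives is drawn, the remaining data is balanced by
#' down-sampling, a model is trained from scratch by `trainer`, and
#' metrics are computed on the held-out draw. Draws are independent across
#' repetitions. Deterministic per seed.
#'
#' @param positives,negatives data.frames (or lists) of labeled examples;
#'   each must exceed its test draw size.
#' @param trainer function `(train_pos, train_neg, seed)` returning a
#'   predictor: a function mapping a data.frame/list of examples to
#'   probabilities of the true class.
#' @param repetitions number of repetitions.
#' @param test_pos,test_neg test draw sizes.
#' @param seed integer seed.
#' @return list with `mean` (averaged precision/recall/F1) and `per_rep`.
#' @export
subsampling_validation <- function(positives, negatives, trainer,
                                   repetitions = 5L,
                                   test_pos = 100L, test_neg = 100L,
                                   seed = 1L) {
  npos <- NROW(positives); nneg <- NROW(negatives)
  if (npos <= test_pos || nneg <= test_neg) {
    stop("configuration error: need more than ", test_pos, " positives and ",
         test_neg, " negatives")
  }
  take <- function(x, i) if (is.data.frame(x)) x[i, , drop = FALSE] else x[i]
  old <- .Random.seed.save(); set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, repetitions)
  .Random.seed.restore(old)
  reports <- vector("list", repetitions)
  test_draws <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    old <- .Random.seed.save(); set.seed(rep_seeds[r])
    ti_pos <- sample.int(npos, test_pos)
    ti_neg <- sample.int(nneg, test_neg)
    tr_pos <- setdiff(seq_len(npos), ti_pos)
    tr_neg <- setdiff(seq_len(nneg), ti_neg)
    n_bal <- min(length(tr_pos), length(tr_neg))
    tr_pos <- sample(tr_pos, n_bal); tr_neg <- sample(tr_neg, n_bal)
    .Random.seed.restore(old)
    predictor <- trainer(take(positives, tr_pos), take(negatives, tr_neg),
                         rep_seeds[r])
    p_pos <- predictor(take(positives, ti_pos))
    p_neg <- predictor(take(negatives, ti_neg))
    truth <- c(rep(TRUE, test_pos), rep(FALSE, test_neg))
    reports[[r]] <- prf_from_labels(truth, c(p_pos, p_neg) >= 0.5)
    test_draws[[r]] <- list(pos = ti_pos, neg = ti_neg)
  }
  list(mean = average_reports(reports), per_rep = reports,
       test_draws = test_draws)
}

#' Co-occurrence ("no learning") baseline
#'
#' Every candidate is predicted positive, since candidates exist exactly
#' because the pair co-occurs. Recall is 1 by construction; on a balanced
#' candidate set precision is 0.5 and F1 is 2/3.
#'
#' @param candidates a data.frame (or anything with rows) of candidates.
#' @return logical vector of all-TRUE predictions.
#' @export
cooccurrence_baseline <- function(candidates) {
  rep(TRUE, NROW(candidates))
}

#' Export predicted sentence-level relations as a table
#'
#' One row per predicted-positive candidate sentence, sorted by descending
#' probability; optional deduplication keeps the maximum-probability row
#' per unique (doc_id, mutation, partner) triple.
#'
#' @param sentences data.frame with `doc_id`, `sentence_index`, `mutation`,
#'   `partner`, `text`.
#' @param probabilities numeric vector, P(true) per row of `sentences`.
#' @param partner_kind `"gene"` or `"drug"`.
#' @param threshold minimum probability for export.
#' @param dedupe collapse to unique (doc_id, mutation, partner) triples.
#' @return data.frame of exported relations.
#' @export
export_relation_table <- function(sentences, probabilities,
                                  partner_kind = "drug",
                                  threshold = 0.5, dedupe = FALSE) {
  stopifnot(NROW(sentences) == length(probabilities))
  keep <- which(probabilities >= threshold)
  out <- sentences[keep, c("doc_id", "sentence_index", "mutation",
                           "partner", "text"), drop = FALSE]
  out$partner_kind <- rep(partner_kind, nrow(out))
  out$probability <- probabilities[keep]
  out <- out[order(-out$probability, out$doc_id, out$sentence_index), ,
             drop = FALSE]
  if (dedupe && nrow(out) > 0L) {
    key <- paste(out$doc_id, out$mutation, out$partner, sep = "\r")
    out <- out[!duplicated(key), , drop = FALSE]   # rows sorted by prob desc
  }
  rownames(out) <- NULL
  out[, c("doc_id", "sentence_index", "mutation", "partner", "partner_kind",
          "probability", "text")]
}

#' Compare an extracted relation set against a curated gold list
#'
#' Partitions the gold pairs into those found by the extractor, those that
#' never co-occur in any sentence of the corpus (undetectable by a
#' sentence-level extractor), and the remaining misses.
#'
#' @param extracted data.frame with `mutation`, `partner`.
#' @param gold data.frame with `mutation`, `partner`.
#' @param corp the corpus searched.
#' @return list with counts `n_gold`, `found`, `missed_no_cooccurrence`,
#'   `missed_other`, and the partitioned data.frames.
#' @export
compare_to_gold_list <- function(extracted, gold, corp) {
  ex_keys <- unique(relation_key(extracted$mutation, extracted$partner))
  gold <- unique(gold[, c("mutation", "partner")])
  gold_keys <- relation_key(gold$mutation, gold$partner)
  cooc <- new.env(parent = emptyenv())
  for (doc in corp) {
    mn <- doc$mentions
    for (si in unique(mn$sentence_index)) {
      sm <- mn[mn$sentence_index == si, , drop = FALSE]
      muts <- unique(sm$normalized[sm$kind == "mutation"])
      others <- unique(sm$normalized[sm$kind != "mutation"])
      for (m in muts) for (p in others) {
        assign(relation_key(m, p), TRUE, cooc)
      }
    }
  }
  found <- gold_keys %in% ex_keys
  cooccurs <- vapply(gold_keys, function(k)
    isTRUE(get0(k, cooc, ifnotfound = FALSE)), logical(1))
  buckets <- ifelse(found, "found",
                    ifelse(!cooccurs, "missed_no_cooccurrence", "missed_other"))
  list(n_gold = nrow(gold),
       found = sum(buckets == "found"),
       missed_no_cooccurrence = sum(buckets == "missed_no_cooccurrence"),
       missed_other = sum(buckets == "missed_other"),
       detail = cbind(gold, bucket = buckets))
}

#' Feature-ablation harness for the document-level classifier
#'
#' Runs the same balanced cross-validation once per named feature subset
#' under identical seeds, so only the feature set differs between rows.
#'
#' @param features as for [cross_validate()].
#' @param subsets named list of character vectors over [DOC_FEATURE_NAMES].
#' @param model_kind,folds,seed passed to [cross_validate()].
#' @return data.frame with one row per subset: precision, recall, f1.
#' @export
feature_ablation <- function(features, subsets,
                             model_kind = "random_forest",
                             folds = 10L, seed = 1L) {
  bad <- setdiff(unique(unlist(subsets)), DOC_FEATURE_NAMES)
  if (length(bad) > 0L) {
    stop("configuration error: unknown feature name(s): ",
         paste(bad, collapse = ", "))
  }
  rows <- lapply(names(subsets), function(nm) {
    cv <- cross_validate(features, model_kind, folds = folds, seed = seed,
                         feature_names = subsets[[nm]])
    data.frame(subset = nm, precision = cv$mean$precision,
               recall = cv$mean$recall, f1 = cv$mean$f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
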