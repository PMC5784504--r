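test_that("candidate generation enumerates exactly m x n labeled pairs", {
  set.seed(21)
  for (i in 1:30) {
    doc <- random_document(sprintf("C%d", i), n_sent = sample(2:5, 1),
                           n_mut = sample(1:3, 1), n_gene = sample(1:3, 1),
                           n_drug = sample(0:3, 1))
    for (pk in c("gene", "drug")) {
      mn <- doc$mentions
      m <- length(unique(mn$normalized[mn$kind == "mutation"]))
      n <- length(unique(mn$normalized[mn$kind == pk]))
      cand <- generate_doc_candidates(doc, pk)
      expect_equal(nrow(cand), m * n)
      expect_false(is.unsorted(paste(cand$mutation, cand$partner)))
    }
  }
  # gold labeling: exactly the gold pair is positive
  doc <- random_document("G1", n_mut = 2, n_drug = 3)
  cand <- generate_doc_candidates(doc, "drug")
  if (nrow(cand) > 0) {
    gold <- data.frame(mutation = cand$mutation[1], partner = cand$partner[1],
                       doc_id = "G1")
    lab <- generate_doc_candidates(doc, "drug", gold)
    expect_equal(sum(lab$label), 1L)
    expect_true(lab$label[1])
  }
})

test_that("document features match hand-evaluated fixtures", {
  # one mutation and partner in the same sentence, nothing else
  d1 <- mutrelex:::assemble_document("F1", list(
    mutrelex:::render_template(
      c("The", "{M}", "responds", "to", "{D}"),
      list("{M}" = list(surface = "V600E", kind = "mutation", normalized = "V600E"),
           "{D}" = list(surface = "vemu", kind = "drug", normalized = "vemu")))))
  f1 <- compute_doc_features(d1, data.frame(mutation = "V600E", partner = "vemu",
                                            partner_kind = "drug"))
  expect_equal(unname(f1[c("ntds", "tdfs", "odfs", "dmcs")]), c(1, 1, 0, 1))

  # partner never shares a sentence; a rival drug sits next to the mutation
  d2 <- mutrelex:::assemble_document("F2", list(
    mutrelex:::render_template(
      c("Here", "{M}", "with", "{R}", "appears"),
      list("{M}" = list(surface = "V600E", kind = "mutation", normalized = "V600E"),
           "{R}" = list(surface = "rival", kind = "drug", normalized = "rival"))),
    mutrelex:::render_template(
      c("Elsewhere", "{D}", "is", "mentioned"),
      list("{D}" = list(surface = "vemu", kind = "drug", normalized = "vemu")))))
  f2 <- compute_doc_features(d2, data.frame(mutation = "V600E", partner = "vemu",
                                            partner_kind = "drug"))
  expect_equal(unname(f2["ntds"]), 0)
  expect_equal(unname(f2["dmcs"]), 0)
  expect_equal(unname(f2["tdfs"]), 1)
  expect_equal(unname(f2["odfs"]), 1)

  # frequency counting: partner 3x, rival 5x
  reps <- function(tok, n) lapply(seq_len(n), function(i)
    mutrelex:::render_template(
      c("Sentence", "{M}", "and", "{X}"),
      list("{M}" = list(surface = "K100N", kind = "mutation", normalized = "K100N"),
           "{X}" = list(surface = tok, kind = "drug", normalized = tok))))
  d3 <- mutrelex:::assemble_document("F3", c(reps("vemu", 3), reps("rival", 5)))
  f3 <- compute_doc_features(d3, data.frame(mutation = "K100N", partner = "vemu",
                                            partner_kind = "drug"))
  expect_equal(unname(f3["tdfs"]), 3)
  expect_equal(unname(f3["odfs"]), 5)

  # candidate not mentioned in the document is a contract violation
  expect_error(
    compute_doc_features(d1, data.frame(mutation = "V600E", partner = "absent",
                                        partner_kind = "drug")),
    "contract violation")
})

test_that("document features agree with a brute-force re-implementation", {
  set.seed(31)
  n_checked <- 0L
  for (i in 1:200) {
    doc <- random_document(sprintf("B%d", i), n_sent = sample(2:5, 1),
                           n_mut = sample(1:3, 1), n_gene = sample(1:3, 1),
                           n_drug = sample(1:3, 1))
    for (pk in c("gene", "drug")) {
      cand <- generate_doc_candidates(doc, pk)
      if (nrow(cand) == 0) next
      j <- sample(nrow(cand), 1)
      got <- compute_doc_features(doc, cand[j, ])
      want <- brute_doc_features(doc, cand$mutation[j], cand$partner[j], pk)
      expect_equal(unname(got[c("ntds", "tdfs", "odfs", "dmcs")]),
                   unname(as.numeric(want)),
                   info = sprintf("doc B%d %s %s-%s", i, pk,
                                  cand$mutation[j], cand$partner[j]))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("distant supervision routes sentences by table and residue filter", {
  g <- small_gen(seed = 13)
  gold <- g$truth$doc_relations
  ds <- build_pair_sentence_dataset(
    g$corpus, gold[gold$partner_kind == "gene", ],
    proteins = g$truth$proteins, partner_kind = "gene")
  # positives equal the distinct sentences expressing planted gene pairs
  sr <- g$truth$sent_relations
  planted <- unique(sr[sr$partner_kind == "gene", c("doc_id", "sentence_index")])
  expect_equal(nrow(ds$positives), nrow(planted))
  expect_setequal(paste(ds$positives$doc_id, ds$positives$sentence_index),
                  paste(planted$doc_id, planted$sentence_index))
  # disjoint sentence sets, one row per sentence
  key <- function(d) paste(d$doc_id, d$sentence_index)
  expect_length(intersect(key(ds$positives), key(ds$negatives)), 0L)
  expect_false(any(duplicated(key(ds$positives))))
  # every positive passes the residue filter; negatives' pairs fail it
  for (i in seq_len(nrow(ds$positives))) {
    expect_true(seq_filter(g$truth$proteins[[ds$positives$partner[i]]],
                           ds$positives$mutation[i]))
  }
  for (i in seq_len(nrow(ds$negatives))) {
    expect_false(seq_filter(g$truth$proteins[[ds$negatives$partner[i]]],
                            ds$negatives$mutation[i]))
  }
})

test_that("known relations are removed from drug negatives", {
  g <- small_gen(seed = 14)
  gold <- g$truth$doc_relations
  drug_gold <- gold[gold$partner_kind == "drug", ]
  ds <- build_pair_sentence_dataset(g$corpus, drug_gold, partner_kind = "drug")
  # no negative pair appears anywhere in the relation table
  truth_keys <- paste(g$truth$mutation_drug$mutation, g$truth$mutation_drug$partner)
  expect_false(any(paste(ds$negatives$mutation, ds$negatives$partner) %in%
                     truth_keys))
  # passing extra known relations removes matching negatives
  if (nrow(ds$negatives) > 0) {
    known <- ds$negatives[1, c("mutation", "partner")]
    ds2 <- build_pair_sentence_dataset(g$corpus, drug_gold,
                                       partner_kind = "drug",
                                       known_relations = known)
    expect_false(any(ds2$negatives$mutation == known$mutation &
                       ds2$negatives$partner == known$partner))
  }
})

test_that("gene partners without protein records are skipped with a warning", {
  g <- small_gen(seed = 15)
  gold <- g$truth$doc_relations
  prot <- g$truth$proteins
  prot <- prot[-(1:2)]
  expect_warning(
    build_pair_sentence_dataset(g$corpus, gold[gold$partner_kind == "gene", ],
                                proteins = prot, partner_kind = "gene"),
    "without protein")
})
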