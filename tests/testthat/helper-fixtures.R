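# Shared fixtures and independent brute-force oracles.

# a hand-assembled document: "BRAF study V600E was found."
tiny_doc <- function() {
  text <- "BRAF study. V600E was found in BRAF."
  mn <- entity_mentions(
    doc_id = "D1",
    start = c(0L, 12L, 31L), end = c(4L, 17L, 35L),
    surface = c("BRAF", "V600E", "BRAF"),
    kind = c("gene", "mutation", "gene")
  )
  annotated_document("D1", text, mn)
}

# random annotated document built directly from primitives (not via the
# package generator) for randomized-oracle tests
random_document <- function(doc_id, n_sent = 4, n_mut = 2, n_gene = 2,
                            n_drug = 2) {
  muts <- sprintf("M%dK", sample(100:999, n_mut))
  genes <- sprintf("GN%02d", sample(1:80, n_gene))
  drugs <- sprintf("dr%02dx", sample(1:80, n_drug))
  sents <- list()
  for (s in seq_len(n_sent)) {
    ents <- list()
    pool <- c(muts, genes, drugs)
    kinds <- c(rep("mutation", n_mut), rep("gene", n_gene), rep("drug", n_drug))
    pick <- sample(length(pool), sample(min(4, length(pool)), 1))
    toks <- c("Word", "filler")
    fill <- list()
    for (j in seq_along(pick)) {
      mk <- paste0("{E", j, "}")
      toks <- append(toks, mk, after = sample(length(toks), 1))
      fill[[mk]] <- list(surface = pool[pick[j]], kind = kinds[pick[j]],
                         normalized = pool[pick[j]])
    }
    sents[[s]] <- mutrelex:::render_template(toks, fill)
  }
  mutrelex:::assemble_document(doc_id, sents)
}

# brute-force re-implementation of the document features by direct scans
brute_doc_features <- function(doc, mutation, partner, partner_kind) {
  mn <- doc$mentions
  mut <- mn[mn$kind == "mutation" & mn$normalized == mutation, ]
  par <- mn[mn$kind == partner_kind & mn$normalized == partner, ]
  same <- mn[mn$kind == partner_kind, ]
  ntds <- 0L
  for (s in unique(doc$sentences$sentence_index)) {
    if (any(mut$sentence_index == s) && any(par$sentence_index == s)) {
      ntds <- ntds + 1L
    }
  }
  tdfs <- nrow(par)
  odfs <- 0L
  for (e in unique(same$normalized)) {
    if (e != partner) odfs <- max(odfs, sum(same$normalized == e))
  }
  dmcs <- 0L
  for (i in seq_len(nrow(mut))) {
    best_d <- Inf; best_j <- NA
    for (j in seq_len(nrow(same))) {
      d <- abs((same$start[j] + same$end[j]) / 2 - (mut$start[i] + mut$end[i]) / 2)
      if (d < best_d || (d == best_d && same$start[j] < same$start[best_j])) {
        best_d <- d; best_j <- j
      }
    }
    if (!is.na(best_j) && same$normalized[best_j] == partner &&
        same$sentence_index[best_j] == mut$sentence_index[i]) {
      dmcs <- 1L
    }
  }
  c(ntds = ntds, tdfs = tdfs, odfs = odfs, dmcs = dmcs)
}

# brute-force retrieval: scan every document's term set
brute_retrieve <- function(corp, required, optional = character(0)) {
  hits <- character(0)
  for (doc in corp) {
    terms <- c(mutrelex:::tokenize_words(doc$text),
               tolower(doc$mentions$normalized))
    if (all(tolower(required) %in% terms) &&
        (length(optional) == 0 || any(tolower(optional) %in% terms))) {
      hits <- c(hits, doc$doc_id)
    }
  }
  sort(hits)
}

# brute-force entity scoring from first principles
brute_score <- function(corp, docs, target_kind, entity) {
  N <- length(corp)
  df <- 0L; total <- 0L
  for (doc in corp) {
    mn <- doc$mentions
    if (entity %in% mn$normalized) df <- df + 1L
    if (doc$doc_id %in% docs) {
      total <- total + sum(mn$normalized == entity & mn$kind == target_kind)
    }
  }
  if (total == 0L) 0 else total * log(1 + N / df)
}

# tiny default generator scaled for unit tests
small_gen <- function(seed = 1, ...) {
  generate_corpus(generator_config(seed = seed, n_documents = 30,
                                   n_background_documents = 60,
                                   n_mutations = 20, ...))
}
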