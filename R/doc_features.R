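# Document-level candidate generation, the four distance/frequency
# features, and distant-supervision sentence dataset construction.

#' Generate all document-level candidate pairs
#'
#' Every combination of a unique mutation and a unique partner-kind entity
#' in the document is a candidate (m x n). A candidate is labeled true when
#' the pair appears in the gold table for this document (the any-sentence
#' rule: co-occurrence in the same sentence is not required).
#'
#' @param document an `mrx_document`.
#' @param partner_kind `"gene"` or `"drug"`.
#' @param gold data.frame with columns `mutation`, `partner`, `doc_id`.
#' @return data.frame of candidates `(doc_id, mutation, partner,
#'   partner_kind, label)` in lexicographic (mutation, partner) order.
#' @export
generate_doc_candidates <- function(document, partner_kind, gold = NULL) {
  mn <- document$mentions
  muts <- sort(unique(mn$normalized[mn$kind == "mutation"]))
  partners <- sort(unique(mn$normalized[mn$kind == partner_kind]))
  if (length(muts) == 0L || length(partners) == 0L) {
    return(data.frame(doc_id = character(0), mutation = character(0),
                      partner = character(0), partner_kind = character(0),
                      label = logical(0)))
  }
  cand <- expand.grid(partner = partners, mutation = muts,
                      stringsAsFactors = FALSE)[, c("mutation", "partner")]
  cand <- cand[order(cand$mutation, cand$partner), ]
  cand$doc_id <- document$doc_id
  cand$partner_kind <- partner_kind
  cand$label <- FALSE
  if (!is.null(gold) && nrow(gold) > 0L) {
    g <- gold[gold$doc_id == document$doc_id, , drop = FALSE]
    cand$label <- paste(cand$mutation, cand$partner) %in%
      paste(g$mutation, g$partner)
  }
  rownames(cand) <- NULL
  cand[, c("doc_id", "mutation", "partner", "partner_kind", "label")]
}

#' Canonical order of the document-level feature columns
#'
#' Four distance/frequency features followed by the four search scores.
#' @export
DOC_FEATURE_NAMES <- c("ntds", "tdfs", "odfs", "dmcs",
                       "bssm", "bssa", "bsso", "bssao")

#' Compute the distance/frequency and search-score features of a candidate
#'
#' \itemize{
#'   \item `ntds` — number of sentences where the mutation and the partner
#'     co-occur.
#'   \item `tdfs` — total mention count of the partner in the document.
#'   \item `odfs` — mention count of the most frequent same-kind entity
#'     other than the partner (0 when none).
#'   \item `dmcs` — 1 iff some mutation mention's nearest partner-kind
#'     mention (span-midpoint distance, ties broken leftward) is the
#'     candidate partner and lies in the same sentence.
#' }
#' The four search scores use all non-target-kind document entities as
#' query context against the background index.
#'
#' @param document an `mrx_document` containing the candidate pair.
#' @param candidate one row of [generate_doc_candidates()] output.
#' @param index an `mrx_index` over the background corpus, or `NULL` to
#'   return zero search scores.
#' @return named numeric vector over [DOC_FEATURE_NAMES].
#' @export
compute_doc_features <- function(document, candidate, index = NULL) {
  mn <- document$mentions
  mut_rows <- mn[mn$kind == "mutation" & mn$normalized == candidate$mutation, , drop = FALSE]
  kind_rows <- mn[mn$kind == candidate$partner_kind, , drop = FALSE]
  par_rows <- kind_rows[kind_rows$normalized == candidate$partner, , drop = FALSE]
  if (nrow(mut_rows) == 0L || nrow(par_rows) == 0L) {
    stop("contract violation: candidate pair not mentioned in document '",
         document$doc_id, "'")
  }
  ntds <- length(intersect(unique(mut_rows$sentence_index),
                           unique(par_rows$sentence_index)))
  tdfs <- nrow(par_rows)
  other <- kind_rows[kind_rows$normalized != candidate$partner, , drop = FALSE]
  odfs <- if (nrow(other) == 0L) 0L else max(table(other$normalized))
  dmcs <- 0L
  if (nrow(kind_rows) > 0L) {
    kmid <- (kind_rows$start + kind_rows$end) / 2
    for (i in seq_len(nrow(mut_rows))) {
      mmid <- (mut_rows$start[i] + mut_rows$end[i]) / 2
      d <- abs(kmid - mmid)
      # nearest partner-kind mention; ties broken leftward (smaller start)
      best <- order(d, kind_rows$start)[1]
      if (kind_rows$normalized[best] == candidate$partner &&
          kind_rows$sentence_index[best] == mut_rows$sentence_index[i]) {
        dmcs <- 1L
        break
      }
    }
  }
  scores <- if (is.null(index)) {
    c(bssm = 0, bssa = 0, bsso = 0, bssao = 0)
  } else {
    search_score_features(index, candidate$mutation, mn,
                          candidate$partner_kind, candidate$partner)
  }
  c(ntds = as.numeric(ntds), tdfs = as.numeric(tdfs),
    odfs = as.numeric(odfs), dmcs = as.numeric(dmcs), scores)
}

#' Featurize all document-level candidates of a corpus
#'
#' @param corp an `mrx_corpus`.
#' @param partner_kind `"gene"` or `"drug"`.
#' @param gold gold relation table (`mutation`, `partner`, `doc_id`).
#' @param index background `mrx_index` (or `NULL` for zero search scores).
#' @return data.frame: candidate columns, the eight feature columns
#'   ([DOC_FEATURE_NAMES]), and `label`.
#' @export
featurize_candidates <- function(corp, partner_kind, gold, index = NULL) {
  out <- list()
  for (doc in corp) {
    cand <- generate_doc_candidates(doc, partner_kind, gold)
    if (nrow(cand) == 0L) next
    feats <- t(vapply(seq_len(nrow(cand)), function(i)
      compute_doc_features(doc, cand[i, ], index),
      numeric(length(DOC_FEATURE_NAMES))))
    out[[length(out) + 1L]] <- cbind(cand, as.data.frame(feats))
  }
  if (length(out) == 0L) stop("no candidates in corpus")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

relation_key <- function(mutation, partner) paste(mutation, partner, sep = "\r")

#' Build a sentence-level dataset by distant supervision
#'
#' Positive sentences contain a co-occurring (mutation, partner) pair that
#' is recorded in the relation table for that document and — for gene
#' partners — passes the wild-type residue check against the partner's
#' protein. Negative sentences contain a co-occurring pair absent from both
#' the relation table and the known-relations set, and — for gene partners
#' — failing the residue check. Mutations that do not parse to the
#' amino-acid scheme are excluded from gene-pair datasets (the residue
#' check cannot be applied). Each sentence contributes at most once, and a
#' sentence holding any positive pair is never also a negative.
#'
#' @param corp an `mrx_corpus`.
#' @param relation_table data.frame (`mutation`, `partner`, `doc_id`).
#' @param proteins named character vector gene -> sequence (gene task).
#' @param partner_kind `"gene"` or `"drug"`.
#' @param known_relations optional data.frame (`mutation`, `partner`) of
#'   additional known relations removed from the negatives.
#' @return list of two data.frames, `positives` and `negatives`, with
#'   columns `doc_id`, `sentence_index`, `mutation`, `partner`, `text`.
#' @export
build_pair_sentence_dataset <- function(corp, relation_table,
                                        proteins = NULL,
                                        partner_kind = c("gene", "drug"),
                                        known_relations = NULL) {
  partner_kind <- match.arg(partner_kind)
  tab_doc_keys <- paste(relation_table$mutation, relation_table$partner,
                        relation_table$doc_id, sep = "\r")
  tab_pair_keys <- relation_key(relation_table$mutation, relation_table$partner)
  known_keys <- if (is.null(known_relations)) character(0) else
    relation_key(known_relations$mutation, known_relations$partner)
  missing_protein <- character(0)
  pos <- list(); neg <- list()
  for (doc in corp) {
    mn <- doc$mentions
    for (si in unique(mn$sentence_index)) {
      sm <- mn[mn$sentence_index == si, , drop = FALSE]
      muts <- sort(unique(sm$normalized[sm$kind == "mutation"]))
      partners <- sort(unique(sm$normalized[sm$kind == partner_kind]))
      if (length(muts) == 0L || length(partners) == 0L) next
      span <- doc$sentences[doc$sentences$sentence_index == si, ]
      stext <- text_slice(doc$text, span$start, span$end)
      pos_pair <- NULL; neg_pair <- NULL
      for (m in muts) {
        parsed <- parse_mutation(m)
        if (partner_kind == "gene" && is.null(parsed)) next
        for (p in partners) {
          sf <- NA
          if (partner_kind == "gene") {
            if (!p %in% names(proteins)) {
              missing_protein <- union(missing_protein, p)
              next
            }
            sf <- seq_filter(proteins[[p]], parsed)
          }
          in_table <- paste(m, p, doc$doc_id, sep = "\r") %in% tab_doc_keys
          known <- relation_key(m, p) %in% c(tab_pair_keys, known_keys)
          if (in_table && (partner_kind != "gene" || isTRUE(sf))) {
            if (is.null(pos_pair)) pos_pair <- c(m, p)
          } else if (!known && (partner_kind != "gene" || identical(sf, FALSE))) {
            if (is.null(neg_pair)) neg_pair <- c(m, p)
          }
        }
      }
      if (!is.null(pos_pair)) {
        pos[[length(pos) + 1L]] <- data.frame(
          doc_id = doc$doc_id, sentence_index = si,
          mutation = pos_pair[1], partner = pos_pair[2], text = stext,
          stringsAsFactors = FALSE)
      } else if (!is.null(neg_pair)) {
        neg[[length(neg) + 1L]] <- data.frame(
          doc_id = doc$doc_id, sentence_index = si,
          mutation = neg_pair[1], partner = neg_pair[2], text = stext,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(missing_protein) > 0L) {
    warning("skipped gene partner(s) without protein records: ",
            paste(missing_protein, collapse = ", "))
  }
  empty <- data.frame(doc_id = character(0), sentence_index = integer(0),
                      mutation = character(0), partner = character(0),
                      text = character(0), stringsAsFactors = FALSE)
  list(positives = if (length(pos)) do.call(rbind, pos) else empty,
       negatives = if (length(neg)) do.call(rbind, neg) else empty)
}
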