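# Local co-occurrence search index and the four search-score features.
#
# The index answers AND/OR entity queries over a background corpus and
# scores the entities found in the retrieved documents with a transparent
# tf-idf-style formula: score(e) = sum_d count(d, e) * log(1 + N / df(e)).
# Only the relative magnitudes of these scores matter downstream.

tokenize_words <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9_.'>-]+")[[1]]
  toks[nzchar(toks)]
}

#' Build a co-occurrence search index from an annotated corpus
#'
#' Posting terms are the lower-cased words of each document's text plus the
#' lower-cased normalized form of every mention. Entity occurrence counts
#' and document frequencies are tracked per kind for scoring. Deterministic
#' for a fixed corpus.
#'
#' @param corp an `mrx_corpus` whose documents carry mentions.
#' @return An object of class `mrx_index` with fields `N`, `doc_ids`,
#'   `postings`, `entity_counts`, `entity_kind`, `df`.
#' @export
build_index <- function(corp) {
  stopifnot(inherits(corp, "mrx_corpus"))
  postings <- new.env(parent = emptyenv())
  entity_counts <- list()
  df_env <- new.env(parent = emptyenv())
  kind_env <- new.env(parent = emptyenv())
  for (doc in corp) {
    id <- doc$doc_id
    terms <- unique(c(tokenize_words(doc$text),
                      tolower(doc$mentions$normalized)))
    for (t in terms) assign(t, c(get0(t, postings, ifnotfound = character(0)), id), postings)
    counts <- list()
    mn <- doc$mentions
    if (nrow(mn) > 0L) {
      for (k in unique(mn$kind)) {
        tab <- table(mn$normalized[mn$kind == k])
        counts[[k]] <- stats::setNames(as.integer(tab), names(tab))
      }
      for (e in unique(mn$normalized)) {
        assign(e, get0(e, df_env, ifnotfound = 0L) + 1L, df_env)
        assign(e, mn$kind[match(e, mn$normalized)], kind_env)
      }
    }
    entity_counts[[id]] <- counts
  }
  postings <- as.list(postings)
  if (length(postings) > 0L) postings <- postings[order(names(postings))]
  kinds <- as.list(kind_env)
  if (length(kinds) > 0L) kinds <- kinds[order(names(kinds))]
  df <- unlist(as.list(df_env), use.names = TRUE)
  if (is.null(df)) df <- stats::setNames(integer(0), character(0))
  df <- df[order(names(df))]
  structure(
    list(N = length(corp),
         doc_ids = names(corp),
         postings = postings,
         entity_counts = entity_counts,
         entity_kind = kinds,
         df = df),
    class = "mrx_index"
  )
}

#' @export
print.mrx_index <- function(x, ...) {
  cat(sprintf("mrx_index: %d documents, %d terms, %d entities\n",
              x$N, length(x$postings), length(x$df)))
  invisible(x)
}

#' Retrieve documents matching an AND query with an optional OR group
#'
#' Returns the documents containing every required term and, when the
#' optional group is non-empty, at least one optional term. Terms are
#' matched case-insensitively against posting keys.
#'
#' @param index an `mrx_index`.
#' @param required character vector of required terms (at least one).
#' @param optional character vector forming the OR group (may be empty).
#' @return sorted character vector of doc_ids.
#' @export
retrieve <- function(index, required, optional = character(0)) {
  stopifnot(inherits(index, "mrx_index"), length(required) >= 1L)
  get_post <- function(t) {
    p <- index$postings[[tolower(t)]]
    if (is.null(p)) character(0) else p
  }
  docs <- get_post(required[1])
  for (t in required[-1]) docs <- intersect(docs, get_post(t))
  if (length(optional) > 0L) {
    opt <- unique(unlist(lapply(optional, get_post)))
    docs <- intersect(docs, opt)
  }
  sort(docs)
}

#' Score entities of a kind across a retrieved document set
#'
#' `score(e) = sum over docs of count(doc, e) * log(1 + N / df(e))`;
#' entities with zero total count are omitted.
#'
#' @param index an `mrx_index`.
#' @param docs character vector of doc_ids (subset of the index).
#' @param target_kind entity kind to score.
#' @return named numeric vector, entity -> score (possibly empty).
#' @export
score_entities <- function(index, docs, target_kind) {
  stopifnot(inherits(index, "mrx_index"))
  totals <- numeric(0)
  for (d in docs) {
    cnt <- index$entity_counts[[d]][[target_kind]]
    if (is.null(cnt)) next
    for (e in names(cnt)) {
      totals[e] <- (if (is.na(totals[e])) 0 else totals[e]) + cnt[[e]]
    }
  }
  if (length(totals) == 0L) return(stats::setNames(numeric(0), character(0)))
  idf <- log(1 + index$N / index$df[names(totals)])
  sc <- totals * idf
  sc[order(-sc, names(sc))]   # deterministic tie-break on entity name
}

#' Compute the four search-score features for a candidate pair
#'
#' Context entities of the target kind are excluded (same-kind entities add
#' noise rather than context), the remainder deduplicated to normalized
#' forms C. The four scores of the candidate are then read from the entity
#' ranking of four query strategies:
#' \itemize{
#'   \item `bssm` — mutation-only query.
#'   \item `bssa` — conjunctive query: mutation AND all of C.
#'   \item `bsso` — mutation required, C as an OR group.
#'   \item `bssao` — mean over `c_i` in C of the pairwise conjunctive query
#'     (mutation AND `c_i`); 0 when C is empty.
#' }
#'
#' @param index an `mrx_index`.
#' @param mutation canonical mutation string.
#' @param context a mention table (or data.frame with `kind`/`normalized`)
#'   drawn from the candidate's sentence or document.
#' @param target_kind kind of the candidate entity (`"gene"` or `"drug"`).
#' @param candidate normalized form of the candidate entity.
#' @return named numeric vector `c(bssm, bssa, bsso, bssao)`.
#' @export
search_score_features <- function(index, mutation, context, target_kind,
                                  candidate) {
  ctx <- context[context$kind != target_kind, , drop = FALSE]
  C <- setdiff(unique(ctx$normalized), mutation)
  cand_score <- function(required, optional = character(0)) {
    docs <- retrieve(index, required, optional)
    sc <- score_entities(index, docs, target_kind)
    if (candidate %in% names(sc)) unname(sc[candidate]) else 0
  }
  bssm <- cand_score(mutation)
  if (length(C) == 0L) {
    bssa <- bssm; bsso <- bssm; bssao <- 0
  } else {
    bssa <- cand_score(c(mutation, C))
    bsso <- cand_score(mutation, optional = C)
    bssao <- mean(vapply(C, function(ci) cand_score(c(mutation, ci)), numeric(1)))
  }
  c(bssm = bssm, bssa = bssa, bsso = bsso, bssao = bssao)
}
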