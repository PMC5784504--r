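# Data model for entity-annotated documents and corpus I/O.
#
# Offsets are 0-based, half-open [start, end) throughout; a document's text
# is sliced with text_slice(). PubTator abstract offsets count from the
# title, so title and abstract are joined by a single space.

#' Closed set of entity kinds
#'
#' Every mention in a corpus carries one of these kinds.
#' @export
MENTION_KINDS <- c("mutation", "gene", "drug", "disease", "cell_line")

#' Slice document text by a 0-based half-open span
#'
#' @param text character scalar.
#' @param start,end 0-based half-open character offsets.
#' @return The substring `text[start, end)`.
#' @export
text_slice <- function(text, start, end) {
  substring(text, start + 1L, end)
}

empty_mentions <- function() {
  data.frame(
    doc_id = character(), sentence_index = integer(),
    start = integer(), end = integer(),
    surface = character(), kind = character(), normalized = character(),
    stringsAsFactors = FALSE
  )
}

#' Construct an entity mention table
#'
#' @param doc_id document identifier (recycled).
#' @param start,end 0-based half-open offsets within the document text.
#' @param surface mention surface strings.
#' @param kind one of [MENTION_KINDS] per mention.
#' @param normalized canonical form; defaults to the surface.
#' @param sentence_index containing sentence, filled in by [annotated_document()]
#'   when `NA`.
#' @return data.frame with one row per mention.
#' @export
entity_mentions <- function(doc_id, start, end, surface, kind,
                            normalized = surface,
                            sentence_index = NA_integer_) {
  n <- length(start)
  if (n == 0L) return(empty_mentions())
  stopifnot(length(end) == n, length(surface) == n, length(kind) == n)
  if (!all(kind %in% MENTION_KINDS)) {
    stop("unknown mention kind(s): ",
         paste(setdiff(unique(kind), MENTION_KINDS), collapse = ", "))
  }
  data.frame(
    doc_id = rep_len(as.character(doc_id), n),
    sentence_index = rep_len(as.integer(sentence_index), n),
    start = as.integer(start), end = as.integer(end),
    surface = as.character(surface), kind = as.character(kind),
    normalized = rep_len(as.character(normalized), n),
    stringsAsFactors = FALSE
  )
}

#' Split text into sentence spans
#'
#' Rule-based, deterministic splitter: a boundary is a run of `.`, `!` or `?`
#' followed by whitespace and an uppercase letter or digit. Boundaries are
#' suppressed inside supplied mention spans (e.g. the dot of `p.V600E`) and
#' after common abbreviations. When no boundary is found the whole text is a
#' single span.
#'
#' @param text document text (non-empty).
#' @param mentions optional mention table; periods inside mention spans never
#'   split.
#' @return data.frame with columns `sentence_index`, `start`, `end`
#'   (0-based half-open spans, disjoint and ordered).
#' @export
split_sentences <- function(text, mentions = NULL) {
  stopifnot(is.character(text), length(text) == 1L, nchar(text) > 0L)
  m <- gregexpr("[.!?]+(?=[ \t\r\n]+[A-Z0-9])", text, perl = TRUE)[[1]]
  abbrev <- c("e.g", "i.e", "et al", "vs", "Fig", "Figs", "Dr", "cf",
              "approx", "resp", "ca", "No")
  breaks <- integer(0)
  if (m[1] != -1L) {
    for (j in seq_along(m)) {
      p0 <- as.integer(m[j]) - 1L                      # 0-based punct start
      plen <- attr(m, "match.length")[j]
      # inside a mention span?
      if (!is.null(mentions) && nrow(mentions) > 0L &&
          any(mentions$start <= p0 & p0 < mentions$end)) next
      # abbreviation immediately before the period?
      head_txt <- substr(text, max(1L, p0 - 6L), p0)
      if (any(vapply(abbrev, function(a) endsWith(head_txt, a), logical(1)))) next
      breaks <- c(breaks, p0 + plen)                   # 0-based end of sentence
    }
  }
  nall <- nchar(text)
  bounds <- unique(c(breaks[breaks < nall], nall))
  starts <- integer(0); ends <- integer(0); prev <- 0L
  for (b in bounds) {
    seg <- text_slice(text, prev, b)
    lead <- attr(regexpr("^[ \t\r\n]*", seg), "match.length")
    trail <- attr(regexpr("[ \t\r\n]*$", seg), "match.length")
    s <- prev + lead; e <- b - trail
    if (e > s) { starts <- c(starts, s); ends <- c(ends, e) }
    prev <- b
  }
  if (length(starts) == 0L) { starts <- 0L; ends <- nall }
  data.frame(sentence_index = seq_along(starts) - 1L,
             start = starts, end = ends)
}

#' Construct an annotated document
#'
#' Splits sentences when `sentences` is not supplied (protecting periods
#' inside mention spans), assigns each mention to its containing sentence,
#' and validates all mention invariants.
#'
#' @param doc_id document identifier.
#' @param text document text.
#' @param mentions mention table from [entity_mentions()].
#' @param sentences optional precomputed sentence spans.
#' @param strict if `TRUE` (default) offset/surface mismatches are errors;
#'   otherwise offending mentions are dropped with a warning.
#' @return An object of class `mrx_document`.
#' @export
annotated_document <- function(doc_id, text, mentions = empty_mentions(),
                               sentences = NULL, strict = TRUE) {
  if (is.null(sentences)) sentences <- split_sentences(text, mentions)
  if (nrow(mentions) > 0L) {
    mentions$doc_id <- as.character(doc_id)
    ok <- mentions$start < mentions$end &
      mentions$end <= nchar(text) &
      text_slice(text, mentions$start, mentions$end) == mentions$surface
    if (!all(ok)) {
      bad <- which(!ok)[1]
      msg <- sprintf(
        "document '%s': mention %d surface '%s' does not match text slice [%d,%d)",
        doc_id, bad, mentions$surface[bad], mentions$start[bad], mentions$end[bad])
      if (strict) stop(msg) else { warning(msg, "; dropped"); mentions <- mentions[ok, , drop = FALSE] }
    }
    sidx <- vapply(seq_len(nrow(mentions)), function(i) {
      hit <- which(sentences$start <= mentions$start[i] &
                     mentions$end[i] <= sentences$end)
      if (length(hit) != 1L) NA_integer_ else sentences$sentence_index[hit]
    }, integer(1))
    if (anyNA(sidx)) {
      msg <- sprintf("document '%s': mention(s) not contained in a single sentence", doc_id)
      if (strict) stop(msg) else { warning(msg, "; dropped"); keep <- !is.na(sidx); mentions <- mentions[keep, , drop = FALSE]; sidx <- sidx[keep] }
    }
    mentions$sentence_index <- sidx
    rownames(mentions) <- NULL
  }
  structure(
    list(doc_id = as.character(doc_id), text = text,
         sentences = sentences, mentions = mentions),
    class = "mrx_document"
  )
}

#' Construct a corpus from documents
#' @param documents list of `mrx_document` objects.
#' @return An object of class `mrx_corpus` (a list of documents, named by
#'   doc_id).
#' @export
corpus <- function(documents = list()) {
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate doc_id in corpus")
  names(documents) <- ids
  structure(documents, class = "mrx_corpus")
}

#' @export
print.mrx_corpus <- function(x, ...) {
  nm <- sum(vapply(x, function(d) nrow(d$mentions), integer(1)))
  cat(sprintf("mrx_corpus: %d documents, %d mentions\n", length(x), nm))
  invisible(x)
}

#' Validate all corpus invariants
#'
#' Checks mention offsets against the text, kind membership, sentence span
#' ordering/disjointness, and that every mention lies in exactly one
#' sentence whose index it carries. Errors on the first violation.
#'
#' @param corp an `mrx_corpus`.
#' @return `TRUE` invisibly.
#' @export
validate_corpus <- function(corp) {
  stopifnot(inherits(corp, "mrx_corpus"))
  for (doc in corp) {
    s <- doc$sentences
    if (nrow(s) > 1L) {
      if (any(diff(s$start) <= 0)) stop(doc$doc_id, ": sentence spans not ordered")
      if (any(s$end[-nrow(s)] > s$start[-1])) stop(doc$doc_id, ": sentence spans overlap")
    }
    if (any(s$start >= s$end)) stop(doc$doc_id, ": empty sentence span")
    mn <- doc$mentions
    if (nrow(mn) == 0L) next
    if (!all(mn$kind %in% MENTION_KINDS)) stop(doc$doc_id, ": unknown mention kind")
    if (!all(mn$start < mn$end)) stop(doc$doc_id, ": mention start >= end")
    if (!all(text_slice(doc$text, mn$start, mn$end) == mn$surface)) {
      stop(doc$doc_id, ": mention surface/offset mismatch")
    }
    for (i in seq_len(nrow(mn))) {
      hit <- which(s$start <= mn$start[i] & mn$end[i] <= s$end)
      if (length(hit) != 1L || s$sentence_index[hit] != mn$sentence_index[i]) {
        stop(doc$doc_id, ": mention ", i, " sentence assignment invalid")
      }
    }
  }
  invisible(TRUE)
}

# mapping from PubTator annotation types to the closed kind set
PUBTATOR_TYPE_MAP <- c(
  Mutation = "mutation", ProteinMutation = "mutation", DNAMutation = "mutation",
  SNP = "mutation", Gene = "gene", Chemical = "drug", Drug = "drug",
  Disease = "disease", CellLine = "cell_line", Cellline = "cell_line",
  Species = NA_character_
)

#' Read a PubTator-format annotation file
#'
#' Records are blocks of lines separated by blank lines: `ID|t|title`,
#' optionally `ID|a|abstract`, then tab-separated annotation lines
#' `ID<TAB>start<TAB>end<TAB>surface<TAB>type[<TAB>normalized]`. Document
#' text is title + one space + abstract; offsets are treated as 0-based and
#' validated against the assembled text. Annotation types are mapped to the
#' closed kind set; unmappable types are dropped with a warning.
#'
#' @param lines character vector of lines, or a file path.
#' @param strict if `TRUE`, offset/surface mismatches are errors naming the
#'   document; otherwise such mentions are dropped with a warning.
#' @return An `mrx_corpus`.
#' @export
read_pubtator <- function(lines, strict = TRUE) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  lines <- sub("\r$", "", lines)
  blocks <- split(lines, cumsum(lines == ""))
  docs <- list()
  for (blk in blocks) {
    blk <- blk[blk != ""]
    if (length(blk) == 0L) next
    tl <- grep("^[^\t|]+\\|t\\|", blk, value = TRUE)
    if (length(tl) != 1L) {
      stop("malformed PubTator record (missing title line): ",
           substr(blk[1], 1, 60))
    }
    doc_id <- sub("\\|.*$", "", tl)
    title <- sub("^[^|]+\\|t\\|", "", tl)
    al <- grep(paste0("^", doc_id, "\\|a\\|"), blk, value = TRUE)
    text <- if (length(al) == 1L) {
      paste(title, sub("^[^|]+\\|a\\|", "", al))
    } else title
    ann <- blk[grepl("\t", blk, fixed = TRUE)]
    mn <- empty_mentions()
    if (length(ann) > 0L) {
      parts <- strsplit(ann, "\t", fixed = TRUE)
      nf <- vapply(parts, length, integer(1))
      if (any(nf < 5L)) {
        stop("malformed annotation line in document '", doc_id, "': ",
             ann[which(nf < 5L)[1]])
      }
      typ <- vapply(parts, `[`, character(1), 5L)
      kind <- ifelse(typ %in% MENTION_KINDS, typ,
                     unname(PUBTATOR_TYPE_MAP[typ]))
      drop <- is.na(kind)
      if (any(drop)) {
        warning("document '", doc_id, "': dropped ", sum(drop),
                " annotation(s) of unmapped type(s) ",
                paste(unique(typ[drop]), collapse = ", "))
      }
      keep <- which(!drop)
      if (length(keep) > 0L) {
        norm <- vapply(parts[keep], function(p) {
          if (length(p) >= 6L && nzchar(p[6]) && p[6] != "-") p[6] else p[4]
        }, character(1))
        mn <- entity_mentions(
          doc_id = doc_id,
          start = as.integer(vapply(parts[keep], `[`, character(1), 2L)),
          end = as.integer(vapply(parts[keep], `[`, character(1), 3L)),
          surface = vapply(parts[keep], `[`, character(1), 4L),
          kind = kind[keep], normalized = norm
        )
      }
    }
    docs[[length(docs) + 1L]] <-
      annotated_document(doc_id, text, mn, strict = strict)
  }
  corpus(docs)
}

#' Write a corpus in PubTator format
#'
#' The first sentence is emitted as the title and the remainder as the
#' abstract, preserving offsets (title and abstract are joined by one space
#' on re-read when the gap is a single space; otherwise the whole text is
#' the title line).
#'
#' @param corp an `mrx_corpus`.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_pubtator <- function(corp, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (doc in corp) {
    s <- doc$sentences
    split_ok <- nrow(s) > 1L && s$end[1] + 1L == s$start[2]
    if (split_ok) {
      title <- text_slice(doc$text, 0L, s$end[1])
      abstract <- text_slice(doc$text, s$start[2], nchar(doc$text))
      writeLines(paste0(doc$doc_id, "|t|", title), con)
      writeLines(paste0(doc$doc_id, "|a|", abstract), con)
    } else {
      writeLines(paste0(doc$doc_id, "|t|", doc$text), con)
    }
    mn <- doc$mentions
    kind_to_type <- c(mutation = "Mutation", gene = "Gene", drug = "Chemical",
                      disease = "Disease", cell_line = "CellLine")
    for (i in seq_len(nrow(mn))) {
      writeLines(paste(doc$doc_id, mn$start[i], mn$end[i], mn$surface[i],
                       kind_to_type[[mn$kind[i]]], mn$normalized[i],
                       sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

CORPUS_FORMAT <- "mutrelex-corpus"
CORPUS_VERSION <- 1L

#' Write a corpus to the internal line-delimited format
#'
#' One JSON header line followed by one JSON document record per line;
#' lossless round trip with [read_corpus()].
#'
#' @param corp an `mrx_corpus`.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_corpus <- function(corp, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(jsonlite::toJSON(
    list(format = CORPUS_FORMAT, version = CORPUS_VERSION),
    auto_unbox = TRUE), con)
  for (doc in corp) {
    rec <- list(
      doc_id = doc$doc_id, text = doc$text,
      sentences = unname(as.matrix(doc$sentences)),
      mentions = doc$mentions
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a corpus from the internal line-delimited format
#' @param path file written by [write_corpus()].
#' @return An `mrx_corpus`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("corpus format error: empty file")
  hdr <- tryCatch(jsonlite::fromJSON(lines[1]),
                  error = function(e) stop("corpus format error: bad header"))
  if (!identical(hdr$format, CORPUS_FORMAT) ||
      !identical(as.integer(hdr$version), CORPUS_VERSION)) {
    stop("corpus format error: unsupported format/version")
  }
  docs <- lapply(lines[-1][nzchar(lines[-1])], function(ln) {
    rec <- tryCatch(jsonlite::fromJSON(ln, simplifyDataFrame = TRUE),
                    error = function(e) stop("corpus format error: truncated or invalid record"))
    if (is.null(rec$doc_id) || is.null(rec$text) || is.null(rec$sentences)) {
      stop("corpus format error: record missing required fields")
    }
    sm <- matrix(as.integer(rec$sentences), ncol = 3)
    sentences <- data.frame(sentence_index = sm[, 1], start = sm[, 2], end = sm[, 3])
    mn <- rec$mentions
    if (is.null(mn) || length(mn) == 0L || NROW(mn) == 0L) {
      mn <- empty_mentions()
    } else {
      mn <- as.data.frame(mn, stringsAsFactors = FALSE)
      mn$sentence_index <- as.integer(mn$sentence_index)
      mn$start <- as.integer(mn$start); mn$end <- as.integer(mn$end)
    }
    annotated_document(rec$doc_id, rec$text, mn, sentences = sentences)
  })
  corpus(docs)
}
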