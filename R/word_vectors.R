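# Word vectors: skip-gram negative-sampling training on a tokenized
# corpus, and reader/writer for the standard word2vec text and binary
# formats. Training is chunk-vectorized SGD: pairs are processed in blocks
# with gradients gathered/scattered through rowsum(), which keeps the
# inner loop in BLAS.

#' Tokenize every sentence of a corpus, merging entity surfaces
#'
#' @param corp an `mrx_corpus`.
#' @param lexicon multi-word entity surfaces to merge (defaults to all
#'   multi-word mention surfaces in the corpus).
#' @return list of character vectors, one per sentence.
#' @export
corpus_sentences_tokens <- function(corp, lexicon = NULL) {
  if (is.null(lexicon)) {
    surf <- unique(unlist(lapply(corp, function(d) d$mentions$surface)))
    lexicon <- surf[grepl(" ", surf, fixed = TRUE)]
  }
  out <- list()
  for (doc in corp) {
    s <- doc$sentences
    for (i in seq_len(nrow(s))) {
      txt <- text_slice(doc$text, s$start[i], s$end[i])
      txt <- gsub("[.,;:!?]+(\\s|$)", "\\1", txt)  # strip clause punctuation
      out[[length(out) + 1L]] <- merge_entity_tokens(txt, lexicon)
    }
  }
  out
}

#' Train skip-gram word vectors with negative sampling
#'
#' Words with corpus frequency below `min_count` are excluded. Negative
#' samples are drawn from the unigram distribution raised to 3/4.
#' Deterministic per seed.
#'
#' @param sentences list of token vectors (e.g. from
#'   [corpus_sentences_tokens()]), or an `mrx_corpus`.
#' @param dim embedding dimension.
#' @param min_count minimum corpus frequency for a word to be kept.
#' @param window one-sided context window size.
#' @param negative negative samples per positive pair.
#' @param epochs training passes over the pair list.
#' @param learning_rate initial SGD step size (linearly decayed).
#' @param seed integer seed.
#' @return object of class `mrx_word_vectors`: list with `vectors` (a
#'   vocab x dim matrix with rownames) and `dim`.
#' @export
train_word_vectors <- function(sentences, dim = 300L, min_count = 5L,
                               window = 5L, negative = 5L, epochs = 3L,
                               learning_rate = 0.05, seed = 1L) {
  if (inherits(sentences, "mrx_corpus")) {
    sentences <- corpus_sentences_tokens(sentences)
  }
  stopifnot(length(sentences) > 0L)
  freq <- table(unlist(sentences))
  vocab <- names(freq)[freq >= min_count]
  if (length(vocab) == 0L) stop("no word reaches min_count")
  vocab <- sort(vocab)
  vid <- stats::setNames(seq_along(vocab), vocab)
  # center/context index pairs (symmetric window)
  cen_l <- list(); ctx_l <- list()
  for (toks in sentences) {
    ids <- unname(vid[toks]); ids <- ids[!is.na(ids)]
    n <- length(ids)
    if (n < 2L) next
    for (off in seq_len(min(window, n - 1L))) {
      i <- seq_len(n - off)
      cen_l[[length(cen_l) + 1L]] <- c(ids[i], ids[i + off])
      ctx_l[[length(ctx_l) + 1L]] <- c(ids[i + off], ids[i])
    }
  }
  centers <- unlist(cen_l, use.names = FALSE)
  contexts <- unlist(ctx_l, use.names = FALSE)
  npairs <- length(centers)
  V <- length(vocab)
  ufreq <- as.numeric(freq[vocab])^0.75
  neg_prob <- ufreq / sum(ufreq)

  old <- .Random.seed.save(); set.seed(seed)
  W_in <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim)
  W_out <- matrix(0, V, dim)
  sigm <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))
  chunk <- 1024L
  total_steps <- epochs * ceiling(npairs / chunk)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(npairs)
    for (lo in seq(1L, npairs, by = chunk)) {
      idx <- ord[lo:min(lo + chunk - 1L, npairs)]
      b <- length(idx)
      lr <- learning_rate * max(1 - step / total_steps, 1e-4)
      step <- step + 1L
      c_id <- centers[idx]
      pos_id <- contexts[idx]
      neg_id <- matrix(sample.int(V, b * negative, replace = TRUE,
                                  prob = neg_prob), b, negative)
      Xc <- W_in[c_id, , drop = FALSE]
      # positive pairs
      Po <- W_out[pos_id, , drop = FALSE]
      g_pos <- sigm(rowSums(Xc * Po)) - 1            # d loss / d score
      dXc <- Po * g_pos
      dPo <- Xc * g_pos
      # negative samples
      for (k in seq_len(negative)) {
        No <- W_out[neg_id[, k], , drop = FALSE]
        g_neg <- sigm(rowSums(Xc * No))
        dXc <- dXc + No * g_neg
        dNo <- Xc * g_neg
        upd <- rowsum(dNo, neg_id[, k])
        rows <- as.integer(rownames(upd))
        W_out[rows, ] <- W_out[rows, , drop = FALSE] - lr * upd
      }
      upd <- rowsum(dXc, c_id)
      rows <- as.integer(rownames(upd))
      W_in[rows, ] <- W_in[rows, , drop = FALSE] - lr * upd
      upd <- rowsum(dPo, pos_id)
      rows <- as.integer(rownames(upd))
      W_out[rows, ] <- W_out[rows, , drop = FALSE] - lr * upd
    }
  }
  .Random.seed.restore(old)
  rownames(W_in) <- vocab
  structure(list(vectors = W_in, dim = as.integer(dim)),
            class = "mrx_word_vectors")
}

#' @export
print.mrx_word_vectors <- function(x, ...) {
  cat(sprintf("mrx_word_vectors: %d words x %d dims\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Cosine similarity between two vocabulary words
#' @param wv an `mrx_word_vectors`.
#' @param a,b vocabulary words.
#' @return cosine similarity, or `NA` when a word is out of vocabulary.
#' @export
word_similarity <- function(wv, a, b) {
  V <- wv$vectors
  if (!(a %in% rownames(V)) || !(b %in% rownames(V))) return(NA_real_)
  va <- V[a, ]; vb <- V[b, ]
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

#' Write word vectors in word2vec text or binary format
#'
#' @param wv an `mrx_word_vectors`.
#' @param path output path.
#' @param format `"word2vec_text"` or `"word2vec_binary"`.
#' @return `path` invisibly.
#' @export
write_word_vectors <- function(wv, path,
                               format = c("word2vec_text", "word2vec_binary")) {
  format <- match.arg(format)
  V <- wv$vectors
  if (format == "word2vec_text") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste(nrow(V), ncol(V)), con)
    for (i in seq_len(nrow(V))) {
      writeLines(paste(rownames(V)[i],
                       paste(sprintf("%.8g", V[i, ]), collapse = " ")), con)
    }
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(charToRaw(paste(nrow(V), ncol(V))), con)
    writeBin(charToRaw("\n"), con)
    for (i in seq_len(nrow(V))) {
      writeBin(charToRaw(paste0(rownames(V)[i], " ")), con)
      writeBin(as.numeric(V[i, ]), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' Load word vectors from word2vec text or binary format
#'
#' The header's word and dimension counts are validated against the file
#' contents; a truncated or inconsistent file is a format error.
#'
#' @param path input path.
#' @param format `"word2vec_text"` or `"word2vec_binary"`.
#' @return an `mrx_word_vectors`.
#' @export
load_word_vectors <- function(path,
                              format = c("word2vec_text", "word2vec_binary")) {
  format <- match.arg(format)
  if (format == "word2vec_text") {
    lines <- readLines(path)
    hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
    if (length(hdr) != 2L || anyNA(hdr)) stop("word vector format error: bad header")
    n <- hdr[1]; d <- hdr[2]
    body <- lines[-1][nzchar(lines[-1])]
    if (length(body) != n) stop("word vector format error: word count mismatch")
    parts <- strsplit(body, " ", fixed = TRUE)
    words <- vapply(parts, `[`, character(1), 1L)
    vecs <- lapply(parts, function(p) as.numeric(p[-1]))
    if (any(vapply(vecs, length, integer(1)) != d) ||
        anyNA(unlist(vecs, use.names = FALSE))) {
      stop("word vector format error: dimension mismatch")
    }
    M <- do.call(rbind, vecs)
    rownames(M) <- words
  } else {
    con <- file(path, "rb"); on.exit(close(con))
    read_token <- function(stop_chars) {
      out <- raw(0)
      repeat {
        ch <- readBin(con, "raw", n = 1L)
        if (length(ch) == 0L) stop("word vector format error: truncated file")
        if (rawToChar(ch) %in% stop_chars) break
        out <- c(out, ch)
      }
      rawToChar(out)
    }
    hdr <- strsplit(read_token("\n"), " ", fixed = TRUE)[[1]]
    n <- as.integer(hdr[1]); d <- as.integer(hdr[2])
    if (anyNA(c(n, d))) stop("word vector format error: bad header")
    M <- matrix(0, n, d); words <- character(n)
    for (i in seq_len(n)) {
      words[i] <- read_token(" ")
      v <- readBin(con, "numeric", n = d, size = 4L, endian = "little")
      if (length(v) != d) stop("word vector format error: truncated file")
      M[i, ] <- v
    }
    rownames(M) <- words
  }
  structure(list(vectors = M, dim = ncol(M)), class = "mrx_word_vectors")
}
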