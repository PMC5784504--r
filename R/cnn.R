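# Sentence-level convolutional relation classifier.
#
# Architecture: each token is represented by the concatenation of a word
# embedding, a 10-d entity-type embedding and two 10-d position embeddings
# (relative offsets from the target mutation and the target partner).
# Convolution filters of widths 3/4/5 (100 maps each) run over the token
# axis with ReLU, followed by max-over-time pooling. The pooled vector is
# concatenated with standardized scalar features (the search scores, and
# optionally the distance/frequency features), passed through dropout and
# an affine softmax layer over {false, true}.
#
# Implemented directly in matrix algebra: convolutions are unrolled to a
# windows-by-(width x depth) matrix and a single BLAS matrix product per
# filter width; gradients flow back through the same unrolling and are
# scattered into the embedding tables with rowsum(). Training is
# mini-batch Adam (or plain SGD), fully seeded.

#' Token type alphabet of the sentence encoder
#'
#' Entity roles a token can take in an encoded sentence; index 1 is the
#' padding type.
#' @export
TYPE_ALPHABET <- c("pad", "plain", "target_mutation", "target_gene",
                   "target_drug", "other_mutation", "other_gene",
                   "other_drug", "disease", "cell_line")
PAD_ID <- 1L
UNK_ID <- 2L

#' CNN configuration
#'
#' Defaults follow the widely used convolutional sentence-classification
#' setup: filter widths 3/4/5 with 100 maps each, dropout keep 0.5, batch
#' size 50, 300-d word embeddings, 10-d type and position embeddings.
#'
#' @param word_dim word embedding dimension.
#' @param type_dim entity-type embedding dimension.
#' @param pos_dim position embedding dimension (per target channel).
#' @param filter_widths integer vector of convolution widths.
#' @param maps_per_width feature maps per width.
#' @param dropout_keep keep probability of dropout on the penultimate layer.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param max_sentence_len tokens per encoded sentence (pad/truncate).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate optimizer step size.
#' @param seed integer seed.
#' @return list of class `mrx_cnn_config`.
#' @export
cnn_config <- function(word_dim = 300L, type_dim = 10L, pos_dim = 10L,
                       filter_widths = c(3L, 4L, 5L), maps_per_width = 100L,
                       dropout_keep = 0.5, batch_size = 50L, epochs = 3L,
                       max_sentence_len = 30L,
                       optimizer = c("adam", "sgd"), learning_rate = 1e-3,
                       seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(word_dim > 0, type_dim > 0, pos_dim > 0, maps_per_width > 0,
            dropout_keep > 0, dropout_keep <= 1, batch_size > 0, epochs > 0,
            max_sentence_len >= max(filter_widths))
  structure(as.list(environment()), class = "mrx_cnn_config")
}

tokenize_plain <- function(text) {
  toks <- strsplit(gsub("[.,;:!?]+", " ", text), "[ \t\r\n]+")[[1]]
  toks[nzchar(toks)]
}

#' Tokenize one sentence, collapsing entity mentions to single tokens
#'
#' @param doc an `mrx_document`.
#' @param sentence_index 0-based sentence index.
#' @return list with parallel vectors `tokens`, `kinds` (`"plain"` or a
#'   mention kind) and `norms` (normalized form; `NA` for plain tokens).
#' @export
sentence_tokens <- function(doc, sentence_index) {
  span <- doc$sentences[doc$sentences$sentence_index == sentence_index, ]
  if (nrow(span) != 1L) stop("no sentence with index ", sentence_index)
  mn <- doc$mentions[doc$mentions$sentence_index == sentence_index, , drop = FALSE]
  mn <- mn[order(mn$start), , drop = FALSE]
  tokens <- character(0); kinds <- character(0); norms <- character(0)
  cur <- span$start
  emit_plain <- function(a, b) {
    if (b > a) {
      tk <- tokenize_plain(text_slice(doc$text, a, b))
      tokens <<- c(tokens, tk)
      kinds <<- c(kinds, rep("plain", length(tk)))
      norms <<- c(norms, rep(NA_character_, length(tk)))
    }
  }
  for (i in seq_len(nrow(mn))) {
    if (mn$start[i] < cur) next            # overlapping mention; keep first
    emit_plain(cur, mn$start[i])
    tokens <- c(tokens, gsub(" ", "_", mn$normalized[i]))
    kinds <- c(kinds, mn$kind[i])
    norms <- c(norms, mn$normalized[i])
    cur <- mn$end[i]
  }
  emit_plain(cur, span$end)
  list(tokens = tokens, kinds = kinds, norms = norms)
}

#' Build a token vocabulary from a corpus
#'
#' Ids 1 and 2 are reserved for the padding and unknown tokens.
#'
#' @param corp an `mrx_corpus`.
#' @param min_count minimum token frequency.
#' @return named integer vector token -> id, including `<pad>` and `<unk>`.
#' @export
cnn_vocab <- function(corp, min_count = 1L) {
  counts <- new.env(parent = emptyenv())
  for (doc in corp) {
    for (si in doc$sentences$sentence_index) {
      for (tk in sentence_tokens(doc, si)$tokens) {
        assign(tk, get0(tk, counts, ifnotfound = 0L) + 1L, counts)
      }
    }
  }
  freq <- unlist(as.list(counts))
  words <- sort(names(freq)[freq >= min_count])
  stats::setNames(seq_along(words) + 2L,
                  words) -> ids
  c(stats::setNames(c(PAD_ID, UNK_ID), c("<pad>", "<unk>")), ids)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Encode a sentence for the CNN
#'
#' Entity mentions are collapsed to single tokens; each token gets a type
#' from the closed alphabet (target mutation, target gene/drug, non-target
#' entity kinds, plain) and two relative positions (token offset from each
#' target, clipped to the sentence-length window). Sentences are padded or
#' truncated to `max_sentence_len`; truncation keeps a window centered
#' between the two targets.
#'
#' @param doc an `mrx_document`.
#' @param sentence_index 0-based sentence index.
#' @param target_mutation normalized mutation string (must be mentioned in
#'   the sentence).
#' @param target_partner normalized partner string.
#' @param partner_kind `"gene"` or `"drug"`.
#' @param vocab from [cnn_vocab()].
#' @param config a [cnn_config()].
#' @param scalar_features numeric vector fused after pooling.
#' @param label `TRUE`/`FALSE` or `NA`.
#' @return list of class `mrx_encoded_sentence`.
#' @export
encode_sentence <- function(doc, sentence_index, target_mutation,
                            target_partner, partner_kind, vocab, config,
                            scalar_features = numeric(0), label = NA) {
  st <- sentence_tokens(doc, sentence_index)
  i_mut <- which(st$kinds == "mutation" & st$norms == target_mutation)[1]
  i_par_all <- which(st$kinds == partner_kind & st$norms == target_partner)
  i_par <- setdiff(i_par_all, i_mut)[1]
  if (is.na(i_mut) || is.na(i_par)) {
    stop("contract violation: target mention not found in sentence ",
         sentence_index, " of document '", doc$doc_id, "'")
  }
  other_type <- c(mutation = "other_mutation", gene = "other_gene",
                  drug = "other_drug", disease = "disease",
                  cell_line = "cell_line")
  types <- ifelse(st$kinds == "plain", "plain", other_type[st$kinds])
  types[i_mut] <- "target_mutation"
  types[i_par] <- paste0("target_", partner_kind)
  n <- length(st$tokens)
  L <- config$max_sentence_len
  if (n > L) {
    if (abs(i_par - i_mut) + 1L > L) {
      stop("contract violation: targets further apart than max_sentence_len")
    }
    center <- floor((i_mut + i_par) / 2)
    lo <- clip(center - floor(L / 2) + 1L, 1L, n - L + 1L)
    lo <- clip(lo, max(i_mut, i_par) - L + 1L, min(i_mut, i_par))
    sel <- lo:(lo + L - 1L)
    st$tokens <- st$tokens[sel]; types <- types[sel]
    i_mut <- i_mut - lo + 1L; i_par <- i_par - lo + 1L
    n <- L
  }
  ids <- unname(vocab[st$tokens]); ids[is.na(ids)] <- UNK_ID
  type_ids <- match(types, TYPE_ALPHABET)
  offs <- seq_len(n)
  pos_m <- clip(offs - i_mut, -L, L) + L + 1L
  pos_p <- clip(offs - i_par, -L, L) + L + 1L
  pad <- L - n
  structure(list(
    token_ids = as.integer(c(ids, rep(PAD_ID, pad))),
    type_ids = as.integer(c(type_ids, rep(1L, pad))),
    pos_mut = as.integer(c(pos_m, rep(2L * L + 2L, pad))),
    pos_partner = as.integer(c(pos_p, rep(2L * L + 2L, pad))),
    scalar_features = as.numeric(scalar_features),
    label = label, n_tokens = n
  ), class = "mrx_encoded_sentence")
}

#' Encode a table of candidate sentences
#'
#' @param corp an `mrx_corpus`.
#' @param pairs data.frame with `doc_id`, `sentence_index`, `mutation`,
#'   `partner` and optionally `label`.
#' @param partner_kind `"gene"` or `"drug"`.
#' @param vocab,config as for [encode_sentence()].
#' @param index optional background `mrx_index`; when given, the four
#'   search scores of each pair (sentence-level context) become the scalar
#'   features.
#' @return list of `mrx_encoded_sentence`.
#' @export
encode_dataset <- function(corp, pairs, partner_kind, vocab, config,
                           index = NULL) {
  lapply(seq_len(NROW(pairs)), function(i) {
    doc <- corp[[pairs$doc_id[i]]]
    if (is.null(doc)) stop("unknown doc_id: ", pairs$doc_id[i])
    scal <- numeric(0)
    if (!is.null(index)) {
      ctx <- doc$mentions[doc$mentions$sentence_index == pairs$sentence_index[i], ,
                          drop = FALSE]
      scal <- search_score_features(index, pairs$mutation[i], ctx,
                                    partner_kind, pairs$partner[i])
    }
    encode_sentence(doc, pairs$sentence_index[i], pairs$mutation[i],
                    pairs$partner[i], partner_kind, vocab, config,
                    scalar_features = scal,
                    label = if ("label" %in% names(pairs)) pairs$label[i] else NA)
  })
}

# stack a list of encodings into index matrices for batched training
pack_encodings <- function(examples) {
  L <- length(examples[[1]]$token_ids)
  grab <- function(f) t(vapply(examples, `[[`, integer(L), f))
  ns <- length(examples[[1]]$scalar_features)
  S <- if (ns > 0) t(vapply(examples, `[[`, numeric(ns), "scalar_features")) else
    matrix(0, length(examples), 0)
  list(TOK = grab("token_ids"), TYP = grab("type_ids"),
       PM = grab("pos_mut"), PP = grab("pos_partner"), S = S,
       y = vapply(examples, function(e) as.logical(e$label), logical(1)),
       L = L, n = length(examples))
}

init_params <- function(config, V, ns, initial_vectors, vocab) {
  dw <- config$word_dim; dt <- config$type_dim; dp <- config$pos_dim
  D <- dw + dt + 2L * dp
  L <- config$max_sentence_len
  P <- 2L * L + 2L
  ru <- function(n, m, a) matrix(stats::runif(n * m, -a, a), n, m)
  E_word <- ru(V, dw, 0.25)
  if (!is.null(initial_vectors)) {
    if (initial_vectors$dim != dw) {
      stop("configuration error: pre-trained vector dimension ",
           initial_vectors$dim, " != word_dim ", dw)
    }
    hit <- intersect(rownames(initial_vectors$vectors), names(vocab))
    E_word[vocab[hit], ] <- initial_vectors$vectors[hit, , drop = FALSE]
  }
  th <- list(E_word = E_word,
             E_type = ru(length(TYPE_ALPHABET), dt, 0.25),
             E_pm = ru(P, dp, 0.25), E_pp = ru(P, dp, 0.25))
  for (w in config$filter_widths) {
    a <- sqrt(6 / (w * D + config$maps_per_width))
    th[[paste0("W", w)]] <- ru(w * D, config$maps_per_width, a)
    th[[paste0("b", w)]] <- numeric(config$maps_per_width)
  }
  nh <- length(config$filter_widths) * config$maps_per_width + ns
  th$W_o <- ru(nh, 2L, sqrt(6 / (nh + 2)))
  th$b_o <- numeric(2L)
  th
}

# window-start row indices for offset o of a width-w filter, sentences of
# length L stacked B deep
conv_rows <- function(B, L, nwin, o) {
  rep((seq_len(B) - 1L) * L, each = nwin) + seq_len(nwin) + (o - 1L)
}

# forward pass over a batch; returns intermediates when backward = TRUE.
# The convolution is computed as a sum over filter offsets of shifted
# matrix products, avoiding an unrolled windows matrix.
cnn_forward <- function(th, pk, idx, config, dropout_mask = NULL,
                        keep_interm = FALSE) {
  B <- length(idx); L <- pk$L
  dw <- config$word_dim; dt <- config$type_dim; dp <- config$pos_dim
  D <- dw + dt + 2L * dp
  tok <- as.vector(t(pk$TOK[idx, , drop = FALSE]))
  typ <- as.vector(t(pk$TYP[idx, , drop = FALSE]))
  pm <- as.vector(t(pk$PM[idx, , drop = FALSE]))
  pp <- as.vector(t(pk$PP[idx, , drop = FALSE]))
  X <- cbind(th$E_word[tok, , drop = FALSE], th$E_type[typ, , drop = FALSE],
             th$E_pm[pm, , drop = FALSE], th$E_pp[pp, , drop = FALSE])
  m <- config$maps_per_width
  pooled <- list(); interm <- list()
  for (w in config$filter_widths) {
    nwin <- L - w + 1L
    W <- th[[paste0("W", w)]]
    Z <- matrix(rep(th[[paste0("b", w)]], each = B * nwin), B * nwin, m)
    for (o in seq_len(w)) {
      ro <- conv_rows(B, L, nwin, o)
      Z <- Z + X[ro, , drop = FALSE] %*% W[((o - 1L) * D + 1L):(o * D), ,
                                           drop = FALSE]
    }
    A <- pmax(Z, 0)
    # max-over-time pooling: rows are (window within sentence) fastest
    arr <- array(A, dim = c(nwin, B, m))
    M2 <- matrix(aperm(arr, c(2, 3, 1)), B * m, nwin)
    argv <- max.col(M2, ties.method = "first")
    Pw <- matrix(M2[cbind(seq_len(B * m), argv)], B, m)
    arg <- matrix(argv, B, m)
    pooled[[as.character(w)]] <- Pw
    if (keep_interm) {
      interm[[as.character(w)]] <- list(Z = Z, arg = arg, nwin = nwin)
    }
  }
  h <- do.call(cbind, c(unname(pooled),
                        if (ncol(pk$S) > 0) list(pk$S[idx, , drop = FALSE])))
  hd <- if (is.null(dropout_mask)) h else h * dropout_mask
  logits <- hd %*% th$W_o + rep(th$b_o, each = B)
  mx <- apply(logits, 1, max)
  el <- exp(logits - mx)
  probs <- el / rowSums(el)
  out <- list(probs = probs, h = h, hd = hd)
  if (keep_interm) {
    out$interm <- interm
    out$X <- X; out$tok <- tok; out$typ <- typ; out$pm <- pm; out$pp <- pp
  }
  out
}

zero_like <- function(th) lapply(th, function(p) p * 0)

cnn_backward <- function(th, fw, pk, idx, config, dropout_mask) {
  B <- length(idx)
  dw <- config$word_dim; dt <- config$type_dim; dp <- config$pos_dim
  D <- dw + dt + 2L * dp
  m <- config$maps_per_width
  y <- pk$y[idx]
  Y <- cbind(!y, y) + 0
  dlogits <- (fw$probs - Y) / B
  g <- list()
  g$W_o <- unname(t(fw$hd) %*% dlogits)
  g$b_o <- as.vector(colSums(dlogits))
  dh <- (dlogits %*% t(th$W_o)) * dropout_mask
  L <- pk$L
  dX <- matrix(0, nrow(fw$X), D)
  col0 <- 0L
  for (w in config$filter_widths) {
    iw <- fw$interm[[as.character(w)]]
    dP <- dh[, (col0 + 1L):(col0 + m), drop = FALSE]
    col0 <- col0 + m
    nwin <- iw$nwin
    dA <- matrix(0, B * nwin, m)
    rows_vec <- as.vector(iw$arg + (seq_len(B) - 1L) * nwin)
    dA[cbind(rows_vec, rep(seq_len(m), each = B))] <- as.vector(dP)
    dZ <- dA * (iw$Z > 0)
    W <- th[[paste0("W", w)]]
    gW <- matrix(0, w * D, m)
    for (o in seq_len(w)) {
      ro <- conv_rows(B, L, nwin, o)
      cols <- ((o - 1L) * D + 1L):(o * D)
      Xo <- fw$X[ro, , drop = FALSE]
      gW[cols, ] <- crossprod(Xo, dZ)
      dX[ro, ] <- dX[ro, , drop = FALSE] +
        dZ %*% t(W[cols, , drop = FALSE])
    }
    g[[paste0("W", w)]] <- gW
    g[[paste0("b", w)]] <- colSums(dZ)
  }
  scatter <- function(dpart, ids, nrow_out) {
    acc <- rowsum(dpart, ids)
    out <- matrix(0, nrow_out, ncol(dpart))
    out[as.integer(rownames(acc)), ] <- acc
    out
  }
  g$E_word <- scatter(dX[, 1:dw, drop = FALSE], fw$tok, nrow(th$E_word))
  g$E_type <- scatter(dX[, (dw + 1L):(dw + dt), drop = FALSE], fw$typ,
                      nrow(th$E_type))
  g$E_pm <- scatter(dX[, (dw + dt + 1L):(dw + dt + dp), drop = FALSE], fw$pm,
                    nrow(th$E_pm))
  g$E_pp <- scatter(dX[, (dw + dt + dp + 1L):(dw + dt + 2L * dp), drop = FALSE],
                    fw$pp, nrow(th$E_pp))
  g
}

#' Train the convolutional relation classifier
#'
#' Mini-batch training with dropout; scalar features are standardized with
#' mean and variance estimated on the training set only. When a dev set is
#' supplied the parameters at the best dev F1 epoch are returned.
#' Deterministic per seed on a single compute thread.
#'
#' @param train list of `mrx_encoded_sentence` with labels.
#' @param dev optional labeled dev list for epoch selection.
#' @param config a [cnn_config()].
#' @param vocab the vocabulary the examples were encoded with.
#' @param initial_vectors optional `mrx_word_vectors` to initialize the
#'   word embeddings (dimension must equal `word_dim`); all embeddings are
#'   fine-tuned.
#' @param verbose print per-epoch loss / dev F1.
#' @return object of class `mrx_cnn_model`.
#' @export
cnn_train <- function(train, dev = NULL, config = cnn_config(),
                      vocab, initial_vectors = NULL, verbose = FALSE) {
  stopifnot(length(train) > 0L)
  ns <- length(train[[1]]$scalar_features)
  pk <- pack_encodings(train)
  if (ns > 0) {
    mu <- colMeans(pk$S); sd <- apply(pk$S, 2, stats::sd)
    sd[!is.finite(sd) | sd == 0] <- 1
    pk$S <- sweep(sweep(pk$S, 2, mu), 2, sd, "/")
  } else {
    mu <- numeric(0); sd <- numeric(0)
  }
  pk_dev <- if (!is.null(dev)) {
    pd <- pack_encodings(dev)
    if (ns > 0) pd$S <- sweep(sweep(pd$S, 2, mu), 2, sd, "/")
    pd
  }
  old <- .Random.seed.save(); set.seed(config$seed)
  th <- init_params(config, length(vocab), ns, initial_vectors, vocab)
  opt_m <- zero_like(th); opt_v <- zero_like(th)
  t_adam <- 0
  best <- list(f1 = -1, th = th)
  n <- pk$n
  history <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (lo in seq(1L, n, by = config$batch_size)) {
      idx <- ord[lo:min(lo + config$batch_size - 1L, n)]
      B <- length(idx)
      nh <- length(config$filter_widths) * config$maps_per_width + ns
      mask <- matrix((stats::runif(B * nh) < config$dropout_keep) /
                       config$dropout_keep, B, nh)
      fw <- cnn_forward(th, pk, idx, config, dropout_mask = mask,
                        keep_interm = TRUE)
      yb <- pk$y[idx]
      pt <- fw$probs[cbind(seq_len(B), ifelse(yb, 2L, 1L))]
      ep_loss <- ep_loss - mean(log(pmax(pt, 1e-12))); nb <- nb + 1L
      g <- cnn_backward(th, fw, pk, idx, config, mask)
      t_adam <- t_adam + 1
      for (nm in names(g)) {
        if (config$optimizer == "adam") {
          opt_m[[nm]] <- 0.9 * opt_m[[nm]] + 0.1 * g[[nm]]
          opt_v[[nm]] <- 0.999 * opt_v[[nm]] + 0.001 * g[[nm]]^2
          mh <- opt_m[[nm]] / (1 - 0.9^t_adam)
          vh <- opt_v[[nm]] / (1 - 0.999^t_adam)
          th[[nm]] <- th[[nm]] - config$learning_rate * mh / (sqrt(vh) + 1e-8)
        } else {
          th[[nm]] <- th[[nm]] - config$learning_rate * g[[nm]]
        }
      }
    }
    dev_f1 <- NA_real_
    if (!is.null(dev)) {
      pr <- predict_packed(th, pk_dev, config)
      dev_f1 <- prf_from_labels(pk_dev$y, pr >= 0.5)$f1
      if (dev_f1 > best$f1) best <- list(f1 = dev_f1, th = th)
    }
    history <- c(history, if (is.null(dev)) ep_loss / nb else dev_f1)
    if (verbose) {
      message(sprintf("epoch %d loss %.4f dev F1 %s", ep, ep_loss / nb,
                      ifelse(is.na(dev_f1), "-", sprintf("%.3f", dev_f1))))
    }
  }
  .Random.seed.restore(old)
  if (!is.null(dev) && best$f1 >= 0) th <- best$th
  structure(list(params = th, config = config, vocab = vocab,
                 scalar_mu = mu, scalar_sd = sd, n_scalars = ns,
                 history = history,
                 best_dev_f1 = if (is.null(dev)) NA_real_ else best$f1),
            class = "mrx_cnn_model")
}

predict_packed <- function(th, pk, config, batch = 200L) {
  n <- pk$n
  out <- numeric(n)
  for (lo in seq(1L, n, by = batch)) {
    idx <- lo:min(lo + batch - 1L, n)
    fw <- cnn_forward(th, pk, idx, config)
    out[idx] <- fw$probs[, 2]
  }
  out
}

#' Predict relation probabilities with a trained CNN
#'
#' @param object an `mrx_cnn_model`.
#' @param examples list of `mrx_encoded_sentence` encoded with the model's
#'   vocabulary and config.
#' @param ... unused.
#' @return numeric vector of probabilities of the true class.
#' @export
predict.mrx_cnn_model <- function(object, examples, ...) {
  if (length(examples) == 0L) return(numeric(0))
  ns <- length(examples[[1]]$scalar_features)
  if (ns != object$n_scalars) {
    stop("contract violation: examples carry ", ns, " scalar features, ",
         "model expects ", object$n_scalars)
  }
  if (length(examples[[1]]$token_ids) != object$config$max_sentence_len) {
    stop("contract violation: encoding length mismatch")
  }
  pk <- pack_encodings(examples)
  if (ns > 0) {
    pk$S <- sweep(sweep(pk$S, 2, object$scalar_mu), 2, object$scalar_sd, "/")
  }
  predict_packed(object$params, pk, object$config)
}
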