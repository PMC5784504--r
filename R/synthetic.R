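# Seeded generator of annotated corpora, relation tables, protein records
# and a background co-occurrence corpus. Stands in for curated corpora
# (BRONCO-like gold sets, ClinVar/COSMIC/PharmGKB-style relation tables)
# and for the PubMed-scale background a live entity search engine would
# index.
#
# Positive relations are expressed through trigger-word templates
# ("conferred sensitivity to", "drives"), negatives through neutral
# co-mention templates; a template_noise fraction of positives uses
# trigger-free phrasing so the sentence classifier has an irreducible
# error floor. True pairs co-occur in the background corpus at a
# configurable multiple of random pairs, which is what the search-score
# features pick up.

#' Generator configuration
#'
#' @param seed integer seed; the generator is fully deterministic per seed.
#' @param n_genes,n_drugs,n_mutations lexicon sizes.
#' @param n_documents foreground (annotated) documents.
#' @param sentences_per_document sentences per foreground document (first
#'   sentence is an intro/filler, the rest are relation-candidate slots).
#' @param positive_rate probability that a candidate slot expresses a true
#'   relation.
#' @param seqfilter_violation_rate fraction of decoy mutation-gene pairs
#'   whose wild-type residue check fails.
#' @param cooccurrence_boost factor by which true pairs are over-represented
#'   in the background corpus relative to random pairs.
#' @param template_noise fraction of positive sentences phrased without
#'   trigger words.
#' @param n_background_documents background corpus size.
#' @param protein_length length of each generated protein sequence.
#' @return list of class `mrx_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_genes = 25L, n_drugs = 25L, n_mutations = 60L,
                             n_documents = 120L, sentences_per_document = 6L,
                             positive_rate = 0.5,
                             seqfilter_violation_rate = 0.8,
                             cooccurrence_boost = 4,
                             template_noise = 0.1,
                             n_background_documents = 300L,
                             protein_length = 400L) {
  stopifnot(n_genes > 0, n_drugs > 0, n_mutations > 0, n_documents > 0,
            sentences_per_document > 1,
            positive_rate > 0, positive_rate < 1,
            seqfilter_violation_rate >= 0, seqfilter_violation_rate <= 1,
            cooccurrence_boost >= 1,
            template_noise >= 0, template_noise < 1)
  if (n_mutations > n_genes * protein_length) {
    stop("configuration error: n_mutations exceeds total protein positions")
  }
  structure(as.list(environment()), class = "mrx_generator_config")
}

DISEASE_SURFACES <- c("alpha carcinoma", "beta lymphoma", "gamma sarcoma",
                      "delta melanoma", "epsilon glioma", "zeta leukemia",
                      "eta adenoma", "theta blastoma")

CELL_LINES <- sprintf("CL-%03d", 1:6)

# sentence templates; {M} mutation, {G} gene, {D} drug, {DIS} disease,
# {CL} cell line. All templates start with an uppercase word so the
# rule-based splitter finds every boundary.
TPL <- list(
  pos_gene = list(
    c("The", "{M}", "mutation", "in", "{G}", "drives", "tumor", "growth", "in", "{DIS}"),
    c("Tumors", "harboring", "the", "{G}", "{M}", "variant", "progressed", "in", "{DIS}"),
    c("Sequencing", "revealed", "that", "{M}", "is", "located", "in", "{G}"),
    c("The", "{M}", "substitution", "constitutively", "activates", "{G}", "signaling")
  ),
  pos_gene_noise = list(
    c("The", "study", "measured", "{M}", "and", "{G}", "in", "{DIS}"),
    c("Samples", "were", "profiled", "for", "{M}", "and", "{G}", "status")
  ),
  neg_gene = list(
    c("Expression", "of", "{G}", "was", "unchanged", "while", "{M}", "status", "was", "recorded", "in", "{DIS}"),
    c("Patients", "were", "screened", "for", "{G}", "and", "separately", "genotyped", "for", "{M}"),
    c("The", "cohort", "reported", "{G}", "expression", "alongside", "unrelated", "{M}", "carriers"),
    c("Control", "assays", "used", "{G}", "probes", "whereas", "{M}", "was", "not", "linked", "in", "{CL}")
  ),
  pos_drug = list(
    c("Patients", "harboring", "{M}", "in", "{G}", "were", "resistant", "to", "{D}", "in", "{DIS}"),
    c("The", "{M}", "mutation", "conferred", "sensitivity", "to", "{D}"),
    c("Treatment", "with", "{D}", "improved", "survival", "of", "{M}", "positive", "patients", "in", "{DIS}"),
    c("Cells", "carrying", "{M}", "showed", "marked", "response", "to", "{D}", "in", "{CL}")
  ),
  pos_drug_noise = list(
    c("The", "trial", "recorded", "{M}", "status", "and", "{D}", "dosing", "in", "{DIS}"),
    c("Both", "{M}", "and", "{D}", "were", "analyzed", "in", "the", "cohort")
  ),
  neg_drug = list(
    c("Patients", "received", "{D}", "while", "{M}", "status", "remained", "unknown", "in", "{DIS}"),
    c("The", "assay", "quantified", "{M}", "independently", "of", "{D}", "exposure"),
    c("Baseline", "{D}", "pharmacokinetics", "and", "{M}", "frequency", "were", "reported", "separately"),
    c("Unrelated", "arms", "evaluated", "{D}", "dosing", "and", "{M}", "prevalence", "in", "{CL}")
  ),
  intro = list(
    c("We", "studied", "{G}", "alterations", "in", "{DIS}", "patients"),
    c("This", "report", "describes", "molecular", "profiling", "of", "{DIS}", "cohorts"),
    c("Clinical", "outcomes", "were", "collected", "for", "{DIS}", "patients", "treated", "at", "baseline")
  ),
  background = list(
    c("Analysis", "of", "{M}", "and", "{P}", "was", "reported", "in", "{DIS}"),
    c("Observations", "on", "{M}", "together", "with", "{P}", "appeared", "in", "{DIS}", "studies"),
    c("Records", "mention", "{M}", "and", "{P}", "in", "clinical", "material")
  ),
  background_ctx = list(
    c("Analysis", "of", "{M}", "in", "{G}", "and", "{P}", "was", "reported", "in", "{DIS}"),
    c("Reports", "link", "{M}", "in", "{G}", "with", "{P}", "in", "{DIS}", "cases")
  )
)

slot_kind <- c("{M}" = "mutation", "{G}" = "gene", "{D}" = "drug",
               "{DIS}" = "disease", "{CL}" = "cell_line", "{P}" = NA)

# Render a token template into (text, mention table). `fill` maps slot
# marker -> list(surface, kind, normalized). Returns 0-based offsets.
render_template <- function(tokens, fill) {
  text <- ""
  rows <- list()
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (tok %in% names(fill)) {
      f <- fill[[tok]]
      start <- nchar(text)
      text <- paste0(text, f$surface)
      rows[[length(rows) + 1L]] <- data.frame(
        start = start, end = nchar(text), surface = f$surface,
        kind = f$kind, normalized = f$normalized, stringsAsFactors = FALSE)
    } else {
      text <- paste0(text, tok)
    }
    text <- paste0(text, if (i < length(tokens)) " " else ".")
  }
  mn <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), surface = character(0),
               kind = character(0), normalized = character(0))
  list(text = text, mentions = mn)
}

disease_fill <- function(surface) {
  list(surface = surface, kind = "disease",
       normalized = gsub(" ", "_", surface))
}

assemble_document <- function(doc_id, sent_list) {
  text <- ""
  sent_rows <- list(); mention_rows <- list()
  for (si in seq_along(sent_list)) {
    if (nzchar(text)) text <- paste0(text, " ")
    off <- nchar(text)
    s <- sent_list[[si]]
    text <- paste0(text, s$text)
    sent_rows[[si]] <- data.frame(sentence_index = si - 1L,
                                  start = off, end = nchar(text))
    if (nrow(s$mentions) > 0L) {
      m <- s$mentions
      m$start <- m$start + off; m$end <- m$end + off
      m$sentence_index <- si - 1L
      mention_rows[[length(mention_rows) + 1L]] <- m
    }
  }
  mn <- if (length(mention_rows)) do.call(rbind, mention_rows) else empty_mentions()
  if (nrow(mn) > 0L) {
    mn <- entity_mentions(doc_id, mn$start, mn$end, mn$surface, mn$kind,
                          mn$normalized, mn$sentence_index)
  }
  annotated_document(doc_id, text, mn,
                     sentences = do.call(rbind, sent_rows))
}

#' Generate a synthetic annotated corpus with ground truth
#'
#' Produces a foreground corpus of entity-annotated documents built from
#' sentence templates, the planted relation truth at sentence and document
#' level (document labels follow the any-sentence rule), protein records
#' consistent with every true mutation-gene pair, decoy mutation-gene
#' pairs failing the residue check at the configured rate, and a background
#' corpus in which true pairs co-occur `cooccurrence_boost` times more
#' often than random pairs.
#'
#' @param config a [generator_config()].
#' @return list with elements `corpus`, `truth` (list: `mutation_gene`,
#'   `mutation_drug`, `doc_relations`, `sent_relations`, `proteins`,
#'   `decoy_gene_pairs`), and `background` (an `mrx_corpus`).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "mrx_generator_config"))
  set.seed(config$seed)
  genes <- sprintf("GENE%03d", seq_len(config$n_genes))
  drugs <- sprintf("drugab%03d", seq_len(config$n_drugs))
  diseases <- DISEASE_SURFACES

  # proteins, then mutations whose wild type is read off the true gene
  seqs <- lapply(genes, function(g)
    sample(AA1, config$protein_length, replace = TRUE))
  names(seqs) <- genes
  used_pos <- lapply(genes, function(g) integer(0)); names(used_pos) <- genes

  muts <- character(0); mut_gene <- character(0); mut_pos <- integer(0)
  while (length(muts) < config$n_mutations) {
    g <- sample(genes, 1L)
    p <- sample.int(config$protein_length, 1L)
    if (p %in% used_pos[[g]]) next
    wt <- seqs[[g]][p]
    vr <- sample(setdiff(AA1, wt), 1L)
    m <- paste0(wt, p, vr)
    if (m %in% muts) next
    muts <- c(muts, m); mut_gene <- c(mut_gene, g); mut_pos <- c(mut_pos, p)
    used_pos[[g]] <- c(used_pos[[g]], p)
  }
  names(mut_gene) <- muts; names(mut_pos) <- muts

  # decoy mutation-gene pairs; a (1 - violation_rate) fraction is forced to
  # pass the residue check by planting the wild type in the decoy sequence
  decoy <- list()
  for (m in muts) {
    cand <- setdiff(genes, mut_gene[[m]])
    dg <- sample(cand, min(2L, length(cand)))
    for (g in dg) {
      force_pass <- stats::runif(1) > config$seqfilter_violation_rate
      p <- mut_pos[[m]]; wt <- substr(m, 1, 1)
      if (force_pass && !(p %in% used_pos[[g]])) {
        seqs[[g]][p] <- wt
        used_pos[[g]] <- c(used_pos[[g]], p)
      } else if (!force_pass && seqs[[g]][p] == wt && !(p %in% used_pos[[g]])) {
        seqs[[g]][p] <- sample(setdiff(AA1, wt), 1L)
        used_pos[[g]] <- c(used_pos[[g]], p)
      }
      decoy[[length(decoy) + 1L]] <- data.frame(
        mutation = m, gene = g, stringsAsFactors = FALSE)
    }
  }
  decoy <- do.call(rbind, decoy)
  proteins <- vapply(seqs, paste, character(1), collapse = "")
  decoy$passes <- vapply(seq_len(nrow(decoy)), function(i)
    seq_filter(proteins[[decoy$gene[i]]], decoy$mutation[i]), logical(1))

  # mutation-drug truth: ~60% of mutations get 1-3 drugs (mixed 1:1/1:n)
  md <- list()
  for (m in muts) {
    if (stats::runif(1) < 0.6) {
      k <- sample(1:3, 1L, prob = c(0.5, 0.3, 0.2))
      for (d in sample(drugs, k)) {
        md[[length(md) + 1L]] <- data.frame(mutation = m, partner = d,
                                            stringsAsFactors = FALSE)
      }
    }
  }
  mutation_drug <- do.call(rbind, md)
  mutation_drug$partner_kind <- "drug"
  mutation_gene <- data.frame(mutation = muts, partner = unname(mut_gene),
                              partner_kind = "gene", stringsAsFactors = FALSE)
  drug_map <- split(mutation_drug$partner, mutation_drug$mutation)

  pick_tpl <- function(key) TPL[[key]][[sample.int(length(TPL[[key]]), 1L)]]
  base_fill <- function(m = NULL, g = NULL, d = NULL) {
    f <- list(
      "{DIS}" = disease_fill(sample(diseases, 1L)),
      "{CL}" = list(surface = sample(CELL_LINES, 1L), kind = "cell_line",
                    normalized = sample(CELL_LINES, 1L))
    )
    f[["{CL}"]]$normalized <- f[["{CL}"]]$surface
    if (!is.null(m)) f[["{M}"]] <- list(surface = m, kind = "mutation", normalized = m)
    if (!is.null(g)) f[["{G}"]] <- list(surface = g, kind = "gene", normalized = g)
    if (!is.null(d)) f[["{D}"]] <- list(surface = d, kind = "drug", normalized = d)
    f
  }

  docs <- list(); sent_truth <- list()
  for (di in seq_len(config$n_documents)) {
    doc_id <- sprintf("SYN%04d", di)
    doc_muts <- sample(muts, sample(1:2, 1L))
    sents <- list()
    sents[[1]] <- render_template(pick_tpl("intro"),
                                  base_fill(g = mut_gene[[doc_muts[1]]]))
    for (si in 2:config$sentences_per_document) {
      m <- sample(doc_muts, 1L)
      has_drug <- !is.null(drug_map[[m]])
      task <- if (has_drug && stats::runif(1) < 0.5) "drug" else "gene"
      positive <- stats::runif(1) < config$positive_rate
      noisy <- positive && stats::runif(1) < config$template_noise
      if (task == "gene") {
        g <- if (positive) mut_gene[[m]] else
          sample(decoy$gene[decoy$mutation == m], 1L)
        tpl <- pick_tpl(if (!positive) "neg_gene"
                        else if (noisy) "pos_gene_noise" else "pos_gene")
        sents[[si]] <- render_template(tpl, base_fill(m = m, g = g))
        if (positive) {
          sent_truth[[length(sent_truth) + 1L]] <- data.frame(
            mutation = m, partner = g, partner_kind = "gene",
            doc_id = doc_id, sentence_index = si - 1L, stringsAsFactors = FALSE)
        }
      } else {
        d <- if (positive) sample(drug_map[[m]], 1L) else
          sample(setdiff(drugs, drug_map[[m]]), 1L)
        tpl <- pick_tpl(if (!positive) "neg_drug"
                        else if (noisy) "pos_drug_noise" else "pos_drug")
        fill <- base_fill(m = m, g = mut_gene[[m]], d = d)
        sents[[si]] <- render_template(tpl, fill)
        if (positive) {
          sent_truth[[length(sent_truth) + 1L]] <- data.frame(
            mutation = m, partner = d, partner_kind = "drug",
            doc_id = doc_id, sentence_index = si - 1L, stringsAsFactors = FALSE)
          # the template may also realize the (mutation, true gene) pair
          if ("{G}" %in% tpl) {
            sent_truth[[length(sent_truth) + 1L]] <- data.frame(
              mutation = m, partner = mut_gene[[m]], partner_kind = "gene",
              doc_id = doc_id, sentence_index = si - 1L, stringsAsFactors = FALSE)
          }
        }
      }
    }
    docs[[di]] <- assemble_document(doc_id, sents)
  }
  fg <- corpus(docs)
  sent_relations <- unique(do.call(rbind, sent_truth))
  doc_relations <- unique(sent_relations[, c("mutation", "partner",
                                             "partner_kind", "doc_id")])
  rownames(sent_relations) <- NULL; rownames(doc_relations) <- NULL

  # background corpus: true pairs boosted by cooccurrence_boost
  true_pairs <- rbind(
    data.frame(mutation = mutation_gene$mutation, partner = mutation_gene$partner,
               kind = "gene", stringsAsFactors = FALSE),
    data.frame(mutation = mutation_drug$mutation, partner = mutation_drug$partner,
               kind = "drug", stringsAsFactors = FALSE))
  n_rand <- nrow(true_pairs)
  rand_pairs <- data.frame(
    mutation = sample(muts, n_rand, replace = TRUE),
    partner = c(sample(genes, floor(n_rand / 2), replace = TRUE),
                sample(drugs, ceiling(n_rand / 2), replace = TRUE)),
    kind = rep(c("gene", "drug"), c(floor(n_rand / 2), ceiling(n_rand / 2))),
    stringsAsFactors = FALSE)
  is_true <- function(p) {
    tt <- if (p$kind == "gene") mutation_gene else mutation_drug
    any(tt$mutation == p$mutation & tt$partner == p$partner)
  }
  pool <- rbind(true_pairs[rep(seq_len(nrow(true_pairs)),
                               round(config$cooccurrence_boost)), ],
                rand_pairs)
  bg_docs <- list()
  for (bi in seq_len(config$n_background_documents)) {
    n_s <- sample(2:4, 1L)
    rows <- pool[sample.int(nrow(pool), n_s, replace = TRUE), , drop = FALSE]
    sents <- lapply(seq_len(n_s), function(j) {
      p <- rows[j, ]
      fill <- base_fill(m = p$mutation)
      fill[["{P}"]] <- list(surface = p$partner, kind = p$kind,
                            normalized = p$partner)
      with_ctx <- p$kind == "drug" && is_true(p) && stats::runif(1) < 0.5
      if (with_ctx) {
        fill[["{G}"]] <- list(surface = mut_gene[[p$mutation]], kind = "gene",
                              normalized = mut_gene[[p$mutation]])
        render_template(pick_tpl("background_ctx"), fill)
      } else {
        render_template(pick_tpl("background"), fill)
      }
    })
    bg_docs[[bi]] <- assemble_document(sprintf("BG%05d", bi), sents)
  }
  list(
    corpus = fg,
    truth = list(
      mutation_gene = mutation_gene,
      mutation_drug = mutation_drug,
      doc_relations = doc_relations,
      sent_relations = sent_relations,
      proteins = proteins,
      decoy_gene_pairs = decoy
    ),
    background = corpus(bg_docs)
  )
}

#' Summary statistics of a generated corpus
#'
#' @param corp an `mrx_corpus`.
#' @param truth optional ground-truth list from [generate_corpus()].
#' @return list of counts: documents, sentences, mentions per kind, and
#'   (when truth is given) positives at sentence and document level.
#' @export
corpus_statistics <- function(corp, truth = NULL) {
  kinds <- stats::setNames(integer(length(MENTION_KINDS)), MENTION_KINDS)
  n_sent <- 0L
  for (doc in corp) {
    n_sent <- n_sent + nrow(doc$sentences)
    if (nrow(doc$mentions) > 0L) {
      tab <- table(doc$mentions$kind)
      kinds[names(tab)] <- kinds[names(tab)] + as.integer(tab)
    }
  }
  out <- list(documents = length(corp), sentences = n_sent,
              mentions_by_kind = kinds)
  if (!is.null(truth)) {
    out$sentence_level_positives <- nrow(truth$sent_relations)
    out$document_level_positives <- nrow(truth$doc_relations)
  }
  out
}
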