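# Mutation mention normalization, the wild-type residue sequence filter,
# and multi-token entity merging for embedding training.

AA1 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
AA3 <- c("Ala","Arg","Asn","Asp","Cys","Gln","Glu","Gly","His","Ile","Leu","Lys",
         "Met","Phe","Pro","Ser","Thr","Trp","Tyr","Val")
names(AA1) <- toupper(AA3)

#' Normalize a protein substitution mention
#'
#' Recognizes one-letter (`V600E`), three-letter (`Val600Glu`) and
#' `p.`-prefixed (`p.V600E`, `p.Thr790Met`) substitution forms and maps them
#' to the canonical one-letter `XnY` form. DNA-level (`c.1799T>A`) and
#' unrecognized strings are returned unchanged with `parsed = FALSE`.
#' Idempotent on canonical forms.
#'
#' @param surface non-empty mention string.
#' @return list with `canonical` (string) and `parsed` (logical).
#' @export
normalize_mutation <- function(surface) {
  stopifnot(is.character(surface), length(surface) == 1L, nzchar(surface))
  s <- trimws(surface)
  s <- sub("^p\\.", "", s)
  s <- gsub(" ", "", s)          # "T790 M" -> "T790M"
  aa <- paste(AA1, collapse = "")
  m1 <- regmatches(s, regexec(paste0("^([", aa, "])([0-9]+)([", aa, "])$"), s))[[1]]
  if (length(m1) == 4L) {
    return(list(canonical = paste0(m1[2], as.integer(m1[3]), m1[4]), parsed = TRUE))
  }
  m3 <- regmatches(s, regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", s))[[1]]
  if (length(m3) == 4L) {
    wt <- AA1[toupper(m3[2])]; vr <- AA1[toupper(m3[4])]
    if (!is.na(wt) && !is.na(vr)) {
      return(list(canonical = paste0(wt, as.integer(m3[3]), vr), parsed = TRUE))
    }
  }
  list(canonical = surface, parsed = FALSE)
}

#' Parse a canonical mutation string into its components
#'
#' @param canonical a canonical `XnY` string (as produced by
#'   [normalize_mutation()]).
#' @return list with `wild_type`, `position`, `variant`, or `NULL` when the
#'   string is not canonical.
#' @export
parse_mutation <- function(canonical) {
  aa <- paste(AA1, collapse = "")
  m <- regmatches(canonical,
                  regexec(paste0("^([", aa, "])([0-9]+)([", aa, "])$"), canonical))[[1]]
  if (length(m) != 4L) return(NULL)
  list(wild_type = m[2], position = as.integer(m[3]), variant = m[4])
}

#' Wild-type residue check (sequence filter)
#'
#' A mutation `XnY` is compatible with a protein iff residue `n` (1-based)
#' of the sequence exists and equals `X`.
#'
#' @param sequence protein sequence, one-letter amino-acid string.
#' @param mutation canonical mutation string or a list from
#'   [parse_mutation()].
#' @return `TRUE`/`FALSE`; `FALSE` for unparseable mutations.
#' @export
seq_filter <- function(sequence, mutation) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  if (is.character(mutation)) mutation <- parse_mutation(mutation)
  if (is.null(mutation)) return(FALSE)
  pos <- mutation$position
  pos >= 1L && pos <= nchar(sequence) &&
    substr(sequence, pos, pos) == mutation$wild_type
}

#' Read protein records
#'
#' Either a FASTA file (first token of each header taken as the gene
#' symbol; parsed with Biostrings when available, else a minimal fallback)
#' or a two-column tab-separated table `gene_symbol<TAB>sequence`.
#'
#' @param path input file.
#' @param format `"auto"`, `"fasta"` or `"table"`.
#' @return named character vector: gene symbol -> amino-acid sequence.
#' @export
read_proteins <- function(path, format = c("auto", "fasta", "table")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "table"
  }
  if (format == "fasta") {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      ss <- Biostrings::readAAStringSet(path)
      seqs <- as.character(ss)
      names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
      return(seqs)
    }
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    ends <- c(hdr[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    }, character(1))
    names(seqs) <- vapply(strsplit(sub("^>", "", lines[hdr]), "\\s+"),
                          `[`, character(1), 1L)
    return(seqs)
  }
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(tab[[2]], tab[[1]])
}

#' Tokenize text, merging multi-word entities into single tokens
#'
#' Greedy longest-match-first replacement of lexicon phrases by single
#' tokens whose internal spaces become underscores (e.g. "non-small cell
#' lung cancer" -> "non-small_cell_lung_cancer"). Matching is
#' case-insensitive; emitted tokens keep the lexicon casing. Remaining text
#' is whitespace-tokenized.
#'
#' @param text input string.
#' @param lexicon character vector of entity surfaces (may be multi-word).
#' @return character vector of tokens.
#' @export
merge_entity_tokens <- function(text, lexicon = character(0)) {
  toks <- strsplit(trimws(text), "[ \t\r\n]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(lexicon) == 0L || length(toks) == 0L) return(toks)
  lex_toks <- strsplit(lexicon, "[ \t\r\n]+")
  ord <- order(-vapply(lex_toks, length, integer(1)), -nchar(lexicon))
  lex_toks <- lex_toks[ord]; lexicon <- lexicon[ord]
  lex_lower <- lapply(lex_toks, tolower)
  toks_lower <- tolower(toks)
  out <- character(0); i <- 1L
  while (i <= length(toks)) {
    matched <- FALSE
    for (j in seq_along(lexicon)) {
      k <- length(lex_lower[[j]])
      if (i + k - 1L <= length(toks) &&
          identical(toks_lower[i:(i + k - 1L)], lex_lower[[j]])) {
        out <- c(out, gsub("[ \t]+", "_", lexicon[j]))
        i <- i + k; matched <- TRUE; break
      }
    }
    if (!matched) { out <- c(out, toks[i]); i <- i + 1L }
  }
  out
}
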