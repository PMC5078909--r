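#' Literature corpus with a gene-synonym lexicon
#'
#' A `corpus` bundles documents (id + searchable text, where text is the
#' title/abstract concatenation) with a lexicon mapping canonical gene symbols
#' to their synonym strings. The lexicon always contains each gene's own
#' symbol as a synonym.
#'
#' @param doc_id character vector of unique document ids.
#' @param text character vector of document texts.
#' @param lexicon named list: canonical gene symbol -> character vector of
#'   synonyms (may be empty; symbols are case-normalized).
#' @return a `corpus` object.
#' @export
corpus <- function(doc_id, text, lexicon = list()) {
  doc_id <- as.character(doc_id)
  text <- as.character(text)
  stopifnot(length(doc_id) == length(text))
  if (anyDuplicated(doc_id)) stop("duplicate doc_id in corpus", call. = FALSE)
  if (length(lexicon)) {
    names(lexicon) <- normalize_gene(names(lexicon))
    lexicon <- lapply(stats::setNames(names(lexicon), names(lexicon)),
                      function(g) {
                        syn <- unique(c(g, trimws(as.character(lexicon[[g]]))))
                        syn <- syn[nzchar(syn)]
                        syn
                      })
  }
  structure(list(docs = data.frame(doc_id = doc_id, text = text,
                                   stringsAsFactors = FALSE),
                 lexicon = lexicon),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("Corpus: %d documents, lexicon for %d genes\n",
              nrow(x$docs), length(x$lexicon)))
  invisible(x)
}

#' Read a JSONL corpus
#'
#' One JSON object per line with fields `doc_id`, `title`, `abstract`; the
#' searchable text is the title and abstract joined by a space.
#'
#' @param path JSONL file path.
#' @param lexicon optional path to a lexicon TSV (see [read_lexicon()]).
#' @return a `corpus`.
#' @export
read_corpus <- function(path, lexicon = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  get <- function(r, f) if (is.null(r[[f]])) "" else as.character(r[[f]])
  ids <- vapply(recs, get, character(1), "doc_id")
  if (any(!nzchar(ids))) stop("corpus record without doc_id: ", path,
                              call. = FALSE)
  txt <- trimws(paste(vapply(recs, get, character(1), "title"),
                      vapply(recs, get, character(1), "abstract")))
  lex <- if (is.null(lexicon)) list() else read_lexicon(lexicon)
  corpus(ids, txt, lexicon = lex)
}

#' Read a gene-synonym lexicon TSV
#'
#' Two columns: `symbol` and pipe-separated `synonyms` (header required).
#'
#' @param path TSV file path.
#' @return named list mapping canonical symbols to synonym vectors.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("symbol", "synonyms") %in% names(df)))
    stop("lexicon TSV needs columns symbol, synonyms: ", path, call. = FALSE)
  syn <- strsplit(df$synonyms, "|", fixed = TRUE)
  stats::setNames(syn, df$symbol)
}

#' Experimental context as a set of keyword phrases
#'
#' The context encodes the user's hypothesis for the knockout (for example
#' "Immune regulation"). Phrases are whitespace-normalized and must be
#' non-empty; they match documents as whole phrases, not bags of words.
#'
#' @param keywords character vector of keyword phrases.
#' @return a `ko_context` character vector.
#' @export
ko_context <- function(keywords) {
  k <- gsub("\\s+", " ", trimws(as.character(keywords)))
  k <- k[!is.na(k)]
  if (length(k) == 0L || any(!nzchar(k)))
    stop("context requires non-empty keyword phrases", call. = FALSE)
  structure(unique(k), class = "ko_context")
}
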