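#' Preprocess a document collection into term counts
#'
#' Lowercases, tokenizes on non-letter boundaries, removes stopwords,
#' applies Porter-style suffix stemming (so e.g. "run", "running" and
#' "runs" collapse to "run"), and counts terms per document.
#'
#' @param documents character vector of document texts; names become
#'   document ids (`doc1`, `doc2`, ... otherwise).
#' @param stopwords character vector of stopwords, `NULL` for the bundled
#'   English list, or `character(0)` to disable removal.
#' @param stem apply the stemmer (default `TRUE`).
#' @return List of class `termdoc`: `counts` (terms x documents integer
#'   matrix, term rows sorted alphabetically), `vocabulary`, `doc_ids`,
#'   and `empty_docs` (ids of documents with no retained terms; their
#'   all-zero columns are kept).
#' @export
preprocess_corpus <- function(documents, stopwords = NULL, stem = TRUE) {
  doc_ids <- names(documents)
  documents <- as.character(documents)
  if (length(documents) == 0L) stop("empty corpus")
  if (is.null(doc_ids)) doc_ids <- paste0("doc", seq_along(documents))
  if (is.null(stopwords)) stopwords <- default_stopwords()
  token_lists <- lapply(documents, function(txt) {
    toks <- strsplit(tolower(txt), "[^a-z]+")[[1L]]
    toks <- toks[nzchar(toks)]
    toks <- toks[!toks %in% stopwords]
    if (stem) toks <- vapply(toks, porter_stem, character(1), USE.NAMES = FALSE)
    toks
  })
  vocab <- sort(unique(unlist(token_lists)))
  if (length(vocab) == 0L) stop("no terms survive preprocessing")
  counts <- vapply(token_lists, function(toks) {
    tabulate(match(toks, vocab), nbins = length(vocab))
  }, integer(length(vocab)))
  counts <- matrix(counts, nrow = length(vocab),
                   dimnames = list(vocab, doc_ids))
  empty <- doc_ids[colSums(counts) == 0L]
  structure(list(counts = counts, vocabulary = vocab, doc_ids = doc_ids,
                 empty_docs = empty), class = "termdoc")
}

#' Bundled English stopword list
#'
#' @return Character vector of common English function words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "v2pigtm",
                      mustWork = TRUE)
  readLines(path, warn = FALSE)
}

# ---- Porter stemmer -------------------------------------------------------
# Rule-based suffix stripper. Words are reduced via the usual five steps;
# the measure m counts vowel-consonant sequences in the candidate stem.

porter_cv <- function(word) {
  chars <- strsplit(word, "")[[1L]]
  n <- length(chars)
  cv <- character(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    cv[i] <- if (ch %in% c("a", "e", "i", "o", "u")) "V"
    else if (ch == "y" && i > 1L && cv[i - 1L] == "C") "V"
    else "C"
  }
  paste(cv, collapse = "")
}

porter_m <- function(stem) {
  if (!nzchar(stem)) return(0L)
  cv <- gsub("C+", "C", gsub("V+", "V", porter_cv(stem)))
  lengths(regmatches(cv, gregexpr("VC", cv)))
}

has_vowel <- function(stem) grepl("V", porter_cv(stem))

ends_double_cons <- function(stem) {
  n <- nchar(stem)
  n >= 2L && substr(stem, n, n) == substr(stem, n - 1L, n - 1L) &&
    substr(porter_cv(stem), n, n) == "C"
}

# *o: stem ends cvc where the final c is not w, x or y
ends_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  cv <- porter_cv(stem)
  substr(cv, n - 2L, n) == "CVC" &&
    !substr(stem, n, n) %in% c("w", "x", "y")
}

chop <- function(word, k) substr(word, 1L, nchar(word) - k)

porter_stem <- function(word) {
  if (nchar(word) <= 2L) return(word)
  w <- word

  # step 1a
  if (grepl("sses$", w)) w <- chop(w, 2L)
  else if (grepl("ies$", w)) w <- chop(w, 2L)
  else if (!grepl("ss$", w) && grepl("s$", w)) w <- chop(w, 1L)

  # step 1b
  if (grepl("eed$", w)) {
    if (porter_m(chop(w, 3L)) > 0L) w <- chop(w, 1L)
  } else {
    hit <- FALSE
    if (grepl("ed$", w) && has_vowel(chop(w, 2L))) { w <- chop(w, 2L); hit <- TRUE }
    else if (grepl("ing$", w) && has_vowel(chop(w, 3L))) { w <- chop(w, 3L); hit <- TRUE }
    if (hit) {
      if (grepl("(at|bl|iz)$", w)) w <- paste0(w, "e")
      else if (ends_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))
        w <- chop(w, 1L)
      else if (porter_m(w) == 1L && ends_cvc(w)) w <- paste0(w, "e")
    }
  }

  # step 1c
  if (grepl("y$", w) && has_vowel(chop(w, 1L))) w <- paste0(chop(w, 1L), "i")

  # step 2 (m > 0), longest match first within the fixed table
  step2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
             izer = "ize", abli = "able", alli = "al", entli = "ent",
             eli = "e", ousli = "ous", ization = "ize", ation = "ate",
             ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
             ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble")
  w <- porter_replace(w, step2, min_m = 1L)

  # step 3 (m > 0)
  step3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
             ical = "ic", ful = "", ness = "")
  w <- porter_replace(w, step3, min_m = 1L)

  # step 4 (m > 1); "ion" only after s or t
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
             "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er",
             "ic", "ou")
  for (suf in step4) {
    if (grepl(paste0(suf, "$"), w)) {
      stem <- chop(w, nchar(suf))
      ok <- porter_m(stem) > 1L &&
        (suf != "ion" || grepl("[st]$", stem))
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (grepl("e$", w)) {
    stem <- chop(w, 1L)
    m <- porter_m(stem)
    if (m > 1L || (m == 1L && !ends_cvc(stem))) w <- stem
  }
  # step 5b
  if (porter_m(w) > 1L && grepl("ll$", w)) w <- chop(w, 1L)
  w
}

porter_replace <- function(w, table, min_m) {
  sufs <- names(table)[order(-nchar(names(table)))]
  for (suf in sufs) {
    if (grepl(paste0(suf, "$"), w)) {
      stem <- chop(w, nchar(suf))
      if (porter_m(stem) >= min_m) w <- paste0(stem, table[[suf]])
      break
    }
  }
  w
}
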