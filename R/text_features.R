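#' @keywords internal
.token_regex <- "[[:alnum:]]+(?:['-][[:alnum:]]+)*"

.tokenize_string <- function(s) {
  m <- gregexpr(.token_regex, tolower(s), perl = TRUE)
  regmatches(tolower(s), m)[[1]]
}

#' Tokenize a document
#'
#' Lowercases the text, splits sentences on `.`, `!` or `?` followed by
#' whitespace (or end of text), and extracts word tokens on non-alphanumeric
#' boundaries. Hyphens and apostrophes *inside* a word are kept, so
#' `"state-funded"` is one token.
#'
#' @param text a single UTF-8 string; must contain at least one token.
#' @param doc_id optional document identifier carried along.
#' @return list with `doc_id`, `tokens` (lowercase character vector) and
#'   `sentence_ends` (strictly increasing token indices at which sentences
#'   end).
#' @examples
#' tokenize("Sustaining care. Beyond funding!")
#' @export
tokenize <- function(text, doc_id = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("text must be a single string")
  }
  if (!nzchar(trimws(text))) stop("empty or whitespace-only document")
  sentences <- strsplit(text, "[.!?]+(\\s+|$)", perl = TRUE)[[1]]
  tok_by_sent <- lapply(sentences, .tokenize_string)
  tok_by_sent <- tok_by_sent[lengths(tok_by_sent) > 0L]
  if (length(tok_by_sent) == 0L) stop("document contains no word tokens")
  list(doc_id = doc_id,
       tokens = unlist(tok_by_sent, use.names = FALSE),
       sentence_ends = cumsum(lengths(tok_by_sent)))
}

#' Count keyword-category occurrences in a token stream
#'
#' Counts non-overlapping occurrences of a category's terms in a token
#' stream. Matching is case-insensitive exact-token (no stemming); multiword
#' terms must appear as consecutive tokens in order; at any position, longer
#' terms are tried before shorter ones, and a match consumes its tokens
#' (greedy longest-match, so a term inside an already-matched phrase is not
#' double-counted).
#'
#' @param tokens character vector of lowercase tokens (or a [tokenize()]
#'   result).
#' @param terms character vector of terms; a term is one or more lowercase
#'   words separated by spaces.
#' @return integer count.
#' @examples
#' ts <- tokenize("sustaining services beyond funding ends")
#' count_category(ts, c("sustaining", "sustainment", "sustainability",
#'                      "beyond funding"))  # 2
#' @export
count_category <- function(tokens, terms) {
  if (is.list(tokens)) tokens <- tokens$tokens
  n <- length(tokens)
  if (n == 0L || length(terms) == 0L) return(0L)
  term_tok <- lapply(terms, .tokenize_string)
  term_tok <- term_tok[lengths(term_tok) > 0L]
  if (length(term_tok) == 0L) return(0L)
  term_tok <- term_tok[order(lengths(term_tok), decreasing = TRUE)]
  firsts <- vapply(term_tok, `[`, "", 1L)
  cand <- which(tokens %in% firsts)
  count <- 0L
  nexti <- 1L
  for (i in cand) {
    if (i < nexti) next
    for (tt in term_tok) {
      L <- length(tt)
      if (i + L - 1L <= n && all(tokens[i:(i + L - 1L)] == tt)) {
        count <- count + 1L
        nexti <- i + L
        break
      }
    }
  }
  count
}

#' Load the packaged closed-class (function) word list
#'
#' Articles, prepositions and auxiliary verbs used for the stylistic
#' features. The list is shipped as a plain CSV (`word,class`) and can be
#' replaced by the user.
#'
#' @param path optional path to a replacement CSV with columns `word`,
#'   `class` (`article`, `preposition` or `auxiliary`).
#' @return data.frame with columns `word` and `class`.
#' @export
load_function_words <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "function_words.csv", package = "sorsustain")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("word", "class") %in% names(d))) {
    stop("function word file must have columns word, class")
  }
  d$word <- tolower(d$word)
  if (anyDuplicated(d$word)) stop("duplicate words in function word list")
  d
}

#' Stylistic profile of a token stream
#'
#' Raw counts of the stylistic indicators: function words (articles,
#' prepositions, auxiliary verbs, per the packaged list), future-tense
#' markers, long words (more than 6 letters), and mean words per sentence.
#'
#' A future-tense marker is `will`, `shall`, or the bigram `going to`,
#' followed by a further token that is not an article or preposition
#' (auxiliaries such as `be` are allowed as continuation, so passive and
#' progressive futures like "will be sustained" count).
#'
#' @param tokens a [tokenize()] result, or a character vector of tokens (in
#'   which case the whole stream is treated as one sentence).
#' @param function_words data.frame from [load_function_words()].
#' @return list with `function_word_count`, `future_tense_count`,
#'   `long_word_count`, `words_per_sentence`, `token_count`.
#' @export
style_profile <- function(tokens, function_words = load_function_words()) {
  if (is.list(tokens)) {
    sent_ends <- tokens$sentence_ends
    tokens <- tokens$tokens
  } else {
    sent_ends <- length(tokens)
  }
  n <- length(tokens)
  fw_all <- function_words$word
  blockers <- function_words$word[function_words$class %in% c("article", "preposition")]

  fw_count <- sum(tokens %in% fw_all)

  # future markers: will / shall, and the bigram "going to"
  fut <- 0L
  if (n >= 2L) {
    ws <- which(tokens[-n] %in% c("will", "shall"))
    fut <- fut + sum(!(tokens[ws + 1L] %in% blockers))
    if (n >= 3L) {
      gt <- which(tokens[seq_len(n - 2L)] == "going" &
                    tokens[seq(2L, n - 1L)] == "to")
      fut <- fut + sum(!(tokens[gt + 2L] %in% blockers))
    }
  }

  letters_only <- gsub("[^a-z]", "", tokens)
  long_count <- sum(nchar(letters_only) > 6L)

  list(function_word_count = fw_count,
       future_tense_count = as.integer(fut),
       long_word_count = long_count,
       words_per_sentence = n / length(sent_ends),
       token_count = n)
}

#' Load a keyword lexicon
#'
#' Reads a two-column CSV (`category,term`) into a validated lexicon: unique
#' category names, non-empty lowercase terms, no duplicate term within a
#' category. Multiword terms use spaces.
#'
#' @param path CSV path.
#' @return named list (class `keyword_lexicon`) mapping category name to a
#'   character vector of terms, in file order.
#' @export
load_lexicon <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("category", "term") %in% names(d)) || nrow(d) == 0L) {
    stop("lexicon must be a non-empty CSV with columns category, term")
  }
  d$term <- trimws(tolower(d$term))
  if (any(!nzchar(d$term))) stop("empty term in lexicon")
  if (anyDuplicated(d[c("category", "term")])) {
    stop("duplicate (category, term) pair in lexicon")
  }
  lex <- split(d$term, factor(d$category, levels = unique(d$category)))
  structure(as.list(lex), class = "keyword_lexicon")
}

#' The packaged default keyword lexicon
#'
#' Seed terms for the content categories (education, prevention, rescue,
#' intervention, implementation, sustainability) and the eight
#' implementation-strategy categories (evaluation, assistance, adaptation,
#' partnership, education strategies, consumer engagement, financial
#' strategies, infrastructure). The full supplementary keyword lists are not
#' public; users can load their own with [load_lexicon()].
#'
#' @return a `keyword_lexicon`.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "sor_lexicon.csv", package = "sorsustain"))
}

.extract_one <- function(text, doc_id, lexicon, function_words) {
  ts <- tokenize(text, doc_id)
  n <- length(ts$tokens)
  counts <- vapply(lexicon, function(terms) count_category(ts$tokens, terms), 0L)
  sp <- style_profile(ts, function_words)
  list(doc_id = doc_id, token_count = n, category_counts = counts, style = sp)
}

#' Extract the feature vector of one document
#'
#' Per-category keyword counts and the stylistic counts, each divided by the
#' document's token count ("text length"); words-per-sentence is left
#' unnormalized.
#'
#' @param text document text.
#' @param lexicon a `keyword_lexicon`; defaults to the packaged seed lexicon.
#' @param doc_id document identifier.
#' @param function_words see [load_function_words()].
#' @return one-row data.frame: `doc_id`, `token_count`, one `freq_<category>`
#'   column per lexicon category (lexicon order), then
#'   `function_word_freq`, `future_tense_freq`, `long_word_freq`,
#'   `words_per_sentence`.
#' @export
extract_features <- function(text, lexicon = default_lexicon(), doc_id = NA_character_,
                             function_words = load_function_words()) {
  e <- .extract_one(text, doc_id, lexicon, function_words)
  n <- e$token_count
  row <- data.frame(doc_id = doc_id, token_count = n, stringsAsFactors = FALSE)
  for (cat in names(lexicon)) {
    row[[paste0("freq_", cat)]] <- e$category_counts[[cat]] / n
  }
  row$function_word_freq <- e$style$function_word_count / n
  row$future_tense_freq <- e$style$future_tense_count / n
  row$long_word_freq <- e$style$long_word_count / n
  row$words_per_sentence <- e$style$words_per_sentence
  row
}

#' Feature matrix for a corpus
#'
#' @param docs data.frame with columns `doc_id`, `text`.
#' @inheritParams extract_features
#' @param counts if `TRUE`, return raw per-category counts (columns
#'   `count_<category>`) instead of length-normalized frequencies -- the form
#'   the multinomial naive Bayes classifier consumes.
#' @return data.frame, one row per document, deterministic column order
#'   (lexicon order, then style features).
#' @export
corpus_features <- function(docs, lexicon = default_lexicon(), counts = FALSE,
                            function_words = load_function_words()) {
  stopifnot(is.data.frame(docs), all(c("doc_id", "text") %in% names(docs)))
  rows <- lapply(seq_len(nrow(docs)), function(i) {
    e <- .extract_one(docs$text[i], docs$doc_id[i], lexicon, function_words)
    n <- e$token_count
    row <- data.frame(doc_id = docs$doc_id[i], token_count = n,
                      stringsAsFactors = FALSE)
    for (cat in names(lexicon)) {
      val <- e$category_counts[[cat]]
      if (!counts) val <- val / n
      row[[paste0(if (counts) "count_" else "freq_", cat)]] <- val
    }
    if (!counts) {
      row$function_word_freq <- e$style$function_word_count / n
      row$future_tense_freq <- e$style$future_tense_count / n
      row$long_word_freq <- e$style$long_word_count / n
      row$words_per_sentence <- e$style$words_per_sentence
    }
    row
  })
  do.call(rbind, rows)
}

#' Read a corpus from a directory of .txt files or a JSON-lines file
#'
#' A directory corpus uses each file's stem as `doc_id`; a `.jsonl` corpus
#' has one JSON object per line with fields `doc_id` and `text`.
#'
#' @param path directory or `.jsonl` file.
#' @return data.frame with columns `doc_id`, `text`.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0L) stop("no .txt files in corpus directory")
    data.frame(doc_id = sub("\\.txt$", "", basename(files)),
               text = vapply(files, function(f)
                 paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                       collapse = "\n"), ""),
               stringsAsFactors = FALSE, row.names = NULL)
  } else if (grepl("\\.jsonl$", path)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    recs <- lapply(lines[nzchar(lines)], jsonlite::fromJSON)
    data.frame(doc_id = vapply(recs, `[[`, "", "doc_id"),
               text = vapply(recs, `[[`, "", "text"),
               stringsAsFactors = FALSE)
  } else {
    stop("corpus path must be a directory of .txt files or a .jsonl file")
  }
}
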