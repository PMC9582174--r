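#' Load a topic lexicon from YAML
#'
#' The lexicon defines the 14 radiological descriptor topics (six associated
#' with a lower likelihood of malignancy, eight with a higher likelihood),
#' their synonym surface forms, and the high-level main-label taxonomy
#' (nodule, vessel, diaphragm/rib, opacity, other) with its priority order.
#' Invariants are enforced at load time: the two topic sets are disjoint with
#' sizes 6 and 8, and every synonym surface form maps to exactly one topic.
#'
#' @param path path to a lexicon YAML file; see the packaged
#'   `extdata/lexicon.yaml` for the schema.
#' @return an object of class `topic_lexicon`.
#' @export
load_lexicon <- function(path) {
  raw <- yaml::read_yaml(path)
  topics <- names(raw$topics)
  synonyms <- lapply(raw$topics, function(t) as.character(t$synonyms))
  display <- vapply(raw$topics, function(t) as.character(t$display), "")
  lex <- structure(list(
    topics = topics,
    display = stats::setNames(display, topics),
    synonyms = stats::setNames(synonyms, topics),
    set1 = as.character(raw$set1),
    set2 = as.character(raw$set2),
    main_labels = lapply(raw$main_labels, as.character),
    main_label_order = names(raw$main_labels),
    dictionary = as.character(raw$dictionary)
  ), class = "topic_lexicon")
  validate_lexicon(lex)
}

validate_lexicon <- function(lex) {
  if (length(intersect(lex$set1, lex$set2)) > 0L)
    stop("topic sets 1 and 2 must be disjoint", call. = FALSE)
  if (length(lex$set1) != 6L || length(lex$set2) != 8L)
    stop("expected 6 lower-likelihood and 8 higher-likelihood topics",
         call. = FALSE)
  if (!setequal(c(lex$set1, lex$set2), lex$topics))
    stop("set1 and set2 must partition the topic list", call. = FALSE)
  all_syn <- unlist(lex$synonyms, use.names = FALSE)
  if (anyDuplicated(all_syn))
    stop("synonym surface form(s) mapped to more than one topic: ",
         paste(unique(all_syn[duplicated(all_syn)]), collapse = ", "),
         call. = FALSE)
  invisible(lex)
}

#' @export
print.topic_lexicon <- function(x, ...) {
  cat(sprintf("topic lexicon: %d topics (%d lower / %d higher likelihood), %d main labels\n",
              length(x$topics), length(x$set1), length(x$set2),
              length(x$main_label_order)))
  invisible(x)
}

#' Default packaged lexicon, dictionary and stop words
#'
#' `default_lexicon()` loads the lexicon shipped with the package.
#' `default_dictionary()` returns the spell-correction word list derived from
#' it (all single-word synonym forms, main-label keywords and auxiliary CT
#' reporting terms). `default_stopwords()` returns a standard English
#' stop-word list.
#'
#' @param lexicon a `topic_lexicon`.
#' @return see description.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "lexicon.yaml", package = "obsm",
                           mustWork = TRUE))
}

#' @rdname default_lexicon
#' @export
default_dictionary <- function(lexicon = default_lexicon()) {
  words <- c(unlist(lexicon$synonyms, use.names = FALSE),
             unlist(lexicon$main_labels, use.names = FALSE),
             lexicon$dictionary)
  words <- unlist(strsplit(words, " ", fixed = TRUE), use.names = FALSE)
  unique(words[grepl("^[a-z]+$", words)])
}

#' @rdname default_lexicon
#' @export
default_stopwords <- function() {
  c("the", "a", "an", "is", "are", "was", "were", "be", "been", "being",
    "of", "in", "on", "at", "to", "for", "with", "and", "or", "as", "by",
    "that", "this", "these", "those", "it", "its", "there", "here",
    "has", "have", "had", "do", "does", "did", "not", "no", "but", "if",
    "then", "than", "so", "very", "can", "could", "would", "should",
    "may", "might", "i", "we", "my", "our", "you", "your", "he", "she",
    "they", "them", "his", "her", "their", "what", "which", "who", "some",
    "any", "most", "more", "other", "such", "also", "just", "about",
    "into", "over", "under", "again", "further", "too", "s", "t")
}
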