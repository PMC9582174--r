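#' Normalize a free-text annotation into lemmas
#'
#' Implements the annotation text pipeline: lowercase and tokenize, correct
#' spelling against a radiology dictionary (maximum edit distance
#' `max_edit_distance`, default 1), remove stop words, and lemmatize tokens to
#' their dictionary forms. The pipeline is deterministic and idempotent:
#' re-normalizing the joined output returns the same lemma list.
#'
#' Tokens containing digits or comparison signs (e.g. the measurement
#' phrase `"< 5 mm"`) and tokens of one or two characters are never
#' spell-corrected. Unknown tokens with no dictionary word within the edit
#' distance are passed through unchanged.
#'
#' @param text character string (may be empty).
#' @param dictionary word list used for spell correction and lemma
#'   validation; defaults to the packaged radiology dictionary.
#' @param stopwords stop words to remove after correction.
#' @param max_edit_distance maximum Levenshtein distance for spell
#'   correction; candidates at minimal distance win, ties broken by
#'   dictionary order.
#' @return character vector of lemmas (empty for empty text).
#' @export
normalize_text <- function(text, dictionary = default_dictionary(),
                           stopwords = default_stopwords(),
                           max_edit_distance = 1L) {
  tokens <- tokenize_text(text)
  if (length(tokens) == 0L) return(character(0))
  known <- unique(c(dictionary, stopwords))
  tokens <- spell_correct(tokens, known, max_edit_distance)
  tokens <- tokens[!(tokens %in% stopwords)]
  vapply(tokens, lemmatize_token, "", dictionary = dictionary,
         USE.NAMES = FALSE)
}

tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  x <- tolower(text)
  x <- gsub("[/-]", " ", x)
  x <- gsub("([<>])", " \\1 ", x)             # "<5" -> "< 5"
  x <- gsub("([0-9])([a-z])", "\\1 \\2", x)   # "5mm" -> "5 mm"
  x <- gsub("([a-z])([0-9])", "\\1 \\2", x)
  x <- gsub("[^a-z0-9<>]+", " ", x)
  tokens <- strsplit(trimws(x), " +")[[1L]]
  tokens[nzchar(tokens)]
}

spell_correct <- function(tokens, dictionary, max_dist = 1L) {
  fix <- function(tok) {
    if (nchar(tok) <= 2L || grepl("[0-9<>]", tok) || tok %in% dictionary)
      return(tok)
    d <- as.vector(utils::adist(tok, dictionary))
    j <- which.min(d)
    if (d[j] <= max_dist) dictionary[j] else tok
  }
  vapply(tokens, fix, "", USE.NAMES = FALSE)
}

# dictionary-form lemmatization without POS disambiguation: suffix rules
# validated against the dictionary; unknown forms pass through unchanged
lemmatize_token <- function(token, dictionary) {
  if (token %in% dictionary) return(token)
  n <- nchar(token)
  if (n > 4L && endsWith(token, "ies")) {
    cand <- paste0(substr(token, 1L, n - 3L), "y")
    if (cand %in% dictionary) return(cand)
  }
  if (n > 3L && endsWith(token, "es")) {
    cand <- substr(token, 1L, n - 2L)
    if (cand %in% dictionary) return(cand)
  }
  if (n > 2L && endsWith(token, "s") && !endsWith(token, "ss")) {
    cand <- substr(token, 1L, n - 1L)
    if (cand %in% dictionary) return(cand)
  }
  token
}

#' Map normalized lemmas to a topic presence vector and main label
#'
#' Sets `presence[t] = 1` if any lemma, or any multi-word phrase in the
#' joined normalized text, is a synonym of topic `t` (so "tiny" and
#' "< 5 mm" both count as the topic "small"). Phrase synonyms are matched
#' before single tokens. The main label is the first label in the lexicon's
#' priority order (nodule before vessel before diaphragm/rib before opacity
#' before other) whose keyword set intersects the lemmas; with no match the
#' annotation is `"unlabeled"`.
#'
#' @param lemmas character vector from [normalize_text()].
#' @param lexicon a `topic_lexicon`.
#' @return list with `presence` (named 0/1 integer vector over all topics)
#'   and `main_label` (string).
#' @export
map_synonyms <- function(lemmas, lexicon = default_lexicon()) {
  stopifnot(inherits(lexicon, "topic_lexicon"))
  joined <- paste0(" ", paste(lemmas, collapse = " "), " ")
  hit <- function(forms) {
    phrases <- forms[grepl(" ", forms, fixed = TRUE)]
    singles <- forms[!grepl(" ", forms, fixed = TRUE)]
    any(singles %in% lemmas) ||
      any(vapply(phrases, function(p)
        grepl(paste0(" ", p, " "), joined, fixed = TRUE), TRUE))
  }
  presence <- vapply(lexicon$synonyms, function(f) as.integer(hit(f)),
                     integer(1))
  main_label <- "unlabeled"
  for (lab in lexicon$main_label_order) {
    if (hit(lexicon$main_labels[[lab]])) { main_label <- lab; break }
  }
  list(presence = presence, main_label = main_label)
}

#' Lemma frequencies across a set of annotations
#'
#' Counts occurrences of each normalized lemma over all annotation texts;
#' used to surface uncommon words for manual lexicon review.
#'
#' @param annotations data frame with a `text` column (or a character vector
#'   of texts).
#' @param ... passed to [normalize_text()].
#' @return named integer vector of counts, sorted decreasing.
#' @export
word_frequency <- function(annotations, ...) {
  texts <- if (is.data.frame(annotations)) annotations$text else annotations
  stopifnot(is.character(texts) || length(texts) == 0L)
  lemmas <- unlist(lapply(texts, normalize_text, ...), use.names = FALSE)
  if (length(lemmas) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(lemmas)
  sort(stats::setNames(as.integer(tab), names(tab)), decreasing = TRUE)
}

#' @rdname word_frequency
#' @param freq a named count vector from `word_frequency()`.
#' @param max_count words with counts at or below this threshold are
#'   returned for review.
#' @export
uncommon_words <- function(freq, max_count = 2L) {
  names(freq)[freq <= max_count]
}

#' Topic vectors for a table of annotations
#'
#' Runs [normalize_text()] and [map_synonyms()] over every annotation and
#' returns one row per annotation: the 0/1 presence column per topic plus the
#' extracted main label. Annotations with empty text are flagged.
#'
#' @param annotations data frame in the annotation-table dialect (see
#'   [read_annotations()]); must contain `annotation_id` and `text`.
#' @param lexicon a `topic_lexicon`.
#' @param ... passed to [normalize_text()].
#' @return data frame: `annotation_id`, one integer column per topic,
#'   `main_label`, `empty_text`.
#' @export
annotation_topic_vectors <- function(annotations, lexicon = default_lexicon(),
                                     ...) {
  stopifnot(is.data.frame(annotations),
            all(c("annotation_id", "text") %in% names(annotations)))
  dict <- default_dictionary(lexicon)
  rows <- lapply(annotations$text, function(txt) {
    lemmas <- normalize_text(txt, dictionary = dict, ...)
    map_synonyms(lemmas, lexicon)
  })
  pres <- do.call(rbind, lapply(rows, function(r) r$presence))
  out <- data.frame(annotation_id = annotations$annotation_id,
                    pres, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$main_label <- vapply(rows, function(r) r$main_label, "")
  out$empty_text <- !nzchar(trimws(annotations$text))
  out
}

#' Read an annotation table from CSV
#'
#' Expected columns: `case_id, reader_id, image_variant, x_ul, y_ul, width,
#' height, slice_index, text` (UTF-8, RFC 4180). `x_ul`/`y_ul` are the
#' 0-based pixel coordinates of the rectangle's upper-left corner — the first
#' point the reader clicked, and the anchor used for spatial clustering.
#' A missing `annotation_id` column is filled with sequential identifiers.
#'
#' @param path CSV path.
#' @return validated annotation data frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_annotations(df)
}

validate_annotations <- function(df) {
  required <- c("case_id", "reader_id", "image_variant", "x_ul", "y_ul",
                "width", "height", "slice_index", "text")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("annotation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!all(df$image_variant %in% c("original", "saliency")))
    stop("image_variant must be 'original' or 'saliency'", call. = FALSE)
  if (any(df$width <= 0) || any(df$height <= 0))
    stop("rectangle width and height must be positive", call. = FALSE)
  if (any(!is.finite(df$x_ul)) || any(!is.finite(df$y_ul)) ||
      any(df$x_ul < 0) || any(df$y_ul < 0))
    stop("rectangle anchors must be finite and non-negative", call. = FALSE)
  df$text[is.na(df$text)] <- ""
  if (is.null(df$annotation_id))
    df$annotation_id <- sprintf("a%04d", seq_len(nrow(df)))
  if (anyDuplicated(df$annotation_id))
    stop("annotation_id values must be unique", call. = FALSE)
  df
}
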