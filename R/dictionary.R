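# Name dictionaries for genes and GO terms.
#
# A dictionary maps a term identifier (HGNC symbol or GO:NNNNNNN accession)
# to the set of surface names under which the term may appear in abstract
# text. Dictionaries are filtered before scanning: very short names and
# common English words generate false-positive mentions (the GO term for
# associative learning shares its name with an everyday word), so they are
# removed while the term identifier itself is kept, keeping the ID space
# stable even for terms that can no longer match anything.

#' Construct a term dictionary
#'
#' @param kind either `"gene"` or `"go"`.
#' @param entries named list; names are term identifiers, elements are
#'   character vectors of surface names. Surface names are whitespace
#'   normalized; an empty name is an error. An empty name *set* is legal
#'   (the term then matches nothing).
#' @return an object of class `term_dictionary`.
#' @examples
#' term_dictionary("gene", list(TP53 = c("TP53", "tumor protein p53")))
#' @export
term_dictionary <- function(kind = c("gene", "go"), entries = list()) {
  kind <- match.arg(kind)
  if (length(entries) > 0 && is.null(names(entries))) {
    stop_("`entries` must be a named list keyed by term id")
  }
  if (any(!nzchar(names(entries)))) stop_("empty term id in dictionary")
  if (anyDuplicated(names(entries))) {
    stop_("duplicate term ids in dictionary: ",
          paste(unique(names(entries)[duplicated(names(entries))]), collapse = ", "))
  }
  entries <- lapply(entries, function(nm) {
    nm <- squish(as.character(nm))
    if (any(!nzchar(nm))) stop_("empty surface name after whitespace normalization")
    unique(nm)
  })
  structure(list(kind = kind, entries = entries), class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  n_names <- sum(lengths(x$entries))
  cat(sprintf("<term_dictionary> kind=%s, %d terms, %d surface names\n",
              x$kind, length(x$entries), n_names))
  invisible(x)
}

#' Filter a dictionary against a stop-word list and a minimum name length
#'
#' Removes surface names shorter than `min_len` characters or equal
#' (case-insensitively) to a stop word. Term identifiers always survive;
#' a term whose names are all removed keeps an empty name set and is
#' reported via `message()` so downstream users know it can never match.
#'
#' @param dict a [term_dictionary()].
#' @param stopwords character vector of words to exclude (compared after
#'   lower-casing both sides).
#' @param min_len minimum surviving name length in characters (default 3:
#'   one- and two-letter gene symbols are overwhelmingly ambiguous).
#' @return a new, filtered `term_dictionary`; the input is unmodified.
#' @examples
#' d <- term_dictionary("go", list(`GO:0007612` = "learning"))
#' filter_dictionary(d, stopwords = "learning")
#' @export
filter_dictionary <- function(dict, stopwords = character(), min_len = 3L) {
  stopifnot(inherits(dict, "term_dictionary"))
  if (!is_count(min_len) || min_len < 1) stop_("`min_len` must be a count >= 1")
  stopwords <- tolower(as.character(stopwords))
  entries <- lapply(dict$entries, function(nm) {
    nm[nchar(nm) >= min_len & !(tolower(nm) %in% stopwords)]
  })
  emptied <- names(entries)[lengths(entries) == 0 & lengths(dict$entries) > 0]
  if (length(emptied) > 0) {
    message(sprintf("filter_dictionary: %d term(s) retain no surface names: %s",
                    length(emptied),
                    paste(utils::head(emptied, 10), collapse = ", ")))
  }
  term_dictionary(dict$kind, entries)
}

#' Read a dictionary from TSV
#'
#' Expects columns `term_id` and `surface_name`, one name per row. A term
#' appearing on several rows accumulates all its names.
#'
#' @param path file path.
#' @param kind `"gene"` or `"go"`.
#' @return a [term_dictionary()].
#' @export
read_dictionary_tsv <- function(path, kind = c("gene", "go")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("term_id", "surface_name")
  if (!all(need %in% names(df))) {
    stop_(path, ": dictionary TSV must have columns ", paste(need, collapse = ", "))
  }
  term_dictionary(kind, split(df$surface_name, factor(df$term_id, levels = unique(df$term_id))))
}

#' Write a dictionary to TSV
#'
#' @param dict a [term_dictionary()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dictionary_tsv <- function(dict, path) {
  stopifnot(inherits(dict, "term_dictionary"))
  df <- data.frame(
    term_id = rep(names(dict$entries), lengths(dict$entries)),
    surface_name = unlist(dict$entries, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled English stop-word list
#'
#' A few hundred common English words shipped as a plain-text fixture for
#' dictionary filtering. Any user-supplied list can be used instead.
#'
#' @return character vector of lower-case words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_english.txt", package = "litgonet",
                      mustWork = TRUE)
  words <- readLines(path, warn = FALSE)
  words <- tolower(squish(words))
  words[nzchar(words) & !startsWith(words, "#")]
}
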