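# Abstract scanning.
#
# Matching rule: text and surface names are lower-cased and split on
# non-alphanumeric characters; a term is present iff one of its surface
# names occurs as a consecutive token sequence. The rule is deterministic
# and whole-token, so "BRCA1" never fires inside "BRCA12", and multi-word
# names ("tumor protein p53") must appear as adjacent tokens.

tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# Delimiter-join a token vector so that fixed-string search on the joined
# haystack is equivalent to consecutive-subsequence search on tokens.
.tok_key <- function(tokens) {
  paste0("", paste(tokens, collapse = ""), "")
}

.match_terms <- function(haystack, dict) {
  hit <- vapply(dict$entries, function(nms) {
    if (length(nms) == 0) return(FALSE)
    keys <- vapply(nms, function(nm) .tok_key(tokenize(nm)), character(1))
    keys <- keys[keys != ""]
    any(vapply(keys, function(k) grepl(k, haystack, fixed = TRUE), logical(1)))
  }, logical(1))
  names(dict$entries)[hit]
}

#' Scan one abstract for gene and GO term mentions
#'
#' @param text abstract text (a single string).
#' @param gene_dict filtered gene [term_dictionary()].
#' @param go_dict filtered GO [term_dictionary()].
#' @param abstract_id identifier to store on the resulting record.
#' @return an [abstract_record()] with the matched gene and GO term ids
#'   (each term reported at most once).
#' @examples
#' gd <- term_dictionary("gene", list(BRCA1 = "BRCA1"))
#' td <- term_dictionary("go", list(`GO:0006915` = "apoptosis"))
#' scan_abstract("BRCA1 regulates apoptosis", gd, td, abstract_id = "A1")
#' @export
scan_abstract <- function(text, gene_dict, go_dict, abstract_id = "A1") {
  stopifnot(inherits(gene_dict, "term_dictionary"),
            inherits(go_dict, "term_dictionary"))
  haystack <- .tok_key(tokenize(text))
  abstract_record(
    abstract_id = abstract_id,
    genes = .match_terms(haystack, gene_dict),
    gos = .match_terms(haystack, go_dict)
  )
}

#' Scan a corpus of abstract texts
#'
#' @param texts named character vector; names are abstract identifiers.
#' @inheritParams scan_abstract
#' @return list of [abstract_record()]s, one per input text.
#' @export
scan_corpus <- function(texts, gene_dict, go_dict) {
  if (is.null(names(texts)) || any(!nzchar(names(texts)))) {
    stop_("`texts` must be a named character vector (names are abstract ids)")
  }
  mapply(function(txt, id) scan_abstract(txt, gene_dict, go_dict, abstract_id = id),
         texts, names(texts), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
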