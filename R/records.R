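# Abstract mention records: the unit of co-occurrence is one abstract,
# reduced to the set of gene ids and GO ids it mentions.

#' Construct an abstract mention record
#'
#' @param abstract_id abstract identifier (non-empty string).
#' @param genes character vector of gene term ids mentioned (de-duplicated).
#' @param gos character vector of GO term ids mentioned (de-duplicated).
#' @return an object of class `abstract_record`.
#' @export
abstract_record <- function(abstract_id, genes = character(), gos = character()) {
  if (!is.character(abstract_id) || length(abstract_id) != 1L || !nzchar(abstract_id)) {
    stop_("`abstract_id` must be a non-empty string")
  }
  structure(
    list(
      abstract_id = abstract_id,
      genes = sort(unique(as.character(genes))),
      gos = sort(unique(as.character(gos)))
    ),
    class = "abstract_record"
  )
}

#' @export
print.abstract_record <- function(x, ...) {
  cat(sprintf("<abstract_record> %s: %d gene(s), %d GO term(s)\n",
              x$abstract_id, length(x$genes), length(x$gos)))
  invisible(x)
}

#' Read mention records from TSV
#'
#' Pre-scanned mode: the pipeline accepts already-extracted mention events
#' and skips text scanning. Expected columns: `abstract_id`, `term_kind`
#' (`gene` or `go`), `term_id`. Abstracts with rows in the file but no
#' valid mentions are impossible by construction; abstracts absent from
#' the file simply contribute nothing.
#'
#' @param path file path.
#' @return list of [abstract_record()]s in order of first appearance.
#' @export
read_mentions_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("abstract_id", "term_kind", "term_id")
  if (!all(need %in% names(df))) {
    stop_(path, ": mention TSV must have columns ", paste(need, collapse = ", "))
  }
  bad <- which(!df$term_kind %in% c("gene", "go"))
  if (length(bad) > 0) {
    stop_(path, ": invalid term_kind at data line(s) ",
          paste(utils::head(bad, 5), collapse = ", "),
          " (must be 'gene' or 'go')")
  }
  ids <- unique(df$abstract_id)
  by_abs <- split(df[c("term_kind", "term_id")],
                  factor(df$abstract_id, levels = ids))
  lapply(ids, function(id) {
    sub <- by_abs[[id]]
    abstract_record(
      abstract_id = id,
      genes = sub$term_id[sub$term_kind == "gene"],
      gos = sub$term_id[sub$term_kind == "go"]
    )
  })
}

#' Write mention records to TSV
#'
#' @param records list of [abstract_record()]s.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mentions_tsv <- function(records, path) {
  rows <- lapply(records, function(r) {
    stopifnot(inherits(r, "abstract_record"))
    kinds <- c(rep("gene", length(r$genes)), rep("go", length(r$gos)))
    if (length(kinds) == 0) return(NULL)
    data.frame(abstract_id = r$abstract_id, term_kind = kinds,
               term_id = c(r$genes, r$gos), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(
    data.frame(abstract_id = character(), term_kind = character(),
               term_id = character(), stringsAsFactors = FALSE))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
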