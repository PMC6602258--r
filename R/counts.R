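# Co-occurrence tallies: the margins of the hypergeometric test.
#
# For gene i and GO term j, n_i. is the number of abstracts mentioning i,
# n_.j the number mentioning j, n_ij the number mentioning both, and
# n_total the number of abstracts mentioning at least one gene or GO term.
# Gene-gene joint counts are tallied as well: they feed the co-occurrence
# baseline similarity used for method comparison.

#' Tally co-occurrence counts from mention records
#'
#' @param records list of [abstract_record()]s with unique abstract ids.
#' @return an object of class `cooccurrence_counts` with fields
#'   `n_total` (abstracts with at least one mention), `n_gene` and `n_go`
#'   (named integer margins), `joint` (data frame `gene`, `go`, `n` for
#'   pairs with `n >= 1`), and `joint_gene` (data frame `gene_a`,
#'   `gene_b`, `n` with `gene_a < gene_b`).
#' @examples
#' recs <- list(
#'   abstract_record("A1", genes = "g1", gos = "t1"),
#'   abstract_record("A2", genes = "g1"),
#'   abstract_record("A3", gos = "t1")
#' )
#' tally_counts(recs)
#' @export
tally_counts <- function(records) {
  ids <- vapply(records, function(r) {
    stopifnot(inherits(r, "abstract_record"))
    r$abstract_id
  }, character(1))
  if (anyDuplicated(ids)) {
    stop_("duplicate abstract_id: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  gene_long <- data.frame(
    abstract = rep(ids, vapply(records, function(r) length(r$genes), integer(1))),
    gene = unlist(lapply(records, `[[`, "genes")) %||% character(),
    stringsAsFactors = FALSE
  )
  go_long <- data.frame(
    abstract = rep(ids, vapply(records, function(r) length(r$gos), integer(1))),
    go = unlist(lapply(records, `[[`, "gos")) %||% character(),
    stringsAsFactors = FALSE
  )

  n_total <- length(unique(c(gene_long$abstract, go_long$abstract)))

  tab_named <- function(x) {
    if (length(x) == 0) return(integer(0))
    tab <- table(x)
    stats::setNames(as.integer(tab), names(tab))
  }
  n_gene <- tab_named(gene_long$gene)
  n_go <- tab_named(go_long$go)

  joint <- if (nrow(gene_long) > 0 && nrow(go_long) > 0) {
    m <- merge(gene_long, go_long, by = "abstract")
    agg <- stats::aggregate(list(n = m$abstract), by = list(gene = m$gene, go = m$go), FUN = length)
    agg[order(agg$gene, agg$go), , drop = FALSE]
  } else {
    data.frame(gene = character(), go = character(), n = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(joint) <- NULL
  joint$n <- as.integer(joint$n)

  joint_gene <- if (nrow(gene_long) > 0) {
    m <- merge(gene_long, gene_long, by = "abstract")
    m <- m[m$gene.x < m$gene.y, , drop = FALSE]
    if (nrow(m) > 0) {
      agg <- stats::aggregate(list(n = m$abstract),
                              by = list(gene_a = m$gene.x, gene_b = m$gene.y),
                              FUN = length)
      agg[order(agg$gene_a, agg$gene_b), , drop = FALSE]
    } else {
      NULL
    }
  } else {
    NULL
  }
  if (is.null(joint_gene)) {
    joint_gene <- data.frame(gene_a = character(), gene_b = character(),
                             n = integer(), stringsAsFactors = FALSE)
  }
  rownames(joint_gene) <- NULL
  joint_gene$n <- as.integer(joint_gene$n)

  structure(
    list(n_total = n_total, n_gene = n_gene, n_go = n_go,
         joint = joint, joint_gene = joint_gene),
    class = "cooccurrence_counts"
  )
}

#' @export
print.cooccurrence_counts <- function(x, ...) {
  cat(sprintf(
    "<cooccurrence_counts> %d abstracts with mentions; %d genes, %d GO terms, %d gene-GO pairs, %d gene-gene pairs\n",
    x$n_total, length(x$n_gene), length(x$n_go), nrow(x$joint), nrow(x$joint_gene)))
  invisible(x)
}

#' Write co-occurrence counts to a directory
#'
#' Serializes as four TSVs (`gene_margins.tsv`, `go_margins.tsv`,
#' `joint_gene_go.tsv`, `joint_gene_gene.tsv`) plus `header.json`
#' recording the any-mention abstract total.
#'
#' @param counts a [tally_counts()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(counts, dir) {
  stopifnot(inherits(counts, "cooccurrence_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(data.frame(gene = names(counts$n_gene), n = unname(counts$n_gene)),
     "gene_margins.tsv")
  wt(data.frame(go = names(counts$n_go), n = unname(counts$n_go)),
     "go_margins.tsv")
  wt(counts$joint, "joint_gene_go.tsv")
  wt(counts$joint_gene, "joint_gene_gene.tsv")
  jsonlite::write_json(list(n_total = counts$n_total),
                       file.path(dir, "header.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read co-occurrence counts written by [write_counts()]
#'
#' @param dir directory containing the serialized counts.
#' @return a `cooccurrence_counts` object.
#' @export
read_counts <- function(dir) {
  rd <- function(f, classes) {
    utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE,
                      colClasses = classes)
  }
  gm <- rd("gene_margins.tsv", c("character", "integer"))
  om <- rd("go_margins.tsv", c("character", "integer"))
  joint <- rd("joint_gene_go.tsv", c("character", "character", "integer"))
  joint_gene <- rd("joint_gene_gene.tsv", c("character", "character", "integer"))
  header <- jsonlite::read_json(file.path(dir, "header.json"))
  structure(
    list(
      n_total = as.integer(header$n_total),
      n_gene = stats::setNames(gm$n, gm$gene),
      n_go = stats::setNames(om$n, om$go),
      joint = joint,
      joint_gene = joint_gene
    ),
    class = "cooccurrence_counts"
  )
}
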